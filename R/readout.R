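# decode-side pipeline: demultiplexing, consensus, metrics, orchestration

# locate a primer (global) inside reads (local): exact match fast path,
# semi-global alignment fallback for reads carrying errors in the primer
locate_primer <- function(reads, primer, scoring) {
  n <- length(reads)
  start <- rep(NA_integer_, n)
  end <- rep(NA_integer_, n)
  score <- rep(-Inf, n)
  hit <- regexpr(primer, reads, fixed = TRUE)
  exact <- hit != -1L
  start[exact] <- hit[exact]
  end[exact] <- hit[exact] + nchar(primer) - 1L
  score[exact] <- nchar(primer) * scoring$match
  rest <- which(!exact)
  if (length(rest)) {
    al <- semi_global_hits(primer, reads[rest], scoring)
    start[rest] <- al$start
    end[rest] <- al$end
    score[rest] <- al$score
  }
  data.frame(start = start, end = end, score = score)
}

#' Demultiplex reads by primer location and index parsing
#'
#' A read is assigned to an index iff both flanking primers are located
#' with alignment score at or above the acceptance threshold and the bases
#' in the index window (immediately after the 5' primer) parse to an index
#' within the manifest's strand count; otherwise it is unassigned. Every
#' input read lands in exactly one bin or in the unassigned set.
#'
#' @param reads A `read_set` (or data.frame with `sequence`).
#' @param manifest An `archive_manifest` (or any list with `layout`,
#'   `primers` and optionally `n_data` + `n_parity`).
#' @param scoring An [alignment_scoring()].
#' @return An object of class `demux_result`: `assignments` (data.frame
#'   `read`, `index`, `score5`, `score3`), `unassigned` (row numbers),
#'   `n_indices`.
#' @export
demux <- function(reads, manifest, scoring = alignment_scoring()) {
  layout <- manifest$layout
  primers <- manifest$primers
  map <- bit_base_map(manifest$map_bases %||% c("A", "C", "G", "T"))
  n_idx <- if (!is.null(manifest$n_data))
    manifest$n_data + manifest$n_parity else 4^layout$index_len
  seqs <- reads$sequence
  thr5 <- scoring$threshold * nchar(primers[1L]) * scoring$match
  thr3 <- scoring$threshold * nchar(primers[2L]) * scoring$match

  p5 <- locate_primer(seqs, primers[1L], scoring)
  p3 <- locate_primer(seqs, primers[2L], scoring)
  ok <- p5$score >= thr5 & p3$score >= thr3 & p3$start > p5$end
  idx <- rep(NA_integer_, length(seqs))
  cand <- which(ok)
  if (length(cand)) {
    win <- substr(seqs[cand], p5$end[cand] + 1L,
                  p5$end[cand] + layout$index_len)
    parsed <- vapply(win, function(w)
      if (nchar(w) == layout$index_len) bases_to_int(w, map) else NA_integer_,
      integer(1L), USE.NAMES = FALSE)
    parsed[!is.na(parsed) & parsed >= n_idx] <- NA_integer_
    idx[cand] <- parsed
  }
  assigned <- which(!is.na(idx))
  structure(list(
    assignments = data.frame(read = assigned, index = idx[assigned],
                             score5 = p5$score[assigned],
                             score3 = p3$score[assigned]),
    unassigned = which(is.na(idx)),
    n_reads = length(seqs), n_indices = n_idx), class = "demux_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("demux: %d/%d reads assigned to %d possible indices\n",
              nrow(x$assignments), x$n_reads, x$n_indices))
  invisible(x)
}

#' Per-position plurality consensus
#'
#' Among the reads whose length equals the expected strand length, takes
#' the plurality base at each position (ties broken in fixed order
#' A < C < G < T). Reads of any other length (indel survivors) are
#' excluded from the positional vote; with no length-conforming read the
#' result is the missing marker `NA`.
#'
#' @param sequences Character vector of read sequences for one index.
#' @param expected_length The designed strand length.
#' @return Consensus base string, or `NA_character_` when missing.
#' @export
consensus <- function(sequences, expected_length) {
  sequences <- sequences[!is.na(sequences) &
                           nchar(sequences) == expected_length]
  if (!length(sequences)) return(NA_character_)
  if (length(sequences) == 1L) return(sequences)
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(sequences),
                                    baseOnly = TRUE)
  picks <- apply(cm[c("A", "C", "G", "T"), , drop = FALSE], 2L, which.max)
  paste(c("A", "C", "G", "T")[picks], collapse = "")
}

#' Per-index depth and perfect-match statistics
#'
#' Depth is the demultiplexed bin size; a perfect match is a read exactly
#' equal to its designed full-strand sequence (the strict reading of
#' per-index perfect matching; set `payload_only = TRUE` to compare the
#' payload region only).
#'
#' @param dm A [demux()] result.
#' @param reads The read set that was demultiplexed.
#' @param designed Data frame of designed strands (`index`, `sequence`).
#' @param manifest The archive manifest (used for the payload window when
#'   `payload_only`).
#' @param payload_only Compare only the payload region instead of the full
#'   strand.
#' @return Data frame (`index`, `depth`, `perfect`, `ratio`) with
#'   attributes `median_depth` and `perfect_pct` (overall percentage of
#'   perfect reads among assigned reads).
#' @export
perfect_match_stats <- function(dm, reads, designed, manifest = NULL,
                                payload_only = FALSE) {
  stopifnot(inherits(dm, "demux_result"))
  if (!all(dm$assignments$index %in% designed$index))
    stop("report error: demultiplexed index missing from the designed strands")
  window <- function(s) {
    if (!payload_only) return(s)
    layout <- manifest$layout
    p0 <- layout$primer5_len + layout$index_len
    substr(s, p0 + 1L, p0 + layout$payload_len)
  }
  ref <- setNames(vapply(designed$sequence, window, character(1L)),
                  as.character(designed$index))
  out <- do.call(rbind, lapply(designed$index, function(ix) {
    rows <- dm$assignments$read[dm$assignments$index == ix]
    depth <- length(rows)
    perfect <- if (depth)
      sum(window(reads$sequence[rows]) == ref[[as.character(ix)]]) else 0L
    data.frame(index = ix, depth = depth, perfect = perfect,
               ratio = if (depth) perfect / depth else NA_real_)
  }))
  rownames(out) <- NULL
  attr(out, "median_depth") <- stats::median(out$depth)
  attr(out, "perfect_pct") <- 100 * sum(out$perfect) / max(1L, sum(out$depth))
  out
}

#' Full decode pipeline: reads to payload
#'
#' Demultiplexes, builds a per-index consensus, Reed-Solomon-decodes every
#' strand, repairs single losses per XOR group, reassembles the byte
#' stream and deserializes it according to the manifest's content profile.
#' For mesh content, coordinates overlapping unrecoverable byte ranges are
#' additionally repaired with the modified-IQR rule.
#'
#' @param reads A `read_set`.
#' @param manifest The `archive_manifest` from [encode_archive()].
#' @param policy An [outlier_policy()] for mesh coordinate repair.
#' @param scoring An [alignment_scoring()] for demultiplexing.
#' @return List with `payload` (bytes, or a [mesh_3d()] / [pixel_image()]
#'   per the manifest content profile), `bytes` (always the raw byte
#'   stream), `report` (per-index status), `index_stats` (depth per index),
#'   `lost_ranges`, and `repaired` (IQR repair bookkeeping, mesh only).
#' @export
decode_pipeline <- function(reads, manifest, policy = outlier_policy(),
                            scoring = alignment_scoring()) {
  if (!inherits(manifest, "archive_manifest"))
    stop("configuration error: manifest is not an archive_manifest")
  layout <- manifest$layout
  n_total <- manifest$n_data + manifest$n_parity
  dm <- demux(reads, manifest, scoring)
  cons <- rep(NA_character_, n_total)
  depth <- integer(n_total)
  for (ix in seq_len(n_total) - 1L) {
    rows <- dm$assignments$read[dm$assignments$index == ix]
    depth[ix + 1L] <- length(rows)
    if (length(rows))
      cons[ix + 1L] <- consensus(reads$sequence[rows], layout$total)
  }
  dec <- decode_archive(cons, manifest)

  payload <- dec$payload
  repaired <- NULL
  if (identical(manifest$content, "mesh")) {
    mesh <- deserialize_mesh(dec$payload)
    if (nrow(dec$lost_ranges) && nrow(mesh$vertices) >= 4L) {
      nv <- nrow(mesh$vertices)
      # byte span of coordinate (vertex v, axis a): header 5 + 6(v-1) + 2(a-1)
      flags <- matrix(FALSE, nrow = nv, ncol = 3L)
      for (r in seq_len(nrow(dec$lost_ranges))) {
        span <- dec$lost_ranges$from[r]:dec$lost_ranges$to[r]
        coord <- span[span > 5L & span <= 5L + 6L * nv] - 6L
        if (!length(coord)) next
        v <- coord %/% 6L + 1L
        a <- (coord %% 6L) %/% 2L + 1L
        flags[cbind(v, a)] <- TRUE
      }
      rep_log <- list()
      for (a in 1:3) {
        adj <- adjust_outliers_iqr(mesh$vertices[, a], flags[, a], policy)
        mesh$vertices[, a] <- adj$values
        rep_log[[a]] <- adj
      }
      repaired <- rep_log
    }
    payload <- mesh
  } else if (identical(manifest$content, "image")) {
    payload <- do.call(deserialize_image_bytes,
                       c(list(dec$payload), manifest$content_meta))
  }

  dec$report$depth <- depth
  list(payload = payload, bytes = dec$payload, report = dec$report,
       demux = dm, lost_ranges = dec$lost_ranges, repaired = repaired)
}

# byte-stream image profile used when images ride the 150-nt archive layout
serialize_image_bytes <- function(image) {
  px <- as.integer(t(image$grid))
  bits <- as.integer(bitwAnd(bitwShiftR(rep(px, each = image$bits),
                                        rep((image$bits - 1L):0L, length(px))),
                             1L))
  pad <- (8L - length(bits) %% 8L) %% 8L
  c(image$width, image$height, image$bits,
    bits_to_bytes(c(bits, integer(pad))))
}

deserialize_image_bytes <- function(bytes, ...) {
  w <- bytes[1L]; h <- bytes[2L]; b <- bytes[3L]
  bits <- bytes_to_bits(bytes[-(1:3)])[seq_len(w * h * b)]
  px <- as.integer(colSums(matrix(bits, nrow = b) * 2L^((b - 1L):0L)))
  pixel_image(matrix(px, nrow = h, byrow = TRUE), b)
}
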