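#' Encode a byte stream as an indexed, RS- and XOR-protected strand archive
#'
#' The payload is split into fixed-size fragments of `rs$k` bytes (the last
#' fragment zero-padded, pad count recorded). Each fragment becomes one data
#' strand: `primer5 + index + RS(payload) + primer3`. Every group of up to
#' `g` data strands gains one XOR parity strand whose payload is the
#' bytewise exclusive-or of the group, so any single lost strand per group
#' is recoverable.
#'
#' @param payload Integer vector of bytes (0-255) or a raw vector.
#' @param layout A [strand_layout()] with an RS spec over GF(256)
#'   (default [archive_layout()]).
#' @param g XOR group size (data strands per parity strand).
#' @param primers Character vector `c(primer5, primer3)`.
#' @param content Content profile recorded in the manifest
#'   (`"bytes"`, `"mesh"` or `"image"`) plus optional `content_meta`.
#' @param content_meta Named list serialized into the manifest (e.g. mesh
#'   precision).
#' @param map A [bit_base_map()].
#' @return List with `strands` (a data.frame: `index`, `role`, `group`,
#'   `payload` list-column of byte vectors, `sequence`) and `manifest`
#'   (class `archive_manifest`).
#' @export
encode_archive <- function(payload, layout = archive_layout(), g = 8L,
                           primers = default_primers(layout),
                           content = "bytes", content_meta = list(),
                           map = bit_base_map()) {
  if (is.raw(payload)) payload <- as.integer(payload)
  if (!length(payload)) stop("payload must be non-empty")
  if (any(payload < 0L | payload > 255L)) stop("payload bytes must be 0-255")
  rs <- layout$rs
  if (is.null(rs) || rs$field$m != 8L)
    stop("archive layout requires an RS spec over GF(256)")
  g <- as.integer(g)
  if (g < 1L) stop("g must be >= 1")

  kb <- rs$k                                  # data bytes per strand
  n_data <- as.integer(ceiling(length(payload) / kb))
  pad <- as.integer(n_data * kb - length(payload))
  padded <- c(as.integer(payload), integer(pad))
  n_groups <- as.integer(ceiling(n_data / g))
  n_total <- n_data + n_groups
  if (n_total > 4^layout$index_len)
    stop(sprintf("capacity error: %d strands exceed the %g-address index space",
                 n_total, 4^layout$index_len))

  frag <- split(padded, rep(seq_len(n_data), each = kb))
  group_of_data <- rep(seq_len(n_groups), each = g)[seq_len(n_data)]
  parity <- lapply(seq_len(n_groups), function(j)
    xor_parity(frag[group_of_data == j]))

  all_payloads <- c(frag, parity)
  roles <- c(rep("data", n_data), rep("parity", n_groups))
  groups <- c(group_of_data, seq_len(n_groups))
  idx <- seq_len(n_total) - 1L

  seqs <- vapply(seq_len(n_total), function(i) {
    cw <- rs_encode(all_payloads[[i]], rs)
    paste0(primers[1L],
           int_to_bases(idx[i], layout$index_len, map),
           bits_to_bases(bytes_to_bits(cw), map)$bases,
           primers[2L])
  }, character(1L))

  strands <- data.frame(index = idx, role = roles, group = groups,
                        sequence = seqs, stringsAsFactors = FALSE)
  strands$payload <- unname(all_payloads)

  manifest <- structure(list(
    layout = layout, g = g, n_data = n_data, n_parity = n_groups,
    pad = pad, source_len = length(payload),
    primers = primers, content = content, content_meta = content_meta,
    group_of_index = c(group_of_data, seq_len(n_groups)),
    map_bases = map$bases), class = "archive_manifest")
  list(strands = strands, manifest = manifest)
}

#' @export
print.archive_manifest <- function(x, ...) {
  cat(sprintf(
    "archive manifest: %d data + %d parity strands (g = %d), %d source bytes (%s)\n",
    x$n_data, x$n_parity, x$g, x$source_len, x$content))
  print(x$layout)
  invisible(x)
}

# decode one consensus sequence to its k payload bytes (or NULL)
decode_strand_payload <- function(sequence, manifest) {
  layout <- manifest$layout
  map <- bit_base_map(manifest$map_bases)
  if (is.na(sequence) || nchar(sequence) != layout$total) return(NULL)
  p0 <- layout$primer5_len + layout$index_len
  payload_nt <- substr(sequence, p0 + 1L, p0 + layout$payload_len)
  if (grepl("[^ACGT]", payload_nt)) return(NULL)
  syms <- bits_to_bytes(bases_to_bits(payload_nt, map))
  dec <- rs_decode(syms, layout$rs)
  if (!dec$ok) return(NULL)
  list(payload = dec$data, corrections = dec$corrections)
}

#' Decode an archive from per-index consensus sequences
#'
#' Each consensus strand is Reed-Solomon decoded (with re-encode
#' verification); a group with exactly one missing or undecodable strand is
#' repaired through its XOR parity; groups with two or more losses have
#' their data regions marked lost and filled with the zero-byte sentinel.
#'
#' @param consensus_by_index Character vector of consensus sequences,
#'   position `i` holding index `i - 1`; `NA` marks a missing index.
#' @param manifest The `archive_manifest` from [encode_archive()].
#' @return List with `payload` (integer bytes, original length), `report`
#'   (data.frame: `index`, `role`, `status` in
#'   recovered/xor_recovered/lost, `corrections`) and `lost_ranges`
#'   (data.frame of 1-based byte ranges of the source stream that were
#'   unrecoverable).
#' @export
decode_archive <- function(consensus_by_index, manifest) {
  stopifnot(inherits(manifest, "archive_manifest"))
  layout <- manifest$layout
  n_total <- manifest$n_data + manifest$n_parity
  kb <- layout$rs$k
  if (length(consensus_by_index) < n_total)
    consensus_by_index <- c(consensus_by_index,
                            rep(NA_character_,
                                n_total - length(consensus_by_index)))

  payloads <- vector("list", n_total)
  corrections <- rep(NA_integer_, n_total)
  for (i in seq_len(n_total)) {
    d <- decode_strand_payload(consensus_by_index[i], manifest)
    if (!is.null(d)) {
      payloads[[i]] <- d$payload
      corrections[i] <- d$corrections
    }
  }

  status <- ifelse(vapply(payloads, is.null, logical(1L)), "lost", "recovered")
  for (grp in seq_len(manifest$n_parity)) {
    members <- which(manifest$group_of_index == grp)
    missing <- members[status[members] == "lost"]
    if (length(missing) == 1L) {
      present <- payloads[setdiff(members, missing)]
      payloads[[missing]] <- xor_recover(present[-length(present)],
                                         present[[length(present)]])
      status[missing] <- "xor_recovered"
    }
  }

  data_idx <- seq_len(manifest$n_data)
  lost <- data_idx[status[data_idx] == "lost"]
  for (i in lost) payloads[[i]] <- integer(kb)   # zero-byte sentinel
  bytes <- unlist(payloads[data_idx], use.names = FALSE)
  bytes <- bytes[seq_len(manifest$source_len)]

  lost_ranges <- if (length(lost)) {
    data.frame(from = (lost - 1L) * kb + 1L,
               to = pmin(lost * kb, manifest$source_len))
  } else data.frame(from = integer(0), to = integer(0))

  roles <- c(rep("data", manifest$n_data), rep("parity", manifest$n_parity))
  list(payload = bytes,
       report = data.frame(index = seq_len(n_total) - 1L, role = roles,
                           status = status, corrections = corrections,
                           stringsAsFactors = FALSE),
       lost_ranges = lost_ranges)
}
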