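# file formats: FASTQ, designed-strand FASTA, JSON manifest

#' Read and write 4-line FASTQ (Phred+33)
#'
#' The reader validates record structure and reports malformed records with
#' their line number; the writer emits records in the same 4-line form so
#' that write-then-read is the identity on conforming files.
#'
#' @param path File path.
#' @param reads Data frame with `id`, `sequence` and optionally `quality`.
#' @return `read_fastq`: a `read_set` data.frame (`id`, `sequence`,
#'   `quality`).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("FASTQ parse error at line %d: truncated record",
                 (length(lines) %/% 4L) * 4L + 1L))
  n <- length(lines) %/% 4L
  out <- data.frame(id = character(n), sequence = character(n),
                    quality = character(n), stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    l <- 4L * (r - 1L)
    if (!startsWith(lines[l + 1L], "@"))
      stop(sprintf("FASTQ parse error at line %d: header must start with @",
                   l + 1L))
    if (!identical(lines[l + 3L], "+") && !startsWith(lines[l + 3L], "+"))
      stop(sprintf("FASTQ parse error at line %d: separator must start with +",
                   l + 3L))
    if (nchar(lines[l + 2L]) != nchar(lines[l + 4L]))
      stop(sprintf("FASTQ parse error at line %d: quality length != sequence length",
                   l + 4L))
    out$id[r] <- sub("^@", "", lines[l + 1L])
    out$sequence[r] <- lines[l + 2L]
    out$quality[r] <- lines[l + 4L]
  }
  class(out) <- c("read_set", "data.frame")
  out
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  qual <- if (!is.null(reads$quality)) reads$quality
          else strrep("?", nchar(reads$sequence))
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$sequence,
                             "+", qual)), path)
  invisible(path)
}

#' Write the ground-truth sidecar of a simulated read set
#'
#' TSV with one row per read: id, true source electrode, true index,
#' crossover flag and injected error counts.
#' @param reads A `read_set` from [simulate_reads()].
#' @param path File path.
#' @export
write_truth_sidecar <- function(reads, path) {
  utils::write.table(
    reads[, c("id", "electrode", "index", "crossover",
              "n_sub", "n_del", "n_ins")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Designed-strand FASTA with the `idx= role= grp= profile=` header dialect
#'
#' @param strands Data frame with `index`, `role`, `group`, `sequence`.
#' @param profile Profile name written into every header.
#' @param path File path.
#' @return `read_strand_fasta`: the strand data frame.
#' @export
write_strand_fasta <- function(strands, path, profile = "archive150") {
  x <- Biostrings::DNAStringSet(strands$sequence)
  names(x) <- sprintf("idx=%d role=%s grp=%d profile=%s",
                      strands$index, strands$role,
                      strands$group %||% 0L, profile)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_strand_fasta
#' @export
read_strand_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  field <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=\\S+"), hdr))
    if (length(m) != length(hdr))
      stop(sprintf("FASTA parse error: header key '%s' missing", key))
    sub(paste0(key, "="), "", m)
  }
  data.frame(index = as.integer(field("idx")), role = field("role"),
             group = as.integer(field("grp")), profile = field("profile"),
             sequence = as.character(x), stringsAsFactors = FALSE)
}

#' Serialize an archive manifest to JSON and back
#'
#' @param manifest An `archive_manifest`.
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  l <- manifest$layout
  obj <- list(
    layout = list(total = l$total, primer5_len = l$primer5_len,
                  primer3_len = l$primer3_len, index_len = l$index_len,
                  payload_len = l$payload_len, name = l$name,
                  rs = if (!is.null(l$rs))
                    list(n = l$rs$n, k = l$rs$k, m = l$rs$field$m,
                         primitive_poly = l$rs$field$primitive_poly,
                         profile = l$rs$profile %||% "custom")),
    g = manifest$g, n_data = manifest$n_data, n_parity = manifest$n_parity,
    pad = manifest$pad, source_len = manifest$source_len,
    primers = manifest$primers, content = manifest$content,
    content_meta = manifest$content_meta,
    group_of_index = manifest$group_of_index,
    map_bases = manifest$map_bases)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rs <- NULL
  if (!is.null(obj$layout$rs))
    rs <- rs_spec(obj$layout$rs$n, obj$layout$rs$k,
                  gf_field(obj$layout$rs$m, obj$layout$rs$primitive_poly))
  layout <- strand_layout(obj$layout$total, obj$layout$primer5_len,
                          obj$layout$primer3_len, obj$layout$index_len,
                          rs = rs, name = obj$layout$name)
  structure(list(layout = layout, g = obj$g, n_data = obj$n_data,
                 n_parity = obj$n_parity, pad = obj$pad,
                 source_len = obj$source_len, primers = obj$primers,
                 content = obj$content,
                 content_meta = as.list(obj$content_meta),
                 group_of_index = obj$group_of_index,
                 map_bases = obj$map_bases),
            class = "archive_manifest")
}

#' Seeded toy fixtures
#'
#' Deterministic stand-ins for the kinds of inputs the archive stores:
#' a 2-bit pixel-art image, a triangle mesh, random payload bytes, or a
#' short word list. Identical spec and seed give byte-identical fixtures.
#'
#' @param kind One of `"image"`, `"mesh"`, `"bytes"`, `"words"`.
#' @param seed Integer seed.
#' @param width,height Image size (default 16 x 16).
#' @param n_vertices,n_faces Mesh size (defaults: the unit cube, 8 vertices
#'   and 12 faces; larger values give a random synthetic mesh).
#' @param n_bytes Payload size for `"bytes"`.
#' @param n_words Word count for `"words"`.
#' @return The fixture object (a [pixel_image()], [mesh_3d()], integer
#'   byte vector, or character vector).
#' @export
make_fixture <- function(kind = c("image", "mesh", "bytes", "words"),
                         seed = 1L, width = 16L, height = 16L,
                         n_vertices = 8L, n_faces = 12L,
                         n_bytes = 5000L, n_words = 4L) {
  kind <- match.arg(kind)
  with_seed(seed, switch(kind,
    image = pixel_image(matrix(sample(0:3, width * height, replace = TRUE),
                               nrow = height), bits = 2L),
    mesh = {
      if (n_vertices == 8L && n_faces == 12L) {
        v <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
        dimnames(v) <- NULL
        f <- rbind(c(1, 2, 3), c(2, 4, 3), c(5, 7, 6), c(6, 7, 8),
                   c(1, 5, 2), c(2, 5, 6), c(3, 4, 7), c(4, 8, 7),
                   c(1, 3, 5), c(3, 7, 5), c(2, 6, 4), c(4, 6, 8))
        mesh_3d(v, f)
      } else {
        v <- matrix(round(stats::runif(3L * n_vertices, -100, 100) * 256) / 256,
                    ncol = 3L)
        f <- matrix(sample.int(n_vertices, 3L * n_faces, replace = TRUE),
                    ncol = 3L)
        mesh_3d(v, f)
      }
    },
    bytes = sample(0:255, n_bytes, replace = TRUE),
    words = {
      vocab <- c("We", "love", "DNA.", "synthesize", "store", "read",
                 "write", "data", "chips", "fields")
      sample(vocab, n_words)
    }))
}
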