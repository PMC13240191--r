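#' Paletted pixel image container
#'
#' @param grid Integer matrix (`height x width`) of palette values.
#' @param bits Bits per pixel.
#' @return An object of class `pixel_image`.
#' @export
pixel_image <- function(grid, bits = 2L) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  bits <- as.integer(bits)
  if (any(grid < 0L | grid >= 2L^bits)) stop("pixel values exceed 2^bits")
  structure(list(grid = grid, width = ncol(grid), height = nrow(grid),
                 bits = bits), class = "pixel_image")
}

#' @export
print.pixel_image <- function(x, ...) {
  cat(sprintf("pixel image: %d x %d, %d bits per pixel\n",
              x$width, x$height, x$bits))
  invisible(x)
}

# 64-codon <-> 6-bit table: codons enumerated lexicographically over ACGT,
# so AAA = 0 ... TTT = 63 (default stand-in for unpublished codon tables)
codon_table <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))  # value i+1 -> codon
}

bits_to_codons <- function(bits) {
  pad <- (6L - length(bits) %% 6L) %% 6L
  bits <- c(bits, integer(pad))
  vals <- as.integer(colSums(matrix(bits, nrow = 6L) * 2L^(5:0)))
  paste(codon_table()[vals + 1L], collapse = "")
}

codons_to_bits <- function(codon_str) {
  n <- nchar(codon_str) %/% 3L
  codons <- substring(codon_str, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  vals <- match(codons, codon_table()) - 1L
  if (anyNA(vals)) return(NULL)
  as.integer(bitwAnd(bitwShiftR(rep(vals, each = 6L),
                                rep(5:0, length(vals))), 1L))
}

#' Encode a pixel image into 90-nt pool strands
#'
#' The image is split into `n_strands` equal horizontal bands (default 8,
#' one band per pool); each band's pixels are serialized row-major at
#' `bits` per pixel and written through the 64-codon/6-bit code into the
#' 48-nt payload region of one strand (`primer5 + 2-nt index + payload +
#' primer3`). Unused payload positions are filled with the zero codon.
#'
#' @param image A [pixel_image()].
#' @param layout A [strand_layout()] without an RS spec
#'   (default [pixel_layout()]).
#' @param n_strands Number of bands/strands; must divide the image height.
#' @param primers Character vector `c(primer5, primer3)`.
#' @param map A [bit_base_map()] used only for the index region.
#' @return Data frame of strands (`index`, `sequence`) with the encoding
#'   parameters attached as attributes.
#' @export
encode_pixels <- function(image, layout = pixel_layout(), n_strands = 8L,
                          primers = default_primers(layout, seed = 21L),
                          map = bit_base_map()) {
  stopifnot(inherits(image, "pixel_image"))
  n_strands <- as.integer(n_strands)
  if (image$height %% n_strands != 0L)
    stop("image height must be divisible by n_strands")
  if (n_strands > 4^layout$index_len)
    stop("capacity error: more strands than the index space addresses")
  rows_per <- image$height %/% n_strands
  band_bits <- rows_per * image$width * image$bits
  capacity <- (layout$payload_len %/% 3L) * 6L
  if (band_bits > capacity)
    stop(sprintf("capacity error: band needs %d bits, payload holds %d",
                 band_bits, capacity))

  seqs <- vapply(seq_len(n_strands), function(s) {
    rows <- ((s - 1L) * rows_per + 1L):(s * rows_per)
    px <- as.integer(t(image$grid[rows, , drop = FALSE]))
    bits <- as.integer(bitwAnd(
      bitwShiftR(rep(px, each = image$bits),
                 rep((image$bits - 1L):0L, length(px))), 1L))
    pay <- bits_to_codons(bits)
    pay <- paste0(pay, strrep("A", layout$payload_len - nchar(pay)))
    paste0(primers[1L], int_to_bases(s - 1L, layout$index_len, map),
           pay, primers[2L])
  }, character(1L))

  out <- data.frame(index = seq_len(n_strands) - 1L, sequence = seqs,
                    stringsAsFactors = FALSE)
  attr(out, "pixel_spec") <- list(width = image$width, height = image$height,
                                  bits = image$bits, n_strands = n_strands,
                                  layout = layout, primers = primers,
                                  map_bases = map$bases)
  out
}

#' @rdname encode_pixels
#' @param sequences Character vector of strand (or consensus) sequences in
#'   index order, `NA` for missing strands.
#' @param spec The `pixel_spec` attribute produced by `encode_pixels`.
#' @return `decode_pixels`: a [pixel_image()]; missing bands decode to
#'   zero-valued pixels.
#' @export
decode_pixels <- function(sequences, spec) {
  layout <- spec$layout
  rows_per <- spec$height %/% spec$n_strands
  band_bits <- rows_per * spec$width * spec$bits
  grid <- matrix(0L, nrow = spec$height, ncol = spec$width)
  for (s in seq_len(spec$n_strands)) {
    seqs <- sequences[s]
    if (is.na(seqs) || nchar(seqs) != layout$total) next
    p0 <- layout$primer5_len + layout$index_len
    pay <- substr(seqs, p0 + 1L, p0 + layout$payload_len)
    bits <- codons_to_bits(substr(pay, 1L, 3L * ceiling(band_bits / 6L)))
    if (is.null(bits)) next
    bits <- bits[seq_len(band_bits)]
    px <- as.integer(colSums(matrix(bits, nrow = spec$bits) *
                               2L^((spec$bits - 1L):0L)))
    rows <- ((s - 1L) * rows_per + 1L):(s * rows_per)
    grid[rows, ] <- matrix(px, nrow = rows_per, byrow = TRUE)
  }
  pixel_image(grid, spec$bits)
}

#' Read and write the plain-text pixel grid format
#'
#' One row per line, one digit per pixel.
#'
#' @param path File path.
#' @param image A [pixel_image()].
#' @param bits Bits per pixel for `read_pixel_grid`.
#' @export
read_pixel_grid <- function(path, bits = 2L) {
  lines <- readLines(path)
  grid <- do.call(rbind, lapply(strsplit(lines, ""), as.integer))
  pixel_image(grid, bits)
}

#' @rdname read_pixel_grid
#' @export
write_pixel_grid <- function(image, path) {
  writeLines(apply(image$grid, 1L, paste, collapse = ""), path)
  invisible(path)
}
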