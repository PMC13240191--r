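#' Bit-to-base mapping
#'
#' Bijection between the four 2-bit values and the four nucleotides, plus the
#' padding rule for odd-length bit strings (zero-pad to even length; the pad
#' count is returned so the inverse is lossless).
#'
#' @param bases Character vector of the four bases assigned, in order, to the
#'   2-bit values `00, 01, 10, 11`.
#' @return An object of class `bit_base_map`.
#' @examples
#' bits_to_bases(c(0L,0L,0L,1L,1L,0L,1L,1L))   # "ACGT"
#' @export
bit_base_map <- function(bases = c("A", "C", "G", "T")) {
  if (length(bases) != 4L || anyDuplicated(bases) ||
      !all(bases %in% c("A", "C", "G", "T")))
    stop("bases must be a permutation of A, C, G, T")
  structure(list(bases = bases), class = "bit_base_map")
}

#' Translate bits to bases and back
#'
#' @param bits Integer vector of 0/1.
#' @param map A [bit_base_map()].
#' @param bases A string of A/C/G/T characters.
#' @param pad Number of zero bits appended at encode time, to strip on the
#'   way back.
#' @return `bits_to_bases`: list with `bases` (string) and `pad` (0 or 1).
#'   `bases_to_bits`: integer 0/1 vector.
#' @export
bits_to_bases <- function(bits, map = bit_base_map()) {
  bits <- as.integer(bits)
  if (length(bits) && !all(bits %in% c(0L, 1L))) stop("bits must be 0/1")
  pad <- length(bits) %% 2L
  if (pad) bits <- c(bits, 0L)
  if (!length(bits)) return(list(bases = "", pad = 0L))
  idx <- 2L * bits[c(TRUE, FALSE)] + bits[c(FALSE, TRUE)]
  list(bases = paste(map$bases[idx + 1L], collapse = ""), pad = pad)
}

#' @rdname bits_to_bases
#' @export
bases_to_bits <- function(bases, map = bit_base_map(), pad = 0L) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% c("A", "C", "G", "T")))
    stop("sequence contains a non-ACGT character")
  if (!length(ch)) return(integer(0))
  idx <- match(ch, map$bases) - 1L
  bits <- as.integer(rbind(idx %/% 2L, idx %% 2L))
  if (pad > 0L) bits <- bits[seq_len(length(bits) - pad)]
  bits
}

# bytes are integers 0..255 throughout (raw vectors converted at the I/O edge)

bytes_to_bits <- function(bytes) {
  if (!length(bytes)) return(integer(0))
  as.integer(vapply(as.integer(bytes), function(b)
    bitwAnd(bitwShiftR(b, 7:0), 1L), integer(8L)))
}

bits_to_bytes <- function(bits) {
  if (length(bits) %% 8L != 0L) stop("bit count must be a multiple of 8")
  if (!length(bits)) return(integer(0))
  m <- matrix(as.integer(bits), nrow = 8L)
  as.integer(colSums(m * 2L^(7:0)))
}

#' XOR parity over equal-length byte blocks
#'
#' The outer erasure code of the archive: one parity block equal to the
#' bytewise exclusive-or of all data blocks in a group. Any single missing
#' block is recoverable with [xor_recover()].
#'
#' @param payloads Non-empty list of equal-length integer byte vectors.
#' @return Integer byte vector, the bytewise XOR of all blocks.
#' @export
xor_parity <- function(payloads) {
  if (!length(payloads)) stop("payload list must be non-empty")
  lens <- lengths(payloads)
  if (length(unique(lens)) != 1L) stop("all payloads must have equal length")
  Reduce(bitwXor, lapply(payloads, as.integer))
}

#' Recover a single missing block from XOR parity
#'
#' @param present List of the blocks still present from one XOR group
#'   (exactly one member missing).
#' @param parity The group's parity block.
#' @return The missing block, bit-exact.
#' @export
xor_recover <- function(present, parity) {
  xor_parity(c(present, list(as.integer(parity))))
}

# fixed-width base-4 integer codec for the strand index region
int_to_bases <- function(value, width, map = bit_base_map()) {
  value <- as.integer(value)
  if (value < 0L || (width < 16 && value >= 4^width))
    stop("index value out of range for index width")
  digits <- integer(width)
  for (i in width:1) { digits[i] <- value %% 4L; value <- value %/% 4L }
  paste(map$bases[digits + 1L], collapse = "")
}

bases_to_int <- function(bases, map = bit_base_map()) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1L]]
  digits <- match(ch, map$bases) - 1L
  if (anyNA(digits)) return(NA_integer_)
  as.integer(sum(digits * 4^(rev(seq_along(digits)) - 1L)))
}
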