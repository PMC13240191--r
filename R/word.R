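#' Encode an ASCII word into a tokenized strand
#'
#' The word codec chain: ASCII text -> 8-bit code points (a 1-byte length
#' prefix makes the payload self-describing) -> bit stream, zero-padded to a
#' whole number of RS message blocks -> per-block systematic Reed-Solomon
#' encoding -> 2-bit-per-base translation -> address tokens appended on both
#' ends.
#'
#' @param word Non-empty printable-ASCII string.
#' @param profile An [rs_spec()], by default the `word_rs` RS(7,3)/GF(8)
#'   profile.
#' @param token5,token3 Token ids (positions in `library`).
#' @param library A [make_token_library()] object.
#' @param map A [bit_base_map()].
#' @return An object of class `tokenized_strand`: `word`, `token5`,
#'   `token3`, `payload` (base string) and `sequence` (token5 + payload +
#'   token3).
#' @export
encode_word <- function(word, profile = codec_profile("word_rs"),
                        token5, token3, library, map = bit_base_map()) {
  if (!is.character(word) || length(word) != 1L || !nzchar(word))
    stop("word must be a non-empty string")
  codes <- utf8ToInt(word)
  if (any(codes < 32L | codes > 126L))
    stop("word must be printable ASCII")
  if (length(codes) > 255L) stop("word longer than 255 characters")

  m <- profile$field$m
  block_bits <- profile$k * m
  bits <- bytes_to_bits(c(length(codes), codes))
  pad <- (block_bits - length(bits) %% block_bits) %% block_bits
  bits <- c(bits, integer(pad))

  cw_bits <- integer(0)
  for (b in seq_len(length(bits) / block_bits)) {
    blk <- bits[((b - 1L) * block_bits + 1L):(b * block_bits)]
    syms <- as.integer(colSums(matrix(blk, nrow = m) * 2L^((m - 1L):0L)))
    cw <- rs_encode(syms, profile)
    cw_bits <- c(cw_bits, as.integer(bitwAnd(
      bitwShiftR(rep(cw, each = m), rep((m - 1L):0L, length(cw))), 1L)))
  }
  payload <- bits_to_bases(cw_bits, map)$bases

  t5 <- library$tokens[token5]
  t3 <- library$tokens[token3]
  structure(list(word = word, token5 = token5, token3 = token3,
                 payload = payload,
                 sequence = paste0(t5, payload, t3)),
            class = "tokenized_strand")
}

#' @export
print.tokenized_strand <- function(x, ...) {
  cat(sprintf("tokenized strand '%s': tokens (%d, %d), %d nt total\n",
              x$word, x$token5, x$token3, nchar(x$sequence)))
  invisible(x)
}

#' Encode a sentence as a chain of tokenized strands
#'
#' Word `i` receives tokens `(i, i + 1)`, so consecutive strands share a
#' token and can be assembled through it.
#'
#' @param words Character vector of words.
#' @inheritParams encode_word
#' @return List of [encode_word()] strands.
#' @export
encode_sentence <- function(words, library,
                            profile = codec_profile("word_rs"),
                            map = bit_base_map()) {
  if (length(words) + 1L > length(library$tokens))
    stop("token library too small for this sentence")
  lapply(seq_along(words), function(i)
    encode_word(words[i], profile, token5 = i, token3 = i + 1L,
                library = library, map = map))
}

#' Assemble tokenized strands through shared tokens
#'
#' In-silico analogue of assembly PCR: consecutive strands overlap at their
#' shared token, which appears exactly once in the product, so the product
#' length is the sum of strand lengths minus the shared-token lengths.
#'
#' @param strands Ordered list of `tokenized_strand` objects.
#' @param library The token library the strands were built with.
#' @return The assembled base string.
#' @export
assemble <- function(strands, library) {
  stopifnot(length(strands) >= 1L)
  out <- strands[[1L]]$sequence
  for (i in seq_along(strands)[-1L]) {
    if (strands[[i - 1L]]$token3 != strands[[i]]$token5)
      stop(sprintf("assembly error at junction %d: token %d != token %d",
                   i, strands[[i - 1L]]$token3, strands[[i]]$token5))
    out <- paste0(out,
                  substr(strands[[i]]$sequence, library$token_len + 1L,
                         nchar(strands[[i]]$sequence)))
  }
  out
}

decode_word_payload <- function(payload, profile, map) {
  if (!nzchar(payload)) return(NA_character_)
  m <- profile$field$m
  bits <- bases_to_bits(payload, map)
  n_cw <- length(bits) %/% (profile$n * m)
  if (n_cw < 1L) return(NA_character_)
  msg_bits <- integer(0)
  for (b in seq_len(n_cw)) {
    cw_bits <- bits[((b - 1L) * profile$n * m + 1L):(b * profile$n * m)]
    syms <- as.integer(colSums(matrix(cw_bits, nrow = m) * 2L^((m - 1L):0L)))
    dec <- rs_decode(syms, profile)
    if (!dec$ok) return(NA_character_)
    msg_bits <- c(msg_bits, as.integer(bitwAnd(
      bitwShiftR(rep(dec$data, each = m), rep((m - 1L):0L, profile$k)), 1L)))
  }
  n_bytes <- length(msg_bits) %/% 8L
  if (n_bytes < 1L) return(NA_character_)
  bytes <- bits_to_bytes(msg_bits[seq_len(8L * n_bytes)])
  w <- bytes[1L]
  if (w == 0L || w + 1L > length(bytes)) return(NA_character_)
  chars <- bytes[2L:(w + 1L)]
  if (any(chars < 32L | chars > 126L)) return(NA_character_)
  intToUtf8(chars)
}

#' Decode words from an assembled (possibly noisy) sequence
#'
#' Locates address tokens by alignment scoring, cuts out the inter-token
#' payload regions and Reed-Solomon-decodes each one. A payload whose RS
#' decode fails (or an empty inter-token region) is reported as `NA`; the
#' remaining words are still returned in order.
#'
#' @param sequence Assembled base string.
#' @param library A [make_token_library()].
#' @param profile The word [rs_spec()] profile.
#' @param scoring An [alignment_scoring()].
#' @param map A [bit_base_map()].
#' @return Character vector of decoded words (`NA` where unrecovered), one
#'   per inter-token region.
#' @export
decode_words <- function(sequence, library,
                         profile = codec_profile("word_rs"),
                         scoring = alignment_scoring(),
                         map = bit_base_map()) {
  hits <- identify_tokens(sequence, library, scoring)
  if (nrow(hits) < 2L) return(character(0))
  vapply(seq_len(nrow(hits) - 1L), function(i) {
    payload <- substr(sequence, hits$end[i] + 1L, hits$offset[i + 1L] - 1L)
    decode_word_payload(payload, profile, map)
  }, character(1L))
}
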