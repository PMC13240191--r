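#' Tokenized-primer library
#'
#' Address tokens flanking each word payload. Tokens double as assembly
#' overlaps and as retrieval handles during readout, so they are generated
#' with a guaranteed pairwise Hamming separation and balanced GC content.
#'
#' @param n_tokens Number of tokens.
#' @param token_len Token length in nt (default 20, the usual primer length).
#' @param min_dist Minimum pairwise Hamming distance between tokens.
#' @param seed Integer seed; the library is a pure function of its arguments.
#' @return An object of class `token_library`: character vector `tokens`
#'   (ids are their positions) plus the generation parameters.
#' @export
make_token_library <- function(n_tokens, token_len = 20L, min_dist = 8L,
                               seed = 11L) {
  stopifnot(n_tokens >= 1L, token_len >= min_dist)
  tokens <- character(0)
  with_seed(seed, {
    tries <- 0L
    while (length(tokens) < n_tokens) {
      tries <- tries + 1L
      if (tries > 5000L * n_tokens) stop("token sampling did not converge")
      cand <- sample(c("A", "C", "G", "T"), token_len, replace = TRUE)
      gc <- mean(cand %in% c("C", "G"))
      if (gc < 0.4 || gc > 0.6 || max(rle(cand)$lengths) > 3L) next
      cand <- paste(cand, collapse = "")
      ok <- all(vapply(tokens, function(t) hamming_dist(t, cand) >= min_dist,
                       logical(1L)))
      if (ok) tokens <- c(tokens, cand)
    }
  })
  structure(list(tokens = tokens, token_len = as.integer(token_len),
                 min_dist = as.integer(min_dist), seed = as.integer(seed)),
            class = "token_library")
}

hamming_dist <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

#' @export
print.token_library <- function(x, ...) {
  cat(sprintf("token library: %d tokens x %d nt, min Hamming distance %d\n",
              length(x$tokens), x$token_len, x$min_dist))
  invisible(x)
}

#' Alignment scoring for token/primer identification
#'
#' Semi-global scoring used to locate tokens and primers inside longer
#' sequences: the token aligns end-to-end, the target locally. A hit is
#' accepted when its score reaches `threshold` times the perfect score
#' (`token length * match`).
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch penalty (negative).
#' @param gap Gap penalty per gapped position (negative).
#' @param threshold Acceptance threshold as a fraction of the perfect score.
#' @return An object of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 1, mismatch = -1, gap = -2,
                              threshold = 0.8) {
  stopifnot(match > 0, threshold > 0, threshold <= 1)
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 threshold = threshold),
            class = "alignment_scoring")
}

# semi-global alignment of `query` (global) inside `subjects` (local),
# vectorized over subjects; returns data.frame(score, start, end)
semi_global_hits <- function(query, subjects, scoring) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(subjects),
    subject = Biostrings::DNAString(query),
    type = "local-global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = -scoring$gap)
  pr <- Biostrings::pattern(al)
  data.frame(score = Biostrings::score(al),
             start = IRanges::start(pr), end = IRanges::end(pr))
}

#' Locate library tokens in a sequence
#'
#' Scans a sequence for every token in the library by semi-global alignment
#' and returns accepted hits left-to-right. Overlapping candidate hits are
#' resolved best-score-first (ties broken by leftmost offset, then token id).
#'
#' @param sequence A base string.
#' @param library A [make_token_library()] object.
#' @param scoring An [alignment_scoring()].
#' @return Data frame with columns `token_id`, `offset` (1-based start),
#'   `end` and `score`, ordered by offset. Zero rows when nothing reaches
#'   the threshold.
#' @export
identify_tokens <- function(sequence, library, scoring = alignment_scoring()) {
  stopifnot(nchar(sequence) > 0L)
  min_score <- scoring$threshold * library$token_len * scoring$match
  cand <- list()
  for (id in seq_along(library$tokens)) {
    tok <- library$tokens[id]
    seq_work <- sequence
    repeat {
      hit <- semi_global_hits(tok, seq_work, scoring)
      if (hit$score[1L] < min_score) break
      cand[[length(cand) + 1L]] <-
        data.frame(token_id = id, offset = hit$start, end = hit$end,
                   score = hit$score)
      # mask the matched window so further occurrences can surface
      masked <- strsplit(seq_work, "")[[1L]]
      masked[hit$start:hit$end] <- "N"
      seq_work <- paste(masked, collapse = "")
      if (sum(masked == "N") >= nchar(sequence) - library$token_len %/% 2L)
        break
    }
  }
  empty <- data.frame(token_id = integer(0), offset = integer(0),
                      end = integer(0), score = numeric(0))
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$offset, cand$token_id), , drop = FALSE]
  keep <- logical(nrow(cand))
  used <- integer(0)
  for (i in seq_len(nrow(cand))) {
    span <- cand$offset[i]:cand$end[i]
    if (!any(span %in% used)) {
      keep[i] <- TRUE
      used <- c(used, span)
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
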