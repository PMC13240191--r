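#' Reed-Solomon code specification
#'
#' Systematic RS(n, k) over GF(2^m). Codewords of `n` symbols carry `k` data
#' symbols followed by `n - k` parity symbols; up to `t = floor((n - k) / 2)`
#' symbol errors per codeword are correctable. `n < 2^m - 1` yields a
#' shortened code.
#'
#' @param n Codeword length in symbols.
#' @param k Data symbols per codeword.
#' @param field A [gf_field()]; defaults to GF(2^m) just large enough only
#'   when supplied explicitly — there is no silent default field.
#' @return An object of class `rs_spec`.
#' @examples
#' spec <- rs_spec(7, 3, gf_field(3))   # RS(7,3) over GF(8), t = 2
#' cw <- rs_encode(c(1L, 2L, 3L), spec)
#' rs_decode(cw, spec)
#' @export
rs_spec <- function(n, k, field) {
  stopifnot(inherits(field, "gf_field"))
  n <- as.integer(n); k <- as.integer(k)
  if (!(k > 0L && k < n && n <= field$q - 1L))
    stop("require 0 < k < n <= 2^m - 1")
  t <- (n - k) %/% 2L
  if (t < 1L) stop("n - k must be at least 2 for t >= 1")
  # generator polynomial g(x) = prod_{i=0}^{n-k-1} (x - alpha^i), ascending
  g <- 1L
  for (i in seq_len(n - k) - 1L)
    g <- gf_poly_mul(field, g, c(gf_pow(field, 2L, i), 1L))
  structure(list(n = n, k = k, t = t, field = field, generator = g),
            class = "rs_spec")
}

#' @export
print.rs_spec <- function(x, ...) {
  cat(sprintf("RS(%d,%d) over GF(%d): t = %d correctable symbol errors\n",
              x$n, x$k, x$field$q, x$t))
  invisible(x)
}

#' Reed-Solomon systematic encode
#'
#' Appends `n - k` parity symbols to `k` data symbols: the parity block is the
#' remainder of `x^(n-k) * m(x)` modulo the generator polynomial, so the
#' first `k` codeword symbols equal the data.
#'
#' @param data Integer vector of `k` field symbols (`data[1]` transmitted
#'   first, i.e. the highest-degree message coefficient).
#' @param spec An [rs_spec()].
#' @return Integer vector of `n` codeword symbols.
#' @export
rs_encode <- function(data, spec) {
  stopifnot(inherits(spec, "rs_spec"))
  data <- as.integer(data)
  if (length(data) != spec$k)
    stop(sprintf("data must have exactly k = %d symbols", spec$k))
  gf_check_symbols(spec$field, data)
  np <- spec$n - spec$k
  # LFSR long division; gr = generator coefficients of degree np-1 .. 0
  gr <- rev(spec$generator[seq_len(np)])
  parity <- integer(np)
  for (d in data) {
    fb <- bitwXor(d, parity[1L])
    parity <- c(parity[-1L], 0L)
    if (fb != 0L) parity <- bitwXor(parity, gf_mul(spec$field, fb, gr))
  }
  c(data, parity)
}

rs_syndromes <- function(received, spec) {
  f <- spec$field
  vapply(seq_len(spec$n - spec$k) - 1L, function(j) {
    # received[1] is the coefficient of x^(n-1)
    gf_poly_eval(f, rev(received), gf_pow(f, 2L, j))
  }, integer(1L))
}

# Berlekamp-Massey: returns error-locator polynomial sigma (ascending,
# sigma[1] = 1)
rs_berlekamp_massey <- function(synd, spec) {
  f <- spec$field
  sigma <- 1L; B <- 1L; L <- 0L; m <- 1L; b <- 1L
  for (r in seq_along(synd)) {
    d <- synd[r]
    if (L > 0L) {
      for (i in seq_len(min(L, length(sigma) - 1L)))
        d <- bitwXor(d, gf_mul(f, sigma[i + 1L], synd[r - i]))
    }
    if (d == 0L) {
      m <- m + 1L
    } else if (2L * L <= r - 1L) {
      Told <- sigma
      coef <- gf_div(f, d, b)
      shiftB <- c(integer(m), gf_mul(f, coef, B))
      len <- max(length(sigma), length(shiftB))
      sigma <- bitwXor(c(sigma, integer(len - length(sigma))),
                       c(shiftB, integer(len - length(shiftB))))
      L <- r - L; B <- Told; b <- d; m <- 1L
    } else {
      coef <- gf_div(f, d, b)
      shiftB <- c(integer(m), gf_mul(f, coef, B))
      len <- max(length(sigma), length(shiftB))
      sigma <- bitwXor(c(sigma, integer(len - length(sigma))),
                       c(shiftB, integer(len - length(shiftB))))
      m <- m + 1L
    }
  }
  list(sigma = gf_poly_trim(sigma), L = L)
}

#' Reed-Solomon decode with re-encode verification
#'
#' Corrects up to `t` symbol errors (syndrome computation, Berlekamp-Massey,
#' Chien search, and an error-value solve over the field). Every successful
#' decode is re-encoded and compared against the corrected codeword: a
#' mismatch is reported as failure, never returned silently.
#'
#' @param received Integer vector of `n` symbols.
#' @param spec An [rs_spec()].
#' @return A list with `ok` (logical), `data` (the `k` data symbols, or
#'   `NULL` on failure) and `corrections` (number of symbols corrected).
#' @export
rs_decode <- function(received, spec) {
  stopifnot(inherits(spec, "rs_spec"))
  received <- as.integer(received)
  if (length(received) != spec$n)
    stop(sprintf("received word must have exactly n = %d symbols", spec$n))
  gf_check_symbols(spec$field, received)
  f <- spec$field
  fail <- list(ok = FALSE, data = NULL, corrections = NA_integer_)

  synd <- rs_syndromes(received, spec)
  if (all(synd == 0L))
    return(list(ok = TRUE, data = received[seq_len(spec$k)], corrections = 0L))

  bm <- rs_berlekamp_massey(synd, spec)
  sigma <- bm$sigma
  v <- length(sigma) - 1L
  if (v < 1L || v > spec$t || bm$L != v) return(fail)

  # Chien search over the n used positions of the (possibly shortened) code;
  # position i holds the coefficient of x^(n-i), error locator X = alpha^(n-i)
  degs <- spec$n - seq_len(spec$n)              # degree of each position
  roots <- vapply(degs, function(dg) {
    X <- gf_pow(f, 2L, dg)
    gf_poly_eval(f, sigma, gf_inv(f, X)) == 0L
  }, logical(1L))
  pos <- which(roots)
  if (length(pos) != v) return(fail)

  # solve for error values from the first v syndromes: S_j = sum e_l X_l^j
  X <- vapply(degs[pos], function(dg) gf_pow(f, 2L, dg), integer(1L))
  A <- t(vapply(seq_len(v) - 1L, function(j)
    vapply(X, function(x) gf_pow(f, x, j), integer(1L)), integer(v)))
  if (v == 1L) A <- matrix(A, nrow = 1L)
  evals <- gf_solve(f, A, synd[seq_len(v)])
  if (is.null(evals)) return(fail)

  corrected <- received
  corrected[pos] <- bitwXor(corrected[pos], evals)
  data <- corrected[seq_len(spec$k)]
  if (!identical(rs_encode(data, spec), corrected)) return(fail)
  list(ok = TRUE, data = data, corrections = v)
}
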