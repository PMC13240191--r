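#' Galois field GF(2^m) specification
#'
#' Builds the exp/log tables for the finite field with `2^m` elements used by
#' the Reed-Solomon inner code. Field elements are integers in `[0, 2^m - 1]`
#' interpreted as polynomials over GF(2); multiplication is carried out modulo
#' the primitive polynomial.
#'
#' @param m Bits per symbol, between 2 and 8.
#' @param primitive_poly Integer bit mask of the primitive polynomial
#'   (degree-`m` term included), e.g. `0x11D` for the conventional GF(256)
#'   polynomial. Defaults to a standard primitive polynomial for each `m`.
#' @return An object of class `gf_field` with the tables and parameters.
#' @examples
#' f <- gf_field(3)            # GF(8), x^3 + x + 1
#' gf_mul(f, 5L, 6L)
#' @export
gf_field <- function(m, primitive_poly = NULL) {
  stopifnot(is.numeric(m), length(m) == 1L)
  m <- as.integer(m)
  if (m < 2L || m > 8L) stop("m must be between 2 and 8")
  defaults <- c(`2` = 0x7L, `3` = 0xBL, `4` = 0x13L, `5` = 0x25L,
                `6` = 0x43L, `7` = 0x83L, `8` = 0x11DL)
  if (is.null(primitive_poly)) primitive_poly <- defaults[[as.character(m)]]
  primitive_poly <- as.integer(primitive_poly)
  q <- bitwShiftL(1L, m)
  if (primitive_poly < q || primitive_poly >= 2L * q)
    stop("primitive_poly must have degree exactly m")

  # generate powers of alpha = x; the polynomial is primitive iff the cycle
  # visits every nonzero element before returning to 1
  exp_tab <- integer(q - 1L)
  a <- 1L
  for (i in seq_len(q - 1L)) {
    exp_tab[i] <- a
    a <- bitwShiftL(a, 1L)
    if (a >= q) a <- bitwXor(a, primitive_poly)
  }
  if (anyDuplicated(exp_tab) || a != 1L)
    stop("primitive_poly is not primitive over GF(2) for this m")
  log_tab <- integer(q - 1L)
  log_tab[exp_tab] <- seq_len(q - 1L) - 1L   # log_tab[value] = exponent

  structure(list(m = m, q = q, primitive_poly = primitive_poly,
                 exp = exp_tab, log = log_tab),
            class = "gf_field")
}

#' @export
print.gf_field <- function(x, ...) {
  cat(sprintf("GF(2^%d) = GF(%d), primitive polynomial mask 0x%X\n",
              x$m, x$q, x$primitive_poly))
  invisible(x)
}

gf_check_symbols <- function(field, x) {
  if (any(x < 0L | x >= field$q))
    stop(sprintf("symbol out of range for GF(%d)", field$q))
  invisible(x)
}

#' Field arithmetic in GF(2^m)
#'
#' Vectorized multiply, divide, invert and power for `gf_field` elements.
#' Addition in characteristic 2 is `bitwXor` and needs no helper.
#'
#' @param field A [gf_field()].
#' @param a,b Integer vectors of field elements.
#' @param e Integer exponent(s).
#' @return Integer vector of field elements.
#' @export
gf_mul <- function(field, a, b) {
  gf_check_symbols(field, c(a, b))
  out <- integer(max(length(a), length(b)))
  a <- rep_len(as.integer(a), length(out))
  b <- rep_len(as.integer(b), length(out))
  nz <- a != 0L & b != 0L
  if (any(nz)) {
    s <- (field$log[a[nz]] + field$log[b[nz]]) %% (field$q - 1L)
    out[nz] <- field$exp[s + 1L]
  }
  out
}

#' @rdname gf_mul
#' @export
gf_div <- function(field, a, b) {
  if (any(b == 0L)) stop("division by zero in GF")
  gf_mul(field, a, gf_inv(field, b))
}

#' @rdname gf_mul
#' @export
gf_inv <- function(field, a) {
  gf_check_symbols(field, a)
  if (any(a == 0L)) stop("zero has no inverse in GF")
  field$exp[(field$q - 1L - field$log[a]) %% (field$q - 1L) + 1L]
}

#' @rdname gf_mul
#' @export
gf_pow <- function(field, a, e) {
  gf_check_symbols(field, a)
  if (length(a) != 1L) stop("gf_pow expects a scalar base")
  if (a == 0L) return(if (e == 0L) 1L else 0L)
  field$exp[(field$log[a] * as.integer(e)) %% (field$q - 1L) + 1L]
}

# polynomial helpers; coefficient vectors are ascending: p[i] is the
# coefficient of x^(i-1)

gf_poly_trim <- function(p) {
  n <- length(p)
  while (n > 1L && p[n] == 0L) n <- n - 1L
  p[seq_len(n)]
}

gf_poly_mul <- function(field, p, q) {
  out <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    out[i:(i + length(q) - 1L)] <-
      bitwXor(out[i:(i + length(q) - 1L)], gf_mul(field, p[i], q))
  }
  out
}

gf_poly_eval <- function(field, p, x) {
  # Horner, highest degree first
  acc <- 0L
  for (i in rev(seq_along(p)))
    acc <- bitwXor(gf_mul(field, acc, x), p[i])
  acc
}

# solve A %*% e = s over the field by Gaussian elimination; A square
gf_solve <- function(field, A, s) {
  n <- length(s)
  A <- cbind(A, s)
  for (col in seq_len(n)) {
    piv <- which(A[col:n, col] != 0L)
    if (length(piv) == 0L) return(NULL)
    piv <- piv[1L] + col - 1L
    if (piv != col) A[c(col, piv), ] <- A[c(piv, col), ]
    A[col, ] <- gf_div(field, A[col, ], A[col, col])
    for (r in seq_len(n)) {
      if (r == col || A[r, col] == 0L) next
      A[r, ] <- bitwXor(A[r, ], gf_mul(field, A[r, col], A[col, ]))
    }
  }
  A[, n + 1L]
}
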