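# shared layout / profile plumbing

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that deterministic fixture and
#' library generation never disturbs the caller's RNG stream.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Named Reed-Solomon codec profiles
#'
#' Two shipped profiles: `word_rs`, the small RS(7,3) code over GF(8) used by
#' the word codec (t = 2, 3-bit symbols), and `archive_rs`, the RS(25,19)
#' code over GF(256) sized so that one codeword fills the 100-nt payload
#' region of the 150-nt archive strand exactly (t = 3, byte symbols).
#'
#' @param name `"word_rs"` or `"archive_rs"`.
#' @return An [rs_spec()].
#' @export
codec_profile <- function(name = c("word_rs", "archive_rs")) {
  name <- match.arg(name)
  spec <- switch(name,
    word_rs    = rs_spec(7L, 3L, gf_field(3L)),
    archive_rs = rs_spec(25L, 19L, gf_field(8L)))
  spec$profile <- name
  spec
}

#' Strand layout: the oligo architecture
#'
#' Describes how a designed strand is partitioned into 5' primer, index,
#' payload and 3' primer regions. All encode and decode operations for a
#' pool share one layout.
#'
#' @param total Total strand length (nt).
#' @param primer5_len,primer3_len Flanking primer lengths (nt).
#' @param index_len Index region length (nt); addresses `4^index_len`
#'   strands.
#' @param rs Optional [rs_spec()] protecting the payload region.
#' @param name Profile name recorded in manifests.
#' @return An object of class `strand_layout`. The payload length is derived
#'   as `total - primer5_len - index_len - primer3_len`.
#' @examples
#' archive_layout()   # 150 nt: 20 + 10 + 100 + 20
#' pixel_layout()     # 90 nt: 20 + 2 + 48 + 20
#' @export
strand_layout <- function(total, primer5_len, primer3_len, index_len,
                          rs = NULL, name = "custom") {
  payload_len <- total - primer5_len - primer3_len - index_len
  if (payload_len <= 0L) stop("layout leaves no payload region")
  if (!is.null(rs)) {
    stopifnot(inherits(rs, "rs_spec"))
    need_nt <- rs$n * rs$field$m / 2
    if (need_nt != payload_len)
      stop(sprintf("RS codeword needs %g nt but payload region is %d nt",
                   need_nt, payload_len))
  }
  structure(list(total = as.integer(total),
                 primer5_len = as.integer(primer5_len),
                 primer3_len = as.integer(primer3_len),
                 index_len = as.integer(index_len),
                 payload_len = as.integer(payload_len),
                 rs = rs, name = name),
            class = "strand_layout")
}

#' @rdname strand_layout
#' @export
archive_layout <- function() {
  strand_layout(150L, 20L, 20L, 10L, rs = codec_profile("archive_rs"),
                name = "archive150")
}

#' @rdname strand_layout
#' @export
pixel_layout <- function() {
  strand_layout(90L, 20L, 20L, 2L, rs = NULL, name = "pixel90")
}

#' @export
print.strand_layout <- function(x, ...) {
  cat(sprintf(
    "strand layout '%s': %d nt = primer5 %d + index %d + payload %d + primer3 %d\n",
    x$name, x$total, x$primer5_len, x$index_len, x$payload_len, x$primer3_len))
  if (!is.null(x$rs))
    cat("  payload code: ", format(x$rs)[1], sep = "")
  invisible(x)
}

#' @export
format.rs_spec <- function(x, ...) {
  sprintf("RS(%d,%d) over GF(%d), t = %d\n", x$n, x$k, x$field$q, x$t)
}

# deterministic primer generation: GC content 40-60%, no homopolymer > 3
random_primer <- function(length, seed) {
  with_seed(seed, {
    repeat {
      s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      gc <- mean(s %in% c("C", "G"))
      runs <- rle(s)$lengths
      if (gc >= 0.4 && gc <= 0.6 && max(runs) <= 3L)
        return(paste(s, collapse = ""))
    }
  })
}

#' Default primer pair for a layout
#'
#' Deterministic 5'/3' primer sequences (seeded), GC-balanced, homopolymer
#' runs capped at 3 nt.
#' @param layout A [strand_layout()].
#' @param seed Integer seed.
#' @return Character vector `c(primer5, primer3)`.
#' @export
default_primers <- function(layout, seed = 7L) {
  c(random_primer(layout$primer5_len, seed),
    random_primer(layout$primer3_len, seed + 1L))
}
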