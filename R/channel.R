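#' Log-linear reuse-cycle degradation model
#'
#' Retrievable copy number after `n` synthesis/access cycles follows
#' `log10(N_n) = log10(N_0) - r * n`: a straight line in log10 space with
#' per-cycle decay slope `r`.
#'
#' @param N0 Initial copy number (> 0).
#' @param r Per-cycle decay slope in log10 units (>= 0).
#' @return An object of class `degradation_model`.
#' @examples
#' m <- degradation_model(N0 = 1e6, r = 3.1e-5)
#' remaining_copies(m, 1e5)   # 1e6 * 10^-3.1
#' @export
degradation_model <- function(N0, r) {
  stopifnot(N0 > 0, r >= 0)
  structure(list(N0 = N0, r = r), class = "degradation_model")
}

#' @rdname degradation_model
#' @param model A `degradation_model`.
#' @param n Cycle count(s), >= 0.
#' @export
remaining_copies <- function(model, n) {
  stopifnot(inherits(model, "degradation_model"))
  if (any(n < 0)) stop("cycle count must be non-negative")
  model$N0 * 10^(-model$r * n)
}

#' Fit the degradation model to observed copy numbers
#'
#' Ordinary least squares of `log10(copies)` on `cycles`; the slope
#' magnitude is reported as the decay rate `r`.
#'
#' @param cycles Numeric vector of cycle counts (>= 3 points).
#' @param copies Positive copy numbers, same length.
#' @return An object of class `degradation_fit` with components `r`,
#'   `log10_N0`, `N0`, `r_squared` and the underlying `lm` fit. Supports
#'   `print()`, `coef()` and `predict(fit, n)`.
#' @export
fit_degradation <- function(cycles, copies) {
  if (length(cycles) < 3L) stop("insufficient data: need at least 3 points")
  if (length(copies) != length(cycles)) stop("length mismatch")
  if (any(copies <= 0)) stop("copy numbers must be positive")
  fit <- stats::lm(log10(copies) ~ cycles)
  y <- log10(copies)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(r = abs(unname(stats::coef(fit)[2L])),
                 slope = unname(stats::coef(fit)[2L]),
                 log10_N0 = unname(stats::coef(fit)[1L]),
                 N0 = 10^unname(stats::coef(fit)[1L]),
                 r_squared = max(0, r2), lm = fit),
            class = "degradation_fit")
}

#' @export
print.degradation_fit <- function(x, ...) {
  cat(sprintf(
    "log-linear degradation fit: r = %.4g per cycle, N0 = %.4g (R^2 = %.4f)\n",
    x$r, x$N0, x$r_squared))
  invisible(x)
}

#' @export
coef.degradation_fit <- function(object, ...) {
  c(log10_N0 = object$log10_N0, r = object$r)
}

#' @export
predict.degradation_fit <- function(object, n, ...) {
  remaining_copies(degradation_model(object$N0, object$r), n)
}

#' An electrode with its immobilized strand pool
#'
#' @param id Electrode identifier.
#' @param pool Data frame with columns `index` and `sequence` (e.g. the
#'   `strands` component of [encode_archive()]).
#' @param weights Non-negative per-strand copy weights (default uniform).
#' @return An object of class `electrode`.
#' @export
electrode <- function(id, pool, weights = rep(1, nrow(pool))) {
  stopifnot(is.data.frame(pool), all(c("index", "sequence") %in% names(pool)),
            nrow(pool) >= 1L, all(weights >= 0), length(weights) == nrow(pool))
  structure(list(id = id, pool = pool, weights = weights), class = "electrode")
}

#' Read-channel parameters
#'
#' @param substitution,deletion,insertion Per-base error rates in `[0, 1]`.
#' @param crossover Probability that a read originates from an inactive
#'   electrode.
#' @param depth_mean Mean reads per strand (> 0).
#' @param depth_dispersion Negative-binomial size parameter of the per-strand
#'   depth distribution (larger = closer to Poisson).
#' @return An object of class `channel_params`.
#' @export
channel_params <- function(substitution = 0.003, deletion = 0.0015,
                           insertion = 0, crossover = 0,
                           depth_mean = 30, depth_dispersion = 10) {
  rates <- c(substitution, deletion, insertion, crossover)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (depth_mean <= 0) stop("mean depth must be positive")
  structure(list(substitution = substitution, deletion = deletion,
                 insertion = insertion, crossover = crossover,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion),
            class = "channel_params")
}

BASES <- c("A", "C", "G", "T")

# apply per-base substitution/deletion/insertion to one sequence; returns
# list(seq, n_sub, n_del, n_ins)
mutate_sequence <- function(seq, p_sub, p_del, p_ins) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  n_sub <- stats::rbinom(1L, L, p_sub)
  if (n_sub > 0L) {
    pos <- sample.int(L, n_sub)
    ch[pos] <- vapply(ch[pos],
                      function(b) sample(setdiff(BASES, b), 1L), character(1L))
  }
  n_del <- stats::rbinom(1L, L, p_del)
  if (n_del > 0L) ch <- ch[-sample.int(L, n_del)]
  n_ins <- if (p_ins > 0) stats::rbinom(1L, length(ch) + 1L, p_ins) else 0L
  if (n_ins > 0L) {
    at <- sample.int(length(ch) + 1L, n_ins, replace = TRUE)
    for (a in sort(at, decreasing = TRUE))
      ch <- append(ch, sample(BASES, 1L), after = a - 1L)
  }
  list(seq = paste(ch, collapse = ""), n_sub = n_sub, n_del = n_del,
       n_ins = n_ins)
}

#' Simulate reads from an electrode array
#'
#' For every strand on every active electrode, a read count is drawn from a
#' negative-binomial depth distribution whose mean is scaled by the
#' remaining copy fraction at the given reuse cycle. Each read then
#' crosses over to a uniformly chosen inactive electrode with the
#' configured probability, and per-base substitution, deletion and
#' insertion errors are applied independently. Ground truth (true source
#' electrode, index and injected error counts) is retained per read.
#'
#' @param electrodes List of [electrode()] objects.
#' @param active Vector of active electrode ids (non-empty).
#' @param params A [channel_params()].
#' @param cycle Reuse cycle count at which the pool is accessed.
#' @param model Optional [degradation_model()]; when supplied, depth means
#'   are scaled by `remaining_copies(model, cycle) / N0`.
#' @param seed Integer seed; identical inputs and seed give a bit-identical
#'   read set.
#' @return A `read_set`: data.frame with `id`, `sequence`, `quality`,
#'   `electrode`, `index`, `crossover`, `n_sub`, `n_del`, `n_ins`.
#' @export
simulate_reads <- function(electrodes, active, params = channel_params(),
                           cycle = 0L, model = NULL, seed = 1L) {
  ids <- vapply(electrodes, function(e) as.character(e$id), character(1L))
  if (!length(active)) stop("configuration error: active electrode set is empty")
  if (!all(as.character(active) %in% ids))
    stop("configuration error: unknown active electrode id")
  act <- which(ids %in% as.character(active))
  inact <- setdiff(seq_along(electrodes), act)
  scale <- if (is.null(model)) 1 else remaining_copies(model, cycle) / model$N0

  with_seed(seed, {
    # per-strand depths on active electrodes
    tmpl <- do.call(rbind, lapply(act, function(e) {
      p <- electrodes[[e]]$pool
      data.frame(electrode = ids[e], index = p$index, sequence = p$sequence,
                 stringsAsFactors = FALSE)
    }))
    counts <- stats::rnbinom(nrow(tmpl), size = params$depth_dispersion,
                             mu = params$depth_mean * scale)
    rows <- rep(seq_len(nrow(tmpl)), counts)
    reads <- tmpl[rows, , drop = FALSE]
    n <- nrow(reads)
    crossed <- logical(n)
    if (params$crossover > 0 && length(inact) && n) {
      crossed <- stats::runif(n) < params$crossover
      if (any(crossed)) {
        src_e <- sample(inact, sum(crossed), replace = TRUE)
        pick <- vapply(src_e, function(e) {
          p <- electrodes[[e]]$pool
          sample.int(nrow(p), 1L, prob = electrodes[[e]]$weights)
        }, integer(1L))
        reads$electrode[crossed] <- ids[src_e]
        reads$index[crossed] <- vapply(seq_along(src_e), function(i)
          electrodes[[src_e[i]]]$pool$index[pick[i]], reads$index[1L])
        reads$sequence[crossed] <- vapply(seq_along(src_e), function(i)
          electrodes[[src_e[i]]]$pool$sequence[pick[i]], character(1L))
      }
    }
    n_sub <- n_del <- n_ins <- integer(n)
    if (n && (params$substitution > 0 || params$deletion > 0 ||
              params$insertion > 0)) {
      for (i in seq_len(n)) {
        mu <- mutate_sequence(reads$sequence[i], params$substitution,
                              params$deletion, params$insertion)
        reads$sequence[i] <- mu$seq
        n_sub[i] <- mu$n_sub; n_del[i] <- mu$n_del; n_ins[i] <- mu$n_ins
      }
    }
    out <- data.frame(id = sprintf("read_%06d", seq_len(n)),
                      sequence = reads$sequence,
                      quality = strrep("?", nchar(reads$sequence)),  # Q30
                      electrode = reads$electrode, index = reads$index,
                      crossover = crossed,
                      n_sub = n_sub, n_del = n_del, n_ins = n_ins,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("read_set", "data.frame")
    out
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read set: %d reads, %d indices, %d electrode(s)\n",
              nrow(x), length(unique(x$index)),
              length(unique(x$electrode))))
  invisible(x)
}
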