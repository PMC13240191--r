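#' Modified-IQR outlier policy
#'
#' Repair rule for reconstructed numeric series whose strands could not be
#' recovered: values flagged as unrecovered and lying outside
#' `[Q1 - k * IQR, Q3 + k * IQR]` are treated as outliers. The shipped
#' multiplier is `k = 0.55`, tighter than the conventional 1.5 because the
#' flagged values are already known to be suspect.
#'
#' @param k IQR multiplier (> 0).
#' @param quantile_type Quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @param replacement `"clamp"` (replace with the violated bound) or
#'   `"median"`.
#' @return An object of class `outlier_policy`.
#' @export
outlier_policy <- function(k = 0.55, quantile_type = 7L,
                           replacement = c("clamp", "median")) {
  stopifnot(k > 0)
  structure(list(k = k, quantile_type = as.integer(quantile_type),
                 replacement = match.arg(replacement)),
            class = "outlier_policy")
}

#' Adjust flagged outliers by the modified-IQR rule
#'
#' Computes `Q1`, `Q3` and `IQR` over all values, bounds
#' `Q1 - k * IQR` and `Q3 + k * IQR`, and repairs only those values that are
#' both flagged (e.g. XOR-unrecovered) and out of bounds. In-bound and
#' unflagged values are never touched.
#'
#' @param values Numeric vector (length >= 4 for quantile estimation).
#' @param flags Logical vector marking repair candidates; defaults to all.
#' @param policy An [outlier_policy()].
#' @return List with `values` (adjusted), `outliers` (logical), `lower`,
#'   `upper`.
#' @examples
#' adjust_outliers_iqr(c(1, 2, 3, 4, 100))   # upper bound 4 + 0.55*2 = 5.1
#' @export
adjust_outliers_iqr <- function(values, flags = rep(TRUE, length(values)),
                                policy = outlier_policy()) {
  if (length(values) < 4L)
    stop("at least 4 values are required for quantile estimation")
  stopifnot(length(flags) == length(values))
  qs <- stats::quantile(values, c(0.25, 0.75), names = FALSE,
                        type = policy$quantile_type)
  iqr <- qs[2L] - qs[1L]
  lower <- qs[1L] - policy$k * iqr
  upper <- qs[2L] + policy$k * iqr
  outliers <- flags & (values < lower | values > upper)
  adjusted <- values
  if (any(outliers)) {
    if (policy$replacement == "clamp") {
      adjusted[outliers & values < lower] <- lower
      adjusted[outliers & values > upper] <- upper
    } else {
      adjusted[outliers] <- stats::median(values[!outliers])
    }
  }
  list(values = adjusted, outliers = outliers, lower = lower, upper = upper)
}
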