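# Compendium-level normalization: global scaling of each array to a common
# trimmed-mean target (the cross-normalization convention for MAS5-style
# signal), the log2 transform, and detection-call filtering.

#' Global-scaling configuration
#'
#' @param target_value Positive target for each array's trimmed mean after
#'   scaling, in signal units. Default 1000, the compendium convention.
#' @param trim_fraction Fraction in `[0, 0.5)` of values removed from each
#'   end of a column (by count, floor-rounded) before taking the mean.
#'   Default 0.02, the Affymetrix scaling convention.
#' @return A `scaling_config` list.
#' @export
scaling_config <- function(target_value = 1000, trim_fraction = 0.02) {
  stopifnot(is.numeric(target_value), length(target_value) == 1,
            target_value > 0,
            is.numeric(trim_fraction), length(trim_fraction) == 1,
            trim_fraction >= 0, trim_fraction < 0.5)
  structure(list(target_value = target_value, trim_fraction = trim_fraction),
            class = "scaling_config")
}

# Two-sided trimmed mean: drops floor(n * trim) values from each end.
trimmed_mean <- function(x, trim) {
  n <- length(x)
  k <- floor(n * trim)
  if (k > 0) {
    s <- sort(x)
    x <- s[(k + 1):(n - k)]
  }
  mean(x)
}

#' Scale each array to a common trimmed-mean target
#'
#' Multiplies every column of a linear-scale matrix by
#' `target_value / trimmed_mean(column)`, so that afterwards each column's
#' trimmed mean equals the target to machine precision. Columns are scaled
#' independently; the operation is idempotent.
#'
#' @param matrix A linear-scale [expression_matrix()].
#' @param config A [scaling_config()].
#' @return A linear-scale `expression_matrix` with rescaled columns.
#' @export
global_scale <- function(matrix, config = scaling_config()) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(config, "scaling_config"))
  if (matrix$scale != "linear") {
    stop("global scaling applies to linear-scale signal", call. = FALSE)
  }
  tm <- apply(matrix$values, 2, trimmed_mean, trim = config$trim_fraction)
  if (any(tm <= 0)) {
    stop(sprintf("non-positive trimmed mean in sample '%s'",
                 colnames(matrix$values)[which(tm <= 0)[1]]), call. = FALSE)
  }
  scaled <- sweep(matrix$values, 2, config$target_value / tm, `*`)
  expression_matrix(scaled, "linear")
}

#' Log2-transform a linear-scale matrix
#'
#' @param matrix A linear-scale [expression_matrix()] (all values > 0).
#' @return The elementwise log2 matrix, scale tag `"log2"`.
#' @export
log_transform <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$scale != "linear") {
    stop("matrix is already on the log2 scale", call. = FALSE)
  }
  bad <- which(matrix$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("cannot log-transform value <= 0 at probe '%s', sample '%s'",
                 rownames(matrix$values)[bad[1, 1]],
                 colnames(matrix$values)[bad[1, 2]]), call. = FALSE)
  }
  expression_matrix(log2(matrix$values), "log2")
}

#' Filter probes by Present-call fraction
#'
#' Keeps probes whose fraction of `"P"` calls over all samples of the matrix
#' is at least `min_present_fraction` (inclusive). Marginal calls count as
#' not Present.
#'
#' @param calls A [detection_calls()] object.
#' @param min_present_fraction Fraction in `[0, 1]`; default 0.10 ("Present
#'   in at least ten percent of arrays").
#' @return Character vector of retained probe ids.
#' @export
detection_filter <- function(calls, min_present_fraction = 0.10) {
  stopifnot(inherits(calls, "detection_calls"),
            is.numeric(min_present_fraction),
            min_present_fraction >= 0, min_present_fraction <= 1)
  frac <- rowMeans(calls$calls == "P")
  rownames(calls$calls)[frac >= min_present_fraction]
}

# Present fraction per probe, used for candidate reports.
present_fraction <- function(calls) {
  rowMeans(calls$calls == "P")
}
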