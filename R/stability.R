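# The core search: rank probes by the sample standard deviation of their
# log2 signal within a chosen selection of arrays, constrain candidates to an
# expression band, and return the lowest-SD survivors.

#' Per-probe stability statistics within a sample selection
#'
#' Computes, for every probe, the mean, median and sample standard deviation
#' (n - 1 denominator) of log2 signal over exactly the selected samples, and
#' ranks probes ascending by SD. Ties in SD break deterministically by probe
#' id (byte order).
#'
#' @param matrix A log2-scale [expression_matrix()].
#' @param selection Character vector of sample ids (>= 2); default all
#'   samples.
#' @return A data.frame of class `stability_table`, sorted by rank, with
#'   columns `probe_id`, `n_samples`, `mean`, `median`, `sd`, `rank`.
#' @export
compute_stability <- function(matrix, selection = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$scale != "log2") {
    stop("stability is computed on the log2 scale; use log_transform() first",
         call. = FALSE)
  }
  all_ids <- colnames(matrix$values)
  if (is.null(selection)) selection <- all_ids
  unknown <- setdiff(selection, all_ids)
  if (length(unknown) > 0) {
    stop(sprintf("unknown sample id in selection: '%s'", unknown[1]),
         call. = FALSE)
  }
  if (anyDuplicated(selection)) {
    stop("duplicate sample id in selection", call. = FALSE)
  }
  if (length(selection) < 2) {
    stop("stability needs at least 2 samples (SD undefined otherwise)",
         call. = FALSE)
  }
  x <- matrix$values[, selection, drop = FALSE]
  tab <- data.frame(
    probe_id = rownames(x),
    n_samples = length(selection),
    mean = rowMeans(x),
    median = row_medians(x),
    sd = row_sds(x),
    stringsAsFactors = FALSE)
  ord <- order(tab$sd, id_order_key(tab$probe_id))
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab, class = c("stability_table", "data.frame"),
            selection = selection)
}

#' Construct a stability table directly
#'
#' Low-level constructor for a pre-computed per-probe stability table, mainly
#' useful for feeding externally derived rankings into the overlap analyses.
#' Rows are (re)sorted ascending by `sd` with the same probe-id tie-break as
#' [compute_stability()] and ranks reassigned.
#'
#' @param df A data.frame with at least `probe_id` and `sd` columns.
#' @return A `stability_table`.
#' @export
stability_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("probe_id", "sd") %in% names(df)))
  check_axis_ids(df$probe_id, "probe")
  if (any(df$sd < 0)) stop("sd must be >= 0", call. = FALSE)
  ord <- order(df$sd, id_order_key(df$probe_id))
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df, class = c("stability_table", "data.frame"))
}

#' Expression band
#'
#' An interval of log2 signal within which candidate reference genes are
#' sought, so that candidates match the abundance of the target genes.
#'
#' @param lower,upper Band bounds in log2 units; `-Inf` / `Inf` for an
#'   unbounded side.
#' @param platform_iqr Optional `(q1, q3)` of all probe medians, carried
#'   along when the band derives from the platform-wide distribution.
#' @return An `expression_band` list.
#' @export
expression_band <- function(lower = -Inf, upper = Inf, platform_iqr = NULL) {
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1,
            length(upper) == 1, !is.na(lower), !is.na(upper))
  if (lower > upper) stop("band lower bound exceeds upper bound",
                          call. = FALSE)
  structure(list(lower = lower, upper = upper, platform_iqr = platform_iqr),
            class = "expression_band")
}

#' Medium expression band of a platform
#'
#' Computes every probe's median log2 signal over all samples and returns the
#' interquartile range of those medians as the "medium" band: low expression
#' is below the first quartile, high is above the third. Quantiles use linear
#' interpolation (type 7).
#'
#' @param matrix A log2-scale [expression_matrix()] with >= 4 probes.
#' @return An [expression_band()] with `lower = q1`, `upper = q3` and
#'   `platform_iqr = c(q1, q3)`.
#' @export
expression_band_from_platform <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$scale != "log2") {
    stop("expression bands are defined on the log2 scale", call. = FALSE)
  }
  if (nrow(matrix$values) < 4) {
    stop("need at least 4 probes to estimate the platform IQR", call. = FALSE)
  }
  med <- row_medians(matrix$values)
  q <- stats::quantile(med, c(0.25, 0.75), names = FALSE, type = 7)
  expression_band(q[1], q[2], platform_iqr = q)
}

#' Search for candidate reference genes
#'
#' The core search: within the selected samples, probes are filtered to those
#' whose median log2 signal lies inside the expression band (inclusive at
#' both bounds) and, if detection calls are supplied, to those passing
#' [detection_filter()]; the `k` survivors with the lowest SD are returned,
#' ranked ascending by SD with probe-id tie-break.
#'
#' @param matrix A log2-scale [expression_matrix()].
#' @param selection Sample ids defining the biological context; default all.
#' @param band An [expression_band()], or `NULL` for no abundance constraint.
#' @param k Number of candidates to return (default 25, the tool's printed
#'   behaviour).
#' @param calls Optional [detection_calls()] paired with `matrix`.
#' @param min_present_fraction Present-call threshold used when `calls` is
#'   given; default 0.10.
#' @return A data.frame of class `candidate_list` with columns `probe_id`,
#'   `median`, `mean`, `sd`, `rank`, `present_fraction` (NA without calls),
#'   sorted ascending by SD. If fewer than `k` probes survive the filters,
#'   all survivors are returned, a warning is raised and the attribute
#'   `truncated` is `TRUE`.
#' @export
find_reference_genes <- function(matrix, selection = NULL, band = NULL,
                                 k = 25, calls = NULL,
                                 min_present_fraction = 0.10) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  k <- as.integer(k)
  stab <- compute_stability(matrix, selection)
  keep <- rep(TRUE, nrow(stab))
  if (!is.null(band)) {
    stopifnot(inherits(band, "expression_band"))
    keep <- stab$median >= band$lower & stab$median <= band$upper
  }
  pf <- rep(NA_real_, nrow(stab))
  if (!is.null(calls)) {
    stopifnot(inherits(calls, "detection_calls"))
    check_calls_match(calls, matrix)
    detected <- detection_filter(calls, min_present_fraction)
    keep <- keep & stab$probe_id %in% detected
    pf <- present_fraction(calls)[stab$probe_id]
  }
  stab$present_fraction <- pf
  surv <- stab[keep, , drop = FALSE]
  if (nrow(surv) == 0) stop("no probes in expression band", call. = FALSE)
  truncated <- nrow(surv) < k
  if (truncated) {
    warning(sprintf("only %d probes survive the filters (k = %d requested)",
                    nrow(surv), k))
  }
  out <- utils::head(surv, k)
  out$rank <- seq_len(nrow(out))
  out <- out[, c("probe_id", "median", "mean", "sd", "rank",
                 "present_fraction")]
  rownames(out) <- NULL
  structure(out, class = c("candidate_list", "data.frame"), k = k,
            truncated = truncated)
}

#' @export
print.candidate_list <- function(x, ...) {
  cat(sprintf("<candidate_list> top %d of k = %d requested%s\n", nrow(x),
              attr(x, "k"),
              if (isTRUE(attr(x, "truncated"))) " (truncated)" else ""))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Advice on the size of a sample selection
#'
#' Purely advisory check of the recommendation to base a search on at least
#' three independent studies comprising at least 60 arrays in total. Never
#' blocks a search.
#'
#' @param annotations An [annotation_table()] with an `experiment_id` axis.
#' @param selection Sample ids of the intended search context.
#' @return A list with `n_samples`, `n_experiments`, and inclusive boolean
#'   flags `enough_samples` (>= 60) and `enough_experiments` (>= 3).
#' @export
selection_advice <- function(annotations, selection) {
  stopifnot(inherits(annotations, "annotation_table"))
  if (!"experiment_id" %in% names(annotations)) {
    stop("annotations need an 'experiment_id' axis for study counting",
         call. = FALSE)
  }
  unknown <- setdiff(selection, annotations$sample_id)
  if (length(unknown) > 0) {
    stop(sprintf("sample '%s' is not annotated", unknown[1]), call. = FALSE)
  }
  rows <- annotations[annotations$sample_id %in% selection, , drop = FALSE]
  n_samples <- length(unique(selection))
  n_experiments <- length(unique(rows$experiment_id))
  list(n_samples = n_samples,
       n_experiments = n_experiments,
       enough_samples = n_samples >= 60,
       enough_experiments = n_experiments >= 3)
}
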