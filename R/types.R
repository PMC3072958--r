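# Shared domain containers. All structural validation happens at construction
# so the statistical code downstream can assume well-formed inputs.

#' Expression matrix container
#'
#' Holds a probe-by-sample signal matrix together with an explicit scale tag.
#' Compendium exports are ambiguous about whether stored signal is linear or
#' log; the tag makes the scale explicit and every operation checks it.
#' Linear-scale values must be strictly positive (so a log2 transform is
#' always defined) and no missing cells are allowed on either scale.
#'
#' @param values Numeric matrix with unique, non-empty rownames (probe ids)
#'   and colnames (sample ids).
#' @param scale `"linear"` (signal intensity, arbitrary units) or `"log2"`.
#' @return An object of class `expression_matrix` with fields `values` and
#'   `scale`.
#' @seealso [read_expression_matrix()], [log_transform()], [global_scale()]
#' @examples
#' m <- matrix(c(100, 200, 300, 400), 2, 2,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' expression_matrix(m, "linear")
#' @export
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  check_axis_ids(rownames(values), "probe")
  check_axis_ids(colnames(values), "sample")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("missing or non-finite value at probe '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
         call. = FALSE)
  }
  if (scale == "linear") {
    bad <- which(values <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "linear-scale signal must be > 0; offending probe '%s', sample '%s'",
        rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
        call. = FALSE)
    }
  }
  structure(list(values = values, scale = scale), class = "expression_matrix")
}

check_axis_ids <- function(ids, what) {
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop(sprintf("%s ids must be present and non-empty", what), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate %s id: '%s'", what, ids[duplicated(ids)][1]),
         call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d probes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Probe and sample identifiers
#'
#' Accessors for the axis identifiers of the package's matrix-like containers.
#'
#' @param x An `expression_matrix`, `detection_calls` or `cq_table`.
#' @return Character vector of ids.
#' @export
probe_ids <- function(x) {
  if (inherits(x, "cq_table")) rownames(x$cq) else rownames(x$values %||% x$calls)
}

#' @rdname probe_ids
#' @export
sample_ids <- function(x) {
  if (inherits(x, "cq_table")) colnames(x$cq) else colnames(x$values %||% x$calls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detection-call matrix (Present / Marginal / Absent)
#'
#' Per-probe, per-sample detection flags as produced by Affymetrix-style
#' summarization. Only `"P"` counts as detected; `"M"` and `"A"` do not.
#'
#' @param calls Character matrix over `{"P", "M", "A"}` with probe rownames
#'   and sample colnames.
#' @return An object of class `detection_calls`.
#' @seealso [detection_filter()]
#' @export
detection_calls <- function(calls) {
  if (!is.matrix(calls) || !is.character(calls)) {
    stop("'calls' must be a character matrix", call. = FALSE)
  }
  check_axis_ids(rownames(calls), "probe")
  check_axis_ids(colnames(calls), "sample")
  if (!all(calls %in% c("P", "M", "A"))) {
    stop("detection calls must be one of 'P', 'M', 'A'", call. = FALSE)
  }
  structure(list(calls = calls), class = "detection_calls")
}

#' @export
print.detection_calls <- function(x, ...) {
  cat(sprintf("<detection_calls> %d probes x %d samples (%.1f%% Present)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(x$calls == "P")))
  invisible(x)
}

# Asserts that a detection_calls object is paired with the given
# expression_matrix (identical ids in identical order).
check_calls_match <- function(calls, matrix) {
  if (!identical(rownames(calls$calls), rownames(matrix$values)) ||
      !identical(colnames(calls$calls), colnames(matrix$values))) {
    stop("detection calls do not match the expression matrix ids",
         call. = FALSE)
  }
  invisible(calls)
}

#' Sample annotation table
#'
#' One row per sample, with categorical annotation axes such as `anatomy`,
#' `development`, `perturbation` and `experiment_id`. Arbitrary additional
#' axes are preserved. `experiment_id`, when present, must be non-empty for
#' every sample: it underlies the "independent studies" count in
#' [selection_advice()].
#'
#' @param df A data.frame whose first column is `sample_id`.
#' @return A data.frame of class `annotation_table`.
#' @export
annotation_table <- function(df) {
  if (!is.data.frame(df) || ncol(df) < 1) {
    stop("annotations must be a data.frame with a sample_id column",
         call. = FALSE)
  }
  if (names(df)[1] != "sample_id") {
    stop("the first annotation column must be named 'sample_id'",
         call. = FALSE)
  }
  df[] <- lapply(df, as.character)
  check_axis_ids(df$sample_id, "sample")
  if ("experiment_id" %in% names(df) &&
      any(is.na(df$experiment_id) | !nzchar(df$experiment_id))) {
    stop("experiment_id must be non-empty for every sample", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' RT-qPCR quantification-cycle table
#'
#' Replicate-averaged Cq values, genes by samples. Lower Cq means higher
#' transcript abundance. The downstream stability algorithms (GeNorm,
#' NormFinder) are undefined for fewer than two genes or two samples.
#'
#' @param cq Numeric matrix of finite Cq values with gene rownames and sample
#'   colnames.
#' @param replicate_counts Optional integer matrix of the same shape giving
#'   the number of technical replicates averaged into each cell.
#' @return An object of class `cq_table`.
#' @seealso [read_cq_table()], [cq_to_relative_quantity()]
#' @export
cq_table <- function(cq, replicate_counts = NULL) {
  if (!is.matrix(cq) || !is.numeric(cq)) {
    stop("'cq' must be a numeric matrix", call. = FALSE)
  }
  check_axis_ids(rownames(cq), "gene")
  check_axis_ids(colnames(cq), "sample")
  if (nrow(cq) < 2 || ncol(cq) < 2) {
    stop("a Cq table needs at least 2 genes and 2 samples", call. = FALSE)
  }
  if (any(!is.finite(cq))) {
    bad <- which(!is.finite(cq), arr.ind = TRUE)
    stop(sprintf("non-finite Cq for gene '%s', sample '%s'",
                 rownames(cq)[bad[1, 1]], colnames(cq)[bad[1, 2]]),
         call. = FALSE)
  }
  if (!is.null(replicate_counts)) {
    stopifnot(is.matrix(replicate_counts),
              dim(replicate_counts) == dim(cq))
    storage.mode(replicate_counts) <- "integer"
    dimnames(replicate_counts) <- dimnames(cq)
  }
  structure(list(cq = cq, replicate_counts = replicate_counts),
            class = "cq_table")
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf("<cq_table> %d genes x %d samples\n", nrow(x$cq), ncol(x$cq)))
  invisible(x)
}

# Internal RNG scoping: runs `expr` under a seed without disturbing the
# caller's RNG state. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Deterministic (byte-order) ranking key for character ids, used to break
# statistical ties reproducibly across platforms and locales.
id_order_key <- function(ids) {
  match(ids, sort(unique(ids), method = "radix"))
}

# Row means / medians / sample SDs (n - 1 denominator), vectorised.
row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  v <- (rowSums(x * x) - n * m * m) / (n - 1)
  sqrt(pmax(v, 0))
}

row_medians <- function(x) {
  apply(x, 1, stats::median)
}
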