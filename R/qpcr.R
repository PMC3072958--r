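# RT-qPCR validation layer: delta-Ct relative quantities, the GeNorm M-value
# with iterative exclusion of the least stable gene, an ungrouped NormFinder
# stability estimate, and panel-level summaries comparing novel candidates to
# commonly used reference genes.

#' Delta-Ct relative quantities
#'
#' Converts Cq values to relative quantities per gene:
#' `rq(g, s) = E_g ^ (min_s' Cq(g, s') - Cq(g, s))`, so the sample with the
#' lowest Cq (highest abundance) gets rq exactly 1 and every other sample a
#' value in (0, 1].
#'
#' @param cq A [cq_table()].
#' @param efficiency Amplification efficiency per gene: a single value or a
#'   vector named by gene id, each in `(1, 2]`. Default 2.0 (perfect
#'   doubling per cycle).
#' @return An `rq_table` list with fields `rq` (gene-by-sample matrix),
#'   `efficiency` (named per-gene vector).
#' @export
cq_to_relative_quantity <- function(cq, efficiency = 2.0) {
  stopifnot(inherits(cq, "cq_table"))
  genes <- rownames(cq$cq)
  if (length(efficiency) == 1 && is.null(names(efficiency))) {
    efficiency <- stats::setNames(rep(efficiency, length(genes)), genes)
  }
  if (!all(genes %in% names(efficiency))) {
    stop("efficiency must cover every gene", call. = FALSE)
  }
  efficiency <- efficiency[genes]
  if (any(efficiency <= 1 | efficiency > 2)) {
    stop("amplification efficiency must lie in (1, 2]", call. = FALSE)
  }
  dct <- apply(cq$cq, 1, min) - cq$cq          # min_s' Cq - Cq, per gene
  rq <- efficiency ^ dct
  dimnames(rq) <- dimnames(cq$cq)
  structure(list(rq = rq, efficiency = efficiency), class = "rq_table")
}

#' @export
print.rq_table <- function(x, ...) {
  cat(sprintf("<rq_table> %d genes x %d samples\n", nrow(x$rq), ncol(x$rq)))
  invisible(x)
}

#' GeNorm expression-stability measure M
#'
#' For each gene `j`, M is the mean over partner genes `k != j` of
#' `V_jk`, the sample standard deviation across samples of the pairwise log2
#' ratio `log2(rq_j / rq_k)`. Lower M means more stable. Computed via the
#' covariance identity `V_jk^2 = var(L_j) + var(L_k) - 2 cov(L_j, L_k)` on
#' `L = log2(rq)`.
#'
#' @param rq An `rq_table` from [cq_to_relative_quantity()].
#' @param genes Optional gene subset (>= 3 genes).
#' @return Named numeric vector of M values.
#' @export
genorm_m <- function(rq, genes = NULL) {
  stopifnot(inherits(rq, "rq_table"))
  if (is.null(genes)) genes <- rownames(rq$rq)
  unknown <- setdiff(genes, rownames(rq$rq))
  if (length(unknown) > 0) {
    stop(sprintf("unknown gene '%s'", unknown[1]), call. = FALSE)
  }
  if (length(genes) < 3) {
    stop("GeNorm M needs at least 3 genes", call. = FALSE)
  }
  if (ncol(rq$rq) < 2) stop("GeNorm M needs at least 2 samples",
                            call. = FALSE)
  L <- log2(rq$rq[genes, , drop = FALSE])
  C <- stats::cov(t(L))
  d <- diag(C)
  V <- sqrt(pmax(outer(d, d, `+`) - 2 * C, 0))
  stats::setNames(rowSums(V) / (length(genes) - 1), genes)
}

# M for exactly 2 genes (the terminal GeNorm pair): each gene's only partner
# is the other, so both get V_12.
genorm_m_pair <- function(rq, genes) {
  L <- log2(rq$rq[genes, , drop = FALSE])
  v <- stats::sd(L[1, ] - L[2, ])
  stats::setNames(c(v, v), genes)
}

#' GeNorm ranking by iterative exclusion
#'
#' Repeatedly computes M on the remaining genes and removes the gene with
#' the highest M (ties break by gene id, byte order, and are flagged),
#' recording after each removal the mean M of the surviving genes ("Avg M"),
#' until two genes remain.
#'
#' @param rq An `rq_table` with at least 3 genes.
#' @return A `genorm_result` list: `iterations` (one entry per evaluated
#'   gene set, each with `genes`, `m`, `excluded`), `exclusion_order`
#'   (least stable first), `final_pair`, `avg_m` (data.frame `n_remaining`,
#'   `avg_m`: the Avg-M trajectory, mean M of the genes remaining after each
#'   removal), and `ties` (logical: any tie encountered).
#' @export
genorm_rank <- function(rq) {
  stopifnot(inherits(rq, "rq_table"))
  remaining <- rownames(rq$rq)
  if (length(remaining) < 3) {
    stop("GeNorm ranking needs at least 3 genes", call. = FALSE)
  }
  iterations <- list()
  exclusion_order <- character()
  ties <- FALSE
  repeat {
    m <- if (length(remaining) > 2) genorm_m(rq, remaining)
         else genorm_m_pair(rq, remaining)
    if (length(remaining) == 2) {
      iterations[[length(iterations) + 1]] <-
        list(genes = remaining, m = m, excluded = NA_character_)
      break
    }
    worst_val <- max(m)
    worst <- names(m)[m == worst_val]
    if (length(worst) > 1) {
      ties <- TRUE
      worst <- worst[order(id_order_key(worst))]
    }
    excluded <- worst[1]
    iterations[[length(iterations) + 1]] <-
      list(genes = remaining, m = m, excluded = excluded)
    exclusion_order <- c(exclusion_order, excluded)
    remaining <- setdiff(remaining, excluded)
  }
  avg_m <- data.frame(
    n_remaining = vapply(iterations[-1], function(it) length(it$genes), 1L),
    avg_m = vapply(iterations[-1], function(it) mean(it$m), 1.0))
  structure(list(iterations = iterations,
                 exclusion_order = exclusion_order,
                 final_pair = remaining,
                 avg_m = avg_m,
                 ties = ties),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("<genorm_result>\n")
  cat("  exclusion order (least stable first):",
      paste(x$exclusion_order, collapse = ", "), "\n")
  cat("  final pair:", paste(x$final_pair, collapse = ", "), "\n")
  cat("  Avg M after each removal:",
      paste(sprintf("%.3f", x$avg_m$avg_m), collapse = ", "), "\n")
  if (x$ties) cat("  note: M ties were broken by gene id\n")
  invisible(x)
}

#' Ungrouped NormFinder stability
#'
#' Decomposes log2 relative quantities into gene and sample effects by
#' double-centering (subtracting gene means and sample means, adding back
#' the grand mean) and scores each gene by the sample standard deviation of
#' its residuals — the ungrouped model-variance estimate. Lower is more
#' stable.
#'
#' @param rq An `rq_table` with >= 3 genes and >= 3 samples.
#' @return A `normfinder_result`: named numeric vector of stabilities
#'   (log2 units, >= 0) with attribute `model = "ungrouped"`.
#' @export
normfinder_stability <- function(rq) {
  stopifnot(inherits(rq, "rq_table"))
  y <- log2(rq$rq)
  if (nrow(y) < 3 || ncol(y) < 3) {
    stop("NormFinder needs at least 3 genes and 3 samples", call. = FALSE)
  }
  z <- y - rowMeans(y)
  z <- sweep(z, 2, colMeans(z), `-`)      # grand mean re-added implicitly
  stab <- apply(z, 1, stats::sd)
  structure(stab, model = "ungrouped", class = "normfinder_result")
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("<normfinder_result> (ungrouped model), stability per gene:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

# Per-gene stability from a genorm_result: a gene's M at the iteration where
# it was excluded; the final pair keeps its terminal M.
gene_stability <- function(result) {
  if (inherits(result, "normfinder_result")) {
    return(stats::setNames(as.numeric(result), names(result)))
  }
  stopifnot(inherits(result, "genorm_result"))
  out <- numeric()
  for (it in result$iterations) {
    if (!is.na(it$excluded)) {
      out[it$excluded] <- it$m[[it$excluded]]
    } else {
      out[it$genes] <- it$m[it$genes]
    }
  }
  out
}

#' Compare a novel candidate panel to a common reference panel
#'
#' Summarises a GeNorm or NormFinder result by panel: mean stability per
#' label group, mean Cq per group (when a Cq table is supplied), and the
#' three most stable genes overall. For a GeNorm result, a gene's stability
#' is its M at the iteration where it was excluded (terminal M for the final
#' pair), and "most stable" follows the exclusion order from the end.
#'
#' @param result A `genorm_result` or `normfinder_result`.
#' @param panel_labels Character vector naming each gene's panel, named by
#'   gene id, with values such as `"novel"` and `"common"`. Every gene in
#'   the result must be labelled.
#' @param cq Optional [cq_table()] for per-panel mean Cq.
#' @return A list with `group_summary` (data.frame `panel`, `n`,
#'   `mean_stability`, `mean_cq`) and `top3` (character vector). Label
#'   groups named in `panel_labels` but empty in the result are kept with
#'   `n = 0` and flagged via the `empty_groups` attribute.
#' @export
compare_panels <- function(result, panel_labels, cq = NULL) {
  stab <- gene_stability(result)
  genes <- names(stab)
  unlabelled <- setdiff(genes, names(panel_labels))
  if (length(unlabelled) > 0) {
    stop(sprintf("gene '%s' has no panel label", unlabelled[1]),
         call. = FALSE)
  }
  labels <- panel_labels[genes]
  groups <- unique(unname(panel_labels))
  mean_cq_gene <- NULL
  if (!is.null(cq)) {
    stopifnot(inherits(cq, "cq_table"))
    if (!all(genes %in% rownames(cq$cq))) {
      stop("Cq table does not cover every gene in the result", call. = FALSE)
    }
    mean_cq_gene <- rowMeans(cq$cq[genes, , drop = FALSE])
  }
  group_summary <- do.call(rbind, lapply(groups, function(g) {
    members <- genes[labels == g]
    data.frame(
      panel = g, n = length(members),
      mean_stability = if (length(members)) mean(stab[members]) else NA_real_,
      mean_cq = if (!is.null(mean_cq_gene) && length(members))
        mean(mean_cq_gene[members]) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  if (inherits(result, "genorm_result")) {
    ranking <- c(result$final_pair[order(stab[result$final_pair])],
                 rev(result$exclusion_order))
  } else {
    ranking <- genes[order(stab, id_order_key(genes))]
  }
  top3 <- utils::head(ranking, 3)
  empty <- group_summary$panel[group_summary$n == 0]
  if (length(empty) > 0) {
    warning(sprintf("panel group(s) with no genes in the result: %s",
                    paste(empty, collapse = ", ")))
  }
  structure(list(group_summary = group_summary, top3 = top3),
            empty_groups = empty)
}
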