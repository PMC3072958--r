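# Cross-context analyses: annotation-driven sample selection, per-category SD
# profiling of candidates, overlap of top-N stable gene lists between
# contexts with a resampling significance test, rank-SD progression, and
# suggestion of related contexts by expression-profile correlation.

#' Select samples by annotation query
#'
#' Returns the samples matching a conjunction of `axis = value` clauses, in
#' the (deterministic) order of the annotation table. An empty query returns
#' all samples; contradictory clauses return an empty set.
#'
#' @param annotations An [annotation_table()].
#' @param query Named character vector, e.g. `c(anatomy = "liver")`.
#' @return Character vector of sample ids.
#' @export
select_samples <- function(annotations, query = character()) {
  stopifnot(inherits(annotations, "annotation_table"))
  if (length(query) == 0) return(annotations$sample_id)
  if (is.null(names(query)) || any(!nzchar(names(query)))) {
    stop("query clauses must be named by annotation axis", call. = FALSE)
  }
  unknown <- setdiff(names(query), names(annotations))
  if (length(unknown) > 0) {
    stop(sprintf("unknown annotation axis '%s'", unknown[1]), call. = FALSE)
  }
  keep <- rep(TRUE, nrow(annotations))
  for (axis in names(query)) {
    keep <- keep & annotations[[axis]] == query[[axis]]
  }
  annotations$sample_id[keep]
}

#' Per-category SD profile of candidate probes
#'
#' Computes, for each candidate probe, the SD of log2 signal within every
#' category of an annotation axis, flagging categories where a nominally
#' stable gene varies strongly. Categories with fewer than 2 samples are
#' skipped and recorded.
#'
#' @param matrix A log2-scale [expression_matrix()].
#' @param candidates Character vector of probe ids to profile.
#' @param annotations An [annotation_table()] covering the matrix samples.
#' @param axis Annotation axis defining the categories (e.g. `"anatomy"`).
#' @param flag_sd_threshold SD (log2 units) above which a (probe, category)
#'   cell is flagged as highly variable. Default 1.0, a package convention.
#' @return A data.frame of class `condition_profile` with columns
#'   `probe_id`, `category`, `n_samples`, `sd`, `flagged`; attribute
#'   `skipped` lists categories dropped for having < 2 samples, attribute
#'   `summary` gives per-probe counts of flagged categories.
#' @export
cross_condition_profile <- function(matrix, candidates, annotations, axis,
                                    flag_sd_threshold = 1.0) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(annotations, "annotation_table"))
  if (matrix$scale != "log2") {
    stop("profiles are computed on the log2 scale", call. = FALSE)
  }
  if (!axis %in% names(annotations)) {
    stop(sprintf("unknown annotation axis '%s'", axis), call. = FALSE)
  }
  missing_probe <- setdiff(candidates, rownames(matrix$values))
  if (length(missing_probe) > 0) {
    stop(sprintf("probe '%s' not in matrix", missing_probe[1]), call. = FALSE)
  }
  ann <- annotations[annotations$sample_id %in% colnames(matrix$values), ,
                     drop = FALSE]
  categories <- unique(ann[[axis]])
  rows <- list()
  skipped <- character()
  for (cat_i in categories) {
    ids <- ann$sample_id[ann[[axis]] == cat_i]
    if (length(ids) < 2) {
      skipped <- c(skipped, cat_i)
      next
    }
    x <- matrix$values[candidates, ids, drop = FALSE]
    rows[[cat_i]] <- data.frame(
      probe_id = candidates, category = cat_i, n_samples = length(ids),
      sd = row_sds(x), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    stop("no category on this axis has >= 2 samples", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$flagged <- out$sd > flag_sd_threshold
  rownames(out) <- NULL
  summary <- stats::aggregate(flagged ~ probe_id, data = out, FUN = sum)
  names(summary)[2] <- "n_flagged"
  structure(out, class = c("condition_profile", "data.frame"),
            skipped = skipped, summary = summary,
            flag_sd_threshold = flag_sd_threshold)
}

top_n_ids <- function(stab, n) {
  stopifnot(inherits(stab, "stability_table"))
  stab$probe_id[stab$rank <= n]
}

#' Overlap of top-N stable genes between contexts
#'
#' Counts, for every pair of contexts, how many probes their top-N most
#' stable lists share. The result is symmetric with diagonal `n`.
#'
#' @param stability_by_context Named list of `stability_table`s over the
#'   same probe universe, one per context.
#' @param n List size (top-N).
#' @return An integer context-by-context matrix of class `overlap_counts`
#'   with attribute `n`.
#' @export
top_n_overlap <- function(stability_by_context, n) {
  stopifnot(is.list(stability_by_context),
            length(stability_by_context) >= 2,
            !is.null(names(stability_by_context)),
            is.numeric(n), length(n) == 1, n >= 1)
  universe <- sort(stability_by_context[[1]]$probe_id, method = "radix")
  for (s in stability_by_context) {
    if (!identical(sort(s$probe_id, method = "radix"), universe)) {
      stop("all stability tables must cover the same probe universe",
           call. = FALSE)
    }
  }
  if (n > length(universe)) {
    stop("n exceeds the number of probes", call. = FALSE)
  }
  tops <- lapply(stability_by_context, top_n_ids, n = n)
  ctx <- names(stability_by_context)
  m <- matrix(0L, length(ctx), length(ctx), dimnames = list(ctx, ctx))
  for (i in seq_along(ctx)) {
    for (j in seq_along(ctx)) {
      m[i, j] <- length(intersect(tops[[i]], tops[[j]]))
    }
  }
  structure(m, class = c("overlap_counts", class(m)), n = as.integer(n))
}

#' Combined top-20 / top-50 overlap matrix
#'
#' Convenience wrapper computing two [top_n_overlap()] matrices at once, the
#' layout used to compare overlaps at a stringent and a relaxed list size
#' (top 20 in the upper triangle, top 50 in the lower, when printed).
#'
#' @param stability_by_context Named list of `stability_table`s.
#' @param n_top Two list sizes, default `c(20, 50)`.
#' @return An `overlap_matrix` list with fields `context_ids`, `counts_topA`,
#'   `counts_topB`, `list_sizes`.
#' @export
overlap_matrix <- function(stability_by_context, n_top = c(20, 50)) {
  stopifnot(length(n_top) == 2)
  a <- top_n_overlap(stability_by_context, n_top[1])
  b <- top_n_overlap(stability_by_context, n_top[2])
  structure(list(context_ids = names(stability_by_context),
                 counts_topA = a, counts_topB = b,
                 list_sizes = as.integer(n_top)),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  m <- unclass(x$counts_topB)
  attr(m, "n") <- NULL
  m[upper.tri(m)] <- unclass(x$counts_topA)[upper.tri(m)]
  diag(m) <- NA
  cat(sprintf("<overlap_matrix> top %d (upper) / top %d (lower)\n",
              x$list_sizes[1], x$list_sizes[2]))
  print(m, ...)
  invisible(x)
}

#' Resampling significance of one context pair's overlap
#'
#' Tests whether the observed overlap of one pair of contexts is high
#' relative to the empirical population of overlaps among the remaining
#' contexts. The null population is the multiset of off-diagonal overlap
#' values excluding every pair that contains either tested context (to avoid
#' leakage); each permutation draws one value from it with replacement, and
#' `p = (1 + #\{null >= observed\}) / (n_permutations + 1)`.
#'
#' @param overlaps An `overlap_counts` matrix from [top_n_overlap()].
#' @param pair Character vector of the two context ids to test.
#' @param n_permutations Number of resampling draws, default 100000.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A `permutation_result` list with `observed`, `null_mean`,
#'   `null_sd` (of the null population), `p_value`, `n_permutations`, `seed`.
#' @export
overlap_permutation_test <- function(overlaps, pair,
                                     n_permutations = 100000, seed = NULL) {
  stopifnot(inherits(overlaps, "overlap_counts"),
            length(pair) == 2, n_permutations >= 1)
  ctx <- rownames(overlaps)
  if (length(ctx) < 3) {
    stop("need at least 3 contexts for a meaningful null population",
         call. = FALSE)
  }
  if (!all(pair %in% ctx)) {
    stop("tested pair not among the overlap matrix contexts", call. = FALSE)
  }
  if (pair[1] == pair[2]) stop("pair must name two distinct contexts",
                               call. = FALSE)
  observed <- overlaps[pair[1], pair[2]]
  rest <- setdiff(ctx, pair)
  if (length(rest) < 2) {
    stop(paste("excluding the tested pair leaves no context pairs to form",
               "the null population; need at least 4 contexts"),
         call. = FALSE)
  }
  sub <- unclass(overlaps)[rest, rest, drop = FALSE]
  population <- sub[upper.tri(sub)]
  null_draws <- with_seed(seed, sample(population, n_permutations,
                                       replace = TRUE))
  p <- (1 + sum(null_draws >= observed)) / (n_permutations + 1)
  structure(list(observed = observed,
                 null_mean = mean(population),
                 null_sd = stats::sd(population),
                 p_value = p,
                 n_permutations = as.integer(n_permutations),
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed = %d, null mean = %.2f (SD %.2f), p = %.4g (%d draws)\n",
    x$observed, x$null_mean, x$null_sd, x$p_value, x$n_permutations))
  invisible(x)
}

#' SD increase along the stability ranking
#'
#' Percentage increase of the SD at selected ranks relative to the SD of the
#' most stable probe: `100 * (sd(rank r) - sd(rank 1)) / sd(rank 1)`.
#'
#' @param table A `stability_table`.
#' @param ranks Ranks to report, default `c(1, 20, 50, 100, 200)`.
#' @return A data.frame with columns `rank`, `sd`, `pct_increase`. If the
#'   rank-1 SD is zero the progression is undefined: `pct_increase` is `NA`,
#'   a warning is raised and the attribute `undefined` is `TRUE`.
#' @export
rank_sd_progression <- function(table, ranks = c(1, 20, 50, 100, 200)) {
  stopifnot(inherits(table, "stability_table"))
  if (max(ranks) > nrow(table)) {
    stop("requested rank exceeds the number of probes", call. = FALSE)
  }
  sds <- table$sd[match(ranks, table$rank)]
  base <- table$sd[table$rank == 1]
  if (base == 0) {
    warning("rank-1 SD is zero; progression undefined")
    pct <- rep(NA_real_, length(ranks))
  } else {
    pct <- 100 * (sds - base) / base
  }
  structure(data.frame(rank = ranks, sd = sds, pct_increase = pct),
            undefined = base == 0)
}

#' Suggest contexts related to a target context
#'
#' When too few arrays exist for a context, the search can be widened to
#' related contexts. Relatedness is estimated by drawing `n_gene_sets`
#' random subsets of `set_size` probes, computing each context's mean log2
#' expression profile over each subset, correlating the target context's
#' profile with every other context (Pearson, across the subset's genes),
#' and averaging the correlations over subsets.
#'
#' @param matrix A log2-scale [expression_matrix()].
#' @param annotations An [annotation_table()] covering the matrix samples.
#' @param axis Annotation axis defining the contexts.
#' @param target_context The context to find relatives of.
#' @param n_gene_sets Number of random gene subsets, default 10.
#' @param set_size Genes per subset, default 400.
#' @param seed Optional integer seed; results are reproducible for a fixed
#'   seed.
#' @return A data.frame with columns `context`, `mean_correlation`, sorted
#'   descending by correlation; attribute `excluded` lists contexts dropped
#'   for having < 2 samples.
#' @export
related_contexts <- function(matrix, annotations, axis, target_context,
                             n_gene_sets = 10, set_size = 400, seed = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(annotations, "annotation_table"))
  if (matrix$scale != "log2") {
    stop("profiles are computed on the log2 scale", call. = FALSE)
  }
  if (!axis %in% names(annotations)) {
    stop(sprintf("unknown annotation axis '%s'", axis), call. = FALSE)
  }
  ann <- annotations[annotations$sample_id %in% colnames(matrix$values), ,
                     drop = FALSE]
  sizes <- table(ann[[axis]])
  if (!target_context %in% names(sizes)) {
    stop(sprintf("target context '%s' not found on axis '%s'",
                 target_context, axis), call. = FALSE)
  }
  usable <- names(sizes)[sizes >= 2]
  excluded <- setdiff(names(sizes), usable)
  if (!target_context %in% usable) {
    stop("target context has fewer than 2 samples", call. = FALSE)
  }
  others <- setdiff(usable, target_context)
  if (length(others) == 0) stop("no other context to compare against",
                                call. = FALSE)
  n_probes <- nrow(matrix$values)
  if (set_size > n_probes) {
    stop("set_size exceeds the number of probes", call. = FALSE)
  }
  ctx_samples <- split(ann$sample_id, ann[[axis]])
  cors <- with_seed(seed, {
    acc <- matrix(NA_real_, n_gene_sets, length(others),
                  dimnames = list(NULL, others))
    for (g in seq_len(n_gene_sets)) {
      genes <- sample(n_probes, set_size)
      prof <- vapply(c(target_context, others), function(ct) {
        rowMeans(matrix$values[genes, ctx_samples[[ct]], drop = FALSE])
      }, numeric(set_size))
      tgt <- prof[, 1]
      for (ct in others) {
        if (stats::sd(tgt) > 0 && stats::sd(prof[, ct]) > 0) {
          acc[g, ct] <- stats::cor(tgt, prof[, ct])
        }
      }
    }
    acc
  })
  mean_r <- colMeans(cors, na.rm = TRUE)
  out <- data.frame(context = names(mean_r), mean_correlation = mean_r,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_correlation, id_order_key(out$context)), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, excluded = excluded)
}
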