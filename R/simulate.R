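# Synthetic data with planted ground truth: a multi-context expression
# compendium (log-normal signal, context effects, experiment batch effects,
# planted context-stable and housekeeping-like genes) and replicate-free
# Cq experiments with a known noise ranking.

#' Configuration for a synthetic expression compendium
#'
#' All signal parameters are in log2 units. The generative model for probe
#' `g` in sample `s` (context `c(s)`, experiment `e(s)`) is
#' `y(g, s) = mu_g + tau(g, c(s)) + beta(e(s)) + eps(g, s)`.
#' Background probes draw `mu_g ~ N(baseline_mean, baseline_sd)` and a
#' per-gene noise SD uniform over `noise_sd_range` (spanning, by default,
#' the 0.5–5 range typical of compendium-wide SD distributions); context
#' effects are `tau ~ N(0, context_effect_sd)` per (gene, context).
#' Context-stable probes have noise SD `stable_sd` and `tau = 0` within
#' their own context, background behaviour elsewhere. Housekeeping-like
#' probes draw `mu_g ~ N(housekeeping_mean, 0.3)`, have `tau = 0`
#' everywhere, and per-gene noise SDs spread uniformly over a
#' `housekeeping_sd_spread`-fold range geometrically centred on
#' `housekeeping_sd` (a panel of nominally stable genes whose actual
#' stabilities differ several-fold). Batch effects `beta ~ N(0, batch_sd)`
#' are shared by all genes of an experiment.
#'
#' @param n_probes Number of probes.
#' @param contexts Named integer vector: samples per context, e.g.
#'   `c(liver = 60, brain = 60)`.
#' @param n_context_stable Planted stable genes per context (default 20).
#' @param n_housekeeping Planted housekeeping-like genes (default 20).
#' @param baseline_mean_log2,baseline_sd_log2 Background abundance
#'   distribution (defaults 9.0, 1.2).
#' @param stable_sd_log2 Noise SD of planted stable genes inside their
#'   context (default 0.25).
#' @param noise_sd_range_log2 Range of background per-gene noise SDs
#'   (default `c(0.5, 5)`).
#' @param housekeeping_mean_log2 Abundance centre of housekeeping-like genes
#'   (default 13.0: very highly expressed).
#' @param housekeeping_sd_log2 Geometric centre of housekeeping noise SDs
#'   (default 0.6).
#' @param housekeeping_sd_spread Fold-range of housekeeping noise SDs
#'   (default 5).
#' @param context_effect_sd_log2 SD of context effects (default 1.0).
#' @param experiment_batch_sd_log2 SD of experiment batch effects
#'   (default 0.3).
#' @param experiments_per_context Experiments each context's samples are
#'   split over (default 3).
#' @param seed Optional integer seed; the simulation is fully determined by
#'   it.
#' @return A `compendium_config` list.
#' @export
compendium_config <- function(n_probes,
                              contexts,
                              n_context_stable = 20,
                              n_housekeeping = 20,
                              baseline_mean_log2 = 9.0,
                              baseline_sd_log2 = 1.2,
                              stable_sd_log2 = 0.25,
                              noise_sd_range_log2 = c(0.5, 5),
                              housekeeping_mean_log2 = 13.0,
                              housekeeping_sd_log2 = 0.6,
                              housekeeping_sd_spread = 5,
                              context_effect_sd_log2 = 1.0,
                              experiment_batch_sd_log2 = 0.3,
                              experiments_per_context = 3,
                              seed = NULL) {
  stopifnot(n_probes >= 1,
            length(contexts) >= 1, all(contexts >= 1),
            !is.null(names(contexts)), all(nzchar(names(contexts))),
            !anyDuplicated(names(contexts)),
            n_context_stable >= 0, n_housekeeping >= 0,
            baseline_sd_log2 >= 0, stable_sd_log2 >= 0,
            length(noise_sd_range_log2) == 2,
            noise_sd_range_log2[1] > 0,
            noise_sd_range_log2[2] >= noise_sd_range_log2[1],
            housekeeping_sd_log2 >= 0, housekeeping_sd_spread >= 1,
            context_effect_sd_log2 >= 0, experiment_batch_sd_log2 >= 0,
            experiments_per_context >= 1)
  if (n_context_stable * length(contexts) + n_housekeeping > n_probes) {
    stop("planted genes exceed the number of probes", call. = FALSE)
  }
  structure(list(n_probes = as.integer(n_probes),
                 contexts = contexts,
                 n_context_stable = as.integer(n_context_stable),
                 n_housekeeping = as.integer(n_housekeeping),
                 baseline_mean_log2 = baseline_mean_log2,
                 baseline_sd_log2 = baseline_sd_log2,
                 stable_sd_log2 = stable_sd_log2,
                 noise_sd_range_log2 = noise_sd_range_log2,
                 housekeeping_mean_log2 = housekeeping_mean_log2,
                 housekeeping_sd_log2 = housekeeping_sd_log2,
                 housekeeping_sd_spread = housekeeping_sd_spread,
                 context_effect_sd_log2 = context_effect_sd_log2,
                 experiment_batch_sd_log2 = experiment_batch_sd_log2,
                 experiments_per_context = as.integer(experiments_per_context),
                 seed = seed),
            class = "compendium_config")
}

#' Simulate a multi-context expression compendium
#'
#' Generates a log2-scale expression matrix with planted context-stable and
#' housekeeping-like genes, matching detection calls (a probe is called
#' `"P"` in a sample iff its linear signal exceeds the 10th percentile of
#' all simulated linear signals), a sample annotation table (axes `anatomy`,
#' `development`, `perturbation`, `experiment_id`), and the ground truth.
#' Fully determined by `config$seed`.
#'
#' @param config A [compendium_config()].
#' @return A list with elements `matrix` ([expression_matrix()], log2),
#'   `calls` ([detection_calls()]), `annotations` ([annotation_table()]),
#'   and `truth` (list: `stable_genes` — probe ids per context,
#'   `housekeeping_genes`, `noise_sd` per probe per context, `config`).
#' @export
simulate_compendium <- function(config) {
  stopifnot(inherits(config, "compendium_config"))
  with_seed(config$seed, {
    n <- config$n_probes
    ctx_names <- names(config$contexts)
    n_ctx <- length(ctx_names)
    probes <- sprintf("probe_%05d", seq_len(n))

    # sample layout: round-robin over experiments within each context
    sample_ctx <- rep(ctx_names, times = config$contexts)
    exp_within <- unlist(lapply(config$contexts, function(m) {
      rep_len(seq_len(config$experiments_per_context), m)
    }), use.names = FALSE)
    experiment <- paste0(sample_ctx, "_exp", exp_within)
    samples <- paste0(sample_ctx, "_s",
                      unlist(lapply(config$contexts, seq_len),
                             use.names = FALSE))

    # planted gene roles (disjoint by construction)
    free <- seq_len(n)
    hk_idx <- sort(sample(free, config$n_housekeeping))
    free <- setdiff(free, hk_idx)
    stable_idx <- list()
    for (ct in ctx_names) {
      pick <- sort(sample(free, config$n_context_stable))
      stable_idx[[ct]] <- pick
      free <- setdiff(free, pick)
    }

    mu <- stats::rnorm(n, config$baseline_mean_log2, config$baseline_sd_log2)
    mu[hk_idx] <- stats::rnorm(length(hk_idx),
                               config$housekeeping_mean_log2, 0.3)

    # per-gene, per-context noise SD
    base_sd <- stats::runif(n, config$noise_sd_range_log2[1],
                            config$noise_sd_range_log2[2])
    hk_lo <- config$housekeeping_sd_log2 / sqrt(config$housekeeping_sd_spread)
    hk_hi <- config$housekeeping_sd_log2 * sqrt(config$housekeeping_sd_spread)
    base_sd[hk_idx] <- stats::runif(length(hk_idx), hk_lo, hk_hi)
    sd_mat <- matrix(base_sd, n, n_ctx, dimnames = list(probes, ctx_names))
    for (ct in ctx_names) {
      sd_mat[stable_idx[[ct]], ct] <- config$stable_sd_log2
    }

    tau <- matrix(stats::rnorm(n * n_ctx, 0, config$context_effect_sd_log2),
                  n, n_ctx, dimnames = list(probes, ctx_names))
    for (ct in ctx_names) tau[stable_idx[[ct]], ct] <- 0
    tau[hk_idx, ] <- 0

    experiments <- unique(experiment)
    beta <- stats::setNames(
      stats::rnorm(length(experiments), 0, config$experiment_batch_sd_log2),
      experiments)

    eps <- matrix(stats::rnorm(n * length(samples)), n, length(samples)) *
      sd_mat[, sample_ctx, drop = FALSE]
    y <- mu + tau[, sample_ctx, drop = FALSE] +
      matrix(beta[experiment], n, length(samples), byrow = TRUE) + eps
    dimnames(y) <- list(probes, samples)

    lin <- 2^y
    thr <- stats::quantile(lin, 0.10, names = FALSE, type = 7)
    calls <- ifelse(lin > thr, "P", "A")

    ann <- annotation_table(data.frame(
      sample_id = samples,
      anatomy = sample_ctx,
      development = "unspecified",
      perturbation = "none",
      experiment_id = experiment,
      stringsAsFactors = FALSE))

    truth <- list(
      stable_genes = lapply(stable_idx, function(i) probes[i]),
      housekeeping_genes = probes[hk_idx],
      noise_sd = sd_mat,
      config = config)

    list(matrix = expression_matrix(y, "log2"),
         calls = detection_calls(calls),
         annotations = ann,
         truth = truth)
  })
}

#' Simulate a replicate-averaged Cq experiment
#'
#' Generates `Cq(g, s) = base_g + delta_s + eta(g, s)` with per-gene noise
#' `eta ~ N(0, noise_sd_g)` and a shared per-sample loading/input effect
#' `delta_s ~ N(0, sample_effect_sd)` — the component that reference-gene
#' normalization is meant to remove. Gene baselines are drawn uniformly over
#' `base_cq_range`.
#'
#' @param n_genes Number of genes (>= 3).
#' @param n_samples Number of samples (>= 3).
#' @param noise_sd Per-gene noise SD in cycles; single value or vector of
#'   length `n_genes`.
#' @param sample_effect_sd SD in cycles of the shared sample effect
#'   (default 1.0).
#' @param base_cq_range Range of per-gene baseline Cq (default
#'   `c(18, 28)`).
#' @param seed Optional integer seed.
#' @return A list with `cq` (a [cq_table()]) and `truth` (list: `noise_sd`
#'   named per gene, `ranking` gene ids from least to most noisy,
#'   `sample_effect` the drawn per-sample effects).
#' @export
simulate_cq_experiment <- function(n_genes, n_samples, noise_sd,
                                   sample_effect_sd = 1.0,
                                   base_cq_range = c(18, 28), seed = NULL) {
  stopifnot(n_genes >= 3, n_samples >= 3,
            all(noise_sd >= 0), sample_effect_sd >= 0)
  noise_sd <- rep_len(noise_sd, n_genes)
  genes <- sprintf("gene_%02d", seq_len(n_genes))
  names(noise_sd) <- genes
  samples <- sprintf("sample_%02d", seq_len(n_samples))
  with_seed(seed, {
    base <- stats::runif(n_genes, base_cq_range[1], base_cq_range[2])
    delta <- stats::rnorm(n_samples, 0, sample_effect_sd)
    eta <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples) *
      noise_sd
    cqm <- base + matrix(delta, n_genes, n_samples, byrow = TRUE) + eta
    dimnames(cqm) <- list(genes, samples)
    list(cq = cq_table(cqm),
         truth = list(noise_sd = noise_sd,
                      ranking = genes[order(noise_sd, id_order_key(genes))],
                      sample_effect = stats::setNames(delta, samples)))
  })
}
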