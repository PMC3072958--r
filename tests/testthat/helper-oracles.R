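# Independent brute-force oracles and small fixture generators. These stay
# deliberately naive (explicit loops, stats:: primitives) so they cannot
# share code paths with the implementation they check.

random_log2_matrix <- function(n_probes, n_samples, mean = 9, sd = 1.5) {
  vals <- matrix(rnorm(n_probes * n_samples, mean, sd), n_probes,
                 dimnames = list(sprintf("p%04d", seq_len(n_probes)),
                                 sprintf("s%03d", seq_len(n_samples))))
  expression_matrix(vals, "log2")
}

random_linear_matrix <- function(n_probes, n_samples) {
  vals <- matrix(2^rnorm(n_probes * n_samples, 9, 1.5), n_probes,
                 dimnames = list(sprintf("p%04d", seq_len(n_probes)),
                                 sprintf("s%03d", seq_len(n_samples))))
  expression_matrix(vals, "linear")
}

# Filter-then-sort reimplementation of find_reference_genes.
brute_force_candidates <- function(matrix, selection = NULL, band = NULL,
                                   k = 25, calls = NULL,
                                   min_present_fraction = 0.10) {
  x <- matrix$values
  if (!is.null(selection)) x <- x[, selection, drop = FALSE]
  med <- apply(x, 1, median)
  sds <- apply(x, 1, sd)
  keep <- rep(TRUE, nrow(x))
  if (!is.null(band)) keep <- med >= band$lower & med <= band$upper
  if (!is.null(calls)) {
    pfrac <- apply(calls$calls, 1, function(r) mean(r == "P"))
    keep <- keep & pfrac >= min_present_fraction
  }
  ids <- rownames(x)[keep]
  o <- order(sds[keep], match(ids, sort(ids, method = "radix")))
  head(data.frame(probe_id = ids[o], sd = sds[keep][o],
                  median = med[keep][o], row.names = NULL), k)
}

# Double-loop GeNorm M on log2 relative quantities.
brute_force_genorm_m <- function(rq_matrix, genes = rownames(rq_matrix)) {
  L <- log2(rq_matrix[genes, , drop = FALSE])
  m <- numeric(length(genes))
  names(m) <- genes
  for (j in genes) {
    vs <- c()
    for (k in setdiff(genes, j)) {
      vs <- c(vs, sd(L[j, ] - L[k, ]))
    }
    m[j] <- mean(vs)
  }
  m
}

random_rq_table <- function(n_genes, n_samples) {
  cqm <- matrix(runif(n_genes * n_samples, 18, 30), n_genes,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
  cq_to_relative_quantity(cq_table(cqm))
}

# Stability table with an arbitrary (externally imposed) SD ordering:
# probes listed first in `ordered_ids` get the smallest SDs.
stability_from_order <- function(universe, ordered_ids) {
  sds <- seq(0.2, 1.2, length.out = length(universe))
  df <- data.frame(probe_id = c(ordered_ids,
                                setdiff(universe, ordered_ids)),
                   sd = sds, stringsAsFactors = FALSE)
  stability_table(df)
}

# Random top-N ordering over a fixed universe (exchangeable-null fixture).
random_stability <- function(universe) {
  stability_table(data.frame(probe_id = universe,
                             sd = runif(length(universe)),
                             stringsAsFactors = FALSE))
}
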