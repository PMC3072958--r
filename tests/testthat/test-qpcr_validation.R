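# Delta-Ct quantities, GeNorm M and ranking, ungrouped NormFinder, and the
# novel-vs-common panel comparison.

mk_cq <- function(vals, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(vals)))
  samples <- samples %||% sprintf("s%02d", seq_len(ncol(vals)))
  dimnames(vals) <- list(genes, samples)
  cq_table(vals)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("delta-Ct relative quantities follow E^(minCq - Cq)", {
  cq <- mk_cq(rbind(c(20, 21, 23), c(25, 25, 26)))
  rq <- cq_to_relative_quantity(cq)          # E = 2
  expect_equal(unname(rq$rq[1, ]), c(1, 0.5, 0.125))
  expect_equal(max(rq$rq[2, ]), 1)           # lowest-Cq sample is exactly 1

  rq19 <- cq_to_relative_quantity(cq, efficiency = 1.9)
  expect_equal(rq19$rq[1, 2], 1 / 1.9, tolerance = 1e-15)

  expect_error(cq_to_relative_quantity(cq, efficiency = 2.1), "\\(1, 2\\]")
  expect_error(cq_to_relative_quantity(cq, efficiency = 1.0), "\\(1, 2\\]")

  # per-gene efficiencies, named
  rqv <- cq_to_relative_quantity(cq, c(g01 = 2, g02 = 1.8))
  expect_equal(rqv$rq[2, 3], 1.8^-1, tolerance = 1e-15)
})

test_that("GeNorm M matches its definition and invariances", {
  # two proportional genes: constant log-ratio, so V between them is 0
  cq <- mk_cq(rbind(c(20, 21, 22, 23),
                    c(24, 25, 26, 27),
                    c(20, 26, 21, 24)))
  rq <- cq_to_relative_quantity(cq)
  L <- log2(rq$rq)
  expect_equal(sd(L[1, ] - L[2, ]), 0)
  m <- genorm_m(rq)
  expect_equal(m[["g01"]], m[["g02"]], tolerance = 1e-12)
  expect_lt(m[["g01"]], m[["g03"]])

  # rescaling one gene's rq leaves every M unchanged
  set.seed(51)
  rq2 <- random_rq_table(6, 10)
  m_before <- genorm_m(rq2)
  rq3 <- rq2
  rq3$rq["g02", ] <- rq3$rq["g02", ] * 0.125
  expect_equal(genorm_m(rq3), m_before, tolerance = 1e-12)

  # sample permutation invariance
  perm <- sample(ncol(rq2$rq))
  rq4 <- rq2
  rq4$rq <- rq4$rq[, perm]
  expect_equal(genorm_m(rq4), m_before, tolerance = 1e-12)

  expect_error(genorm_m(rq2, genes = c("g01", "g02")), "at least 3")
})

test_that("GeNorm M equals the brute-force double loop on random tables", {
  set.seed(52)
  for (r in 1:30) {
    n_g <- sample(3:12, 1)
    n_s <- sample(4:30, 1)
    rq <- random_rq_table(n_g, n_s)
    expect_equal(genorm_m(rq), brute_force_genorm_m(rq$rq),
                 tolerance = 1e-12)
  }
})

test_that("GeNorm ranking excludes planted noise and records the trajectory", {
  # two proportional genes plus one noisy: the noisy gene goes first
  set.seed(53)
  base <- runif(8, 20, 24)
  cqm <- rbind(base, base + 3, base + rnorm(8, 0, 1.5))
  res <- genorm_rank(cq_to_relative_quantity(mk_cq(cqm)))
  expect_identical(res$exclusion_order[1], "g03")
  expect_setequal(res$final_pair, c("g01", "g02"))
  expect_equal(nrow(res$avg_m), 1)
  expect_equal(length(res$iterations), 2)

  # planted instability gradient: exclusion order matches the plant
  hits <- 0
  for (r in 1:100) {
    sim <- simulate_cq_experiment(6, 16, noise_sd = 0.1 * 3^(0:5),
                                  seed = 5300 + r)
    res <- genorm_rank(cq_to_relative_quantity(sim$cq))
    expected <- rev(sim$truth$ranking)[1:4]   # noisiest first
    if (identical(res$exclusion_order, expected)) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.90)
})

test_that("Avg M drops when the removed gene's M exceeds the survivor mean", {
  set.seed(54)
  for (r in 1:20) {
    rq <- random_rq_table(sample(4:8, 1), 12)
    res <- genorm_rank(rq)
    for (i in seq_len(length(res$iterations) - 1)) {
      it <- res$iterations[[i]]
      nxt <- res$iterations[[i + 1]]
      # direct recomputation of the recorded trajectory
      expect_equal(res$avg_m$avg_m[i], mean(nxt$m), tolerance = 1e-12)
      if (it$m[[it$excluded]] > mean(it$m[names(it$m) != it$excluded])) {
        expect_lte(mean(nxt$m),
                   mean(it$m) + 1e-9)
      }
    }
  }
})

test_that("NormFinder stability is a double-centred residual SD", {
  # genes exactly equal to gene constant + sample effect: all residuals 0
  sample_eff <- c(0, 1, -1, 2, 0.5)
  cqm <- rbind(20 + sample_eff, 24 + sample_eff, 22 + sample_eff)
  rq <- cq_to_relative_quantity(mk_cq(cqm))
  stab <- normfinder_stability(rq)
  expect_equal(unname(unclass(stab)), rep(0, 3), tolerance = 1e-12,
               ignore_attr = TRUE)

  # perturbing one gene makes it the least stable of the three
  cqm[3, ] <- cqm[3, ] + c(0.3, -0.2, 0.1, -0.4, 0.2)
  stab2 <- normfinder_stability(cq_to_relative_quantity(mk_cq(cqm)))
  expect_gt(stab2[["g03"]], max(stab2[["g01"]], stab2[["g02"]]))

  # adding a constant to one sample's column leaves stabilities unchanged
  set.seed(55)
  rq2 <- random_rq_table(6, 10)
  stab_before <- normfinder_stability(rq2)
  rq3 <- rq2
  rq3$rq[, 4] <- rq3$rq[, 4] * 2^1.7      # +1.7 log2 units for sample 4
  expect_equal(normfinder_stability(rq3), stab_before, tolerance = 1e-12)

  # per-gene rescaling invariance
  rq4 <- rq2
  rq4$rq["g05", ] <- rq4$rq["g05", ] * 0.01
  expect_equal(normfinder_stability(rq4), stab_before, tolerance = 1e-12)
})

test_that("NormFinder matches an independent two-way ANOVA residual fit", {
  set.seed(56)
  rq <- random_rq_table(6, 10)
  stab <- normfinder_stability(rq)
  df <- data.frame(y = as.vector(log2(rq$rq)),
                   gene = factor(rep(rownames(rq$rq), 10)),
                   sample = factor(rep(colnames(rq$rq), each = 6)))
  fit <- lm(y ~ gene + sample, data = df)
  resid_mat <- matrix(residuals(fit), 6, dimnames = dimnames(rq$rq))
  oracle <- apply(resid_mat, 1, sd)
  expect_equal(unclass(stab)[names(oracle)], oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("panel comparison separates planted low-noise candidates", {
  labels <- c(gene_01 = "novel", gene_02 = "novel", gene_03 = "novel",
              gene_04 = "common", gene_05 = "common", gene_06 = "common")
  wins <- 0
  for (r in 1:100) {
    sim <- simulate_cq_experiment(6, 12,
                                  noise_sd = c(0.15, 0.15, 0.15,
                                               0.6, 0.6, 0.6),
                                  seed = 5600 + r)
    rq <- cq_to_relative_quantity(sim$cq)
    cmp <- compare_panels(genorm_rank(rq), labels, cq = sim$cq)
    gs <- cmp$group_summary
    if (gs$mean_stability[gs$panel == "novel"] <
        gs$mean_stability[gs$panel == "common"]) wins <- wins + 1
  }
  expect_gte(wins / 100, 0.95)

  # group means are plain arithmetic means of member statistics
  sim <- simulate_cq_experiment(6, 12, noise_sd = 0.3, seed = 57)
  rq <- cq_to_relative_quantity(sim$cq)
  nf <- normfinder_stability(rq)
  cmp <- compare_panels(nf, labels, cq = sim$cq)
  gs <- cmp$group_summary
  expect_equal(gs$mean_stability[gs$panel == "novel"],
               mean(unclass(nf)[c("gene_01", "gene_02", "gene_03")]))
  expect_equal(gs$mean_cq[gs$panel == "common"],
               mean(rowMeans(sim$cq$cq)[c("gene_04", "gene_05", "gene_06")]))
  expect_length(cmp$top3, 3)

  # unlabelled gene errors; an empty group is kept and flagged
  expect_error(compare_panels(nf, labels[-1]), "no panel label")
  all_novel <- setNames(rep("novel", 6), names(labels))
  all_novel_plus <- c(all_novel, extra = "common")
  expect_warning(cmp2 <- compare_panels(nf, all_novel_plus), "no genes")
  gs2 <- cmp2$group_summary
  expect_equal(gs2$n[gs2$panel == "common"], 0)
  expect_true(is.na(gs2$mean_stability[gs2$panel == "common"]))
})
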