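# Annotation queries, per-category SD profiling, top-N overlap matrices,
# the resampling significance test, rank-SD progression and related-context
# suggestion.

mk_annotations <- function(ctx_sizes) {
  annotation_table(data.frame(
    sample_id = unlist(lapply(names(ctx_sizes), function(ct) {
      sprintf("%s_s%02d", ct, seq_len(ctx_sizes[[ct]]))
    })),
    anatomy = rep(names(ctx_sizes), unlist(ctx_sizes)),
    experiment_id = "e1",
    stringsAsFactors = FALSE))
}

test_that("annotation queries are conjunctive and tolerate empty results", {
  ann <- annotation_table(data.frame(
    sample_id = sprintf("s%02d", 1:10),
    anatomy = c(rep("liver", 4), rep("brain", 6)),
    development = rep(c("adult", "embryo"), 5),
    experiment_id = "e1", stringsAsFactors = FALSE))
  expect_length(select_samples(ann, c(anatomy = "liver")), 4)
  expect_identical(select_samples(ann), ann$sample_id)
  expect_length(select_samples(ann, c(anatomy = "liver",
                                      development = "adult")), 2)
  # contradictory clauses: empty, not an error
  expect_length(select_samples(ann, c(anatomy = "kidney")), 0)
  expect_error(select_samples(ann, c(tissue = "liver")), "unknown")
})

test_that("cross-condition profiles flag planted category-specific variability", {
  set.seed(41)
  ctx <- list(a = 10, b = 10, c = 10, lone = 1)
  ann <- mk_annotations(ctx)
  n_p <- 30
  vals <- matrix(rnorm(n_p * 31, 9, 0.2), n_p,
                 dimnames = list(sprintf("p%02d", 1:n_p), ann$sample_id))
  vals["p01", ] <- 9                                 # constant everywhere
  b_cols <- grep("^b_", colnames(vals))
  vals["p02", b_cols] <- 9 + 4 * c(-1, 1)[rep_len(1:2, length(b_cols))]
  em <- expression_matrix(vals, "log2")

  prof <- cross_condition_profile(em, c("p01", "p02", "p03"), ann, "anatomy",
                                  flag_sd_threshold = 1.0)
  expect_s3_class(prof, "condition_profile")
  expect_identical(attr(prof, "skipped"), "lone")

  p01 <- prof[prof$probe_id == "p01", ]
  expect_true(all(p01$sd == 0))
  expect_true(all(!p01$flagged))

  p02 <- prof[prof$probe_id == "p02", ]
  # direct SD recomputation for the perturbed category
  expect_equal(p02$sd[p02$category == "b"], sd(vals["p02", b_cols]))
  expect_true(p02$flagged[p02$category == "b"])
  expect_true(all(!p02$flagged[p02$category != "b"]))

  summ <- attr(prof, "summary")
  expect_equal(summ$n_flagged[summ$probe_id == "p02"], 1)
  expect_equal(summ$n_flagged[summ$probe_id == "p01"], 0)
})

test_that("top-N overlap counts are symmetric with diagonal N", {
  universe <- sprintf("p%04d", 1:500)
  s1 <- stability_from_order(universe, universe[1:60])
  s2 <- stability_from_order(universe, universe[1:60])
  s3 <- stability_from_order(universe, universe[101:160])

  om <- top_n_overlap(list(a = s1, b = s2, c = s3), 50)
  expect_equal(om["a", "b"], 50L)         # identical rankings
  expect_equal(om["a", "c"], 0L)          # disjoint top lists
  expect_equal(unname(diag(om)), rep(50L, 3))
  expect_identical(unclass(om), t(unclass(om)))

  expect_error(top_n_overlap(list(a = s1, b = s2), 501), "exceeds")
  both <- overlap_matrix(list(a = s1, b = s2, c = s3))
  expect_equal(both$list_sizes, c(20L, 50L))
  expect_equal(both$counts_topA["a", "c"], 0L)

  # random-list overlap matches the hypergeometric expectation n^2 / N
  set.seed(42)
  reps <- replicate(300, {
    t1 <- sample(universe, 50)
    t2 <- sample(universe, 50)
    length(intersect(t1, t2))
  })
  expect_equal(mean(reps), 50 * 50 / 500, tolerance = 0.1)
})

test_that("the overlap permutation test hits its boundary p-values", {
  universe <- sprintf("p%04d", 1:500)
  set.seed(43)
  stabs <- lapply(setNames(1:6, paste0("ctx", 1:6)),
                  function(i) random_stability(universe))
  om <- top_n_overlap(stabs, 50)

  # force an observed value above every population value
  om2 <- unclass(om)
  om2["ctx1", "ctx2"] <- om2["ctx2", "ctx1"] <- 50L
  om2 <- structure(om2, class = class(om), n = attr(om, "n"))
  res <- overlap_permutation_test(om2, c("ctx1", "ctx2"),
                                  n_permutations = 1000, seed = 7)
  expect_equal(res$p_value, 1 / 1001)
  pop <- unclass(om)[paste0("ctx", 3:6), paste0("ctx", 3:6)]
  pop <- pop[upper.tri(pop)]
  expect_equal(res$null_mean, mean(pop))
  expect_equal(res$null_sd, sd(pop))

  # observed at the population minimum -> p ~ 1
  om3 <- unclass(om)
  om3["ctx1", "ctx2"] <- om3["ctx2", "ctx1"] <- min(pop)
  om3 <- structure(om3, class = class(om), n = attr(om, "n"))
  res3 <- overlap_permutation_test(om3, c("ctx1", "ctx2"),
                                   n_permutations = 1000, seed = 7)
  expect_gt(res3$p_value, 0.9)

  # guard rails
  expect_error(overlap_permutation_test(om, c("ctx1", "nope")), "not among")
  small <- top_n_overlap(stabs[1:3], 50)
  expect_error(overlap_permutation_test(small, c("ctx1", "ctx2")),
               "at least 4")
})

test_that("the permutation test is reproducible and seed-scoped", {
  universe <- sprintf("p%04d", 1:500)
  set.seed(44)
  stabs <- lapply(setNames(1:8, paste0("c", 1:8)),
                  function(i) random_stability(universe))
  om <- top_n_overlap(stabs, 50)
  r1 <- overlap_permutation_test(om, c("c1", "c2"), 2000, seed = 99)
  r2 <- overlap_permutation_test(om, c("c1", "c2"), 2000, seed = 99)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("rank-SD progression mirrors the percent-increase definition", {
  universe <- sprintf("p%03d", 1:300)
  sds <- seq(1.0, 2.5, length.out = 300)
  st <- stability_table(data.frame(probe_id = universe, sd = sds))
  prog <- rank_sd_progression(st, ranks = c(1, 20, 50, 100, 200))
  expect_equal(prog$pct_increase[1], 0)
  expect_equal(prog$pct_increase[2], 100 * (sds[20] - sds[1]) / sds[1])
  expect_true(all(diff(prog$pct_increase) >= 0))

  flat <- stability_table(data.frame(probe_id = universe, sd = rep(1, 300)))
  expect_equal(rank_sd_progression(flat)$pct_increase, rep(0, 5))

  zero <- stability_table(data.frame(probe_id = universe,
                                     sd = c(0, sds[-1])))
  expect_warning(pz <- rank_sd_progression(zero), "undefined")
  expect_true(all(is.na(pz$pct_increase)))
  expect_true(attr(pz, "undefined"))

  expect_error(rank_sd_progression(st, ranks = c(1, 400)), "exceeds")
})

test_that("related contexts rank a duplicated context first and independence near zero", {
  set.seed(45)
  n_p <- 600
  ctx <- list(target = 6, twin = 6, noise1 = 6, noise2 = 6, lone = 1)
  ann <- mk_annotations(ctx)
  # independent mean profiles per context, duplicated for the twin
  base <- lapply(ctx, function(n) rnorm(n_p, 0, 1))
  base$twin <- base$target
  vals <- do.call(cbind, lapply(names(ctx), function(ct) {
    matrix(rep(base[[ct]], ctx[[ct]]), n_p) +
      matrix(rnorm(n_p * ctx[[ct]], 0, 0.05), n_p)
  }))
  dimnames(vals) <- list(sprintf("p%04d", 1:n_p), ann$sample_id)
  em <- expression_matrix(vals, "log2")

  rel <- related_contexts(em, ann, "anatomy", "target",
                          n_gene_sets = 10, set_size = 400, seed = 46)
  expect_identical(rel$context[1], "twin")
  expect_gt(rel$mean_correlation[1], 0.99)
  expect_true(all(abs(rel$mean_correlation[rel$context != "twin"]) < 0.2))
  expect_identical(attr(rel, "excluded"), "lone")

  rel2 <- related_contexts(em, ann, "anatomy", "target",
                           n_gene_sets = 10, set_size = 400, seed = 46)
  expect_identical(rel, rel2)
})

test_that("contexts sharing planted stable genes overlap more than unrelated ones", {
  # two contexts share half their planted stable genes, two share none;
  # the sharing pair's top-20 overlap should exceed the non-sharing pair's
  set.seed(47)
  n_p <- 400
  universe <- sprintf("p%04d", 1:n_p)
  wins <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    planted <- list(a = 1:20, b = c(1:10, 21:30), c = 31:50, d = 51:70)
    vals <- NULL
    ids <- character()
    for (ct in names(planted)) {
      sd_vec <- runif(n_p, 0.6, 1.5)
      sd_vec[planted[[ct]]] <- 0.15
      block <- matrix(rnorm(n_p * 10), n_p) * sd_vec + 9
      vals <- cbind(vals, block)
      ids <- c(ids, sprintf("%s_s%02d", ct, 1:10))
    }
    dimnames(vals) <- list(universe, ids)
    em <- expression_matrix(vals, "log2")
    stabs <- lapply(setNames(names(planted), names(planted)), function(ct) {
      compute_stability(em, grep(paste0("^", ct, "_"), ids, value = TRUE))
    })
    om <- top_n_overlap(stabs, 20)
    if (om["a", "b"] > om["c", "d"]) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.95)
})
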