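test_that("a cohort of identical clones bootstraps with zero variance", {
  bt <- bootstrap_lifetable(clone_cohort(10), B = 50, seed = 1)
  expect_true(all(bt$se[c("R0", "r", "lambda", "T", "GRR", "mean_fecundity",
                          "preadult", "APOP", "TPOP")] == 0))
  expect_equal(unname(bt$mean["R0"]), unname(bt$point["R0"]))
})

test_that("the bootstrap is reproducible under a seed", {
  co <- generate_cohort(cohort_spec(n01 = 50, seed = 6))
  b1 <- bootstrap_lifetable(co, B = 100, seed = 42)
  b2 <- bootstrap_lifetable(co, B = 100, seed = 42)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(b1$mean, b2$mean)
})

test_that("replicates reuse the life-table core: spot equality on resamples", {
  co <- generate_cohort(cohort_spec(n01 = 40, seed = 16))
  set.seed(99)
  for (k in 1:3) {
    idx <- sample.int(n01(co), n01(co), replace = TRUE)
    fast <- agestage:::lt_stats(agestage:::lt_arrays(co), idx)$params
    full <- unlist(population_parameters(cohort_subset(co, idx)))
    expect_equal(fast[names(full)], full)
  }
})

test_that("bootstrap SE of mean fecundity matches the analytic SE", {
  co <- generate_cohort(cohort_spec(n01 = 100, seed = 18))
  s <- individual_summaries(co)
  fec <- s$fecundity[!is.na(s$fecundity)]
  analytic <- sd(fec) / sqrt(length(fec))
  bt <- bootstrap_lifetable(co, B = 5000, seed = 7)
  expect_lt(abs(bt$se["mean_fecundity"] - analytic) / analytic, 0.10)
})

test_that("bootstrap means of linear parameters converge to the point estimates", {
  co <- generate_cohort(cohort_spec(n01 = 100, seed = 19))
  bt <- bootstrap_lifetable(co, B = 5000, seed = 8)
  # linear-in-individuals statistics only: for r, lambda and T the
  # bootstrap bias is O(1/n01) and dominates 2*SE/sqrt(B) at this B
  for (pm in c("R0", "GRR", "mean_fecundity", "preadult", "lifespan")) {
    expect_lt(abs(bt$mean[pm] - bt$point[pm]), 2 * bt$se[pm] / sqrt(bt$B),
              label = paste("bootstrap mean of", pm))
  }
})

test_that("replicates without surviving females are excluded from r but not R0", {
  # tiny cohort with a single female: ~25% of resamples have no female
  co <- toy_fecundity_cohort()
  bt <- bootstrap_lifetable(co, B = 400, seed = 5)
  expect_gt(bt$excluded["r"], 0)
  expect_equal(unname(bt$excluded["R0"]), 0)
  nof <- is.na(bt$replicates[, "r"])
  expect_true(all(bt$replicates[nof, "R0"] == 0))
})

test_that("the paired bootstrap test is symmetric and calibrated on equal inputs", {
  co <- generate_cohort(cohort_spec(n01 = 60, seed = 23))
  a <- bootstrap_lifetable(co, B = 300, seed = 11)
  tst <- paired_bootstrap_test(a, a, "R0")
  expect_equal(tst$estimate, 0)
  expect_equal(tst$p.value, 1)
  b <- bootstrap_lifetable(co, B = 300, seed = 12)
  t1 <- paired_bootstrap_test(a, b, "R0")
  t2 <- paired_bootstrap_test(b, a, "R0")
  expect_equal(t1$estimate, -t2$estimate)
  expect_equal(t1$p.value, t2$p.value)
  expect_true(t1$ci[1] <= t1$estimate && t1$estimate <= t1$ci[2])
  expect_error(paired_bootstrap_test(a, bootstrap_lifetable(co, B = 100), "R0"),
               "equal replicate counts")
})

test_that("strains with strongly different R0 are separated by the paired test", {
  ctrl <- generate_cohort(cohort_spec(n01 = 100), seed = 25)
  trt <- generate_cohort(cohort_spec(n01 = 100, fecundity_mult = 0.5,
                                     preadult_delay = 2), seed = 26)
  a <- bootstrap_lifetable(ctrl, B = 2000, seed = 13)
  b <- bootstrap_lifetable(trt, B = 2000, seed = 14)
  tst <- paired_bootstrap_test(a, b, "R0")
  expect_gt(tst$estimate, 0)
  expect_lt(tst$p.value, 0.05)
})

test_that("the paired test holds its nominal type-I error rate", {
  base <- generate_cohort(cohort_spec(n01 = 50), seed = 30)
  set.seed(31)
  n <- n01(base)
  rejections <- vapply(seq_len(200), function(k) {
    a <- cohort_subset(base, sample.int(n, n, replace = TRUE))
    b <- cohort_subset(base, sample.int(n, n, replace = TRUE))
    tst <- paired_bootstrap_test(bootstrap_lifetable(a, B = 1000),
                                 bootstrap_lifetable(b, B = 1000), "R0")
    tst$p.value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("relative fitness is the R0 ratio against the control", {
  expect_equal(relative_fitness(10, 10), 1)
  expect_equal(round(relative_fitness(20.88, 33.72), 2), 0.62)
  expect_error(relative_fitness(5, 0), "positive")
})

test_that("generation correlations match a direct covariance evaluation", {
  mkboot <- function(vals) {
    structure(list(B = length(vals), parameters = "R0",
                   replicates = matrix(vals, ncol = 1,
                                       dimnames = list(NULL, "R0")),
                   mean = c(R0 = mean(vals)), se = c(R0 = sd(vals)),
                   excluded = c(R0 = 0)),
              class = "lifetable_boot")
  }
  # strictly increasing parameter with zero within-generation spread
  res <- list(`1` = mkboot(rep(1, 10)), `2` = mkboot(rep(2, 10)),
              `3` = mkboot(rep(3, 10)))
  ct <- correlate_with_generation(res, "R0")
  expect_equal(ct$r_pooled, 1)
  expect_equal(ct$r_means, 1)

  # 3 x 10 toy table vs the covariance formula written out by hand
  set.seed(40)
  tab <- lapply(1:3, function(g) rnorm(10, mean = g))
  res2 <- list(`0` = mkboot(tab[[1]]), `4` = mkboot(tab[[2]]),
               `8` = mkboot(tab[[3]]))
  g <- rep(c(0, 4, 8), each = 10)
  v <- unlist(tab)
  hand <- sum((g - mean(g)) * (v - mean(v))) /
    sqrt(sum((g - mean(g))^2) * sum((v - mean(v))^2))
  expect_equal(correlate_with_generation(res2, "R0")$r_pooled, hand)

  # generation-independent parameter: r near 0
  set.seed(41)
  res3 <- list(`1` = mkboot(rnorm(2000)), `2` = mkboot(rnorm(2000)),
               `3` = mkboot(rnorm(2000)))
  expect_lt(abs(correlate_with_generation(res3, "R0")$r_pooled), 0.05)
  expect_error(correlate_with_generation(res3[1], "R0"), "at least 2")
})
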