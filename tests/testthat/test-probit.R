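table2_rows <- function() {
  # published slope / LC25 / LC50 triples used for internal-consistency
  # regression checks (one strain, with slope 0.558 / LC25 4.734 /
  # LC50 36.504, is internally inconsistent — a typographical error —
  # and is deliberately not included)
  data.frame(
    strain = c("SS", "Sub1", "Sub2", "Sub4", "Sub5", "Sub6", "Sub7", "Sub8"),
    slope = c(0.465, 1.213, 1.332, 0.983, 0.923, 0.791, 0.844, 0.947),
    lc25 = c(0.006, 1.873, 2.160, 6.762, 5.906, 4.871, 5.699, 7.426),
    lc50 = c(0.170, 6.741, 6.933, 32.816, 31.722, 34.708, 35.878, 38.313))
}

test_that("probit MLE recovers exact parameters from expected counts", {
  doses <- c(500, 125, 50, 12.5, 3.125, 0.78125)
  dat <- data.frame(concentration = doses, n_treated = 1000,
                    n_dead = 1000 * pnorm(1.2 * (log10(doses) - 1)))
  fit <- probit_fit(dat)
  expect_equal(unname(coef(fit)["slope"]), 1.2, tolerance = 1e-6)
  expect_equal(log10(fit$lc50), 1, tolerance = 1e-6)
  expect_equal(fit$chi2, 0, tolerance = 1e-9)
  expect_equal(fit$heterogeneity, 1)
})

test_that("two symmetric dose groups give the exactly identified slope", {
  d <- c(2, 20)
  dat <- data.frame(concentration = d, n_treated = 100,
                    n_dead = c(25, 75))
  fit <- probit_fit(dat)
  expect_equal(unname(coef(fit)["slope"]),
               2 * qnorm(0.75) / diff(log10(d)), tolerance = 1e-6)
  expect_equal(fit$lc50, sqrt(prod(d)), tolerance = 1e-6)
  expect_equal(fit$df, 0L)
})

test_that("degenerate and separable data are rejected as non-identifiable", {
  dat <- data.frame(concentration = c(1, 10, 100), n_treated = 30,
                    n_dead = c(30, 30, 30))
  expect_error(probit_fit(dat), "all subjects dead")
  dat$n_dead <- c(0, 0, 0)
  expect_error(probit_fit(dat), "alive")
  dat$n_dead <- c(0, 0, 30)
  expect_error(probit_fit(dat), "separation")
  expect_error(probit_fit(data.frame(concentration = 5, n_treated = 30,
                                     n_dead = 10)), "2 distinct")
})

test_that("lethal concentration estimates follow the quantile identity", {
  set.seed(50)
  dat <- generate_bioassay(bioassay_spec(slope = 1.2, lc50 = 10,
                                         n_per_well = 10, replicates = 10))
  fit <- probit_fit(dat)
  tab <- lc(fit, p = c(10, 25, 50, 75, 90))
  # p = 50 returns the LC50 itself
  expect_equal(tab$lc[tab$p == 50], fit$lc50)
  # monotone in p, and log10 LC_p affine in the normal quantile
  expect_true(all(diff(tab$lc) > 0))
  z <- qnorm(tab$p / 100)
  slopes <- diff(log10(tab$lc)) / diff(z)
  expect_equal(slopes, rep(1 / unname(coef(fit)["slope"]), 4))
  # Fieller interval contains the point estimate
  expect_true(all(tab$lower < tab$lc & tab$lc < tab$upper))
  # delta-method limits are close to Fieller limits for a stable fit
  tabd <- lc(fit, p = 50, method = "delta")
  expect_equal(tabd$lower, tab$lower[tab$p == 50], tolerance = 0.15)
  expect_error(lc(fit, p = 0), "strictly between")
})

test_that("heterogeneity inflates the confidence limits monotonically", {
  doses <- c(1, 3, 10, 30, 100)
  base <- data.frame(concentration = doses, n_treated = 100,
                     n_dead = round(100 * pnorm(1.2 * (log10(doses) - 1))))
  fit1 <- probit_fit(base)
  noisy <- base
  noisy$n_dead <- noisy$n_dead + c(4, -4, 4, -3, 2)
  fit2 <- probit_fit(noisy)
  expect_gt(fit2$heterogeneity, fit1$heterogeneity)
  w1 <- with(lc(fit1, 50), log10(upper) - log10(lower))
  w2 <- with(lc(fit2, 50), log10(upper) - log10(lower))
  expect_gt(w2, w1)
  # heterogeneity-inflated SEs are reported
  expect_equal(fit2$se[2], sqrt(fit2$heterogeneity * fit2$vcov[2, 2]))
})

test_that("Wald coverage of the true slope is at least 90% at n = 30/dose", {
  spec <- bioassay_spec(slope = 1.2, lc50 = 10, n_per_well = 5, replicates = 6)
  covered <- vapply(seq_len(200), function(s) {
    fit <- probit_fit(generate_bioassay(spec, seed = s))
    b <- unname(coef(fit)["slope"])
    abs(b - 1.2) <= qnorm(0.975) * fit$se[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("published slope/LC50 pairs reproduce their printed LC25", {
  tab <- table2_rows()
  implied <- lc_points(tab$slope, tab$lc50, 25)
  expect_true(all(abs(implied - tab$lc25) / tab$lc25 < 0.005))
})

test_that("resistance ratios are LC50 ratios with guarded inputs", {
  expect_equal(round(resistance_ratio(38.313, 0.170), 2), 225.37)
  expect_equal(round(resistance_ratio(38.313, 6.741), 2), 5.68)
  expect_equal(resistance_ratio(3, 3), 1)
  expect_error(resistance_ratio(3, 0), "positive")
})

test_that("Abbott's correction rescales by control mortality", {
  dat <- data.frame(concentration = c(0, 1, 10), n_treated = c(100, 100, 100),
                    n_dead = c(10, 55, 90))
  out <- abbott_correction(dat)
  expect_equal(out$n_dead[2] / out$n_treated[2], 0.5)
  expect_equal(out$n_dead[1], 10)           # control row unchanged
  # zero control mortality: identity, and the fit is unaffected
  dat0 <- data.frame(concentration = c(0, 1, 3, 10, 30),
                     n_treated = 60, n_dead = c(0, 10, 22, 38, 52))
  expect_identical(abbott_correction(dat0), dat0)
  f1 <- probit_fit(dat0)
  f2 <- probit_fit(dat0, abbott = TRUE)
  expect_equal(coef(f1), coef(f2))
  expect_equal(f1$lc50, f2$lc50)
  dat$n_dead[1] <- 100
  expect_error(abbott_correction(dat), "100%")
})

test_that("probit methods predict, print and plot", {
  set.seed(55)
  fit <- probit_fit(generate_bioassay(bioassay_spec(seed = 55)))
  expect_equal(unname(predict(fit, fit$lc50)), 0.5, tolerance = 1e-9)
  expect_output(print(fit), "LC50")
  expect_output(print(summary(fit)), "Lethal concentrations")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
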