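test_that("age-stage counts census the toy cohort day by day", {
  co <- toy_census_cohort()
  counts <- build_counts(co)
  expect_equal(attr(counts, "n01"), 4)
  rs <- rowSums(counts)
  expect_equal(unname(rs[c("0", "7", "31")]), c(4, 2, 1))
  # transition-day occupancy belongs to the new stage
  expect_equal(unname(counts["5", "L1"]), 4)
  expect_equal(unname(counts["5", "egg"]), 0)
  # total person-days equals the sum of individual lifespans
  expect_equal(sum(counts), sum(co$death_age + 1))

  one <- cohort(id = "x", sex = "u",
                entry = matrix(0L, 1, 1, dimnames = list(NULL, "egg")),
                death_age = 0L)
  m <- build_counts(one)
  expect_equal(dim(m), c(1L, 8L))
  expect_equal(sum(m), 1)
  expect_equal(unname(m[1, "egg"]), 1)
})

test_that("counts are consistent with individual lifespans on synthetic data", {
  co <- generate_cohort(cohort_spec(n01 = 50, seed = 8))
  counts <- build_counts(co)
  expect_equal(sum(counts), sum(co$death_age + 1))
  s <- survival_rates(counts)
  expect_true(all(diff(s$l_x) <= 1e-12))
  expect_true(all(s$s_xj >= 0 & s$s_xj <= 1))
  expect_equal(unname(s$l_x[1]), 1)
})

test_that("survival rates reproduce the hand census of the toy cohort", {
  s <- survival_rates(toy_census_cohort())
  expect_equal(unname(s$s_xj["0", "egg"]), 1)
  expect_equal(unname(s$l_x["7"]), 0.5)
  expect_equal(unname(s$l_x["31"]), 0.25)
})

test_that("fecundity curves follow the stage-weighted definition", {
  lt <- lifetable(toy_fecundity_cohort())
  expect_equal(unname(lt$f_xj["25", "female"]), 3)
  expect_equal(unname(lt$m_x["25"]), 3)
  expect_equal(unname(lt$lxmx["25"]), 0.75)
  expect_equal(sum(lt$lxmx), 1.5)

  # all-male cohort: m_x is identically zero and R0 = 0
  males <- cohort(id = c("m1", "m2"), sex = c("m", "m"),
                  entry = toy_entry(c(0, 5, 8, 11, 14, 17, 23),
                                    c(0, 5, 8, 11, 14, 17, 23)),
                  death_age = c(30, 30))
  ltm <- lifetable(males)
  expect_true(all(ltm$m_x == 0))
  expect_equal(net_reproductive_rate(ltm), 0)
  expect_true(is.na(ltm$params$r))

  # sum l_x m_x = total eggs / n01 on synthetic data
  co <- generate_cohort(cohort_spec(n01 = 60, seed = 2))
  lt2 <- lifetable(co)
  eggs <- sum(unlist(co$fecundity))
  expect_equal(sum(lt2$lxmx), eggs / n01(co))
})

test_that("conditional survival Markov-propagates the empirical transitions", {
  lt <- lifetable(generate_cohort(cohort_spec(n01 = 60, seed = 4)))
  # from (0, egg) the propagation reproduces the marginal s_xj exactly
  cs <- conditional_survival(lt, 0, "egg")
  expect_equal(unclass(cs), unclass(lt$s_xj), tolerance = 1e-12,
               ignore_attr = TRUE)
  # from the last day of the oldest individual: 1 at origin, 0 elsewhere
  A <- nrow(lt$counts) - 1L
  j <- which(lt$counts[A + 1L, ] > 0)[1L]
  cs2 <- conditional_survival(lt, A, j)
  expect_equal(nrow(cs2), 1L)
  expect_equal(sum(cs2), 1)
  expect_equal(unname(cs2[1, j]), 1)
  # row sums non-increasing from any occupied origin
  for (x in c(0, 5, 15)) {
    jj <- which(lt$counts[x + 1L, ] > 0)[1L]
    rs <- rowSums(conditional_survival(lt, x, jj))
    expect_true(all(diff(rs) <= 1e-12))
  }
  expect_error(conditional_survival(lt, 0, "female"), "empty")
})

test_that("life expectancy counts the current day and averages remaining life", {
  # everyone alive on day 0 only
  co0 <- cohort(id = c("x", "y"), sex = c("u", "u"),
                entry = matrix(0L, 2, 1, dimnames = list(NULL, "egg")),
                death_age = c(0L, 0L))
  expect_equal(unname(life_expectancy(co0)[1, "egg"]), 1)
  # lifespans 1 and 3 days -> e(0, egg) = 2
  co <- cohort(id = c("x", "y"), sex = c("u", "u"),
               entry = matrix(0L, 2, 1, dimnames = list(NULL, "egg")),
               death_age = c(0L, 2L))
  expect_equal(unname(life_expectancy(co)[1, "egg"]), 2)
  # e(0, egg) equals the cohort mean lifespan exactly
  syn <- generate_cohort(cohort_spec(n01 = 70, seed = 9))
  lt <- lifetable(syn)
  expect_equal(unname(lt$e_xj[1, 1]), mean(syn$death_age + 1))
  # backward recursion agrees with the propagated double sum of s'
  for (x in c(0, 10)) {
    j <- which(lt$counts[x + 1L, ] > 0)[1L]
    cs <- conditional_survival(lt, x, j)
    expect_equal(unname(lt$e_xj[x + 1L, j]), sum(cs))
  }
  expect_true(all(lt$e_xj[lt$counts > 0] >= 1))
})

test_that("reproductive value discounts future reproduction at rate r", {
  lt <- lifetable(generate_cohort(cohort_spec(n01 = 80, seed = 12)))
  r <- lt$params$r
  # v(0, egg) = lambda: the inner sum telescopes to the Euler-Lotka
  # left-hand side, which is 1 at the solved r
  expect_lt(abs(lt$v_xj[1, 1] - lt$params$lambda), 1e-8)
  # brute-force forward propagation reproduces the backward recursion
  for (cell in list(c(0, 1), c(20, 6))) {
    x <- cell[1]; j <- cell[2]
    if (lt$counts[x + 1L, j] == 0) next
    cs <- conditional_survival(lt, x, j)
    ages <- as.integer(rownames(cs))
    inner <- sum(vapply(seq_along(ages), function(k)
      exp(-r * (ages[k] + 1)) * sum(cs[k, ] * lt$f_xj[ages[k] + 1L, ]),
      numeric(1)))
    expect_equal(unname(lt$v_xj[x + 1L, j]), exp(r * (x + 1)) * inner)
  }
  # zero after the last oviposition day
  last_egg <- max(which(rowSums(lt$f_xj) > 0)) - 1L
  late <- lt$v_xj[seq.int(last_egg + 2L, nrow(lt$v_xj)), , drop = FALSE]
  expect_true(all(late[!is.na(late)] == 0))
  # hand evaluation on the toy cohort at (25, female)
  lt2 <- lifetable(toy_fecundity_cohort())
  r2 <- lt2$params$r
  # she is the sole survivor: conditional survival 1 on days 25..35,
  # eggs 3 on days 25 and 26
  hand <- exp(r2 * 26) * (exp(-r2 * 26) * 3 + exp(-r2 * 27) * 3)
  expect_equal(unname(lt2$v_xj[26, "female"]), hand)
})

test_that("the Euler-Lotka solver has the closed-form roots", {
  # single net-maternity entry of 1 at any age -> r = 0
  expect_equal(solve_intrinsic_rate(c(0, 0, 0, 1)), 0)
  # single entry of 2 at age x = 4 -> r = log(2)/5
  lxmx <- c(0, 0, 0, 0, 2)
  r <- solve_intrinsic_rate(lxmx)
  expect_equal(r, log(2) / 5, tolerance = 1e-10)
  expect_equal(log(sum(lxmx)) / r, 5)
  expect_error(solve_intrinsic_rate(numeric(5)), "R0")
  # residual below tolerance on a synthetic schedule
  lt <- lifetable(generate_cohort(cohort_spec(n01 = 100, seed = 21)))
  x1 <- seq_along(lt$lxmx)
  expect_lt(abs(sum(exp(-lt$params$r * x1) * lt$lxmx) - 1), 1e-8)
})

test_that("population parameters satisfy the two-sex identities exactly", {
  lt <- lifetable(toy_fecundity_cohort())
  p <- lt$params
  expect_equal(p$R0, 1.5)
  expect_equal(p$R0, p$mean_fecundity * p$female_ratio)
  expect_equal(p$lambda, exp(p$r))
  expect_equal(p$T, log(p$R0) / p$r)
  for (seed in c(31, 32)) {
    lt <- lifetable(generate_cohort(cohort_spec(n01 = 90, seed = seed)))
    p <- lt$params
    expect_equal(p$R0, p$mean_fecundity * p$female_ratio)
    expect_equal(p$lambda, exp(p$r))
    expect_equal(p$T, log(p$R0) / p$r)
    expect_gte(p$GRR, p$R0)
  }
})

test_that("lifetable methods print, summarise and plot", {
  lt <- lifetable(generate_cohort(cohort_spec(n01 = 40, seed = 14)))
  expect_named(coef(lt), c("R0", "r", "lambda", "T", "GRR"))
  expect_output(print(lt), "R0")
  expect_output(print(summary(lt)), "female_ratio")
  pdf(NULL)
  on.exit(dev.off())
  for (w in c("survival", "fecundity", "expectancy", "value"))
    expect_invisible(plot(lt, which = w))
})
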