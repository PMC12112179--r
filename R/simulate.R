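#' Specification for a synthetic stage-structured cohort
#'
#' Defines the generating process for a cohort of the kind followed in
#' a laboratory two-sex life-table study: an egg cohort develops
#' through larval instars and a pupal stage, each stage lasting
#' `1 + Poisson(mu)` days (guaranteeing at least one census day per
#' stage) with an independent daily survival probability per stage;
#' survivors emerge as adults, are sexed with probability `p_female` of
#' being female, live `1 + Poisson(longevity_mu[sex])` adult days, and
#' females start laying after an adult preoviposition period of
#' `1 + Poisson(apop_mu)` days, with daily egg counts Poisson-distributed
#' around a triangular schedule of adult age (rising to `peak_rate`
#' eggs/day at adult age `peak_day`, falling to zero at `last_day`).
#'
#' The defaults emulate the rearing regime of a tomato leafminer
#' control colony: stage-duration means of roughly 4.9, 3.0, 2.8, 2.7,
#' 2.8 and 7.1 days for egg, L1-L4 and pupa; around 102 eggs per
#' female; a 1:1 sex ratio; APOP near 2.1 days; adult longevity near 18
#' days; and moderate preadult mortality (daily survival 0.99, about
#' 79% egg-to-adult survival).
#'
#' @param n01 Initial egg number.
#' @param stage_mu Named vector of Poisson means for the preadult stage
#'   durations (duration = 1 + Poisson(mu) days).
#' @param stage_survival Named vector of daily survival probabilities
#'   per preadult stage.
#' @param p_female Probability a surviving adult is female.
#' @param apop_mu Poisson mean of the adult preoviposition period
#'   (APOP = 1 + Poisson(apop_mu) days).
#' @param peak_rate,peak_day,last_day Triangular daily fecundity
#'   schedule over adult age: the Poisson laying rate rises linearly to
#'   `peak_rate` eggs/day at adult age `peak_day` and falls to zero at
#'   `last_day`.
#' @param longevity_mu Named vector (`female`, `male`) of Poisson means
#'   for adult longevity (longevity = 1 + Poisson(mu) days).
#' @param fecundity_mult Treatment knob: multiplies the laying rate.
#' @param preadult_delay Treatment knob: extra expected preadult days,
#'   spread evenly over the preadult stage means.
#' @param deterministic If `TRUE`, durations, APOP and longevity are
#'   fixed at `1 + round(mu)` instead of Poisson draws.
#' @param fixed_schedule Optional named vector (adult age -> egg count)
#'   laying exactly these counts on those adult days (overriding the
#'   Poisson schedule and APOP gating).
#' @param seed Optional integer seed used by [generate_cohort()].
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n01 = 100,
                        stage_mu = c(egg = 3.87, L1 = 2.02, L2 = 1.81,
                                     L3 = 1.72, L4 = 1.77, pupa = 6.14),
                        stage_survival = c(egg = 0.99, L1 = 0.99, L2 = 0.99,
                                           L3 = 0.99, L4 = 0.99, pupa = 0.99),
                        p_female = 0.5,
                        apop_mu = 1.12,
                        peak_rate = 13.5, peak_day = 6, last_day = 18,
                        longevity_mu = c(female = 17.1, male = 16.1),
                        fecundity_mult = 1, preadult_delay = 0,
                        deterministic = FALSE, fixed_schedule = NULL,
                        seed = NULL) {
  if (n01 < 1) stop("n01 must be at least 1")
  if (!identical(names(stage_mu), names(stage_survival)))
    stop("stage_mu and stage_survival must name the same stages")
  if (any(stage_mu < 0) || any(apop_mu < 0) || any(longevity_mu < 0))
    stop("Poisson means must be non-negative")
  if (any(stage_survival < 0 | stage_survival > 1) ||
      p_female < 0 || p_female > 1)
    stop("probabilities must lie in [0, 1]")
  if (peak_rate < 0 || fecundity_mult < 0) stop("rates must be non-negative")
  if (peak_day <= 0 || last_day <= peak_day)
    stop("need 0 < peak_day < last_day")
  if (preadult_delay > 0)
    stage_mu <- stage_mu + preadult_delay / length(stage_mu)
  structure(list(
    n01 = as.integer(n01), stage_mu = stage_mu, stage_survival = stage_survival,
    p_female = p_female, apop_mu = apop_mu, peak_rate = peak_rate,
    peak_day = peak_day, last_day = last_day, longevity_mu = longevity_mu,
    fecundity_mult = fecundity_mult, deterministic = deterministic,
    fixed_schedule = fixed_schedule, seed = seed
  ), class = "cohort_spec")
}

# Triangular daily laying rate at adult age a (0 = emergence day).
laying_rate <- function(spec, a) {
  r <- ifelse(a <= spec$peak_day,
              spec$peak_rate * a / spec$peak_day,
              spec$peak_rate * (spec$last_day - a) /
                (spec$last_day - spec$peak_day))
  spec$fecundity_mult * pmax(0, r * (a >= 0 & a <= spec$last_day))
}

draw_1p_pois <- function(n, mu, deterministic) {
  if (deterministic) rep.int(1L + as.integer(round(mu)), n)
  else 1L + stats::rpois(n, mu)
}

#' Generate a synthetic cohort
#'
#' Simulates `spec$n01` individual life histories under the process of
#' [cohort_spec()] and returns them as a validated [cohort()] object,
#' reproducible under the seed.
#'
#' @param spec A `"cohort_spec"` object.
#' @param seed Integer seed (defaults to `spec$seed`; `NULL` uses the
#'   current RNG state).
#' @return A [cohort()] object.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  stages <- names(spec$stage_mu)
  stage_order <- c(stages, "female", "male")
  n <- spec$n01
  entry <- matrix(NA_integer_, n, length(stages) + 1L,
                  dimnames = list(NULL, c(stages, "adult")))
  death <- integer(n)
  sex <- rep("u", n)
  fec <- vector("list", n)
  for (i in seq_len(n)) {
    age <- 0L
    dead <- FALSE
    for (s in seq_along(stages)) {
      entry[i, s] <- age
      dur <- draw_1p_pois(1L, spec$stage_mu[s], spec$deterministic)
      p <- spec$stage_survival[s]
      surv <- if (p >= 1) rep(TRUE, dur) else stats::runif(dur) < p
      if (!all(surv)) {
        death[i] <- age + which(!surv)[1L] - 1L
        dead <- TRUE
        break
      }
      age <- age + dur
    }
    if (dead) next
    entry[i, "adult"] <- age
    female <- stats::runif(1) < spec$p_female
    sex[i] <- if (female) "f" else "m"
    mu_L <- spec$longevity_mu[if (female) "female" else "male"]
    L <- draw_1p_pois(1L, mu_L, spec$deterministic)
    death[i] <- age + L - 1L
    if (female) {
      if (!is.null(spec$fixed_schedule)) {
        a <- as.integer(names(spec$fixed_schedule))
        keep <- a <= L - 1L
        eggs <- as.integer(round(spec$fixed_schedule[keep] * spec$fecundity_mult))
        adays <- a[keep]
      } else {
        apop <- draw_1p_pois(1L, spec$apop_mu, spec$deterministic)
        adays <- seq.int(0L, min(spec$last_day, L - 1L))
        adays <- adays[adays >= apop]
        eggs <- if (length(adays)) stats::rpois(length(adays),
                                                laying_rate(spec, adays)) else integer(0)
      }
      pos <- eggs > 0
      if (any(pos))
        fec[[i]] <- stats::setNames(eggs[pos], age + adays[pos])
    }
  }
  cohort(id = sprintf("sim%04d", seq_len(n)), sex = sex, entry = entry,
         death_age = death, fecundity = fec, stage_order = stage_order)
}

# Defective pmf of (stage duration, survival): g[d] = P(D = d) * p^d.
stage_defective_pmf <- function(mu, p, deterministic, eps = 1e-12) {
  if (deterministic) {
    d <- 1L + as.integer(round(mu))
    g <- numeric(d); g[d] <- p^d
    return(g)
  }
  dmax <- 1L + max(stats::qpois(1 - eps, mu), 1L)
  d <- seq_len(dmax)
  stats::dpois(d - 1L, mu) * p^d
}

#' Expected life-table parameters of a synthetic cohort specification
#'
#' Computes, numerically from the generating distributions (no
#' simulation), the quantities the life table estimates: the defective
#' preadult-duration distribution (convolution of the per-stage
#' duration pmfs weighted by within-stage survival) gives the
#' egg-to-adult survival and the age-at-emergence distribution; the
#' APOP, longevity and laying-rate distributions give the expected
#' lifetime fecundity per emerged female and the expected net maternity
#' schedule l_x m_x, from which R0, r, lambda and T follow via the
#' Euler-Lotka equation.
#'
#' @param spec A `"cohort_spec"` object.
#' @return Named list: `R0`, `r`, `lambda`, `T`, `mean_fecundity` (per
#'   emerged female), `female_ratio`, `preadult_survival`,
#'   `preadult_mean` (mean age at emergence, conditional on emerging),
#'   and the expected `lxmx` schedule.
#' @export
expected_parameters <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  pmfs <- lapply(seq_along(spec$stage_mu), function(s)
    stage_defective_pmf(spec$stage_mu[s], spec$stage_survival[s],
                        spec$deterministic))
  # Convolution over stages.  Vectors are indexed so that element k
  # stands for k - 1 days; pre[k] = P(emerge alive at age k - 1).
  conv <- function(u, v) {
    r <- numeric(length(u) + length(v) - 1L)
    for (i in seq_along(u)) {
      if (u[i] == 0) next
      span <- seq.int(i, i + length(v) - 1L)
      r[span] <- r[span] + u[i] * v
    }
    r
  }
  pre <- 1
  for (g in pmfs) pre <- conv(pre, c(0, g))
  p_pre <- sum(pre)
  preadult_mean <- if (p_pre > 0)
    sum((seq_along(pre) - 1L) * pre) / p_pre else NA_real_

  # Expected eggs laid at adult age a (0-based) by an emerged female,
  # accounting for APOP gating and adult survival (alive at adult age a
  # iff longevity >= a + 1 days).
  amax <- if (!is.null(spec$fixed_schedule))
    max(as.integer(names(spec$fixed_schedule))) else spec$last_day
  a <- 0:amax
  alive <- if (spec$deterministic) {
    L <- 1L + as.integer(round(spec$longevity_mu["female"]))
    as.numeric(a + 1L <= L)
  } else stats::ppois(a - 1L, spec$longevity_mu["female"], lower.tail = FALSE)
  if (!is.null(spec$fixed_schedule)) {
    sched <- numeric(length(a))
    sched[as.integer(names(spec$fixed_schedule)) + 1L] <-
      spec$fixed_schedule * spec$fecundity_mult
  } else {
    papop <- if (spec$deterministic)
      as.numeric(a >= 1L + as.integer(round(spec$apop_mu)))
    else stats::ppois(a - 1L, spec$apop_mu)
    sched <- laying_rate(spec, a) * papop
  }
  eggs_a <- sched * alive
  mean_fec <- sum(eggs_a)

  q <- spec$p_female
  # lxmx[x + 1] = q * sum_d P(emerge at d) * eggs_a at adult age x - d
  lxmx <- q * conv(pre, eggs_a)
  R0 <- sum(lxmx)
  if (R0 > 0) {
    r <- solve_intrinsic_rate(lxmx)
    lambda <- exp(r)
    TT <- if (r != 0) log(R0) / r else NA_real_
  } else {
    r <- NA_real_; lambda <- NA_real_; TT <- NA_real_
  }
  list(R0 = R0, r = r, lambda = lambda, T = TT, mean_fecundity = mean_fec,
       female_ratio = p_pre * q, preadult_survival = p_pre,
       preadult_mean = preadult_mean, lxmx = lxmx)
}

#' Specification for a synthetic dose-mortality bioassay
#'
#' Emulates a leaf-dip bioassay design: a concentration series, a fixed
#' number of larvae per well and replicate wells per concentration,
#' scored once for mortality.  Deaths are binomial with probability
#' `pnorm(slope * (log10(dose) - log10(lc50)))`.
#'
#' @param slope True probit slope (per log10 concentration).
#' @param lc50 True median lethal concentration (mg/L).
#' @param concentrations Concentration series (mg/L); the default is a
#'   4-fold dilution series from 500 down to 0.78125 mg/L.
#' @param n_per_well Larvae per replicate well.
#' @param replicates Replicate wells per concentration.
#' @param control_mortality If non-`NULL`, adds control wells
#'   (concentration 0) with this true mortality.
#' @param seed Optional integer seed used by [generate_bioassay()].
#' @return Object of class `"bioassay_spec"`.
#' @export
bioassay_spec <- function(slope = 1.2, lc50 = 10,
                          concentrations = c(500, 125, 50, 12.5, 3.125, 0.78125),
                          n_per_well = 5, replicates = 6,
                          control_mortality = NULL, seed = NULL) {
  if (slope <= 0) stop("slope must be positive")
  if (lc50 <= 0) stop("lc50 must be positive")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (n_per_well < 1 || replicates < 1) stop("need at least 1 larva and 1 replicate")
  if (!is.null(control_mortality) &&
      (control_mortality < 0 || control_mortality >= 1))
    stop("control_mortality must lie in [0, 1)")
  structure(list(slope = slope, lc50 = lc50, concentrations = concentrations,
                 n_per_well = as.integer(n_per_well),
                 replicates = as.integer(replicates),
                 control_mortality = control_mortality, seed = seed),
            class = "bioassay_spec")
}

#' Generate a synthetic dose-mortality bioassay
#'
#' @param spec A `"bioassay_spec"` object.
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return Data frame with columns `concentration`, `n_treated`,
#'   `n_dead`, `replicate`, suitable for [probit_fit()].
#' @export
generate_bioassay <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "bioassay_spec"))
  if (!is.null(seed)) set.seed(seed)
  conc <- spec$concentrations
  if (!is.null(spec$control_mortality)) conc <- c(conc, 0)
  out <- expand.grid(replicate = seq_len(spec$replicates),
                     concentration = conc)
  pr <- ifelse(out$concentration > 0,
               stats::pnorm(spec$slope * (log10(pmax(out$concentration, 1e-300)) -
                                            log10(spec$lc50))),
               spec$control_mortality %||% 0)
  out$n_treated <- spec$n_per_well
  out$n_dead <- stats::rbinom(nrow(out), spec$n_per_well, pr)
  out[, c("concentration", "n_treated", "n_dead", "replicate")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a synthetic cohort or bioassay specification from YAML
#'
#' Convenience constructors from a YAML file whose keys are the
#' arguments of [cohort_spec()] or [bioassay_spec()].  A seed recorded
#' in the file keeps simulated datasets reproducible.
#'
#' @param path YAML file.
#' @return A `"cohort_spec"` or `"bioassay_spec"` object.
#' @export
read_cohort_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in c("stage_mu", "stage_survival", "longevity_mu", "fixed_schedule"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- unlist(cfg[[k]])
  do.call(cohort_spec, cfg)
}

#' @rdname read_cohort_spec
#' @export
read_bioassay_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$concentrations)) cfg$concentrations <- unlist(cfg$concentrations)
  do.call(bioassay_spec, cfg)
}
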