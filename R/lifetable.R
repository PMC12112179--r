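# Internal numeric arrays for fast repeated life-table computation.
# S: n x (A+1) integer matrix of daily stage codes (0 = dead, j = index
#    into stage_order); F: n x (A+1) matrix of eggs laid per day;
# summ: numeric matrix of per-individual summaries used by Table-3
# style means.
lt_arrays <- function(x) {
  stopifnot(inherits(x, "cohort"))
  meta <- stage_meta(x$stage_order)
  n <- n01(x)
  A <- max(x$death_age)
  A1 <- A + 1L
  beta <- meta$beta
  S <- matrix(0L, n, A1)
  FE <- matrix(0, n, A1)
  for (i in seq_len(n)) {
    e <- x$entry[i, ]
    present <- which(!is.na(e))
    ages <- e[present]
    ends <- c(ages[-1L] - 1L, x$death_age[i])
    for (k in seq_along(present))
      S[i, (ages[k]:ends[k]) + 1L] <- present[k]
    f <- x$fecundity[[i]]
    if (!is.null(f)) FE[i, as.integer(names(f)) + 1L] <- as.numeric(f)
  }
  summ <- individual_summaries(x)
  smat <- as.matrix(summ[, !(names(summ) %in% c("id", "sex"))])
  is_f <- x$sex == "f" & !is.na(x$entry[, meta$female])
  is_m <- x$sex == "m" & !is.na(x$entry[, meta$male])
  list(S = S, FE = FE, summ = smat, is_f = is_f, is_m = is_m,
       beta = beta, A1 = A1, fcol = beta - 1L, mcol = beta,
       stage_order = x$stage_order, death_age = x$death_age)
}

# Age-stage counts, survival/fecundity curves and all scalar population
# parameters for a (re)sample `idx` of individuals.  This single code
# path serves both the full-cohort fit and every bootstrap replicate.
lt_stats <- function(arr, idx) {
  n <- length(idx)
  beta <- arr$beta
  A1 <- arr$A1
  S <- arr$S[idx, , drop = FALSE]
  codes <- as.vector(S) + rep.int((0L:(A1 - 1L)) * (beta + 1L), rep.int(n, A1))
  counts <- matrix(tabulate(codes + 1L, nbins = A1 * (beta + 1L)),
                   nrow = beta + 1L)[-1L, , drop = FALSE]
  counts <- t(counts)
  dimnames(counts) <- list(0:(A1 - 1L), arr$stage_order)
  eggs_x <- .colSums(arr$FE[idx, , drop = FALSE], n, A1)

  s_xj <- counts / n
  l_x <- stats::setNames(.rowSums(s_xj, A1, beta), rownames(counts))
  nf_x <- counts[, arr$fcol]
  f_x <- stats::setNames(ifelse(nf_x > 0, eggs_x / nf_x, 0), names(l_x))
  m_x <- ifelse(l_x > 0, (s_xj[, arr$fcol] * f_x) / l_x, 0)
  lxmx <- l_x * m_x

  R0 <- sum(lxmx)
  GRR <- sum(m_x)
  if (R0 > 0) {
    r <- solve_intrinsic_rate(lxmx)
    lambda <- exp(r)
    TT <- if (r != 0) log(R0) / r else NA_real_
  } else {
    r <- NA_real_; lambda <- NA_real_; TT <- NA_real_
  }
  Nf <- sum(arr$is_f[idx])
  Nm <- sum(arr$is_m[idx])
  mean_fec <- if (Nf > 0) sum(eggs_x) / Nf else NA_real_
  sm <- suppressWarnings(colMeans(arr$summ[idx, , drop = FALSE], na.rm = TRUE))
  sm[is.nan(sm)] <- NA_real_
  params <- c(
    R0 = R0, r = r, lambda = lambda, T = TT, GRR = GRR,
    mean_fecundity = mean_fec,
    female_ratio = Nf / n,
    male_female_ratio = if (Nf > 0) Nm / Nf else NA_real_,
    sm[setdiff(names(sm), "fecundity")]
  )
  list(counts = counts, s_xj = s_xj, l_x = l_x, f_x = f_x, m_x = m_x,
       lxmx = lxmx, eggs_x = eggs_x, params = params)
}

#' Solve the Euler-Lotka equation for the intrinsic rate of increase
#'
#' Finds the unique root r of `sum(exp(-r * (x + 1)) * lxmx) = 1`,
#' where `lxmx[k]` is the net maternity at age `x = k - 1`.  The left
#' side is strictly decreasing in r, so the root is bracketed and
#' refined by bisection followed by Newton polishing.
#'
#' @param lxmx Numeric vector of age-specific net maternity
#'   (`l_x * m_x`), indexed from age 0.
#' @param tol Residual tolerance on the Euler-Lotka equation.
#' @param bracket Initial search interval for r (expanded if needed).
#' @return The intrinsic rate of increase r (per day).
#' @export
solve_intrinsic_rate <- function(lxmx, tol = 1e-10, bracket = c(-2, 2)) {
  R0 <- sum(lxmx)
  if (!is.finite(R0) || R0 <= 0)
    stop("the Euler-Lotka equation has no solution when R0 <= 0")
  x1 <- seq_along(lxmx)                 # x + 1 for age x = 0, 1, ...
  g <- function(r) sum(exp(-r * x1) * lxmx) - 1
  if (g(0) == 0) return(0)
  lo <- bracket[1L]; hi <- bracket[2L]
  it <- 0L
  while (g(hi) > 0 && it < 60L) { hi <- hi + 1; it <- it + 1L }
  while (g(lo) < 0 && it < 120L) { lo <- lo - 1; it <- it + 1L }
  if (g(lo) < 0 || g(hi) > 0) stop("failed to bracket the Euler-Lotka root")
  for (k in 1:80) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  r <- (lo + hi) / 2
  for (k in 1:8) {                      # Newton polish
    fr <- g(r)
    if (abs(fr) < tol) break
    dr <- -sum(x1 * exp(-r * x1) * lxmx)
    step <- fr / dr
    if (!is.finite(step)) break
    r <- r - step
  }
  if (abs(g(r)) > tol)
    warning("Euler-Lotka residual ", format(abs(g(r))), " exceeds tol")
  r
}

# Daily transition tallies from the full cohort: trans[x + 1, j, y + 1]
# = number of individuals in (age x, stage j) found in state y on day
# x + 1 (y = 0 codes death).  Stage-skipping transitions are allowed.
lt_transitions <- function(arr) {
  beta <- arr$beta
  A1 <- arr$A1
  tr <- array(0, c(A1, beta, beta + 1L))
  S <- arr$S
  for (x in seq_len(A1)) {
    from <- S[, x]
    to <- if (x < A1) S[, x + 1L] else rep.int(0L, nrow(S))
    alive <- from > 0L
    if (!any(alive)) next
    tab <- table(factor(from[alive], levels = 1:beta),
                 factor(to[alive], levels = 0:beta))
    tr[x, , ] <- tr[x, , ] + unclass(tab)
  }
  tr
}

#' Fit an age-stage, two-sex life table to a cohort
#'
#' The central fitting function.  From the daily census implied by the
#' individual records it tallies the age-stage counts n_xj, the
#' age-stage survival rates s_xj = n_xj / n01 and age-specific survival
#' l_x = sum_j s_xj, the age-stage fecundity f_xj (eggs per surviving
#' female adult), the age-specific fecundity m_x and net maternity
#' l_x m_x; solves the Euler-Lotka equation for the intrinsic rate of
#' increase r; and computes the age-stage life expectancy e_xj and
#' reproductive value v_xj from the empirical daily transition
#' probabilities.  Population parameters (R0, r, lambda = exp(r),
#' T = log(R0)/r, GRR = sum m_x, mean female fecundity, female ratio
#' N_f/n01, male-to-female ratio) and cohort summary means are stored
#' alongside.
#'
#' Conventions: ages are integer days with day 0 the first egg day; an
#' individual "at age x" is alive on day x; occupancy on a transition
#' day belongs to the new stage; e_xj and v_xj count the current day.
#'
#' @param cohort A [cohort()] object.
#' @param r_tol Residual tolerance for the Euler-Lotka solver.
#' @return An object of class `"lifetable"` with components `counts`,
#'   `s_xj`, `l_x`, `f_xj`, `m_x`, `lxmx`, `e_xj`, `v_xj`, `params`
#'   (named list of population parameters and summary means),
#'   `summaries` (per-individual table), and the input `cohort`.
#' @seealso [bootstrap_lifetable()], [conditional_survival()],
#'   [population_parameters()]
#' @export
lifetable <- function(cohort, r_tol = 1e-10) {
  assert_valid_cohort(cohort)
  arr <- lt_arrays(cohort)
  st <- lt_stats(arr, seq_len(n01(cohort)))
  tr <- lt_transitions(arr)
  beta <- arr$beta
  A1 <- arr$A1

  f_xj <- matrix(0, A1, beta, dimnames = dimnames(st$counts))
  f_xj[, arr$fcol] <- st$f_x

  e_xj <- lt_expectancy(st$counts, tr)
  r <- unname(st$params["r"])
  v_xj <- if (is.finite(r)) lt_repro_value(st$counts, tr, f_xj, r) else
    matrix(NA_real_, A1, beta, dimnames = dimnames(st$counts))

  structure(list(
    cohort = cohort, counts = st$counts, s_xj = st$s_xj, l_x = st$l_x,
    f_xj = f_xj, m_x = st$m_x, lxmx = st$lxmx, e_xj = e_xj, v_xj = v_xj,
    params = as.list(st$params), summaries = individual_summaries(cohort),
    transitions = tr, arrays = arr, call = match.call()
  ), class = "lifetable")
}

# e_xj by backward recursion over the empirical transition
# probabilities: E(x,j) = 1 + sum_y P((x,j)->(x+1,y)) E(x+1,y).  This
# equals the forward-propagated double sum of conditional survival
# because the transition fractions are the empirical fractions of the
# same individuals (mean remaining days, counting the current day).
lt_expectancy <- function(counts, tr) {
  A1 <- nrow(counts); beta <- ncol(counts)
  E <- matrix(NA_real_, A1, beta, dimnames = dimnames(counts))
  nxt <- numeric(beta)
  for (x in A1:1) {
    occ <- which(counts[x, ] > 0)
    for (j in occ)
      E[x, j] <- 1 + sum(tr[x, j, -1L] * nxt) / counts[x, j]
    nxt <- ifelse(is.na(E[x, ]) | counts[x, ] == 0, 0, E[x, ])
    nxt[counts[x, ] == 0] <- 0
  }
  E
}

# v_xj with conditional survival (s' = 1 at the origin cell):
# v(x,j) = exp(r (x+1)) * W(x,j),
# W(x,j) = exp(-r (x+1)) f_xj + sum_y P((x,j)->(x+1,y)) W(x+1,y).
# At (0, egg) the inner sum telescopes to the Euler-Lotka left side,
# so v(0, egg) = exp(r) = lambda.
lt_repro_value <- function(counts, tr, f_xj, r) {
  A1 <- nrow(counts); beta <- ncol(counts)
  W <- matrix(NA_real_, A1, beta)
  V <- matrix(NA_real_, A1, beta, dimnames = dimnames(counts))
  nxt <- numeric(beta)
  for (x in A1:1) {
    occ <- which(counts[x, ] > 0)
    for (j in occ) {
      W[x, j] <- exp(-r * x) * f_xj[x, j] +
        sum(tr[x, j, -1L] * nxt) / counts[x, j]
      V[x, j] <- exp(r * x) * W[x, j]
    }
    nxt <- ifelse(is.na(W[x, ]), 0, W[x, ])
  }
  V
}

#' Conditional survival from an age-stage origin
#'
#' Markov-propagates the empirical daily transition fractions forward
#' from origin (age, stage): the probability that an individual
#' currently in the origin cell is alive in stage y at each later age,
#' with probability 1 at the origin itself.  From origin (0, egg) the
#' propagation reproduces the marginal age-stage survival s_xj exactly.
#'
#' @param object A `"lifetable"` object.
#' @param age Integer origin age (days).
#' @param stage Origin stage name or index.
#' @return Matrix with one row per age from `age` to the cohort's
#'   maximum age and one column per stage.
#' @export
conditional_survival <- function(object, age, stage) {
  stopifnot(inherits(object, "lifetable"))
  beta <- ncol(object$counts)
  A1 <- nrow(object$counts)
  j <- if (is.character(stage)) match(stage, colnames(object$counts)) else as.integer(stage)
  if (is.na(j) || j < 1L || j > beta) stop("unknown stage: ", stage)
  x0 <- as.integer(age)
  if (x0 < 0L || x0 >= A1 || object$counts[x0 + 1L, j] == 0)
    stop("origin cell (", age, ", ", stage, ") is empty")
  out <- matrix(0, A1 - x0, beta,
                dimnames = list(x0:(A1 - 1L), colnames(object$counts)))
  p <- numeric(beta); p[j] <- 1
  out[1L, ] <- p
  if (x0 < A1 - 1L) {
    for (x in x0:(A1 - 2L)) {
      pn <- numeric(beta)
      for (jj in which(p > 0))
        pn <- pn + p[jj] * object$transitions[x + 1L, jj, -1L] /
          object$counts[x + 1L, jj]
      p <- pn
      out[x - x0 + 2L, ] <- p
    }
  }
  out
}

#' Age-stage counts of a cohort
#'
#' Tallies n_xj, the number of individuals alive at age x (rows, from
#' day 0) in stage j (columns), under the census conventions of
#' [lifetable()].
#'
#' @param cohort A [cohort()] object.
#' @return Integer matrix with the initial cohort size as attribute
#'   `"n01"`.
#' @export
build_counts <- function(cohort) {
  assert_valid_cohort(cohort)
  arr <- lt_arrays(cohort)
  st <- lt_stats(arr, seq_len(n01(cohort)))
  structure(st$counts, n01 = n01(cohort))
}

#' Age-stage survival rates and age-specific survival
#'
#' s_xj = n_xj / n01 and l_x = sum_j s_xj.
#'
#' @param x A `"cohort"`, `"lifetable"`, or a counts matrix from
#'   [build_counts()].
#' @return List with elements `s_xj` and `l_x`.
#' @export
survival_rates <- function(x) {
  if (inherits(x, "lifetable")) return(list(s_xj = x$s_xj, l_x = x$l_x))
  if (inherits(x, "cohort")) x <- build_counts(x)
  n0 <- attr(x, "n01")
  if (is.null(n0) || n0 <= 0) stop("counts must carry a positive 'n01' attribute")
  s <- unclass(x) / n0
  attr(s, "n01") <- NULL
  list(s_xj = s, l_x = rowSums(s))
}

#' Age-stage and age-specific fecundity curves
#'
#' f_xj: mean eggs laid at age x per surviving female adult of that
#' age; m_x: population age-specific fecundity, the survival-weighted
#' stage average (0 at ages where no one is alive); lxmx: net
#' maternity.  `sum(lxmx)` is the net reproductive rate R0.
#'
#' @param x A `"cohort"` or `"lifetable"` object.
#' @return List with elements `f_xj`, `m_x`, `lxmx`.
#' @export
fecundity_curves <- function(x) {
  if (inherits(x, "cohort")) x <- lifetable(x)
  stopifnot(inherits(x, "lifetable"))
  list(f_xj = x$f_xj, m_x = x$m_x, lxmx = x$lxmx)
}

#' Age-stage life expectancy
#'
#' e_xj: the expected remaining days of life (counting the current day)
#' of an individual at age x in stage j, obtained by summing the
#' Markov-propagated conditional survival over all later ages and
#' stages.  e at (0, egg) equals the cohort's mean lifespan exactly.
#'
#' @param x A `"cohort"` or `"lifetable"` object.
#' @return Matrix of life expectancies (`NA` for unoccupied cells).
#' @export
life_expectancy <- function(x) {
  if (inherits(x, "cohort")) x <- lifetable(x)
  stopifnot(inherits(x, "lifetable"))
  x$e_xj
}

#' Age-stage reproductive value
#'
#' v_xj: the expected contribution of an individual at age x in stage j
#' to future population growth, discounted at the intrinsic rate r.
#' v at (0, egg) equals the finite rate lambda.
#'
#' @param x A `"cohort"` or `"lifetable"` object.
#' @return Matrix of reproductive values (`NA` for unoccupied cells).
#' @export
reproductive_value <- function(x) {
  if (inherits(x, "cohort")) x <- lifetable(x)
  stopifnot(inherits(x, "lifetable"))
  x$v_xj
}

#' Net reproductive rate
#'
#' R0 = sum_x l_x m_x: expected offspring per initial individual.  On
#' every two-sex cohort R0 also equals the mean fecundity per female
#' times the female ratio N_f / n01, exactly.
#'
#' @param x A `"cohort"` or `"lifetable"` object, or an lxmx vector.
#' @return R0.
#' @export
net_reproductive_rate <- function(x) {
  if (inherits(x, "cohort")) x <- lifetable(x)
  if (inherits(x, "lifetable")) return(sum(x$lxmx))
  sum(x)
}

#' Population parameters of a cohort
#'
#' All scalar life-table outputs: R0, r, lambda, T, GRR, mean fecundity
#' per female, female ratio, male-to-female ratio, and the cohort
#' summary means (stage durations, preadult duration, adult
#' longevities, lifespan, APOP, TPOP, oviposition days).
#'
#' @param x A `"cohort"` or `"lifetable"` object.
#' @return Named list of parameters.
#' @export
population_parameters <- function(x) {
  if (inherits(x, "cohort")) x <- lifetable(x)
  stopifnot(inherits(x, "lifetable"))
  x$params
}

#' @export
coef.lifetable <- function(object, ...) {
  p <- object$params
  unlist(p[c("R0", "r", "lambda", "T", "GRR")])
}

#' @export
print.lifetable <- function(x, digits = 4, ...) {
  p <- x$params
  cat("Age-stage, two-sex life table\n")
  cat("  cohort: n01 =", n01(x$cohort), "individuals,",
      length(x$cohort$stage_order), "stages, max age", nrow(x$counts) - 1, "days\n")
  fmt <- function(v) if (is.na(v)) "NA" else format(signif(v, digits))
  cat("  R0     =", fmt(p$R0), "offspring/individual\n")
  cat("  r      =", fmt(p$r), "per day\n")
  cat("  lambda =", fmt(p$lambda), "per day\n")
  cat("  T      =", fmt(p$T), "days\n")
  cat("  GRR    =", fmt(p$GRR), "offspring/individual\n")
  invisible(x)
}

#' @export
summary.lifetable <- function(object, ...) {
  structure(list(params = object$params, n01 = n01(object$cohort),
                 stage_order = object$cohort$stage_order),
            class = "summary.lifetable")
}

#' @export
print.summary.lifetable <- function(x, digits = 4, ...) {
  cat("Age-stage, two-sex life table (n01 =", x$n01, ")\n\n")
  cat("Population parameters:\n")
  main <- c("R0", "r", "lambda", "T", "GRR", "mean_fecundity",
            "female_ratio", "male_female_ratio")
  for (k in main)
    cat(sprintf("  %-18s %s\n", k, format(signif(x$params[[k]], digits))))
  cat("\nCohort means (days unless noted):\n")
  rest <- setdiff(names(x$params), main)
  for (k in rest)
    cat(sprintf("  %-18s %s\n", k, format(signif(x$params[[k]], digits))))
  invisible(x)
}

#' Plot life-table curves
#'
#' Draws the classic cohort panels: age-stage survival curves s_xj,
#' the fecundity panel (l_x, female age-stage fecundity, m_x, l_x m_x),
#' age-stage life expectancy e_xj, or age-stage reproductive value
#' v_xj.
#'
#' @param x A `"lifetable"` object.
#' @param which One of `"survival"`, `"fecundity"`, `"expectancy"`,
#'   `"value"`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.lifetable <- function(x, which = c("survival", "fecundity",
                                        "expectancy", "value"), ...) {
  which <- match.arg(which)
  ages <- as.integer(rownames(x$counts))
  beta <- ncol(x$counts)
  cols <- grDevices::hcl.colors(beta, "Dark 3")
  if (which == "survival") {
    graphics::matplot(ages, x$s_xj, type = "l", lty = 1, col = cols,
                      xlab = "Age (days)", ylab = expression(s[xj]),
                      main = "Age-stage survival rate", ...)
    graphics::legend("topright", colnames(x$counts), col = cols, lty = 1, cex = 0.7)
  } else if (which == "fecundity") {
    fcol <- beta - 1L
    ymax <- max(x$f_xj[, fcol], x$m_x, x$lxmx, 1)
    graphics::plot(ages, x$l_x, type = "l", ylim = c(0, 1), xlab = "Age (days)",
                   ylab = expression(l[x]), main = "Survival and fecundity", ...)
    graphics::par(new = TRUE)
    graphics::matplot(ages, cbind(x$f_xj[, fcol], x$m_x, x$lxmx), type = "l",
                      lty = 2:4, col = c("firebrick", "darkorange", "navy"),
                      axes = FALSE, xlab = "", ylab = "", ylim = c(0, ymax))
    graphics::axis(4)
    graphics::legend("topleft", c("l_x", "f_x (female)", "m_x", "l_x m_x"),
                     col = c("black", "firebrick", "darkorange", "navy"),
                     lty = 1:4, cex = 0.7)
  } else if (which == "expectancy") {
    graphics::matplot(ages, x$e_xj, type = "l", lty = 1, col = cols,
                      xlab = "Age (days)", ylab = expression(e[xj]),
                      main = "Age-stage life expectancy", ...)
    graphics::legend("topright", colnames(x$counts), col = cols, lty = 1, cex = 0.7)
  } else {
    graphics::matplot(ages, x$v_xj, type = "l", lty = 1, col = cols,
                      xlab = "Age (days)", ylab = expression(v[xj]),
                      main = "Age-stage reproductive value", ...)
    graphics::legend("topright", colnames(x$counts), col = cols, lty = 1, cex = 0.7)
  }
  invisible(x)
}
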