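check_dose_data <- function(data, require_positive = 2L) {
  need <- c("concentration", "n_treated", "n_dead")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dose-response data must have columns ", paste(need, collapse = ", "),
         "; missing: ", paste(miss, collapse = ", "))
  if (any(data$concentration < 0)) stop("concentrations must be >= 0")
  if (any(data$n_treated <= 0)) stop("n_treated must be positive")
  if (any(data$n_dead < 0 | data$n_dead > data$n_treated))
    stop("n_dead must lie in [0, n_treated]")
  pos <- data$concentration > 0
  if (length(unique(data$concentration[pos])) < require_positive)
    stop("at least ", require_positive,
         " distinct positive concentrations are required")
  invisible(data)
}

#' Abbott's correction for control mortality
#'
#' Rescales treated mortalities by the pooled control mortality c:
#' p' = (p - c) / (1 - c), clamped at 0; treated counts are re-expressed
#' as effective (possibly non-integer) dead counts.  Control rows
#' (concentration 0) are returned unchanged.  With zero control
#' mortality the data are returned as-is.
#'
#' @param data Data frame with columns `concentration`, `n_treated`,
#'   `n_dead`, including at least one control row (concentration 0).
#' @return The corrected data frame.
#' @export
abbott_correction <- function(data) {
  check_dose_data(data)
  ctrl <- data$concentration == 0
  if (!any(ctrl)) stop("Abbott's correction requires a control record (concentration 0)")
  cc <- sum(data$n_dead[ctrl]) / sum(data$n_treated[ctrl])
  if (cc >= 1) stop("control mortality is 100%; correction is undefined")
  if (cc == 0) return(data)
  p <- data$n_dead / data$n_treated
  p_corr <- pmax(0, (p - cc) / (1 - cc))
  data$n_dead <- ifelse(ctrl, data$n_dead, p_corr * data$n_treated)
  data
}

#' Fit a probit dose-mortality model
#'
#' Maximum-likelihood probit regression of binomial mortality on log10
#' concentration: probit(pi) = intercept + slope * log10(dose), fitted
#' with [stats::glm()].  Goodness of fit is the Pearson chi-square over
#' dose groups with df = groups - 2; when chi-square exceeds its df the
#' heterogeneity factor h = chi2/df inflates all variances and the
#' normal deviate is replaced by a t deviate on df degrees of freedom
#' in the confidence limits (Finney's convention, as in the classic
#' probit packages).
#'
#' @param data Data frame with columns `concentration` (mg/L),
#'   `n_treated`, `n_dead`, optionally `replicate`; rows with
#'   concentration 0 are controls and are excluded from the fit (see
#'   [abbott_correction()]).
#' @param abbott Apply Abbott's correction for control mortality before
#'   fitting (off by default).
#' @return Object of class `"probit_fit"` with elements `coefficients`
#'   (intercept, slope), `vcov` (unscaled), `se` (heterogeneity-inflated
#'   standard errors), `chi2`, `df`, `heterogeneity`, `lc50`, `groups`
#'   (per-concentration totals), `data`, `call`.
#' @seealso [lc()], [resistance_ratio()]
#' @export
probit_fit <- function(data, abbott = FALSE) {
  check_dose_data(data)
  if (abbott) data <- abbott_correction(data)
  d <- data[data$concentration > 0, , drop = FALSE]
  grp <- stats::aggregate(cbind(n_treated, n_dead) ~ concentration, d, sum)
  prop <- grp$n_dead / grp$n_treated
  if (all(prop == 0) || all(prop == 1))
    stop("non-identifiable probit model: all subjects ",
         if (all(prop == 1)) "dead" else "alive")
  if (all(prop %in% c(0, 1)))
    stop("non-identifiable probit model: complete separation of dose groups")
  resp <- d$n_dead / d$n_treated
  fit <- withCallingHandlers(
    stats::glm(resp ~ log10(d$concentration), family = stats::binomial("probit"),
               weights = d$n_treated),
    warning = function(w) {
      if (grepl("non-integer #successes", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged) stop("probit fit did not converge")
  ab <- unname(stats::coef(fit))
  V <- unname(stats::vcov(fit))
  if (any(!is.finite(V)) || sqrt(V[2, 2]) > 100 * max(abs(ab[2]), 1))
    stop("non-identifiable probit model (unstable slope estimate)")
  pi_hat <- stats::pnorm(ab[1] + ab[2] * log10(grp$concentration))
  chi2 <- sum((grp$n_dead - grp$n_treated * pi_hat)^2 /
                (grp$n_treated * pi_hat * (1 - pi_hat)))
  df <- nrow(grp) - 2L
  h <- if (df > 0) max(1, chi2 / df) else 1
  structure(list(
    coefficients = c(intercept = ab[1], slope = ab[2]),
    vcov = V, se = sqrt(h * diag(V)), chi2 = chi2, df = df,
    heterogeneity = h, lc50 = 10^(-ab[1] / ab[2]),
    groups = grp, data = data, glm = fit, call = match.call()
  ), class = "probit_fit")
}

#' @export
coef.probit_fit <- function(object, ...) object$coefficients

#' @export
vcov.probit_fit <- function(object, heterogeneity = TRUE, ...) {
  if (heterogeneity) object$heterogeneity * object$vcov else object$vcov
}

#' @export
predict.probit_fit <- function(object, newdata, ...) {
  conc <- if (is.data.frame(newdata)) newdata$concentration else newdata
  stats::pnorm(object$coefficients[1] + object$coefficients[2] * log10(conc))
}

#' @export
print.probit_fit <- function(x, digits = 4, ...) {
  cat("Probit dose-mortality fit (probit(pi) = a + b log10 dose)\n")
  cat(sprintf("  slope     = %s +/- %s\n",
              signif(x$coefficients[2], digits), signif(x$se[2], digits)))
  cat(sprintf("  intercept = %s\n", signif(x$coefficients[1], digits)))
  cat(sprintf("  LC50      = %s mg/L\n", signif(x$lc50, digits)))
  cat(sprintf("  chi2 = %s on %d df (heterogeneity factor %s)\n",
              signif(x$chi2, digits), x$df, signif(x$heterogeneity, digits)))
  invisible(x)
}

#' @export
summary.probit_fit <- function(object, p = c(25, 50, 90), ...) {
  structure(list(fit = object, lc = lc(object, p)), class = "summary.probit_fit")
}

#' @export
print.summary.probit_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nLethal concentrations (mg/L):\n")
  print(cbind(p = x$lc$p, round(x$lc[, c("lc", "lower", "upper")], 3)))
  invisible(x)
}

#' @export
plot.probit_fit <- function(x, ...) {
  grp <- x$groups
  lx <- log10(grp$concentration)
  graphics::plot(lx, grp$n_dead / grp$n_treated, pch = 16, ylim = c(0, 1),
                 xlab = "log10 concentration (mg/L)", ylab = "Mortality",
                 main = "Probit dose-mortality fit", ...)
  xx <- seq(min(lx) - 0.5, max(lx) + 0.5, length.out = 200)
  graphics::lines(xx, stats::pnorm(x$coefficients[1] + x$coefficients[2] * xx))
  invisible(x)
}

#' Lethal concentration estimates with confidence limits
#'
#' LC_p = 10^((qnorm(p/100) - intercept)/slope).  Confidence limits are
#' computed on the log10 scale by Fieller's theorem (the fiducial
#' limits of classic probit analysis), with the heterogeneity factor
#' inflating the variance-covariance matrix and a t deviate replacing
#' the normal deviate when the fit is heterogeneous; a delta-method
#' alternative is available for comparison.
#'
#' @param fit A `"probit_fit"` object.
#' @param p Percent mortality level(s), strictly between 0 and 100.
#' @param level Confidence level.
#' @param method `"fieller"` (default) or `"delta"`.
#' @return Data frame with columns `p`, `lc`, `lower`, `upper` (mg/L).
#' @export
lc <- function(fit, p = c(25, 50), level = 0.95, method = c("fieller", "delta")) {
  stopifnot(inherits(fit, "probit_fit"))
  method <- match.arg(method)
  if (any(p <= 0 | p >= 100)) stop("p must be strictly between 0 and 100")
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  if (b <= 0) stop("non-positive slope: lethal concentrations are not finite")
  V <- fit$heterogeneity * fit$vcov
  tq <- if (fit$heterogeneity > 1 && fit$df > 0)
    stats::qt(1 - (1 - level) / 2, fit$df) else stats::qnorm(1 - (1 - level) / 2)
  out <- lapply(p, function(pp) {
    z <- stats::qnorm(pp / 100)
    N <- z - a                       # numerator of log10 LC
    rho <- N / b
    if (method == "fieller") {
      vNN <- V[1, 1]; vbb <- V[2, 2]; vNb <- -V[1, 2]
      A <- b^2 - tq^2 * vbb
      Bq <- N * b - tq^2 * vNb
      disc <- Bq^2 - A * (N^2 - tq^2 * vNN)
      if (A <= 0 || disc < 0) {
        warning("Fieller limits are unbounded (g >= 1); returning NA limits")
        lims <- c(NA_real_, NA_real_)
      } else {
        roots <- (Bq + c(-1, 1) * sqrt(disc)) / A
        lims <- 10^roots
      }
    } else {
      # delta method on rho = (z - a)/b: gradient (-1/b, -rho/b)
      vr <- (V[1, 1] + rho^2 * V[2, 2] + 2 * rho * V[1, 2]) / b^2
      lims <- 10^(rho + c(-1, 1) * tq * sqrt(vr))
    }
    data.frame(p = pp, lc = 10^rho, lower = lims[1], upper = lims[2])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Lethal concentrations implied by a published slope and LC50
#'
#' The probit model implies log10 LC_p is affine in the normal quantile:
#' LC_p = LC50 * 10^(qnorm(p/100)/slope).  This reconstructs LC_p point
#' estimates from a reported slope/LC50 pair, e.g. to check the internal
#' consistency of published dose-mortality tables.
#'
#' @param slope Probit slope (probits per log10 concentration).
#' @param lc50 Median lethal concentration.
#' @param p Percent mortality level(s).
#' @return Numeric vector of LC_p values in the units of `lc50`.
#' @export
lc_points <- function(slope, lc50, p) {
  if (any(slope <= 0)) stop("slope must be positive")
  if (any(lc50 <= 0)) stop("lc50 must be positive")
  if (any(p <= 0 | p >= 100)) stop("p must be strictly between 0 and 100")
  lc50 * 10^(stats::qnorm(p / 100) / slope)
}

#' Resistance ratio
#'
#' LC50 of the test (resistant) strain divided by the LC50 of the
#' susceptible reference strain.
#'
#' @param lc50_test,lc50_reference Median lethal concentrations.
#' @param reference Optional label of the reference strain, stored as an
#'   attribute.
#' @return The resistance ratio (dimensionless).
#' @export
resistance_ratio <- function(lc50_test, lc50_reference, reference = NULL) {
  if (any(lc50_test <= 0)) stop("test LC50 must be positive")
  if (any(lc50_reference <= 0)) stop("reference LC50 must be positive")
  rr <- lc50_test / lc50_reference
  if (!is.null(reference)) attr(rr, "reference") <- reference
  rr
}
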