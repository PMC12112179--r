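#' Bootstrap a cohort life table
#'
#' Resamples the initial individuals (eggs) with replacement, `n01`
#' draws per replicate, and recomputes every population parameter and
#' cohort summary mean through the same code path as [lifetable()].
#' Replicates on which a parameter is undefined (for example r, lambda
#' and T when the resample has no reproducing female, so R0 = 0 and the
#' Euler-Lotka equation has no root) are excluded from that parameter's
#' mean and standard error, with the exclusion count recorded; R0 and
#' GRR contribute 0 on such replicates.
#'
#' @param cohort A [cohort()] object.
#' @param B Number of bootstrap replicates (the default is desk-scale;
#'   raise it for publication-grade standard errors).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `"lifetable_boot"`: list with `replicates`
#'   (B x parameter matrix), `mean`, `se` (standard deviation of the
#'   replicates), `excluded` (NA counts per parameter), `point` (the
#'   full-cohort parameter vector), `B` and `seed`.
#' @export
bootstrap_lifetable <- function(cohort, B = 2000, seed = NULL) {
  assert_valid_cohort(cohort)
  if (B < 1) stop("B must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  arr <- lt_arrays(cohort)
  n <- n01(cohort)
  point <- lt_stats(arr, seq_len(n))$params
  reps <- matrix(NA_real_, B, length(point),
                 dimnames = list(NULL, names(point)))
  for (k in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    reps[k, ] <- lt_stats(arr, idx)$params
  }
  structure(list(
    B = B, seed = seed, parameters = colnames(reps), replicates = reps,
    mean = colMeans(reps, na.rm = TRUE),
    se = apply(reps, 2, stats::sd, na.rm = TRUE),
    excluded = colSums(is.na(reps)),
    point = point, n01 = n
  ), class = "lifetable_boot")
}

#' @export
print.lifetable_boot <- function(x, digits = 4, ...) {
  cat("Bootstrap life-table estimates (B = ", x$B,
      if (!is.null(x$seed)) paste0(", seed = ", x$seed), ")\n", sep = "")
  main <- intersect(c("R0", "r", "lambda", "T", "GRR", "mean_fecundity",
                      "female_ratio", "preadult", "APOP", "TPOP"),
                    x$parameters)
  tab <- data.frame(mean = signif(x$mean[main], digits),
                    se = signif(x$se[main], digits),
                    excluded = x$excluded[main])
  print(tab)
  invisible(x)
}

#' Paired bootstrap test between two strains
#'
#' Pairs the bootstrap replicates of two cohorts by replicate index and
#' tests the per-replicate differences d_k = a_k - b_k of one
#' parameter: the point estimate is the mean difference, the interval
#' is the percentile interval of the differences, and the two-sided
#' p-value is `2 * min(frac(d <= 0), frac(d >= 0))` clamped at 1.
#'
#' @param a,b `"lifetable_boot"` objects with equal `B`.
#' @param parameter Parameter name present in both results.
#' @param level Confidence level of the percentile interval.
#' @return Object of class `"paired_boot_test"` with the mean
#'   difference, interval, p-value and number of replicate pairs used
#'   (pairs where either side is undefined are dropped).
#' @export
paired_bootstrap_test <- function(a, b, parameter, level = 0.95) {
  stopifnot(inherits(a, "lifetable_boot"), inherits(b, "lifetable_boot"))
  if (a$B != b$B) stop("paired bootstrap test requires equal replicate counts")
  if (!parameter %in% a$parameters || !parameter %in% b$parameters)
    stop("unknown parameter: ", parameter)
  d <- a$replicates[, parameter] - b$replicates[, parameter]
  d <- d[!is.na(d)]
  if (!length(d)) stop("no replicate pairs with '", parameter, "' defined")
  alpha <- (1 - level) / 2
  p <- min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
  structure(list(
    parameter = parameter,
    estimate = mean(d),
    ci = stats::quantile(d, c(alpha, 1 - alpha), names = FALSE),
    level = level, p.value = p, B_pairs = length(d)
  ), class = "paired_boot_test")
}

#' @export
print.paired_boot_test <- function(x, digits = 4, ...) {
  cat("Paired bootstrap test:", x$parameter, "\n")
  cat("  difference =", signif(x$estimate, digits),
      sprintf(" [%s, %s] (%.0f%% percentile interval)",
              signif(x$ci[1], digits), signif(x$ci[2], digits), 100 * x$level), "\n")
  cat("  p-value =", format.pval(x$p.value, digits = digits),
      " (", x$B_pairs, "replicate pairs )\n")
  invisible(x)
}

#' Relative fitness
#'
#' The net reproductive rate of a treated (selected) strain divided by
#' that of the control strain.
#'
#' @param R0_treated,R0_control Net reproductive rates.
#' @return Rf, dimensionless.
#' @export
relative_fitness <- function(R0_treated, R0_control) {
  if (any(R0_control <= 0)) stop("control R0 must be positive")
  R0_treated / R0_control
}

#' Pearson correlation of life-table parameters with selection generation
#'
#' Pools the bootstrap replicates of several strains, labelled by their
#' selection-generation number, and reports the Pearson correlation of
#' each parameter with the generation, both over the pooled
#' (generation, replicate) pairs and over the generation means (n =
#' number of generations).  NA replicates are dropped.
#'
#' @param results Named list of `"lifetable_boot"` objects; names must
#'   be coercible to generation numbers unless `generations` is given.
#' @param parameter Parameter name(s); default: all shared parameters.
#' @param generations Optional numeric generation labels.
#' @return Data frame with columns `parameter`, `r_pooled`, `r_means`,
#'   `n_pooled`, `n_generations`.
#' @export
correlate_with_generation <- function(results, parameter = NULL,
                                      generations = NULL) {
  if (length(results) < 2) stop("at least 2 generations are required")
  if (is.null(generations)) generations <- as.numeric(names(results))
  if (anyNA(generations)) stop("generation labels must be numeric")
  params <- Reduce(intersect, lapply(results, `[[`, "parameters"))
  if (is.null(parameter)) parameter <- params
  stopifnot(all(parameter %in% params))
  rows <- lapply(parameter, function(pm) {
    g <- unlist(lapply(seq_along(results), function(i)
      rep(generations[i], results[[i]]$B)))
    v <- unlist(lapply(results, function(res) res$replicates[, pm]))
    ok <- !is.na(v)
    means <- vapply(results, function(res) mean(res$replicates[, pm], na.rm = TRUE),
                    numeric(1))
    data.frame(
      parameter = pm,
      r_pooled = if (stats::sd(v[ok]) > 0) stats::cor(g[ok], v[ok]) else NA_real_,
      r_means = if (stats::sd(means) > 0) stats::cor(generations, means) else NA_real_,
      n_pooled = sum(ok), n_generations = length(results),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
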