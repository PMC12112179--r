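# Short stable checksum of a configuration list, recorded in every
# output header so reruns can be matched to their settings.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_table_stamped <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# seed: ", if (is.null(seed)) "NA" else seed),
               paste0("# config: ", hash)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

matrix_long <- function(m, value = "value") {
  df <- data.frame(
    age = rep(as.integer(rownames(m)), times = ncol(m)),
    stage = rep(colnames(m), each = nrow(m)),
    value = as.vector(m), stringsAsFactors = FALSE)
  names(df)[3] <- value
  df
}

#' Run the full life-table analysis on one cohort and write its outputs
#'
#' Fits [lifetable()] and writes the standard curve tables in long
#' format (`sxj.csv`, `fxj.csv`, `exj.csv`, `vxj.csv` with columns
#' age/stage/value; `lx.csv`, `mx.csv`, `lxmx.csv` with age/value), a
#' one-row `parameters.csv`, a `summaries.csv` of cohort means, and —
#' unless `plots = FALSE` — one PDF per curve family (survival,
#' fecundity, life expectancy, reproductive value).  Every CSV header
#' records the seed and a configuration hash; rerunning the same
#' configuration reproduces the CSVs byte for byte.
#'
#' @param input A [cohort()] object or the path of a cohort CSV.
#' @param out_dir Output directory (created if needed).
#' @param stage_order Census stages used when reading a file.
#' @param seed Seed recorded in the output headers (the fit itself is
#'   deterministic).
#' @param plots Write the PDF plots?
#' @return The fitted `"lifetable"`, invisibly.
#' @export
run_lifetable <- function(input, out_dir, stage_order = default_stage_order(),
                          seed = NULL, plots = TRUE) {
  if (is.character(input)) {
    if (!file.exists(input)) stop("cohort file not found: ", input)
    input <- read_cohort(input, stage_order)
  }
  stopifnot(inherits(input, "cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(fn = "run_lifetable", stage_order = stage_order, seed = seed)
  hash <- config_hash(cfg)
  lt <- lifetable(input)
  ages <- as.integer(rownames(lt$counts))
  w <- function(df, file) write_table_stamped(df, file.path(out_dir, file), seed, hash)
  w(matrix_long(lt$s_xj), "sxj.csv")
  w(matrix_long(lt$f_xj), "fxj.csv")
  w(matrix_long(lt$e_xj), "exj.csv")
  w(matrix_long(lt$v_xj), "vxj.csv")
  w(data.frame(age = ages, value = lt$l_x), "lx.csv")
  w(data.frame(age = ages, value = lt$m_x), "mx.csv")
  w(data.frame(age = ages, value = lt$lxmx), "lxmx.csv")
  w(as.data.frame(lt$params), "parameters.csv")
  w(lt$summaries, "summaries.csv")
  if (plots) {
    panels <- c(survival = "survival", fecundity = "fecundity",
                expectancy = "expectancy", value = "reproductive_value")
    for (k in names(panels)) {
      grDevices::pdf(file.path(out_dir, paste0(panels[k], ".pdf")), 7, 5)
      plot(lt, which = k)
      grDevices::dev.off()
    }
  }
  invisible(lt)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Builds significance letters by the insert-and-absorb algorithm:
#' starting from one group containing every strain, each significant
#' pair splits the groups containing both members, and groups that
#' become subsets of others are absorbed.  Two strains share a letter
#' if and only if they belong to a common surviving group, so strains
#' with the same letter are not significantly different at `alpha`.
#'
#' @param p Symmetric matrix of pairwise p-values with strain names as
#'   dimnames.
#' @param alpha Significance level.
#' @return Named character vector of letter codes.
#' @export
compact_letter_display <- function(p, alpha = 0.05) {
  k <- nrow(p)
  stopifnot(ncol(p) == k, !is.null(rownames(p)))
  groups <- list(rep(TRUE, k))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      if (is.na(p[i, j]) || p[i, j] >= alpha) next
      newg <- list()
      for (g in groups) {
        if (g[i] && g[j]) {
          g1 <- g; g1[j] <- FALSE
          g2 <- g; g2[i] <- FALSE
          newg <- c(newg, list(g1, g2))
        } else newg <- c(newg, list(g))
      }
      # absorb groups that are subsets of another
      keep <- rep(TRUE, length(newg))
      for (a in seq_along(newg)) for (b in seq_along(newg)) {
        if (a != b && keep[a] && keep[b] && all(newg[[a]] <= newg[[b]]) &&
            !identical(newg[[a]], newg[[b]]))
          keep[a] <- FALSE
      }
      if (any(duplicated(newg))) keep[duplicated(newg)] <- FALSE
      groups <- newg[keep]
    }
  }
  ord <- order(vapply(groups, function(g) which(g)[1L], numeric(1)))
  groups <- groups[ord]
  out <- vapply(seq_len(k), function(i)
    paste0(letters[which(vapply(groups, `[`, logical(1), i))], collapse = ""),
    character(1))
  stats::setNames(out, rownames(p))
}

#' Compare strains: bootstrap means, paired tests, letters, fitness and
#' generation correlations
#'
#' Bootstraps every cohort (each strain gets its own seed, derived from
#' `seed` by adding the strain index), computes per-parameter means and
#' standard errors, all pairwise paired bootstrap tests with a compact
#' letter display at `alpha`, relative fitness of every strain against
#' the designated control, and the Pearson correlation of each
#' parameter with the selection generation.
#'
#' @param cohorts Named list of [cohort()] objects or cohort CSV paths.
#' @param generations Numeric generation labels (default: parsed from
#'   the names, else 0, 1, 2, ...).
#' @param control Name or index of the control strain (default: first).
#' @param B Bootstrap replicates per strain.
#' @param seed Master seed; strain i is bootstrapped with `seed + i - 1`.
#' @param alpha Significance level for the letter display.
#' @param parameters Parameters to compare (default: the population
#'   parameters and main cohort summaries).
#' @param out_dir If non-`NULL`, writes `comparison_summary.csv`
#'   (mean, SE and letters per strain and parameter),
#'   `comparison_tests.csv` (pairwise differences, intervals,
#'   p-values), `relative_fitness.csv` and `correlations.csv`, all with
#'   seed/config-hash headers.
#' @return Object of class `"strain_comparison"`.
#' @export
run_strain_comparison <- function(cohorts, generations = NULL, control = 1L,
                                  B = 2000, seed = 1, alpha = 0.05,
                                  parameters = c("R0", "r", "lambda", "T", "GRR",
                                                 "mean_fecundity", "female_ratio",
                                                 "preadult", "adult_longevity",
                                                 "APOP", "TPOP", "ovi_days"),
                                  out_dir = NULL) {
  if (length(cohorts) < 2) stop("at least 2 cohorts are required")
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("strain", seq_along(cohorts))
  cohorts <- lapply(cohorts, function(x) {
    if (is.character(x)) read_cohort(x) else x
  })
  labs <- names(cohorts)
  if (is.null(generations)) {
    generations <- suppressWarnings(as.numeric(labs))
    if (anyNA(generations)) generations <- seq_along(cohorts) - 1
  }
  if (is.character(control)) control <- match(control, labs)
  cfg <- list(fn = "run_strain_comparison", strains = labs,
              generations = generations, control = control, B = B,
              seed = seed, alpha = alpha, parameters = parameters)
  hash <- config_hash(cfg)

  boots <- lapply(seq_along(cohorts), function(i)
    bootstrap_lifetable(cohorts[[i]], B = B, seed = seed + i - 1L))
  names(boots) <- labs
  parameters <- intersect(parameters, boots[[1L]]$parameters)

  k <- length(cohorts)
  summary_rows <- list()
  test_rows <- list()
  letters_tab <- matrix("", length(parameters), k,
                        dimnames = list(parameters, labs))
  for (pm in parameters) {
    pmat <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      tst <- paired_bootstrap_test(boots[[i]], boots[[j]], pm)
      pmat[i, j] <- pmat[j, i] <- tst$p.value
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        parameter = pm, strain_a = labs[i], strain_b = labs[j],
        difference = tst$estimate, lower = tst$ci[1], upper = tst$ci[2],
        p.value = tst$p.value, stringsAsFactors = FALSE)
    }
    letters_tab[pm, ] <- compact_letter_display(pmat, alpha)
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      parameter = pm, strain = labs,
      mean = unname(vapply(boots, function(b) b$mean[pm], numeric(1))),
      se = unname(vapply(boots, function(b) b$se[pm], numeric(1))),
      letters = unname(letters_tab[pm, ]), stringsAsFactors = FALSE)
  }
  r0 <- vapply(boots, function(b) unname(b$point["R0"]), numeric(1))
  rf <- relative_fitness(r0, r0[control])
  correlations <- correlate_with_generation(boots, parameters,
                                            generations = generations)
  out <- structure(list(
    strains = labs, generations = generations, control = labs[control],
    B = B, seed = seed, alpha = alpha, boots = boots,
    summary = do.call(rbind, summary_rows),
    tests = do.call(rbind, test_rows),
    letters = letters_tab,
    relative_fitness = data.frame(strain = labs, generation = generations,
                                  R0 = r0, Rf = rf, stringsAsFactors = FALSE),
    correlations = correlations
  ), class = "strain_comparison")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, file) write_table_stamped(df, file.path(out_dir, file),
                                                seed, hash)
    w(out$summary, "comparison_summary.csv")
    w(out$tests, "comparison_tests.csv")
    w(out$relative_fitness, "relative_fitness.csv")
    w(out$correlations, "correlations.csv")
  }
  out
}

#' @export
print.strain_comparison <- function(x, digits = 4, ...) {
  cat("Strain comparison (", length(x$strains), " strains, B = ", x$B,
      ", control = ", x$control, ")\n\n", sep = "")
  s <- x$summary
  s$mean <- signif(s$mean, digits)
  s$se <- signif(s$se, digits)
  print(s, row.names = FALSE)
  cat("\nRelative fitness (R0 / control R0):\n")
  rf <- x$relative_fitness
  rf$R0 <- signif(rf$R0, digits); rf$Rf <- round(rf$Rf, 2)
  print(rf, row.names = FALSE)
  invisible(x)
}
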