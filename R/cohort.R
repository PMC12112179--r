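#' Default stage order for an insect cohort
#'
#' Eight census stages: egg, four larval instars, pupa, and sexed adult
#' stages.  Adults are split into a female and a male stage (sex is
#' revealed at emergence), so the female adult stage carries the
#' age-stage fecundity.  The last two entries of any stage order must
#' always be the female-adult and male-adult stages, in that order.
#'
#' @return Character vector of stage names.
#' @export
default_stage_order <- function() {
  c("egg", "L1", "L2", "L3", "L4", "pupa", "female", "male")
}

stage_meta <- function(stage_order) {
  beta <- length(stage_order)
  if (beta < 3L) stop("stage_order needs at least one preadult stage plus the two adult stages")
  list(
    beta = beta,
    preadult = stage_order[seq_len(beta - 2L)],
    female = stage_order[beta - 1L],
    male = stage_order[beta]
  )
}

#' Construct a cohort of individual life histories
#'
#' A cohort is the unit of a life-table study: one record per
#' individual followed from the egg on day 0 until death, with daily
#' census resolution.  Stage occupancy on a transition day is
#' attributed to the new stage, and "alive at age x" means alive on day
#' x (day 0 is the first day of the egg stage).
#'
#' @param id Character vector of unique individual labels.
#' @param sex One of `"f"`, `"m"`, `"u"` per individual; `"u"`
#'   (undetermined) is only valid for individuals that died before
#'   adult emergence.
#' @param entry Matrix or data frame of integer stage-entry ages (days),
#'   one row per individual.  Columns are the preadult stages plus a
#'   single `"adult"` column; the adult entry is assigned to the
#'   female-adult or male-adult stage according to `sex`.  `NA` means
#'   the stage was never reached.
#' @param death_age Integer vector: the last day each individual was
#'   alive.
#' @param fecundity List (one element per individual) of named
#'   non-negative integer vectors, names being the ages (days) on which
#'   eggs were laid.  Only females may have entries; zero counts are
#'   dropped.
#' @param stage_order Character vector of census stages; see
#'   [default_stage_order()].
#' @param validate If `TRUE` (default) the cohort invariants are
#'   checked and violation raises an error of class
#'   `"agestage_validation_error"` carrying the validation report.
#'
#' @return An object of class `"cohort"`: a list with elements
#'   `stage_order`, `id`, `sex`, `entry` (n x beta integer matrix of
#'   stage-entry ages), `death_age` and `fecundity`.
#' @export
cohort <- function(id, sex, entry, death_age, fecundity = NULL,
                   stage_order = default_stage_order(), validate = TRUE) {
  meta <- stage_meta(stage_order)
  n <- length(id)
  id <- as.character(id)
  sex <- as.character(sex)
  entry <- as.matrix(entry)
  if (is.null(colnames(entry))) stop("'entry' must have stage names as column names")
  storage.mode(entry) <- "integer"
  death_age <- as.integer(death_age)
  if (length(sex) != n || nrow(entry) != n || length(death_age) != n)
    stop("id, sex, entry and death_age must describe the same number of individuals")

  full <- matrix(NA_integer_, n, meta$beta, dimnames = list(id, stage_order))
  for (s in intersect(colnames(entry), meta$preadult)) full[, s] <- entry[, s]
  if ("adult" %in% colnames(entry)) {
    ad <- entry[, "adult"]
    if (any(sex == "u" & !is.na(ad))) {
      bad <- id[sex == "u" & !is.na(ad)][1L]
      cond <- structure(
        class = c("agestage_validation_error", "error", "condition"),
        list(message = paste0("invalid cohort: individual '", bad,
                              "' has sex 'u' but an adult entry age ",
                              "(sex is revealed at emergence)"),
             call = sys.call(-1),
             report = data.frame(id = bad, rule = "sex-adult",
                                 message = "undetermined sex with adult entry",
                                 stringsAsFactors = FALSE)))
      stop(cond)
    }
    full[sex == "f", meta$female] <- ad[sex == "f"]
    full[sex == "m", meta$male] <- ad[sex == "m"]
  } else {
    for (s in intersect(colnames(entry), c(meta$female, meta$male))) full[, s] <- entry[, s]
  }
  bad <- setdiff(colnames(entry), c(meta$preadult, "adult", meta$female, meta$male))
  if (length(bad)) stop("unknown stage columns in 'entry': ", paste(bad, collapse = ", "))

  if (is.null(fecundity)) fecundity <- rep(list(NULL), n)
  fecundity <- lapply(fecundity, function(f) {
    if (is.null(f) || !length(f)) return(NULL)
    f <- f[f > 0]
    if (!length(f)) return(NULL)
    storage.mode(f) <- "integer"
    f[order(as.integer(names(f)))]
  })

  obj <- structure(
    list(stage_order = stage_order, id = id, sex = sex, entry = full,
         death_age = death_age, fecundity = fecundity),
    class = "cohort"
  )
  if (validate) assert_valid_cohort(obj)
  obj
}

#' Number of individuals at the start of the cohort
#'
#' With no censoring, the initial egg number equals the number of
#' records.
#'
#' @param x A `"cohort"` object.
#' @return Integer cohort size.
#' @export
n01 <- function(x) {
  stopifnot(inherits(x, "cohort"))
  length(x$id)
}

#' Validate a cohort against the life-table invariants
#'
#' Checks, per individual: egg entry at age 0; strictly increasing
#' stage-entry ages along the stage order; death age not before the
#' last stage entry; sex `"u"` only for preadult deaths (and a sexed
#' adult entry for `"f"`/`"m"` individuals that emerged); fecundity
#' only on females, with laying days inside `[adult entry, death age]`.
#'
#' @param x A `"cohort"` object.
#' @return A data frame (the validation report) with columns `id`,
#'   `rule` and `message`; zero rows iff the cohort is valid.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  meta <- stage_meta(x$stage_order)
  issues <- list()
  note <- function(id, rule, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      id = id, rule = rule, message = message, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(x$id)) note("*", "unique-id", "duplicated individual ids")
  for (i in seq_along(x$id)) {
    id <- x$id[i]
    e <- x$entry[i, ]
    present <- which(!is.na(e))
    if (!x$sex[i] %in% c("f", "m", "u"))
      note(id, "sex-code", sprintf("sex '%s' is not one of f/m/u", x$sex[i]))
    if (is.na(e[1L]) || e[1L] != 0L)
      note(id, "egg-entry", "egg entry age must be 0")
    if (length(present) > 1L && any(diff(e[present]) <= 0L))
      note(id, "stage-order", "stage entry ages must be strictly increasing along the stage order")
    if (is.na(x$death_age[i]) || x$death_age[i] < 0L)
      note(id, "death-age", "death_age must be a non-negative integer")
    else if (length(present) && x$death_age[i] < max(e[present]))
      note(id, "death-age", "death_age is before the last stage entry")
    adult_entry <- e[c(meta$female, meta$male)]
    emerged <- any(!is.na(adult_entry))
    if (x$sex[i] == "u" && emerged)
      note(id, "sex-adult", "sex 'u' is only allowed for individuals dying before adult emergence")
    if (x$sex[i] == "f" && !is.na(e[meta$male]))
      note(id, "sex-adult", "female individual has a male-adult entry")
    if (x$sex[i] == "m" && !is.na(e[meta$female]))
      note(id, "sex-adult", "male individual has a female-adult entry")
    f <- x$fecundity[[i]]
    if (!is.null(f)) {
      if (x$sex[i] != "f")
        note(id, "fecundity-sex", "only females may have fecundity records")
      else {
        days <- as.integer(names(f))
        if (any(f < 0L)) note(id, "fecundity-count", "egg counts must be non-negative")
        fa <- e[meta$female]
        if (is.na(fa))
          note(id, "fecundity-range", "fecundity recorded but no adult entry")
        else if (any(days < fa) || any(days > x$death_age[i]))
          note(id, "fecundity-range", "laying days must lie in [adult entry, death_age]")
      }
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(id = character(), rule = character(), message = character(),
                  stringsAsFactors = FALSE)
}

assert_valid_cohort <- function(x) {
  report <- validate_cohort(x)
  if (nrow(report)) {
    msg <- paste0(
      "invalid cohort (", nrow(report), " issue(s)):\n",
      paste(sprintf("  [%s] %s: %s", report$id, report$rule, report$message),
            collapse = "\n"))
    cond <- structure(
      class = c("agestage_validation_error", "error", "condition"),
      list(message = msg, call = sys.call(-1), report = report))
    stop(cond)
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  meta <- stage_meta(x$stage_order)
  nf <- sum(!is.na(x$entry[, meta$female]))
  nm <- sum(!is.na(x$entry[, meta$male]))
  cat("Age-stage cohort: ", n01(x), " individuals (",
      nf, " female adults, ", nm, " male adults, ",
      n01(x) - nf - nm, " preadult deaths)\n", sep = "")
  cat("Stages:", paste(x$stage_order, collapse = " > "), "\n")
  cat("Maximum age:", max(x$death_age), "days\n")
  invisible(x)
}

fec_col <- function(day) paste0("egg_day:", day)

#' Read a cohort from its tabular text format
#'
#' The file is a CSV with one row per individual and columns `id`,
#' `sex` (coded `f`/`m`/`u`), `entry_<stage>` for every preadult stage,
#' `entry_adult`, `death_age`, plus zero or more sparse fecundity
#' columns named `egg_day:<d>` giving eggs laid on day `d`.  Blank
#' entries mean a stage was never reached (or no eggs that day).
#'
#' @param path File to read.
#' @param stage_order Census stages; see [default_stage_order()].
#' @return A validated [cohort()] object.
#' @export
read_cohort <- function(path, stage_order = default_stage_order()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  meta <- stage_meta(stage_order)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "#")
  need <- c("id", "sex", paste0("entry_", meta$preadult), "entry_adult", "death_age")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed cohort file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  entry_cols <- c(paste0("entry_", meta$preadult), "entry_adult")
  for (cl in c(entry_cols, "death_age")) {
    v <- df[[cl]]
    if (is.character(v)) v[v == ""] <- NA
    vi <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & (is.na(vi) | vi != floor(vi)))
    if (length(bad))
      stop("malformed cohort file ", path, ": row ", bad[1L],
           ", column '", cl, "' is not an integer age")
    df[[cl]] <- as.integer(vi)
  }
  fcols <- grep("^egg_day:", names(df), value = TRUE)
  fdays <- as.integer(sub("^egg_day:", "", fcols))
  if (anyNA(fdays)) stop("malformed cohort file ", path, ": bad egg_day column name")
  fec <- lapply(seq_len(nrow(df)), function(i) {
    if (!length(fcols)) return(NULL)
    v <- suppressWarnings(as.numeric(unlist(df[i, fcols])))
    v[is.na(v)] <- 0
    keep <- v > 0
    if (!any(keep)) return(NULL)
    stats::setNames(as.integer(v[keep]), fdays[keep])
  })
  entry <- as.matrix(df[, entry_cols])
  colnames(entry) <- c(meta$preadult, "adult")
  cohort(id = df$id, sex = df$sex, entry = entry, death_age = df$death_age,
         fecundity = fec, stage_order = stage_order)
}

#' Write a cohort to its tabular text format
#'
#' Inverse of [read_cohort()]; `read_cohort(write_cohort(x, f))`
#' reproduces `x` field by field.
#'
#' @param x A `"cohort"` object.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  meta <- stage_meta(x$stage_order)
  adult <- ifelse(x$sex == "f", x$entry[, meta$female], x$entry[, meta$male])
  df <- data.frame(id = x$id, sex = x$sex, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (s in meta$preadult) df[[paste0("entry_", s)]] <- x$entry[, s]
  df$entry_adult <- adult
  df$death_age <- x$death_age
  days <- sort(unique(unlist(lapply(x$fecundity, function(f) as.integer(names(f))))))
  for (d in days) {
    df[[fec_col(d)]] <- vapply(x$fecundity, function(f) {
      if (is.null(f)) 0L else {
        v <- f[as.character(d)]
        if (is.na(v)) 0L else as.integer(v)
      }
    }, integer(1))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-individual life-history summaries
#'
#' One row per individual with: days spent in each stage (occupancy
#' durations, which sum to the lifespan; `NA` for stages never
#' entered), preadult duration (age at adult emergence), adult
#' longevity, lifespan, total fecundity, oviposition days (days with at
#' least one egg), APOP (adult preoviposition period: days from adult
#' emergence to first oviposition) and TPOP (total preoviposition
#' period: age at first oviposition).  Quantities undefined for an
#' individual (e.g. APOP for a male) are `NA`, never zero.
#'
#' @param x A `"cohort"` object.
#' @return A data frame with one row per individual.
#' @export
individual_summaries <- function(x) {
  stopifnot(inherits(x, "cohort"))
  meta <- stage_meta(x$stage_order)
  n <- n01(x)
  beta <- meta$beta
  dur <- matrix(NA_real_, n, beta, dimnames = list(NULL, paste0("dur_", x$stage_order)))
  for (i in seq_len(n)) {
    e <- x$entry[i, ]
    present <- which(!is.na(e))
    ages <- e[present]
    ends <- c(ages[-1L] - 1L, x$death_age[i])
    dur[i, present] <- ends - ages + 1
  }
  adult_entry <- ifelse(x$sex == "f", x$entry[, meta$female],
                        ifelse(x$sex == "m", x$entry[, meta$male], NA_integer_))
  first_egg <- vapply(x$fecundity, function(f)
    if (is.null(f)) NA_real_ else min(as.integer(names(f))), numeric(1))
  total_fec <- vapply(seq_len(n), function(i) {
    if (x$sex[i] != "f" || is.na(adult_entry[i])) return(NA_real_)
    f <- x$fecundity[[i]]
    if (is.null(f)) 0 else sum(f)
  }, numeric(1))
  ovi_days <- vapply(seq_len(n), function(i) {
    if (x$sex[i] != "f" || is.na(adult_entry[i])) return(NA_real_)
    f <- x$fecundity[[i]]
    if (is.null(f)) 0 else sum(f > 0)
  }, numeric(1))
  out <- data.frame(id = x$id, sex = x$sex, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(dur))
  out$preadult <- as.numeric(adult_entry)
  out$adult_longevity <- as.numeric(x$death_age - adult_entry + 1)
  out$female_longevity <- ifelse(x$sex == "f", out$adult_longevity, NA_real_)
  out$male_longevity <- ifelse(x$sex == "m", out$adult_longevity, NA_real_)
  out$lifespan <- as.numeric(x$death_age + 1)
  out$fecundity <- total_fec
  out$ovi_days <- ovi_days
  out$APOP <- first_egg - adult_entry
  out$TPOP <- first_egg
  out
}

#' Extract a sub-cohort by individual index
#'
#' Materializes a resampled (or subset) cohort, re-labelling ids so
#' duplicated draws stay unique.  This is the resampling unit of the
#' bootstrap: the initial individual (egg).
#'
#' @param x A `"cohort"` object.
#' @param idx Integer indices into the individuals (duplicates allowed).
#' @return A `"cohort"` object.
#' @export
cohort_subset <- function(x, idx) {
  stopifnot(inherits(x, "cohort"))
  meta <- stage_meta(x$stage_order)
  adult <- ifelse(x$sex == "f", x$entry[, meta$female], x$entry[, meta$male])
  entry <- cbind(x$entry[idx, meta$preadult, drop = FALSE], adult = adult[idx])
  colnames(entry) <- c(meta$preadult, "adult")
  cohort(id = sprintf("%s.%d", x$id[idx], seq_along(idx)),
         sex = x$sex[idx], entry = entry, death_age = x$death_age[idx],
         fecundity = x$fecundity[idx], stage_order = x$stage_order,
         validate = FALSE)
}
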