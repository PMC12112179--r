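# Small hand-built cohorts used across the suite.  Ages are integer
# days, day 0 = first egg day; entry columns are the preadult stages
# plus a single "adult" column routed to the sexed adult stage.

toy_entry <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("egg", "L1", "L2", "L3", "L4", "pupa", "adult")
  m
}

# Census toy: two L1 deaths on day 6, a male dying day 30, a female
# dying day 35.  Row sums of the count matrix: 4 at age 0, 2 at age 7,
# 1 at age 31.
toy_census_cohort <- function() {
  cohort(
    id = c("a", "b", "c", "d"), sex = c("u", "u", "m", "f"),
    entry = toy_entry(
      c(0, 5, NA, NA, NA, NA, NA),
      c(0, 5, NA, NA, NA, NA, NA),
      c(0, 5, 8, 11, 14, 17, 23),
      c(0, 5, 8, 11, 14, 17, 23)),
    death_age = c(6, 6, 30, 35),
    fecundity = list(NULL, NULL, NULL, c("25" = 3, "26" = 3)))
}

# Fecundity toy: the third individual dies as a pupa on day 20, so the
# female is the only survivor from day 21 on.  She lays 3 + 3 eggs on
# days 25-26: f(25, female) = 3, m_25 = 3, l_25 m_25 = 0.75, R0 = 1.5.
toy_fecundity_cohort <- function() {
  cohort(
    id = c("a", "b", "c", "d"), sex = c("u", "u", "u", "f"),
    entry = toy_entry(
      c(0, 5, NA, NA, NA, NA, NA),
      c(0, 5, NA, NA, NA, NA, NA),
      c(0, 5, 8, 11, 14, 17, NA),
      c(0, 5, 8, 11, 14, 17, 23)),
    death_age = c(6, 6, 20, 35),
    fecundity = list(NULL, NULL, NULL, c("25" = 3, "26" = 3)))
}

# A cohort of n identical clones of the toy female (bootstrap SE = 0).
clone_cohort <- function(n = 10) {
  entry <- toy_entry(c(0, 5, 8, 11, 14, 17, 23))[rep(1, n), , drop = FALSE]
  cohort(id = sprintf("c%02d", seq_len(n)), sex = rep("f", n),
         entry = entry, death_age = rep(35L, n),
         fecundity = rep(list(c("25" = 3, "26" = 3)), n))
}

default_sim_spec <- function(n01 = 100) cohort_spec(n01 = n01)
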