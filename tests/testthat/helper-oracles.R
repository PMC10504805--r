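# Independent oracles and fixture builders used across the suite.

# pairwise-concordance AUC by brute force over all case/control pairs
brute_force_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (a in cases) {
    for (b in controls) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(cases) * length(controls))
}

# G statistic (likelihood-ratio chi-square) of a 2x2 exposure-by-outcome
# table from closed-form binomial log-likelihoods
g_statistic_2x2 <- function(n11, n10, n01, n00) {
  # n11 events among exposed, n10 non-events among exposed, etc.
  ll_binom <- function(k, n) {
    if (n == 0 || k == 0 || k == n) return(0)
    p <- k / n
    k * log(p) + (n - k) * log(1 - p)
  }
  n1 <- n11 + n10
  n0 <- n01 + n00
  k <- n11 + n01
  ll_full <- ll_binom(n11, n1) + ll_binom(n01, n0)
  ll_null <- ll_binom(k, n1 + n0)
  2 * (ll_full - ll_null)
}

# Hanley-McNeil asymptotic standard error of an AUC estimate
hanley_mcneil_se <- function(a, n1, n0) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
         (n1 * n0))
}

# one fully complete participant record, with overridable fields
make_participant <- function(id = 1L, dentate_2006 = TRUE,
                             edentulous_2018 = FALSE, age = 67L,
                             race = "Caucasian", gender = "Female",
                             education = "CollegePlus", smoking = "Never",
                             dental_visit_2y = "Within2y",
                             alcohol = "Drinks", cognition_score = 30L,
                             self_rated_health = "GoodPlus", lonely = "No",
                             income = "Ge75k") {
  data.frame(id = id, dentate_2006 = dentate_2006,
             edentulous_2018 = edentulous_2018, age = age, race = race,
             gender = gender, education = education, smoking = smoking,
             dental_visit_2y = dental_visit_2y, alcohol = alcohol,
             cognition_score = cognition_score,
             self_rated_health = self_rated_health, lonely = lonely,
             income = income, stringsAsFactors = FALSE)
}

make_participants <- function(n, seed = 1L) {
  cohort <- generate_cohort(synthetic_config(n = n, seed = seed))
  data.frame(id = cohort$id, dentate_2006 = TRUE,
             edentulous_2018 = cohort$outcome == 1L, age = cohort$age,
             race = as.character(cohort$race),
             gender = as.character(cohort$gender),
             education = as.character(cohort$education),
             smoking = as.character(cohort$smoking),
             dental_visit_2y = as.character(cohort$dental_visit),
             alcohol = as.character(cohort$alcohol),
             cognition_score = cohort$cognition_score,
             self_rated_health = as.character(cohort$self_rated_health),
             lonely = as.character(cohort$loneliness),
             income = as.character(cohort$income),
             stringsAsFactors = FALSE)
}

# memoized large cohort from the published generating equation, shared by
# the parameter-recovery checks
.big_cohort_cache <- new.env(parent = emptyenv())
big_truth_cohort <- function(n = 100000L, seed = 20260901L) {
  key <- paste0("n", n, "s", seed)
  if (is.null(.big_cohort_cache[[key]])) {
    .big_cohort_cache[[key]] <- generate_cohort(
      synthetic_config(n = n, seed = seed))
  }
  .big_cohort_cache[[key]]
}

published_coefficients <- function() {
  c(intercept = -4.866, R1 = 0.472, R2 = 0.322, R3 = -0.130, G = 0.078,
    A = 0.158, E0 = 0.908, E1 = 0.646, S0 = 1.261, S1 = 0.389, D = 0.850,
    C = 0.599)
}

# independent Monte Carlo oracle for the expected incidence of the
# independence generator: draws covariates directly with sample() and
# evaluates L by explicit arithmetic (no package encoding path)
oracle_expected_incidence <- function(n = 1e6, seed = 999L) {
  withr::local_seed(seed)
  draw <- function(counts) {
    sample(names(counts), n, replace = TRUE, prob = counts / sum(counts))
  }
  race <- draw(c(Caucasian = 3198, AfricanAmerican = 547, Hispanic = 441,
                 Other = 102))
  gender <- draw(c(Female = 2491, Male = 1797))
  education <- draw(c(CollegePlus = 1199, NoHS = 615,
                      LessThanCollege = 2474))
  smoking <- draw(c(Never = 2094, Current = 398, Former = 1796))
  dental <- draw(c(Within2y = 3319, Over2y = 969))
  cognition_low <- sample(c(1, 0), n, replace = TRUE,
                          prob = c(1424, 2864) / 4288)
  lo <- pnorm((50.5 - 66.3) / 8.4)
  age <- floor(66.3 + 8.4 * qnorm(runif(n, lo, 1)) + 0.5)
  L <- -4.866 +
    0.472 * (race == "AfricanAmerican") +
    0.322 * (race == "Hispanic") -
    0.130 * (race == "Other") +
    0.078 * (gender == "Male") +
    0.158 * (age / 10) +
    0.908 * (education == "NoHS") +
    0.646 * (education == "LessThanCollege") +
    1.261 * (smoking == "Current") +
    0.389 * (smoking == "Former") +
    0.850 * (dental == "Over2y") +
    0.599 * cognition_low
  mean(1 / (1 + exp(-L)))
}

# rebuild a cohort whose marginals reproduce a published cross-tab row
cohort_from_counts <- function(var, counts_by_outcome) {
  # counts_by_outcome: named list level -> c(dentate, edentulous)
  rows <- list()
  template <- make_participant()
  for (lev in names(counts_by_outcome)) {
    k <- counts_by_outcome[[lev]]
    for (j in 1:2) {
      if (k[j] == 0) next
      r <- template[rep(1, k[j]), ]
      r[[var]] <- lev
      r$edentulous_2018 <- (j == 2)
      rows[[length(rows) + 1]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$id <- seq_len(nrow(out))
  apply_eligibility(out)$cohort
}

cramers_v <- function(x, y) {
  tab <- table(x, y)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  sqrt(unname(chi2) / (sum(tab) * (min(dim(tab)) - 1)))
}
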