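#' Default marginal category probabilities of the emulated analytic cohort
#'
#' Category proportions derived from the published frequency table of the
#' n = 4,288 analytic cohort (e.g. 398/4,288 current smokers, 547/4,288
#' African American participants).
#'
#' @return named list of per-variable category probability vectors.
#' @export
default_marginals <- function() {
  lapply(default_marginal_counts(), function(x) x / sum(x))
}

# the underlying published counts (n = 4,288)
default_marginal_counts <- function() {
  list(
    race              = c(Caucasian = 3198, AfricanAmerican = 547,
                          Hispanic = 441, Other = 102),
    gender            = c(Female = 2491, Male = 1797),
    education         = c(CollegePlus = 1199, NoHS = 615,
                          LessThanCollege = 2474),
    smoking           = c(Never = 2094, Current = 398, Former = 1796),
    dental_visit      = c(Within2y = 3319, Over2y = 969),
    alcohol           = c(Drinks = 2490, DoesNotDrink = 1798),
    cognition         = c(Normal = 2864, Low = 1424),
    self_rated_health = c(GoodPlus = 3558, FairPoor = 730),
    loneliness        = c(No = 3706, Yes = 582),
    income            = c(Ge75k = 1275, Lt25k = 1011, From25to75k = 2002)
  )
}

# Category order from least to most "disadvantaged" for the shared latent
# factor; variables not listed do not load on the factor.
disadvantage_order <- function() {
  list(
    education         = c("CollegePlus", "LessThanCollege", "NoHS"),
    income            = c("Ge75k", "From25to75k", "Lt25k"),
    smoking           = c("Never", "Former", "Current"),
    dental_visit      = c("Within2y", "Over2y"),
    cognition         = c("Normal", "Low"),
    self_rated_health = c("GoodPlus", "FairPoor"),
    loneliness        = c("No", "Yes")
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the analytic cohort behind the published prediction
#' equation: n = 4,288, the published marginal category frequencies, age
#' distributed Normal(66.3, 8.4) truncated to adults over 50 and rounded to
#' whole years, and the outcome generated from the published logistic
#' equation (see [edentulism_equation()]).
#'
#' @param n cohort size (default 4288).
#' @param marginals named list of per-variable category probabilities, each
#'   summing to 1 within 1e-9; defaults to [default_marginals()], the
#'   published frequencies.
#' @param age_mean,age_sd,age_floor age distribution in years; the latent
#'   normal is truncated so rounded ages are `>= age_floor` (default 51,
#'   adults over 50).
#' @param true_coefficients named term coefficients of the generating
#'   equation; terms absent from the list have no effect.  Default: the
#'   published 11-term equation.
#' @param intercept intercept of the generating equation (default -4.866).
#' @param dependence latent-factor loading in \[0, 1): 0 draws covariates
#'   independently; larger values correlate the disadvantage-related
#'   covariates (education, income, smoking, dental visit, cognition,
#'   self-rated health, loneliness) through one shared standard-normal
#'   factor that shifts each variable's cut-points.  Marginals are
#'   preserved.
#' @param target_incidence optional proportion in (0, 1); when set, the
#'   intercept is re-solved by monotone root-finding so the cohort's
#'   expected incidence matches it to within 1e-4.
#' @param seed optional integer seed; the global RNG state is restored on
#'   exit.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n = 4288L,
                             marginals = default_marginals(),
                             age_mean = 66.3, age_sd = 8.4,
                             age_floor = 51L,
                             true_coefficients = NULL,
                             intercept = NULL,
                             dependence = 0,
                             target_incidence = NULL,
                             seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (dependence < 0 || dependence >= 1) {
    stop("dependence must be in [0, 1)")
  }
  if (!is.null(target_incidence) &&
      (target_incidence <= 0 || target_incidence >= 1)) {
    stop("target_incidence must be in (0, 1)")
  }
  if (is.null(true_coefficients) || is.null(intercept)) {
    eq <- edentulism_equation()
    if (is.null(true_coefficients)) true_coefficients <- eq$coefficients
    if (is.null(intercept)) intercept <- eq$intercept
  }
  marg <- lapply(seq_along(marginals), function(i) {
    p <- marginals[[i]]
    if (any(p < 0)) stop("marginal has negative entries")
    if (abs(sum(p) - 1) > 1e-9) {
      stop("marginal for '", names(marginals)[i],
           "' does not sum to 1 (within 1e-9)")
    }
    p
  })
  names(marg) <- names(marginals)
  expected <- default_marginal_counts()
  missing_vars <- setdiff(names(expected), names(marg))
  if (length(missing_vars) > 0) {
    stop("marginals missing for: ", paste(missing_vars, collapse = ", "))
  }
  for (v in names(expected)) {
    if (!setequal(names(marg[[v]]), names(expected[[v]]))) {
      stop("marginal for '", v, "' must name categories ",
           paste(names(expected[[v]]), collapse = ", "))
    }
  }
  structure(
    list(n = as.integer(n), marginals = marg, age_mean = age_mean,
         age_sd = age_sd, age_floor = as.integer(age_floor),
         true_coefficients = true_coefficients, intercept = intercept,
         dependence = dependence, target_incidence = target_incidence,
         seed = seed),
    class = "synthetic_config"
  )
}

#' Generate a synthetic analytic cohort
#'
#' Draws a complete-case cohort with the configured marginal structure and a
#' Bernoulli outcome from the configured logistic equation, so every
#' downstream pipeline stage can be exercised without the access-restricted
#' source micro-data.  With `dependence = 0` covariates are mutually
#' independent; the published joint covariate distribution is unknown, so
#' independence is the default.
#'
#' @param config a [synthetic_config()].
#' @return a `cohort_table` with attributes `intercept_used` (the generating
#'   intercept after any re-solving) and `expected_incidence` (mean of the
#'   generating probabilities).
#' @examples
#' cohort <- generate_cohort(synthetic_config(n = 500, seed = 1))
#' mean(cohort$outcome)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(config$seed)
  }
  n <- config$n
  rho <- config$dependence
  f <- if (rho > 0) stats::rnorm(n) else numeric(n)
  dis <- disadvantage_order()

  draw_categorical <- function(v) {
    probs <- config$marginals[[v]]
    ord <- if (v %in% names(dis)) dis[[v]] else names(probs)
    p_ord <- probs[ord]
    lambda <- if (rho > 0 && v %in% names(dis)) rho else 0
    x <- lambda * f + sqrt(1 - lambda^2) * stats::rnorm(n)
    cuts <- stats::qnorm(cumsum(p_ord))
    cuts[length(cuts)] <- Inf
    ord[findInterval(x, cuts, left.open = TRUE) + 1L]
  }

  race <- draw_categorical("race")
  gender <- draw_categorical("gender")
  education <- draw_categorical("education")
  smoking <- draw_categorical("smoking")
  dental_visit <- draw_categorical("dental_visit")
  alcohol <- draw_categorical("alcohol")
  cognition <- draw_categorical("cognition")
  cognition_score <- draw_cognition_score(cognition)
  self_rated_health <- draw_categorical("self_rated_health")
  loneliness <- draw_categorical("loneliness")
  income <- draw_categorical("income")
  age <- draw_truncated_age(n, config$age_mean, config$age_sd,
                            config$age_floor)

  cohort <- data.frame(
    id = seq_len(n), age = age, race = race, gender = gender,
    education = education, smoking = smoking, dental_visit = dental_visit,
    alcohol = alcohol, cognition_score = cognition_score,
    self_rated_health = self_rated_health, loneliness = loneliness,
    income = income, outcome = 0L, stringsAsFactors = FALSE
  )

  X <- encode_design(cohort, model_spec(candidate_variables()))
  beta <- config$true_coefficients
  present <- intersect(names(beta), colnames(X))
  eta0 <- drop(X[, present, drop = FALSE] %*% beta[present])

  b0 <- config$intercept
  if (!is.null(config$target_incidence)) {
    target <- config$target_incidence
    froot <- function(b) mean(stats::plogis(b + eta0)) - target
    b0 <- stats::uniroot(froot, lower = -30, upper = 10,
                         tol = 1e-10)$root
  }
  p <- stats::plogis(b0 + eta0)
  cohort$outcome <- stats::rbinom(n, 1L, p)

  out <- as_cohort_table(cohort)
  attr(out, "intercept_used") <- b0
  attr(out, "expected_incidence") <- mean(p)
  out
}

# integer cognition scores consistent with the Low (< 23) / Normal (>= 23)
# split; within-band shape is a discretised normal (the model only uses the
# dichotomy)
draw_cognition_score <- function(cognition) {
  n <- length(cognition)
  score <- integer(n)
  low <- cognition == "Low"
  if (any(low)) {
    vals <- 0:22
    w <- stats::dnorm(vals, mean = 19, sd = 4)
    score[low] <- sample(vals, sum(low), replace = TRUE, prob = w)
  }
  if (any(!low)) {
    vals <- 23:35
    w <- stats::dnorm(vals, mean = 26, sd = 4)
    score[!low] <- sample(vals, sum(!low), replace = TRUE, prob = w)
  }
  score
}

# truncated-normal ages rounded to whole years, all >= floor
draw_truncated_age <- function(n, mean, sd, floor_years) {
  lo <- stats::pnorm((floor_years - 0.5 - mean) / sd)
  u <- stats::runif(n, lo, 1)
  x <- mean + sd * stats::qnorm(u)
  pmax(as.integer(floor(x + 0.5)), floor_years)
}
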