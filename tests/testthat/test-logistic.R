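make_2x2_design <- function(n11, n10, n01, n00) {
  # exposed: n11 events / n10 non-events; unexposed: n01 / n00
  x <- c(rep(1, n11 + n10), rep(0, n01 + n00))
  y <- c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00))
  list(X = cbind(intercept = 1, x = x), y = y)
}

test_that("fit_logistic matches the closed form on saturated 2x2 problems", {
  d <- make_2x2_design(5, 15, 2, 18)
  fit <- fit_logistic(d$X, d$y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients["x"]), log(3), tolerance = 1e-7)
  expect_equal(unname(fit$coefficients["intercept"]), log(2 / 18),
               tolerance = 1e-7)

  # property: random tables with all cells >= 1
  withr::local_seed(123)
  for (i in 1:25) {
    cells <- 1 + stats::rpois(4, 8)
    d <- make_2x2_design(cells[1], cells[2], cells[3], cells[4])
    fit <- fit_logistic(d$X, d$y)
    expect_true(fit$converged)
    expect_equal(unname(fit$coefficients["intercept"]),
                 log(cells[3] / cells[4]), tolerance = 1e-6)
    expect_equal(unname(fit$coefficients["x"]),
                 log(cells[1] / cells[2]) - log(cells[3] / cells[4]),
                 tolerance = 1e-6)
  }
})

test_that("intercept-only fit on balanced outcomes gives zero", {
  X <- cbind(intercept = rep(1, 100))
  y <- rep(c(0, 1), 50)
  fit <- fit_logistic(X, y)
  expect_equal(unname(fit$coefficients["intercept"]), 0, tolerance = 1e-10)
})

test_that("fit_logistic agrees with glm on realistic cohort data", {
  co <- generate_cohort(synthetic_config(n = 3000, seed = 51))
  X <- encode_design(co, model_spec(c("cognition", "income")))
  fit <- fit_logistic(X, co$outcome)
  ref <- stats::glm.fit(unclass(X), co$outcome,
                        family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(ref$coefficients),
               tolerance = 1e-6)
  expect_equal(fit$log_likelihood,
               -ref$deviance / 2 - 0,
               tolerance = 1e-6)
  # Wald SEs agree with the glm information matrix
  ref_cov <- chol2inv(ref$qr$qr[1:ncol(X), 1:ncol(X)])
  expect_equal(unname(fit$standard_errors), sqrt(diag(ref_cov)),
               tolerance = 1e-4)
})

test_that("degenerate outcomes and collinearity are errors", {
  X <- cbind(intercept = rep(1, 10), x = rnorm(10))
  expect_error(fit_logistic(X, rep(1, 10)), "all-one or all-zero")
  expect_error(fit_logistic(X, rep(0, 10)), "all-one or all-zero")
  X2 <- cbind(X, x2 = X[, "x"] * 2)
  expect_error(fit_logistic(X2, rep(c(0, 1), 5)), "linearly dependent")
})

test_that("complete separation is flagged, not silently returned", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x
  fit <- fit_logistic(cbind(intercept = 1, x = x), y)
  expect_false(fit$converged)
  expect_true(fit$separation)
  expect_error(odds_ratios(fit), "converge")
})

test_that("predict_prob evaluates the published equation correctly", {
  eq <- edentulism_equation()
  ref_row <- c(R1 = 0, R2 = 0, R3 = 0, G = 0, A = 6.7, E0 = 0, E1 = 0,
               S0 = 0, S1 = 0, D = 0, C = 0)
  # all-reference 67-year-old: L = -4.866 + 0.158*6.7 = -3.8074
  expect_equal(predict_prob(eq, ref_row), plogis(-3.8074),
               tolerance = 1e-12)
  expect_equal(round(predict_prob(eq, ref_row), 4), 0.0217)

  risk_row <- c(R1 = 1, R2 = 0, R3 = 0, G = 1, A = 6.7, E0 = 1, E1 = 0,
                S0 = 1, S1 = 0, D = 1, C = 1)
  expect_equal(predict_prob(eq, risk_row), plogis(0.3606),
               tolerance = 1e-12)
  expect_equal(round(predict_prob(eq, risk_row), 3), 0.589)

  # probabilities are strictly inside (0, 1) and increase in risk terms
  expect_gt(predict_prob(eq, risk_row), predict_prob(eq, ref_row))
  one_up <- ref_row; one_up["S0"] <- 1
  expect_gt(predict_prob(eq, one_up), predict_prob(eq, ref_row))

  # an L = 0 equation gives the logistic midpoint
  eq0 <- prediction_equation(0, c(x = 1))
  expect_equal(predict_prob(eq0, c(x = 0)), 0.5)

  expect_error(predict_prob(eq, ref_row[-5]), "missing term.*A")
})

test_that("odds ratios reproduce the published adjusted estimates", {
  eq <- edentulism_equation()
  or <- odds_ratios(eq)
  or_of <- function(term) round(or$or[or$term == term], 2)
  expect_equal(or_of("S0"), 3.53)
  expect_equal(or_of("D"), 2.34)
  expect_equal(or_of("C"), 1.82)
  expect_equal(or_of("R1"), 1.60)
  expect_equal(or_of("E0"), 2.48)
  expect_equal(or_of("S1"), 1.48)
  expect_equal(or_of("E1"), 1.91)
  expect_equal(or_of("R2"), 1.38)
  expect_equal(or_of("R3"), 0.88)
  expect_equal(or_of("G"), 1.08)
  expect_equal(or_of("A"), 1.17)
})

test_that("odds ratio intervals are Wald limits and log-consistent", {
  co <- generate_cohort(synthetic_config(n = 2000, seed = 61))
  X <- encode_design(co, model_spec("cognition"))
  fit <- fit_logistic(X, co$outcome)
  or <- odds_ratios(fit, confidence = 0.95)
  keep <- setdiff(names(fit$coefficients), "intercept")
  # log(OR) returns the coefficient
  expect_equal(log(or$or), unname(fit$coefficients[keep]),
               tolerance = 1e-12)
  z <- qnorm(0.975)
  expect_equal(or$lower,
               exp(unname(fit$coefficients[keep] -
                            z * fit$standard_errors[keep])),
               tolerance = 1e-12)
  expect_true(all(or$lower < or$or & or$or < or$upper))
  # a zero coefficient maps to OR 1
  expect_equal(odds_ratios(prediction_equation(0, c(x = 0)))$or, 1)
})

test_that("factor LRT equals the hand-computed G statistic on 2x2 data", {
  d <- make_2x2_design(7, 13, 3, 27)
  X <- d$X
  colnames(X) <- c("intercept", "D")
  attr(X, "variable_map") <- c(D = "dental_visit")
  res <- lrt_factor(X, d$y, "dental_visit")
  expect_equal(res$statistic, g_statistic_2x2(7, 13, 3, 27),
               tolerance = 1e-6)
  expect_equal(res$df, 1L)
  expect_error(lrt_factor(X, d$y, "smoking"), "not in the model")
})

test_that("factor LRT drops all of a factor's terms", {
  co <- generate_cohort(synthetic_config(n = 2500, seed = 71))
  X <- encode_design(co, model_spec("income"))
  full <- fit_logistic(X, co$outcome)
  race <- lrt_factor(X, co$outcome, "race", full)
  expect_equal(race$df, 3L)
  income <- lrt_factor(X, co$outcome, "income", full)
  expect_equal(income$df, 2L)
  gender <- lrt_factor(X, co$outcome, "gender", full)
  expect_equal(gender$df, 1L)
  expect_true(all(c(race$p_value, income$p_value, gender$p_value) >= 0 &
                    c(race$p_value, income$p_value, gender$p_value) <= 1))
})

test_that("null-effect LRT p-values are uniform", {
  withr::local_seed(202)
  pvals <- replicate(200, {
    x <- rbinom(400, 1, 0.5)
    y <- rbinom(400, 1, 0.3)  # independent of x
    X <- cbind(intercept = 1, G = x)
    attr(X, "variable_map") <- c(G = "gender")
    lrt_factor(X, y, "gender")$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("auc equals brute-force pairwise concordance", {
  expect_equal(auc(c(0.9, 0.4, 0.3, 0.4, 0.1), c(1, 1, 0, 0, 0)), 5.5 / 6)
  expect_equal(auc(rep(0.2, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)

  withr::local_seed(303)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    scores <- round(runif(n), 1)  # coarse grid to force ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels), brute_force_auc(scores, labels))
  }
})

test_that("auc is invariant under strictly increasing transforms", {
  withr::local_seed(404)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, 0.3)
  a <- auc(scores, labels)
  expect_equal(auc(exp(scores), labels), a)
  expect_equal(auc(plogis(scores), labels), a)
  expect_equal(auc(scores * 100 + 3, labels), a)
  expect_error(auc(scores, rep(0, 200)), "both classes")
})

test_that("auc agrees with an independent ROC implementation", {
  withr::local_seed(505)
  scores <- runif(300)
  labels <- rbinom(300, 1, 0.25)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(scores, labels), ref, tolerance = 1e-12)
})
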