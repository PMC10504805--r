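#' Maximum-likelihood logistic regression
#'
#' Fits a binary-outcome logistic model by Newton/IRLS iterations.
#' Convergence is declared when the largest absolute coefficient change
#' falls below `tol_coef` or the log-likelihood change falls below `tol_ll`;
#' at most `max_iter` iterations are taken.  Complete or quasi-complete
#' separation is flagged (any coefficient diverging beyond 15 in absolute
#' value) and the result is marked non-converged rather than returned
#' silently.
#'
#' @param X numeric design matrix including an intercept column (see
#'   [encode_design()]).
#' @param y 0/1 outcome vector, one per row of `X`.
#' @param max_iter,tol_coef,tol_ll iteration controls.
#' @return a `fit_result`: `coefficients`, `standard_errors`, `covariance`,
#'   `log_likelihood`, `converged`, `separation`, `iterations`, `n`,
#'   `n_events`.
#' @export
fit_logistic <- function(X, y, max_iter = 50L, tol_coef = 1e-8,
                         tol_ll = 1e-10) {
  X <- unclass(X)
  vm <- attr(X, "variable_map")
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  if (all(y == 1) || all(y == 0)) {
    stop("outcome is all-one or all-zero; need both classes")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("design matrix columns are linearly dependent (rank ",
         qx$rank, " < ", ncol(X), ")")
  }

  p <- ncol(X)
  beta <- numeric(p)
  eta <- numeric(nrow(X))
  ll <- logistic_loglik_eta(eta, y)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    score <- crossprod(X, y - mu)
    info <- crossprod(X * w, X)
    delta <- tryCatch(solve(info, score),
                      error = function(e) stop(
                        "information matrix is singular: ",
                        conditionMessage(e)))
    beta <- beta + drop(delta)
    eta <- drop(X %*% beta)
    ll_new <- logistic_loglik_eta(eta, y)
    change <- abs(ll_new - ll)
    ll <- ll_new
    if (max(abs(delta)) < tol_coef || change < tol_ll) {
      converged <- TRUE
      break
    }
  }

  separation <- any(abs(beta) > 15)
  if (separation) converged <- FALSE

  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(X * w, X)
  cov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(pmax(diag(cov), 0))
  nm <- colnames(X)
  names(beta) <- nm
  names(se) <- nm
  dimnames(cov) <- list(nm, nm)

  structure(
    list(coefficients = beta,
         standard_errors = se,
         covariance = cov,
         log_likelihood = ll,
         converged = converged,
         separation = separation,
         iterations = iter,
         n = nrow(X),
         n_events = sum(y == 1),
         variable_map = vm),
    class = "fit_result"
  )
}

logistic_loglik <- function(X, y, beta) {
  logistic_loglik_eta(drop(X %*% beta), y)
}

logistic_loglik_eta <- function(eta, y) {
  sum(stats::plogis(ifelse(y == 1, eta, -eta), log.p = TRUE))
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Logistic fit:", x$n, "obs,", x$n_events, "events;",
      if (x$converged) "converged" else
        if (x$separation) "NOT converged (separation)" else "NOT converged",
      "in", x$iterations, "iterations\n")
  tab <- data.frame(coef = x$coefficients, se = x$standard_errors)
  print(round(tab, 4))
  invisible(x)
}

#' Construct a prediction equation
#'
#' A prediction equation is the portable form of a fitted risk model: an
#' intercept plus named term coefficients, evaluated as
#' `p = exp(L) / (1 + exp(L))` on the linear predictor `L`.
#'
#' @param intercept real intercept.
#' @param coefficients named numeric vector of term coefficients (names are
#'   design-matrix terms, e.g. `R1`, `A`, `S0`).
#' @return a `prediction_equation`.
#' @export
prediction_equation <- function(intercept, coefficients) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))))
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients),
            class = "prediction_equation")
}

#' @export
print.prediction_equation <- function(x, ...) {
  terms <- sprintf("%+.3f %s", x$coefficients, names(x$coefficients))
  cat("L =", sprintf("%.3f", x$intercept), paste(terms, collapse = " "),
      "\np = exp(L) / (1 + exp(L))\n")
  invisible(x)
}

#' Convert a fitted model to a prediction equation
#'
#' @param fit a converged `fit_result` whose design included an `intercept`
#'   column.
#' @return a `prediction_equation`.
#' @export
as_prediction_equation <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged) stop("fit did not converge")
  b <- fit$coefficients
  if (!("intercept" %in% names(b))) stop("fit has no intercept term")
  prediction_equation(b[["intercept"]], b[setdiff(names(b), "intercept")])
}

#' The published 12-year edentulism prediction equation
#'
#' Returns the reference 7-variable prediction equation for 12-year incident
#' edentulism among US adults over 50 (HRS 2006 baseline, 2018 outcome),
#' recalibrated on its selection set:
#' `L = -4.866 + 0.472 R1 + 0.322 R2 - 0.130 R3 + 0.078 G + 0.158 A +
#' 0.908 E0 + 0.646 E1 + 1.261 S0 + 0.389 S1 + 0.850 D + 0.599 C`.
#' The constants are shipped as a package fixture
#' (`inst/extdata/edentulism_equation.json`).
#'
#' @return a `prediction_equation`.
#' @examples
#' eq <- edentulism_equation()
#' round(exp(eq$coefficients[["S0"]]), 2)  # adjusted OR, current vs never smoker
#' @export
edentulism_equation <- function() {
  path <- system.file("extdata", "edentulism_equation.json",
                      package = "edentrisk", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  prediction_equation(j$intercept, unlist(j$coefficients))
}

#' Predict outcome probability from a prediction equation
#'
#' Evaluates `p = exp(L)/(1 + exp(L))` for each row of a design matrix.
#'
#' @param eq a `prediction_equation`.
#' @param newdata a `design_matrix` (or numeric matrix with named columns)
#'   supplying every term of `eq`; a single named numeric vector is also
#'   accepted.
#' @return numeric vector of probabilities, strictly inside (0, 1).
#' @examples
#' eq <- edentulism_equation()
#' row <- c(R1 = 0, R2 = 0, R3 = 0, G = 0, A = 6.7, E0 = 0, E1 = 0,
#'          S0 = 0, S1 = 0, D = 0, C = 0)
#' predict_prob(eq, row)  # ~0.0217 for an all-reference 67-year-old
#' @export
predict_prob <- function(eq, newdata) {
  stopifnot(inherits(eq, "prediction_equation"))
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L,
                      dimnames = list(NULL, names(newdata)))
  }
  newdata <- unclass(newdata)
  need <- names(eq$coefficients)
  missing_terms <- setdiff(need, colnames(newdata))
  if (length(missing_terms) > 0) {
    stop("design row is missing term(s): ",
         paste(missing_terms, collapse = ", "))
  }
  L <- eq$intercept + drop(newdata[, need, drop = FALSE] %*%
                             eq$coefficients)
  stats::plogis(L)
}

#' Odds ratios with Wald confidence intervals
#'
#' Exponentiates model coefficients; for a fitted model, Wald limits
#' `exp(b +/- z * SE)` are attached at the requested confidence level.  For a
#' bare [prediction_equation()] (no standard errors) only point odds ratios
#' are returned.
#'
#' @param fit a converged `fit_result` or a `prediction_equation`.
#' @param confidence confidence level (default 0.95).
#' @return a data.frame with columns `term`, `or` and, for fitted models,
#'   `lower`, `upper`.  The intercept is omitted.
#' @export
odds_ratios <- function(fit, confidence = 0.95) {
  stopifnot(confidence > 0, confidence < 1)
  if (inherits(fit, "prediction_equation")) {
    return(data.frame(term = names(fit$coefficients),
                      or = exp(unname(fit$coefficients)),
                      stringsAsFactors = FALSE))
  }
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged) stop("fit did not converge; odds ratios unavailable")
  keep <- setdiff(names(fit$coefficients), "intercept")
  b <- fit$coefficients[keep]
  se <- fit$standard_errors[keep]
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  data.frame(term = keep,
             or = exp(unname(b)),
             lower = exp(unname(b - z * se)),
             upper = exp(unname(b + z * se)),
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio test of a whole factor
#'
#' Type-III style test of a multi-level factor's contribution given all
#' other terms: twice the log-likelihood difference between the full model
#' and the model with the factor's indicator terms removed, referred to a
#' chi-square with as many degrees of freedom as terms dropped.
#'
#' @param X a `design_matrix` carrying a `variable_map` attribute.
#' @param y 0/1 outcome vector.
#' @param factor name of an analysis variable present in `X` (e.g.
#'   `"race"`, `"smoking"`).
#' @param full_fit optional pre-computed full fit of `X` on `y`.
#' @return a list with `statistic`, `df`, `p_value`.
#' @export
lrt_factor <- function(X, y, factor, full_fit = NULL) {
  vm <- attr(X, "variable_map")
  if (is.null(vm)) stop("X must be a design_matrix with a variable_map")
  drop_terms <- names(vm)[vm == factor]
  if (length(drop_terms) == 0) {
    stop("factor '", factor, "' is not in the model")
  }
  if (is.null(full_fit)) full_fit <- fit_logistic(X, y)
  if (!full_fit$converged) stop("full fit did not converge")
  keep <- setdiff(colnames(X), drop_terms)
  Xr <- X[, keep, drop = FALSE]
  attr(Xr, "variable_map") <- vm[setdiff(names(vm), drop_terms)]
  reduced <- fit_logistic(Xr, y)
  if (!reduced$converged) stop("reduced fit did not converge")
  stat <- 2 * (full_fit$log_likelihood - reduced$log_likelihood)
  stat <- max(stat, 0)
  df <- length(drop_terms)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' The probability that a randomly chosen case scores higher than a randomly
#' chosen non-case, with half credit for ties:
#' `(wins + 0.5 * ties) / (cases x controls)`.  Computed from mid-ranks, and
#' identical to the trapezoidal area under the ROC curve over all distinct
#' thresholds.
#'
#' @param scores numeric predictions (any monotone scale).
#' @param labels 0/1 outcome per score.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.4, 0.3, 0.4, 0.1), c(1, 1, 0, 0, 0))  # 5.5/6
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- as.numeric(sum(labels == 1))
  n0 <- as.numeric(sum(labels == 0))
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUC")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
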