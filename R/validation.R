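#' Recalibrate the selected model and score the Test set
#'
#' Refits the selected model to the full Selection set ("recalibration") and
#' applies the updated equation to the Test data, returning the portable
#' prediction equation and the per-record predicted probabilities.
#'
#' @param best the selected [model_spec()].
#' @param selection,test Selection and Test `cohort_table`s.
#' @return a list with `equation` (a [prediction_equation()]), `scores`
#'   (probabilities on the Test records, strictly inside (0,1)), `labels`
#'   (Test outcomes) and `fit` (the Selection-set `fit_result`).
#' @export
validate_final <- function(best, selection, test) {
  stopifnot(inherits(best, "model_spec"))
  X_sel <- encode_design(selection, best)
  fit <- fit_logistic(X_sel, selection$outcome)
  if (!fit$converged) {
    stop("recalibration fit on the selection set did not converge")
  }
  eq <- as_prediction_equation(fit)
  X_test <- encode_design(test, best)
  scores <- predict_prob(eq, X_test)
  list(equation = eq, scores = scores, labels = test$outcome, fit = fit)
}

#' Percentile-bootstrap confidence interval for the test-set AUC
#'
#' Draws `B` with-replacement samples of the full test size, computes the
#' AUC of each, and reports the bootstrap mean together with the empirical
#' 2.5th and 97.5th percentiles (for `confidence = 0.95`).  Bootstrap
#' samples containing a single outcome class are re-drawn (with a count
#' recorded), preserving `B`.
#'
#' @param scores predicted probabilities on the test set.
#' @param labels 0/1 outcomes.
#' @param B number of bootstrap samples (default 1000).
#' @param seed integer seed; the global RNG state is restored on exit.
#' @param confidence confidence level (default 0.95).
#' @return a list with `mean_auc`, `ci_lower`, `ci_upper`, `point_auc`,
#'   `B`, `n_redrawn`, and the full vector `auc_values`.
#' @export
bootstrap_auc <- function(scores, labels, B = 1000L, seed = 1L,
                          confidence = 0.95) {
  if (B < 1) stop("B must be >= 1")
  labels <- as.numeric(labels)
  point <- auc(scores, labels)
  n <- length(scores)
  local_seed(seed)
  vals <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 10000L) {
        stop("bootstrap could not draw a two-class sample")
      }
    }
    vals[b] <- auc(scores[idx], labels[idx])
  }
  alpha <- 1 - confidence
  ci <- stats::quantile(vals, probs = c(alpha / 2, 1 - alpha / 2),
                        names = FALSE)
  list(mean_auc = mean(vals), ci_lower = ci[1L], ci_upper = ci[2L],
       point_auc = point, B = as.integer(B), n_redrawn = n_redrawn,
       auc_values = vals)
}

#' Classification metrics at a probability cutpoint
#'
#' Dichotomises predictions at `cutpoint` (score >= cutpoint counts as
#' predicted positive) and reports the 2x2 confusion table with
#' sensitivity, specificity, positive and negative predictive values.  The
#' default cutpoint is the observed event proportion of the evaluated data
#' (the prevalence cutpoint), unrounded.
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 outcomes.
#' @param cutpoint probability threshold in (0, 1); default
#'   `mean(labels)`.
#' @return a list with `cutpoint`, `confusion` (2x2 integer matrix,
#'   predicted x observed), `sensitivity`, `specificity`, `ppv`, `npv`, and
#'   `undefined` (names of metrics with a zero denominator, reported as
#'   `NA`).
#' @export
classification_metrics <- function(scores, labels,
                                   cutpoint = mean(as.numeric(labels))) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (cutpoint <= 0 || cutpoint >= 1) stop("cutpoint must be in (0, 1)")
  pred <- as.numeric(scores >= cutpoint)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  confusion <- matrix(c(tp, fn, fp, tn), nrow = 2,
                      dimnames = list(predicted = c("positive", "negative"),
                                      observed = c("event", "no_event")))
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(
    cutpoint = cutpoint,
    confusion = confusion,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn)
  )
  out$undefined <- names(which(vapply(
    out[c("sensitivity", "specificity", "ppv", "npv")], is.na, TRUE)))
  out
}

#' ROC curve over all distinct thresholds
#'
#' @param scores predicted probabilities (or any monotone score).
#' @param labels 0/1 outcomes.
#' @return a data.frame of `(fpr, tpr)` pairs starting at (0,0) and ending
#'   at (1,1), both coordinates non-decreasing; attribute `auc` holds the
#'   trapezoidal area, identical to [auc()].
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # collapse tied scores into single ROC vertices
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- data.frame(fpr = c(0, fp[last] / n0),
                    tpr = c(0, tp[last] / n1))
  area <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                 utils::tail(roc$tpr, -1)) / 2)
  attr(roc, "auc") <- area
  roc
}

#' Predicted-risk table for covariate profiles
#'
#' Evaluates a prediction equation over a table of covariate profiles (for
#' example, all combinations of risk factors at a fixed age) and returns
#' the profiles with their predicted probabilities, sorted by descending
#' risk.
#'
#' @param eq a [prediction_equation()].
#' @param profiles a data.frame of covariate columns as in a
#'   `cohort_table` (age in years, `cognition_score`, category labels for
#'   the rest), complete for every variable the equation uses.
#' @return `profiles` with a `risk` column, ordered by descending `risk`.
#' @export
risk_profile_table <- function(eq, profiles) {
  stopifnot(inherits(eq, "prediction_equation"))
  tt <- term_table()
  vars <- unique(tt$variable[tt$term %in% names(eq$coefficients)])
  spec_vars <- intersect(candidate_variables(), vars)
  X <- encode_design(profiles, model_spec(spec_vars))
  risk <- predict_prob(eq, X)
  out <- profiles
  out$risk <- risk
  out[order(-out$risk), , drop = FALSE]
}
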