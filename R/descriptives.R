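#' Table-1 style bivariate description of a cohort
#'
#' Cross-tabulates each analysis variable against the 12-year outcome with
#' row percentages, a Pearson chi-square test on the full cross-tab
#' (continuity correction off by default; a Yates switch is provided for
#' 2x2 tables), and a two-sample t-test for age (Welch's unequal-variance
#' test by default).
#'
#' @param cohort a `cohort_table`.
#' @param yates apply Yates continuity correction to 2x2 chi-square tests
#'   (default `FALSE`).
#' @param pooled_variance use the pooled-variance t-test for age instead of
#'   Welch's (default `FALSE`).
#' @return a `table_one` object: a list with one element per variable, each
#'   holding the category counts by outcome, row percentages (to full
#'   precision; the print method rounds to 1 decimal), and the test
#'   (`statistic`, `df`, `p_value`, `valid`).  The `age` element reports
#'   mean (SD) by outcome group.  Tests with a zero expected cell count are
#'   flagged `valid = FALSE`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n = 2000, seed = 7))
#' t1 <- table_one(cohort)
#' t1$smoking$percent
#' @export
table_one <- function(cohort, yates = FALSE, pooled_variance = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  variables <- c("race", "gender", "education", "smoking", "dental_visit",
                 "alcohol", "cognition", "self_rated_health", "loneliness",
                 "income")
  out <- list()
  outcome <- factor(cohort$outcome, levels = c(0, 1),
                    labels = c("dentate", "edentulous"))

  for (v in variables) {
    vals <- if (v == "cognition") {
      factor(ifelse(cohort$cognition_score < COGNITION_CUT, "Low", "Normal"),
             levels = c("Low", "Normal"))
    } else cohort[[v]]
    tab <- table(vals, outcome)
    pct <- prop.table(tab, margin = 1) * 100
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    valid <- all(expected > 0)
    test <- if (valid) {
      correct <- yates && all(dim(tab) == c(2L, 2L))
      suppressWarnings(stats::chisq.test(tab, correct = correct))
    } else NULL
    out[[v]] <- list(
      counts = tab,
      percent = pct,
      statistic = if (valid) unname(test$statistic) else NA_real_,
      df = if (valid) unname(test$parameter) else NA_real_,
      p_value = if (valid) test$p.value else NA_real_,
      valid = valid
    )
  }

  by_grp <- split(cohort$age, outcome)
  tt <- tryCatch(
    stats::t.test(by_grp$edentulous, by_grp$dentate,
                  var.equal = pooled_variance),
    error = function(e) NULL  # e.g. constant ages
  )
  out$age <- list(
    mean = vapply(by_grp, mean, 0),
    sd = vapply(by_grp, stats::sd, 0),
    statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
    p_value = if (is.null(tt)) NA_real_ else tt$p.value,
    valid = !is.null(tt)
  )
  structure(list(variables = out, n = nrow(cohort),
                 n_events = sum(cohort$outcome)),
            class = "table_one")
}

#' @export
print.table_one <- function(x, ...) {
  cat(sprintf("Cohort: n = %d, events = %d (%.1f%%)\n",
              x$n, x$n_events, 100 * x$n_events / x$n))
  for (v in names(x$variables)) {
    e <- x$variables[[v]]
    if (v == "age") {
      cat(sprintf(
        "age: dentate %.1f (%.1f), edentulous %.1f (%.1f), P = %.2g\n",
        e$mean[["dentate"]], e$sd[["dentate"]],
        e$mean[["edentulous"]], e$sd[["edentulous"]], e$p_value))
      next
    }
    cat(sprintf("%s: P = %s\n", v,
                if (e$valid) sprintf("%.2g", e$p_value) else "invalid"))
    tab <- e$counts
    pct <- e$percent
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %-16s %5d (%4.1f)  %4d (%4.1f)\n",
                  rownames(tab)[i], tab[i, 1], pct[i, 1],
                  tab[i, 2], pct[i, 2]))
    }
  }
  invisible(x)
}

#' Unadjusted odds ratio from a 2x2 table
#'
#' Cross-product odds ratio `(a d)/(b c)` with a Woolf (log-scale normal)
#' 95% confidence interval.  If any cell is zero, 0.5 is added to every
#' cell (Haldane-Anscombe).  Tables with two zero cells in one row or
#' column have an undefined odds ratio and are flagged.
#'
#' @param table a 2x2 numeric matrix of counts: rows = exposure levels,
#'   columns = outcome levels (`a = table[1,1]` etc.).
#' @param confidence confidence level (default 0.95).
#' @return a list with `or`, `lower`, `upper`, `defined`.
#' @examples
#' unadjusted_or(matrix(c(193, 223, 776, 3096), nrow = 2))
#' @export
unadjusted_or <- function(table, confidence = 0.95) {
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)),
            all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(or = NA_real_, lower = NA_real_, upper = NA_real_,
                defined = FALSE))
  }
  t2 <- if (any(table == 0)) table + 0.5 else table
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  se <- sqrt(sum(1 / t2))
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  list(or = or,
       lower = exp(log(or) - z * se),
       upper = exp(log(or) + z * se),
       defined = TRUE)
}
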