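#' Enumerate the 32 candidate models
#'
#' All subsets of the five candidate predictors on top of the fixed
#' six-variable core: `2^5 = 32` models, ordered by number of candidates and
#' then lexicographically by candidate names.
#'
#' @return a list of [model_spec()] objects, length 32.
#' @export
enumerate_models <- function() {
  cand <- sort(candidate_variables())
  specs <- list(model_spec(character()))
  for (k in seq_along(cand)) {
    combos <- utils::combn(cand, k, simplify = FALSE)
    combos <- combos[order(vapply(combos, paste, "", collapse = "+"))]
    specs <- c(specs, lapply(combos, model_spec))
  }
  specs
}

#' Partition plan for splitting and Monte Carlo cross-validation
#'
#' @param selection_fraction proportion of the cohort assigned to the
#'   Selection set (default 0.70); sizes round half away from zero, so
#'   0.70 x 4,288 = 3,002.
#' @param validate_size number of Selection records held out as the Validate
#'   set in each Monte Carlo replicate (default 1,286, the test-set size, so
#'   the training sets have n = 1,716 when the cohort has 4,288 records).
#' @param replicates number of random training/validation partitions
#'   (default 500).
#' @param seed integer root seed; replicate `r` uses a child seed derived
#'   from `(seed, r)` so each replicate is independently reproducible.
#' @return a `partition_plan`.
#' @export
partition_plan <- function(selection_fraction = 0.70,
                           validate_size = 1286L,
                           replicates = 500L,
                           seed = 1L) {
  if (selection_fraction <= 0 || selection_fraction >= 1) {
    stop("selection_fraction must be in (0, 1)")
  }
  if (replicates < 1) stop("replicates must be >= 1")
  structure(
    list(selection_fraction = selection_fraction,
         validate_size = as.integer(validate_size),
         replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "partition_plan"
  )
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

child_seed <- function(root, r) {
  as.integer((as.numeric(root) * 48271 + as.numeric(r) * 16807) %%
               2147483647)
}

# draw a subset of given size whose in/out halves both contain both outcome
# classes; redraw (with a warning) up to 100 times
draw_two_class_subset <- function(outcome, size, what) {
  n <- length(outcome)
  for (attempt in seq_len(100L)) {
    idx <- sample.int(n, size)
    in_half <- outcome[idx]
    out_half <- outcome[-idx]
    if (length(unique(in_half)) == 2L && length(unique(out_half)) == 2L) {
      if (attempt > 1L) {
        warning(what, ": redrew partition ", attempt - 1L,
                " time(s) to keep both outcome classes in each half")
      }
      return(idx)
    }
  }
  stop(what, ": could not draw a partition with both outcome classes ",
       "in each half after 100 attempts")
}

#' One-time Selection/Test split
#'
#' Randomly partitions the analytic cohort into a Selection set (used for
#' model selection and recalibration) and a Test set (untouched until final
#' evaluation).  The Selection size is `round(selection_fraction * n)` with
#' halves rounded away from zero.
#'
#' @param cohort a `cohort_table` with at least 10 records and both outcome
#'   classes.
#' @param plan a [partition_plan()].
#' @return a list with `selection` and `test` cohort tables (disjoint,
#'   exhaustive, reproducible from the plan seed).
#' @export
split_selection_test <- function(cohort, plan = partition_plan()) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(plan, "partition_plan"))
  n <- nrow(cohort)
  if (n < 10) stop("cohort must have at least 10 records")
  if (length(unique(cohort$outcome)) < 2L) {
    stop("cohort must contain both outcome classes")
  }
  n_sel <- as.integer(round_half_up(plan$selection_fraction * n))
  if (n_sel < 1 || n_sel >= n) stop("degenerate split sizes")
  local_seed(plan$seed)
  idx <- draw_two_class_subset(cohort$outcome, n_sel, "selection/test split")
  list(selection = cohort[sort(idx), , drop = FALSE],
       test = cohort[sort(setdiff(seq_len(n), idx)), , drop = FALSE])
}

# set the RNG seed for the calling function's scope, restoring the previous
# global state when that scope exits
local_seed <- function(seed, env = parent.frame()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  withr::defer({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, envir = env)
  set.seed(seed)
}

#' Monte Carlo cross-validation of candidate models
#'
#' Repeatedly partitions the Selection set into Training and Validate sets
#' (training size = selection size - `validate_size`), fits every candidate
#' model to the Training data, scores the Validate data, and records the
#' validation AUC.  All models share the same partition within a replicate,
#' so AUC differences between models are paired.
#'
#' @param selection the Selection `cohort_table`.
#' @param models list of [model_spec()]s (default [enumerate_models()]).
#' @param plan a [partition_plan()]; `plan$replicates` partitions are drawn.
#' @return an `mccv_summary`: a data.frame with one row per model (`label`,
#'   `n_variables`, `n_candidates`, `mean_auc`, `p10_auc`, `p90_auc`,
#'   `n_failed`, `n_separated`) ordered as `models`, with the full
#'   replicate-by-model AUC matrix in attribute `auc_values`.  Failed
#'   (model, replicate) fits are recorded as `NA` and excluded from the
#'   summaries, with a warning giving the count.  Quasi-separated training
#'   fits (a rare factor level with no events) are scored anyway — their
#'   ranked predictions are valid — and counted in `n_separated`.
#' @export
run_mccv <- function(selection, models = enumerate_models(),
                     plan = partition_plan()) {
  stopifnot(inherits(selection, "cohort_table"))
  n_sel <- nrow(selection)
  if (plan$validate_size >= n_sel) {
    stop("validate_size must be smaller than the selection set")
  }
  y <- selection$outcome
  X_full <- encode_design(selection, model_spec(candidate_variables()))
  model_cols <- lapply(models, function(m) {
    c("intercept", terms_for_variables(model_variables(m)))
  })
  labels <- vapply(models, function(m) m$label, "")

  R <- plan$replicates
  auc_mat <- matrix(NA_real_, nrow = R, ncol = length(models),
                    dimnames = list(NULL, labels))
  n_failed <- integer(length(models))
  n_separated <- integer(length(models))

  for (r in seq_len(R)) {
    local({
      local_seed(child_seed(plan$seed, r))
      val_idx <- draw_two_class_subset(y, plan$validate_size,
                                       sprintf("replicate %d", r))
      train_idx <- setdiff(seq_len(n_sel), val_idx)
      X_train <- X_full[train_idx, , drop = FALSE]
      y_train <- y[train_idx]
      X_val <- X_full[val_idx, , drop = FALSE]
      y_val <- y[val_idx]
      for (m in seq_along(models)) {
        cols <- model_cols[[m]]
        fit <- tryCatch(
          fit_logistic(X_train[, cols, drop = FALSE], y_train),
          error = function(e) NULL
        )
        # a quasi-separated training fit (e.g. a rare factor level with no
        # events) still yields finite coefficients whose ranked predictions
        # are usable; only genuinely failed fits are excluded, since all
        # models share the core factors and would otherwise drop together
        usable <- !is.null(fit) && (fit$converged || fit$separation)
        if (!usable) {
          n_failed[m] <<- n_failed[m] + 1L
        } else {
          if (fit$separation) n_separated[m] <<- n_separated[m] + 1L
          eta <- drop(X_val[, cols, drop = FALSE] %*% fit$coefficients)
          auc_mat[r, m] <<- auc(stats::plogis(eta), y_val)
        }
      }
    })
  }
  if (sum(n_failed) > 0) {
    warning(sum(n_failed), " (model, replicate) fits failed ",
            "and were excluded from the AUC summaries")
  }
  if (sum(n_separated) > 0) {
    warning(sum(n_separated), " (model, replicate) training fits showed ",
            "quasi-complete separation; their validation AUCs were kept")
  }

  summary <- data.frame(
    label = labels,
    n_variables = vapply(models, function(m)
      length(model_variables(m)), 0L),
    n_candidates = vapply(models, function(m) length(m$candidates), 0L),
    mean_auc = colMeans(auc_mat, na.rm = TRUE),
    p10_auc = apply(auc_mat, 2, stats::quantile, probs = 0.10,
                    na.rm = TRUE, names = FALSE),
    p90_auc = apply(auc_mat, 2, stats::quantile, probs = 0.90,
                    na.rm = TRUE, names = FALSE),
    n_failed = n_failed,
    n_separated = n_separated,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(summary, "auc_values") <- auc_mat
  attr(summary, "models") <- models
  attr(summary, "train_size") <- n_sel - plan$validate_size
  class(summary) <- c("mccv_summary", "data.frame")
  summary
}

#' Select the best parsimonious model
#'
#' Among the models whose mean validation AUC is within
#' `parsimony_tolerance` of the maximum, returns the one with the fewest
#' variables (ties broken by fewest candidates, then enumeration order).
#' With `parsimony_tolerance = 0` this is the exact arg-max.  The default of
#' 0.002 treats AUC differences of two in the third decimal as negligible,
#' matching the parsimony behaviour of the reference analysis.
#'
#' @param summary an `mccv_summary` from [run_mccv()].
#' @param parsimony_tolerance non-negative AUC slack (default 0.002).
#' @return the selected [model_spec()].
#' @export
select_best <- function(summary, parsimony_tolerance = 0.002) {
  stopifnot(inherits(summary, "mccv_summary"), nrow(summary) >= 1,
            parsimony_tolerance >= 0)
  models <- attr(summary, "models")
  if (all(!is.finite(summary$mean_auc))) {
    stop("no model has a defined mean AUC")
  }
  best_auc <- max(summary$mean_auc, na.rm = TRUE)
  eligible <- which(summary$mean_auc >= best_auc - parsimony_tolerance)
  ord <- order(summary$n_variables[eligible],
               summary$n_candidates[eligible],
               eligible)
  models[[eligible[ord[1L]]]]
}
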