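#' Specify a candidate model
#'
#' Every candidate model contains the six core variables (age,
#' race/ethnicity, gender, education, smoking, last dental visit) and any
#' subset of the five candidate predictors (income, alcohol use, self-rated
#' health, loneliness, cognition).
#'
#' @param candidates character vector, a subset of
#'   `c("income", "alcohol", "self_rated_health", "loneliness",
#'   "cognition")`.
#' @return a `model_spec` with components `core`, `candidates` (sorted) and
#'   `label` (e.g. `"core6+cognition"`).
#' @export
model_spec <- function(candidates = character()) {
  allowed <- candidate_variables()
  bad <- setdiff(candidates, allowed)
  if (length(bad) > 0) {
    stop("unknown candidate variable(s): ", paste(bad, collapse = ", "))
  }
  candidates <- sort(unique(candidates))
  label <- if (length(candidates) == 0) "core6" else
    paste(c("core6", candidates), collapse = "+")
  structure(
    list(core = core_variables(), candidates = candidates, label = label),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model:", x$label, "(", length(x$core) + length(x$candidates),
      "variables )\n")
  invisible(x)
}

model_variables <- function(spec) {
  c(spec$core, spec$candidates)
}

#' Encode a cohort into a logistic design matrix
#'
#' Codes the analysis variables into the indicator terms of the prediction
#' equation: `R1`-`R3` (race/ethnicity vs Caucasian), `G` (male vs female),
#' `A` (age in years / 10, untransformed), `E0`/`E1` (education vs
#' college-plus), `S0`/`S1` (current/former vs never smoking), `D` (last
#' dental visit more than 2 years ago), `C` (cognition score below 23),
#' `AL` (does not drink alcohol), `H` (fair/poor self-rated health), `LN`
#' (felt lonely), `I1`/`I2` (income below $25k / $25-75k vs $75k+).
#' Reference categories produce all-zero indicators.
#'
#' @param cohort a `cohort_table` (see [as_cohort_table()]), or any
#'   data.frame with the cohort's covariate columns (e.g. risk profiles).
#' @param spec a `model_spec`; default is the full 11-variable model.
#' @return a numeric matrix of class `design_matrix` with an `intercept`
#'   column of ones and one column per term, in canonical order; attribute
#'   `variable_map` maps each term to its source variable.
#' @examples
#' eq <- edentulism_equation()
#' # an all-reference 67-year-old
#' prof <- data.frame(age = 67L, race = "Caucasian", gender = "Female",
#'                    education = "CollegePlus", smoking = "Never",
#'                    dental_visit = "Within2y", alcohol = "Drinks",
#'                    cognition_score = 30L, self_rated_health = "GoodPlus",
#'                    loneliness = "No", income = "Ge75k")
#' X <- encode_design(prof, model_spec("cognition"))
#' X[1, "A"]  # 6.7
#' @export
encode_design <- function(cohort, spec = model_spec(candidate_variables())) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- model_variables(spec)
  src_cols <- c(age = "age", race = "race", gender = "gender",
                education = "education", smoking = "smoking",
                dental_visit = "dental_visit", alcohol = "alcohol",
                cognition = "cognition_score",
                self_rated_health = "self_rated_health",
                loneliness = "loneliness", income = "income")
  missing_cols <- setdiff(unname(src_cols[vars]), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s) required by the model: ",
         paste(missing_cols, collapse = ", "))
  }

  n <- nrow(cohort)
  lv <- variable_levels()
  tt <- term_table()
  tt <- tt[tt$variable %in% vars, , drop = FALSE]

  check_levels <- function(vals, field, levels) {
    if (anyNA(vals)) {
      stop("row ", which(is.na(vals))[1L], ": field '", field,
           "' is missing")
    }
    bad <- !(as.character(vals) %in% levels)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("row ", i, ": field '", field, "' has unknown category '",
           as.character(vals)[i], "'")
    }
  }

  cols <- vector("list", nrow(tt))
  names(cols) <- tt$term
  for (k in seq_len(nrow(tt))) {
    v <- tt$variable[k]
    if (v == "age") {
      age <- cohort[["age"]]
      if (anyNA(age)) stop("row ", which(is.na(age))[1L],
                           ": field 'age' is missing")
      if (any(age < 0)) stop("negative age")
      cols[[k]] <- as.numeric(age) / 10
    } else if (v == "cognition") {
      cs <- cohort[["cognition_score"]]
      if (anyNA(cs)) stop("row ", which(is.na(cs))[1L],
                          ": field 'cognition_score' is missing")
      if (any(cs < 0 | cs > 35)) stop("cognition_score outside 0-35")
      cols[[k]] <- as.numeric(cs < COGNITION_CUT)
    } else {
      vals <- cohort[[v]]
      check_levels(vals, v, lv[[v]])
      cols[[k]] <- as.numeric(as.character(vals) == tt$level[k])
    }
  }

  X <- cbind(intercept = rep(1, n), do.call(cbind, cols))
  colnames(X) <- c("intercept", tt$term)
  attr(X, "variable_map") <- stats::setNames(tt$variable, tt$term)
  class(X) <- c("design_matrix", class(X))
  X
}

#' Decode a design matrix back to covariate categories
#'
#' Inverse of [encode_design()]: recovers the category labels (and age in
#' years) from the indicator columns.  Used mainly to verify that the coding
#' is lossless.
#'
#' @param X a `design_matrix`.
#' @return a data.frame with one column per encoded variable.
#' @export
decode_design <- function(X) {
  vm <- attr(X, "variable_map")
  if (is.null(vm)) stop("not a design_matrix: no variable_map attribute")
  tt <- term_table()
  lv <- variable_levels()
  out <- list()
  for (v in unique(vm)) {
    if (v == "age") {
      out$age <- as.integer(round(X[, "A"] * 10))
    } else {
      terms_v <- tt$term[tt$variable == v & tt$term %in% colnames(X)]
      ind <- X[, terms_v, drop = FALSE]
      if (any(rowSums(ind) > 1)) {
        stop("invalid design matrix: multiple indicators set for '", v, "'")
      }
      if (v == "cognition") {
        out$cognition <- ifelse(ind[, "C"] == 1, "Low", "Normal")
      } else {
        labels <- tt$level[match(terms_v, tt$term)]
        ref <- lv[[v]][1L]
        pick <- rep(ref, nrow(ind))
        for (j in seq_along(terms_v)) {
          pick[ind[, j] == 1] <- labels[j]
        }
        out[[v]] <- pick
      }
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
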