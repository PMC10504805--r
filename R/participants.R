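#' Read a participant table from CSV
#'
#' Reads one-row-per-person baseline records in the documented column layout:
#' `id, dentate_2006, edentulous_2018, age, race, gender, education, smoking,
#' dental_visit_2y, alcohol, cognition_score, self_rated_health, lonely,
#' income`.  Missing values are encoded as empty strings.  Boolean columns
#' accept `TRUE`/`FALSE` or `1`/`0` (case-insensitive).
#'
#' The full column dictionary (types, allowed labels) ships with the
#' package: `system.file("extdata", "participant_dictionary.csv",
#' package = "edentrisk")`.
#'
#' @param path path to a comma-separated file with a header row.
#' @return a data.frame of participant records with `NA` for missing fields.
#' @seealso [write_participants()], [apply_eligibility()]
#' @export
read_participants <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = "", check.names = FALSE)
  missing_cols <- setdiff(participant_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("participant file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[participant_columns()]
  raw$dentate_2006 <- parse_boolean(raw$dentate_2006, "dentate_2006")
  raw$edentulous_2018 <- parse_boolean(raw$edentulous_2018, "edentulous_2018")
  raw$age <- parse_integer(raw$age, "age")
  raw$cognition_score <- parse_integer(raw$cognition_score, "cognition_score")
  raw
}

#' Write a participant table to CSV
#'
#' Inverse of [read_participants()]: missing values become empty strings.
#'
#' @param participants a participant data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE, na = "")
  invisible(path)
}

parse_boolean <- function(x, field) {
  out <- rep(NA, length(x))
  lx <- tolower(trimws(as.character(x)))
  out[lx %in% c("true", "1", "yes")] <- TRUE
  out[lx %in% c("false", "0", "no")] <- FALSE
  bad <- !is.na(lx) & lx != "" & is.na(out)
  if (any(bad)) {
    stop("field '", field, "' has non-boolean value(s) at row(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  out
}

parse_integer <- function(x, field) {
  out <- suppressWarnings(as.integer(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("field '", field, "' has non-integer value(s) at row(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  out
}

# Validate category labels and numeric ranges of a participant table.
# Missing values are allowed here; eligibility filtering handles them.
validate_participants <- function(participants) {
  lv <- variable_levels()
  src <- variable_source_column()
  for (v in names(lv)) {
    col <- src[[if (v == "cognition") "cognition" else v]]
    if (v == "cognition") next
    vals <- as.character(participants[[col]])
    bad <- !is.na(vals) & !(vals %in% lv[[v]])
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("row ", i, ": field '", col, "' has unknown category '",
           vals[i], "'")
    }
  }
  bad_age <- !is.na(participants$age) & participants$age < 0
  if (any(bad_age)) {
    stop("row ", which(bad_age)[1L], ": field 'age' is negative")
  }
  cs <- participants$cognition_score
  bad_cs <- !is.na(cs) & (cs < 0 | cs > 35)
  if (any(bad_cs)) {
    stop("row ", which(bad_cs)[1L],
         ": field 'cognition_score' outside 0-35")
  }
  invisible(participants)
}
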