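# Variable dictionary shared by every module: analysis variables, category
# levels (reference level last is NOT assumed -- reference is named
# explicitly), and the map from variables to design-matrix terms.

# cognition risk threshold: Cogtot35 < 23 is the at-risk ("low") level
COGNITION_CUT <- 23

core_variables <- function() {
  c("age", "race", "gender", "education", "smoking", "dental_visit")
}

candidate_variables <- function() {
  c("income", "alcohol", "self_rated_health", "loneliness", "cognition")
}

# levels per categorical variable; first level is the reference category
variable_levels <- function() {
  list(
    race              = c("Caucasian", "AfricanAmerican", "Hispanic", "Other"),
    gender            = c("Female", "Male"),
    education         = c("CollegePlus", "NoHS", "LessThanCollege"),
    smoking           = c("Never", "Current", "Former"),
    dental_visit      = c("Within2y", "Over2y"),
    alcohol           = c("Drinks", "DoesNotDrink"),
    self_rated_health = c("GoodPlus", "FairPoor"),
    loneliness        = c("No", "Yes"),
    income            = c("Ge75k", "Lt25k", "From25to75k")
  )
}

# variable -> design terms, and term -> (variable, level) in canonical
# column order.  A is age/10; indicator terms are 0/1.
term_table <- function() {
  data.frame(
    term     = c("R1", "R2", "R3", "G", "A", "E0", "E1", "S0", "S1", "D",
                 "C", "AL", "H", "LN", "I1", "I2"),
    variable = c("race", "race", "race", "gender", "age", "education",
                 "education", "smoking", "smoking", "dental_visit",
                 "cognition", "alcohol", "self_rated_health", "loneliness",
                 "income", "income"),
    level    = c("AfricanAmerican", "Hispanic", "Other", "Male", NA,
                 "NoHS", "LessThanCollege", "Current", "Former", "Over2y",
                 "Low", "DoesNotDrink", "FairPoor", "Yes",
                 "Lt25k", "From25to75k"),
    stringsAsFactors = FALSE
  )
}

terms_for_variables <- function(variables) {
  tt <- term_table()
  tt$term[tt$variable %in% variables]
}

# CSV column names of a participant table, in the documented order
participant_columns <- function() {
  c("id", "dentate_2006", "edentulous_2018", "age", "race", "gender",
    "education", "smoking", "dental_visit_2y", "alcohol", "cognition_score",
    "self_rated_health", "lonely", "income")
}

# participant-table column that carries each analysis variable
variable_source_column <- function() {
  c(age = "age", race = "race", gender = "gender", education = "education",
    smoking = "smoking", dental_visit = "dental_visit_2y",
    alcohol = "alcohol", cognition = "cognition_score",
    self_rated_health = "self_rated_health", loneliness = "lonely",
    income = "income")
}
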