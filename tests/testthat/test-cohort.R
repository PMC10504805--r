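test_that("eligibility filtering attributes each exclusion to one reason", {
  p <- rbind(
    make_participant(id = 1L),                               # retained, 0
    make_participant(id = 2L, edentulous_2018 = TRUE),       # retained, 1
    make_participant(id = 3L, dentate_2006 = FALSE),         # baseline
    make_participant(id = 4L, dentate_2006 = NA),            # dentate missing
    make_participant(id = 5L, edentulous_2018 = NA),         # outcome missing
    make_participant(id = 6L, cognition_score = NA,
                     income = NA),                           # -> cognition
    make_participant(id = 7L, income = NA, smoking = NA),    # -> income
    make_participant(id = 8L, dentate_2006 = FALSE,
                     cognition_score = NA)                   # baseline first
  )
  res <- apply_eligibility(p)

  expect_s3_class(res$cohort, "cohort_table")
  expect_equal(nrow(res$cohort), 2L)
  expect_equal(res$cohort$outcome, c(0L, 1L))

  cnt <- res$exclusions$counts
  expect_equal(cnt[["baseline_edentulous"]], 2L)
  expect_equal(cnt[["missing:dentate_2006"]], 1L)
  expect_equal(cnt[["outcome_missing"]], 1L)
  expect_equal(cnt[["missing:cognition"]], 1L)
  expect_equal(cnt[["missing:income"]], 1L)
  expect_equal(cnt[["missing:smoking"]], 0L)
  # sum of exclusions + retained equals input size
  expect_equal(sum(cnt) + res$exclusions$n_retained, nrow(p))
})

test_that("exclusion accounting balances under random injected missingness", {
  withr::local_seed(42)
  for (rep in 1:5) {
    p <- make_participants(300, seed = rep)
    # random missingness over all fields but id
    for (col in setdiff(names(p), "id")) {
      hit <- runif(nrow(p)) < 0.08
      p[[col]][hit] <- NA
    }
    p$dentate_2006[runif(nrow(p)) < 0.15] <- FALSE
    res <- apply_eligibility(p)
    expect_equal(sum(res$exclusions$counts) + nrow(res$cohort), nrow(p))
    expect_false(anyNA(res$cohort[setdiff(names(res$cohort), "id")]))
    expect_true(all(res$cohort$outcome %in% 0:1))
  }
})

test_that("eligibility rejects empty input and bad categories", {
  expect_error(apply_eligibility(make_participant()[0, ]), "empty")
  bad <- make_participant()
  bad$race <- "Martian"
  expect_error(apply_eligibility(bad), "row 1.*race.*Martian")
})

test_that("design coding matches the prediction-equation conventions", {
  prof <- data.frame(
    age = c(67L, 55L, 80L),
    race = c("Caucasian", "AfricanAmerican", "Hispanic"),
    gender = c("Female", "Male", "Female"),
    education = c("CollegePlus", "NoHS", "LessThanCollege"),
    smoking = c("Never", "Current", "Former"),
    dental_visit = c("Within2y", "Over2y", "Within2y"),
    alcohol = c("Drinks", "DoesNotDrink", "Drinks"),
    cognition_score = c(30L, 20L, 23L),
    self_rated_health = c("GoodPlus", "FairPoor", "GoodPlus"),
    loneliness = c("No", "Yes", "No"),
    income = c("Ge75k", "Lt25k", "From25to75k"),
    stringsAsFactors = FALSE
  )
  X <- encode_design(prof)

  # all-reference row codes to zero on every indicator
  ref <- X[1, ]
  expect_equal(unname(ref[c("R1", "R2", "R3", "G", "E0", "E1", "S0", "S1",
                            "D", "C", "AL", "H", "LN", "I1", "I2")]),
               rep(0, 15))
  expect_equal(unname(ref["A"]), 6.7)
  expect_equal(unname(ref["intercept"]), 1)

  # risk levels set exactly their own indicator
  expect_equal(unname(X[2, c("R1", "S0", "C", "G", "E0", "D", "AL", "H",
                             "LN", "I1", "I2", "A")]),
               c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 5.5))
  expect_equal(unname(X[3, c("R2", "S1", "E1", "I2", "I1", "C")]),
               c(1, 1, 1, 1, 0, 0))
})

test_that("cognition dichotomization boundary sits at 23", {
  prof <- make_participant(id = 1:2)[, -(1:3)]
  names(prof)[names(prof) == "dental_visit_2y"] <- "dental_visit"
  names(prof)[names(prof) == "lonely"] <- "loneliness"
  prof$cognition_score <- c(22L, 23L)
  X <- encode_design(prof, model_spec("cognition"))
  expect_equal(unname(X[, "C"]), c(1, 0))
})

test_that("encoding is lossless over an exhaustive category sweep", {
  lv <- list(
    race = c("Caucasian", "AfricanAmerican", "Hispanic", "Other"),
    gender = c("Female", "Male"),
    education = c("CollegePlus", "NoHS", "LessThanCollege"),
    smoking = c("Never", "Current", "Former"),
    dental_visit = c("Within2y", "Over2y"),
    alcohol = c("Drinks", "DoesNotDrink"),
    self_rated_health = c("GoodPlus", "FairPoor"),
    loneliness = c("No", "Yes"),
    income = c("Ge75k", "Lt25k", "From25to75k")
  )
  grid <- expand.grid(lv, stringsAsFactors = FALSE)
  grid$age <- rep_len(c(55L, 67L, 83L), nrow(grid))
  grid$cognition_score <- rep_len(c(10L, 22L, 23L, 35L), nrow(grid))

  X <- encode_design(grid)
  # one-hot invariants
  expect_true(all(rowSums(X[, c("R1", "R2", "R3")]) <= 1))
  expect_true(all(rowSums(X[, c("E0", "E1")]) <= 1))
  expect_true(all(rowSums(X[, c("S0", "S1")]) <= 1))
  expect_true(all(rowSums(X[, c("I1", "I2")]) <= 1))
  expect_true(all(X[, "intercept"] == 1))

  dec <- decode_design(X)
  for (v in names(lv)) expect_equal(dec[[v]], grid[[v]])
  expect_equal(dec$age, grid$age)
  expect_equal(dec$cognition,
               ifelse(grid$cognition_score < 23, "Low", "Normal"))
})

test_that("encode_design errors name the offending row and field", {
  prof <- make_participant(id = 1:2)[, -(1:3)]
  names(prof)[names(prof) == "dental_visit_2y"] <- "dental_visit"
  names(prof)[names(prof) == "lonely"] <- "loneliness"
  prof$smoking[2] <- "Pipe"
  expect_error(encode_design(prof), "row 2.*smoking.*Pipe")
  prof$smoking[2] <- NA
  expect_error(encode_design(prof), "row 2.*smoking")
})

test_that("participant CSV round-trips with empty-string missing values", {
  p <- rbind(make_participant(id = 1L),
             make_participant(id = 2L, cognition_score = NA, lonely = NA,
                              edentulous_2018 = NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_participants(p, path)
  txt <- readLines(path)
  expect_length(txt, 3L)
  back <- read_participants(path)
  expect_equal(back$cognition_score, c(30L, NA))
  expect_equal(back$edentulous_2018, c(FALSE, NA))
  expect_equal(back$lonely, c("No", NA))
  expect_equal(back$age, p$age)
})

test_that("exclusion logs serialize to JSON", {
  res <- apply_eligibility(rbind(make_participant(id = 1L),
                                 make_participant(id = 2L,
                                                  dentate_2006 = FALSE)))
  path <- withr::local_tempfile(fileext = ".json")
  write_exclusion_log(res$exclusions, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$counts$baseline_edentulous, 1L)
  expect_equal(j$n_retained, 1L)
  expect_equal(j$n_input, 2L)
})
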