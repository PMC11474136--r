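test_that("direction classification is total and mutually exclusive", {
  labs <- triage_labels()
  for (a in labs) for (r in labs) {
    d <- classify_direction(a, r)
    expect_true(d %in% c("match", "overtriage", "undertriage"))
    if (a == r) expect_equal(d, "match")
    if (triage_ordinal(a) < triage_ordinal(r))
      expect_equal(d, "overtriage")
    if (triage_ordinal(a) > triage_ordinal(r))
      expect_equal(d, "undertriage")
  }
  expect_equal(classify_direction("red", "yellow"), "overtriage")
  expect_equal(classify_direction("green", "red"), "undertriage")
  # black holds the top ordinal: live codes on a black reference overtriage
  expect_equal(classify_direction("yellow", "black"), "overtriage")
})

test_that("confusion matrices tally every trial once", {
  cohort <- generate_cohort(cohort_spec(2, 2, 3, 3, seed = 15))
  ref <- cohort_reference(cohort)
  design <- study_design(cohort, "e1", n_replicates = 1, seed = 3)
  trials <- run_crossed_study(design, list(identity_appraiser("e1")))
  m <- build_confusion(trials, ref)
  expect_equal(sum(m), nrow(trials))
  expect_equal(sum(diag(m[, 1:4])), nrow(trials))  # purely diagonal

  one <- trials[1, ]; one$parsed <- "red"; one$vignette_id <- names(ref)[ref == "yellow"][1]
  m1 <- build_confusion(one, ref)
  expect_equal(unname(m1["yellow", "red"]), 1)
  expect_equal(sum(m1), 1)

  # invalid responses land in the invalid column for their reference class
  two <- trials[1:2, ]; two$parsed <- NA_character_
  m2 <- build_confusion(two, ref)
  expect_equal(sum(m2[, "invalid"]), 2)

  expect_error(build_confusion(trials, ref[-1]), names(ref)[1])
})

test_that("accuracy excludes invalid responses from the denominator", {
  ref <- c(v1 = "red")
  trials <- data.frame(
    appraiser_id = "a", vignette_id = "v1", replicate = 1:4,
    raw_response = c("red", "red", "green", ""),
    parsed = c("red", "red", "green", NA), stringsAsFactors = FALSE)
  trials$ordinal <- triage_ordinal(trials$parsed)
  class(trials) <- c("trial_table", "data.frame")
  acc <- triage_accuracy(trials, ref)
  expect_equal(round(acc$overall_accuracy, 1), 66.7)
  expect_equal(acc$n_valid, 3)
  # adding more invalid trials leaves accuracy unchanged
  more <- rbind(as.data.frame(trials),
                data.frame(appraiser_id = "a", vignette_id = "v1",
                           replicate = 5:6, raw_response = "",
                           parsed = NA_character_, ordinal = NA_integer_))
  class(more) <- c("trial_table", "data.frame")
  expect_equal(triage_accuracy(more, ref)$overall_accuracy,
               acc$overall_accuracy)
})

test_that("per-class rates respect the ordinal boundary classes", {
  cohort <- generate_cohort(cohort_spec(3, 3, 3, 3, seed = 25))
  ref <- cohort_reference(cohort)
  eps <- 0.3
  m <- (1 - eps) * diag(4) + eps * (1 - diag(4)) / 3
  apps <- list(make_confusion_appraiser(m, 0, "n1"))
  design <- study_design(cohort, "n1", 10, seed = 5)
  acc <- triage_accuracy(run_crossed_study(design, apps), ref)
  pc <- acc$per_class
  # match + over + under = 100 within each class
  expect_equal(pc$match + pc$overtriage + pc$undertriage,
               rep(100, 4), tolerance = 0.1)
  expect_equal(pc$overtriage[pc$reference == "red"], 0)
  expect_equal(pc$undertriage[pc$reference == "black"], 0)
})

test_that("estimated accuracy matches its analytic expectation", {
  cohort <- generate_cohort(cohort_spec(seed = 55))
  ref <- cohort_reference(cohort)
  eps <- 0.25
  m <- (1 - eps) * diag(4) + eps * (1 - diag(4)) / 3
  apps <- list(make_confusion_appraiser(m, 0, "n1"),
               make_confusion_appraiser(m, 0, "n2"))
  design <- study_design(cohort, c("n1", "n2"), 5, seed = 77)
  acc <- triage_accuracy(run_crossed_study(design, apps), ref)
  p <- (1 - eps)
  n <- acc$n_valid
  se <- 100 * sqrt(p * (1 - p) / n)
  expect_lt(abs(acc$overall_accuracy - 100 * p), 3 * se)
})

test_that("per-appraiser accuracy is averaged with replicate-level SDs", {
  cohort <- generate_cohort(cohort_spec(2, 2, 2, 2, seed = 61))
  ref <- cohort_reference(cohort)
  apps <- list(identity_appraiser("good"),
               make_confusion_appraiser(
                 0.5 * diag(4) + 0.5 * (1 - diag(4)) / 3, 0, "bad"))
  design <- study_design(cohort, c("good", "bad"), 10, seed = 9)
  acc <- triage_accuracy(run_crossed_study(design, apps), ref)
  pa <- acc$per_appraiser
  expect_equal(pa$accuracy[pa$appraiser_id == "good"], 100)
  expect_equal(pa$sd[pa$appraiser_id == "good"], 0)
  expect_lt(pa$accuracy[pa$appraiser_id == "bad"], 90)
  expect_gt(pa$sd[pa$appraiser_id == "bad"], 0)
})

test_that("confusion matrices write to CSV with an invalid column", {
  cohort <- generate_cohort(cohort_spec(1, 1, 1, 1, seed = 65))
  ref <- cohort_reference(cohort)
  design <- study_design(cohort, "e", 2, seed = 1)
  m <- build_confusion(run_crossed_study(design, list(identity_appraiser("e"))),
                       ref)
  f <- tempfile(fileext = ".csv")
  write_confusion(m, f)
  back <- utils::read.csv(f)
  expect_equal(names(back), c("reference", triage_labels(), "invalid"))
  expect_equal(back$reference, triage_labels())
  expect_equal(sum(back[, -1]), sum(m))
})
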