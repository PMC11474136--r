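test_that("queries end with the fixed answer-format instruction", {
  q <- build_query("Triage this patient with START.", "A 30-year-old male.")
  expect_match(q, "Answer only with the color code and no other text$")
  expect_lt(regexpr("P", build_query("P", "V"), fixed = TRUE),
            regexpr("V", build_query("P", "V"), fixed = TRUE))
  expect_identical(build_query("P", "V"), build_query("P", "V"))
  expect_error(build_query("", "V"), "prompt_text")
  expect_error(build_query("P", ""), "narrative")
})

test_that("responses parse iff exactly one distinct colour word occurs", {
  expect_equal(parse_response("Red"), "red")
  expect_equal(parse_response(""), NA_character_)
  expect_equal(parse_response("The code is: YELLOW."), "yellow")
  expect_equal(parse_response("red or yellow"), NA_character_)
  expect_equal(parse_response("RED."), "red")
  expect_equal(parse_response("one hundred injured"), NA_character_)
  expect_equal(parse_response("red red red"), "red")   # repeats allowed
  expect_equal(parse_response("no idea"), NA_character_)
  expect_equal(parse_response(c("green", "black!", "teal")),
               c("green", "black", NA))
})

test_that("parsing inverts sampling for every response template", {
  app <- identity_appraiser()
  for (tmpl in default_response_templates()) {
    for (code in triage_labels()) {
      expect_equal(parse_response(sprintf(tmpl, code)), code)
    }
  }
})

test_that("the crossed study yields one record per planned trial in order", {
  cohort <- generate_cohort(cohort_spec(1, 1, 1, 0, seed = 2))
  apps <- list(identity_appraiser("a1"), identity_appraiser("a2"))
  design <- study_design(cohort, c("a1", "a2"), n_replicates = 4, seed = 1)
  trials <- run_crossed_study(design, apps)
  expect_equal(nrow(trials), 2 * 3 * 4)
  # appraiser-outermost ordering
  expect_equal(trials$appraiser_id, rep(c("a1", "a2"), each = 12))
  expect_equal(trials$replicate[1:4], 1:4)
  expect_equal(unique(trials$vignette_id[1:8]),
               cohort$vignette_id[1:2])
  # identity appraiser reproduces the reference codes
  expect_identical(trials$parsed,
                   unname(cohort_reference(cohort)[trials$vignette_id]))
  expect_true(all(trials$ordinal == triage_ordinal(trials$parsed)))
})

test_that("a 1x1x1 design gives a single matching record", {
  cohort <- generate_cohort(cohort_spec(0, 1, 0, 0, seed = 4))
  design <- study_design(cohort, "a1", n_replicates = 1, seed = 9)
  trials <- run_crossed_study(design, list(identity_appraiser("a1")))
  expect_equal(nrow(trials), 1)
  expect_equal(trials$parsed, cohort$reference_code)
})

test_that("study runs are byte-reproducible under a fixed seed", {
  cohort <- generate_cohort(cohort_spec(2, 2, 3, 3, seed = 6))
  apps <- preset_appraisers()[1:3]
  ids <- vapply(apps, `[[`, "", "appraiser_id")
  design <- study_design(cohort, ids, n_replicates = 5, seed = 33)
  t1 <- run_crossed_study(design, apps)
  t2 <- run_crossed_study(design, apps)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  f1 <- tempfile(); f2 <- tempfile()
  write_trial_table(t1, f1); write_trial_table(t2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("no trial is dropped or duplicated when responses are invalid", {
  cohort <- generate_cohort(cohort_spec(2, 2, 2, 2, seed = 8))
  noisy <- make_confusion_appraiser(diag(4), invalid_rate = 0.5, "noisy")
  design <- study_design(cohort, "noisy", n_replicates = 6, seed = 3)
  trials <- run_crossed_study(design, list(noisy))
  expect_equal(nrow(trials), 8 * 6)
  expect_equal(sum(is.na(trials$parsed)) + sum(!is.na(trials$parsed)),
               8 * 6)
  expect_true(all(is.na(trials$ordinal) == is.na(trials$parsed)))
})

test_that("failing external callbacks yield invalid records after retries", {
  cohort <- generate_cohort(cohort_spec(0, 1, 1, 0, seed = 10))
  calls <- new.env(); calls$n <- 0
  flaky <- function(query) { calls$n <- calls$n + 1; stop("API down") }
  design <- study_design(cohort, "flaky", n_replicates = 2, seed = 5)
  trials <- run_crossed_study(design, list(flaky), retries = 2)
  expect_equal(nrow(trials), 4)
  expect_true(all(is.na(trials$parsed)))
  expect_equal(calls$n, 4 * 3)  # each trial tried 1 + 2 times

  # a working callback flows through build_query and parse_response
  always_red <- function(query) "RED."
  t2 <- run_crossed_study(design, list(always_red))
  expect_true(all(t2$parsed == "red"))
})

test_that("valid_rate reports counts and percent", {
  df <- data.frame(parsed = c(rep("red", 7), NA, NA, NA))
  expect_equal(valid_rate(df),
               list(n_valid = 7, n_total = 10, percent_valid = 70))
  expect_error(valid_rate(df[0, , drop = FALSE]), "empty")
})

test_that("trial tables round-trip through RFC 4180 CSV", {
  cohort <- generate_cohort(cohort_spec(1, 1, 1, 1, seed = 12))
  noisy <- make_confusion_appraiser(diag(4), invalid_rate = 0.3, "n1")
  design <- study_design(cohort, "n1", n_replicates = 5, seed = 2)
  trials <- run_crossed_study(design, list(noisy))
  trials$raw_response[1] <- "line one\nline two, with comma"
  f <- tempfile(fileext = ".csv")
  write_trial_table(trials, f)
  back <- read_trial_table(f)
  expect_equal(as.data.frame(back), as.data.frame(trials),
               ignore_attr = TRUE)
  expect_error(read_trial_table({
    g <- tempfile(); writeLines("a,b\n1,2", g); g
  }), "missing column")
})
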