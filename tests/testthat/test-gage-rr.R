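test_that("d2 constants reproduce the published control-chart table", {
  for (n in 2:10)
    expect_lt(abs(d2_constant(n) - published_d2[as.character(n)]), 1e-3)
  expect_error(d2_constant(1), ">= 2")
  # strictly increasing, including the large-n extension
  vals <- vapply(c(2:12, 50, 100, 391), d2_constant, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("cell ranges are max - min of valid ordinals per cell", {
  df <- random_trial_table(2, 2, 10, p_na = 0)
  df$ordinal[df$appraiser_id == "a01" & df$vignette_id == "p01"] <- 2L
  df$ordinal[df$appraiser_id == "a01" & df$vignette_id == "p02"] <-
    rep(c(1L, 2L), 5)                       # red/yellow mix -> range 1
  df$ordinal[df$appraiser_id == "a02" & df$vignette_id == "p01"] <-
    c(1L, 4L, rep(2L, 8))                   # red and black -> range 3
  df$parsed <- triage_label(df$ordinal)
  cr <- cell_ranges(df)
  g <- function(a, p) cr$cells$range[cr$cells$appraiser_id == a &
                                       cr$cells$vignette_id == p]
  expect_equal(g("a01", "p01"), 0)
  expect_equal(g("a01", "p02"), 1)
  expect_equal(g("a02", "p01"), 3)
  expect_equal(cr$n_excluded, 0)

  # a cell with < 2 valid responses is excluded and tallied
  df$ordinal[df$appraiser_id == "a02" & df$vignette_id == "p02"] <-
    c(3L, rep(NA_integer_, 9))
  cr2 <- cell_ranges(df)
  expect_equal(cr2$n_excluded, 1)
  expect_equal(nrow(cr2$cells), 3)
})

test_that("EV, AV and GRR evaluate their closed forms", {
  # EV = R-bar / d2(10): all-zero ranges give EV = 0
  df <- random_trial_table(2, 3, 10, p_na = 0)
  df$ordinal <- 2L
  df$parsed <- "yellow"
  expect_equal(repeatability_ev(df)$EV, 0)
  # R-bar = 0.6, m = 10 -> EV = 0.6 / 3.078 = 0.195
  expect_equal(round(0.6 / d2_constant(10), 3), 0.195)
  # AV formula with the bias correction
  av <- sqrt((0.1 / d2_constant(9))^2 - 0.2^2 / (391 * 10))
  expect_equal(round(av, 4), 0.0335)
  # AV clips at zero when appraiser means are identical
  expect_equal(reproducibility_av(df, EV = 0.5)$AV, 0)
  # combined GRR
  expect_equal(combined_grr(0, 0), 0)
  expect_equal(combined_grr(3, 4), 5)
  expect_equal(round(combined_grr(0.17, 0.091), 2), 0.19)
  expect_error(combined_grr(-1, 0), "non-negative")
})

test_that("part variation matches the two-part worked example", {
  # two parts with constant ordinals 1 and 3: PV = 2 / d2(2) = 1.773
  df <- random_trial_table(1, 2, 10, p_na = 0)
  df$ordinal <- ifelse(df$vignette_id == "p01", 1L, 3L)
  df$parsed <- triage_label(df$ordinal)
  pv <- part_variation_pv(df)
  expect_equal(pv$PV, 2 / d2_constant(2), tolerance = 1e-12)
  expect_lt(abs(pv$PV - 1.773), 2e-3)  # vs the 3-digit table constant
  expect_equal(pv$part_range, 2)
  # pooled per-part ranges are 0 for constant parts
  expect_equal(pv$part_range_frequency$range, 0)
  expect_equal(pv$part_range_frequency$n, 2)
  expect_error(part_variation_pv(df[df$vignette_id == "p01", ]), "2 parts")
})

test_that("percent contributions are variance shares summing to 100", {
  pc <- percent_contributions(0.17, 0.091, 0.412)
  expect_equal(round(pc$pct_EV, 1), 14.0)
  expect_equal(round(pc$pct_AV, 1), 4.0)
  expect_equal(round(pc$pct_PV, 1), 82.0)
  expect_equal(pc$pct_EV + pc$pct_AV + pc$pct_PV, 100, tolerance = 1e-10)
  expect_equal(pc$pct_GRR, pc$pct_EV + pc$pct_AV)

  pc2 <- percent_contributions(1, 0, 0)
  expect_equal(c(pc2$pct_EV, pc2$pct_AV, pc2$pct_GRR, pc2$pct_PV),
               c(100, 0, 100, 0))
  pc3 <- percent_contributions(1, 1, 1)
  expect_equal(round(c(pc3$pct_EV, pc3$pct_AV, pc3$pct_GRR, pc3$pct_PV), 1),
               c(33.3, 33.3, 66.7, 33.3))
  expect_error(percent_contributions(0, 0, 0), "undefined")
})

test_that("usability bands follow the 10%/30% guideline", {
  expect_equal(usability_rating(5), "adequate_general")
  expect_equal(usability_rating(10), "adequate_low_risk")
  expect_equal(usability_rating(30), "adequate_low_risk")
  expect_equal(usability_rating(31), "inadequate")
  expect_error(usability_rating(101), "0, 100")
})

test_that("gage_rr matches the brute-force oracle on random designs", {
  set.seed(2025)
  for (rep in 1:20) {
    df <- random_trial_table(3, 5, 4, p_na = 0.05)
    fit <- gage_rr(df)
    want <- oracle_gage(as.data.frame(df), 4)
    expect_equal(fit$EV, want$EV, tolerance = 1e-12)
    expect_equal(fit$AV, want$AV, tolerance = 1e-12)
    expect_equal(fit$GRR, want$GRR, tolerance = 1e-12)
    expect_equal(fit$mean_range_overall, want$rbar, tolerance = 1e-12)
    # structural identities
    expect_equal(fit$GRR^2 - fit$EV^2 - fit$AV^2, 0, tolerance = 1e-12)
    expect_equal(fit$TV^2, fit$GRR^2 + fit$PV^2, tolerance = 1e-12)
    expect_equal(fit$pct_EV + fit$pct_AV + fit$pct_PV, 100,
                 tolerance = 0.01)
  }
})

test_that("identity appraisers give zero gage R&R and pure part variation", {
  cohort <- generate_cohort(cohort_spec(3, 3, 4, 4, seed = 19))
  apps <- list(identity_appraiser("e1"), identity_appraiser("e2"),
               identity_appraiser("e3"))
  design <- study_design(cohort, c("e1", "e2", "e3"), 5, seed = 7)
  fit <- gage_rr(run_crossed_study(design, apps))
  expect_equal(fit$EV, 0)
  expect_equal(fit$AV, 0)
  expect_equal(fit$GRR, 0)
  expect_gt(fit$PV, 0)
  expect_equal(fit$pct_PV, 100)
  expect_equal(fit$usability, "adequate_general")
})

test_that("frequency tables count every usable cell and part", {
  cohort <- generate_cohort(cohort_spec(2, 2, 3, 3, seed = 21))
  apps <- preset_appraisers()[1:3]
  design <- study_design(cohort, vapply(apps, `[[`, "", "appraiser_id"),
                         6, seed = 13)
  fit <- gage_rr(run_crossed_study(design, apps))
  expect_equal(sum(fit$cell_range_frequency$n) + fit$n_excluded_cells,
               3 * 10)
  expect_equal(sum(fit$part_range_frequency$n), 10)
  expect_equal(sum(fit$cell_range_frequency$percent), 100)
  expect_equal(nrow(fit$mean_range_by_appraiser), 3)
})

test_that("more off-diagonal mass increases repeatability variation", {
  cohort <- generate_cohort(cohort_spec(3, 4, 6, 7, seed = 29))
  evs <- vapply(seq_along(c(0.05, 0.2, 0.45)), function(i) {
    eps <- c(0.05, 0.2, 0.45)[i]
    m <- (1 - eps) * diag(4) + eps * (1 - diag(4)) / 3
    apps <- list(make_confusion_appraiser(m, 0, "n1"),
                 make_confusion_appraiser(m, 0, "n2"))
    design <- study_design(cohort, c("n1", "n2"), 10, seed = 40 + i)
    gage_rr(run_crossed_study(design, apps))$EV
  }, numeric(1))
  expect_true(all(diff(evs) > 0))
})
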