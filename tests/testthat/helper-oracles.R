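# Independent oracles used across the suite.  These are deliberately coded
# from first principles (flat decision table, naive loops) and kept separate
# from the package implementation they check.

# START decision table: first matching row wins.  Conditions are encoded as
# plain predicates over the raw field values, not via the package engine.
oracle_start <- function(amb, breath, after, rr, pulse, cap, obeys) {
  cap_fail <- !is.na(cap) && cap > 2
  pulse_fail <- !is.na(pulse) && !pulse
  rules <- list(
    list(test = amb,                     code = "green"),
    list(test = !amb && !breath && !after, code = "black"),
    list(test = !amb && !breath && after,  code = "red"),
    list(test = !amb && breath && rr > 30, code = "red"),
    list(test = !amb && breath && rr <= 30 && (pulse_fail || cap_fail),
         code = "red"),
    list(test = !amb && breath && rr <= 30 && !pulse_fail && !cap_fail &&
           !obeys, code = "red"),
    list(test = TRUE, code = "yellow")
  )
  for (rule in rules) if (isTRUE(rule$test)) return(rule$code)
}

# published control-chart d2 table for subgroup sizes 2..10
published_d2 <- c(`2` = 1.128, `3` = 1.693, `4` = 2.059, `5` = 2.326,
                  `6` = 2.534, `7` = 2.704, `8` = 2.847, `9` = 2.970,
                  `10` = 3.078)

# Brute-force range-method gage R&R: naive loops over a long-format table
# with columns appraiser_id, vignette_id, replicate, ordinal.  d2 constants
# come from d2_constant(), which is validated against the published table
# separately; everything else is computed independently of the package.
oracle_gage <- function(df, n_replicates) {
  apps <- unique(df$appraiser_id)
  parts <- unique(df$vignette_id)
  ranges <- c()
  for (a in apps) for (p in parts) {
    v <- df$ordinal[df$appraiser_id == a & df$vignette_id == p]
    v <- v[!is.na(v)]
    if (length(v) >= 2) ranges <- c(ranges, max(v) - min(v))
  }
  rbar <- sum(ranges) / length(ranges)
  EV <- rbar / d2_constant(n_replicates)
  means <- c()
  for (a in apps) {
    v <- df$ordinal[df$appraiser_id == a]
    means <- c(means, mean(v[!is.na(v)]))
  }
  RA <- max(means) - min(means)
  av2 <- (RA / d2_constant(length(apps)))^2 -
    EV^2 / (length(parts) * n_replicates)
  AV <- sqrt(max(0, av2))
  list(EV = EV, AV = AV, GRR = sqrt(EV^2 + AV^2), rbar = rbar)
}

# random long-format ordinal trial table (crossed design)
random_trial_table <- function(k, n, r, p_na = 0.02) {
  df <- expand.grid(replicate = seq_len(r),
                    vignette_id = sprintf("p%02d", seq_len(n)),
                    appraiser_id = sprintf("a%02d", seq_len(k)),
                    stringsAsFactors = FALSE)[, 3:1]
  df$raw_response <- ""
  df$ordinal <- sample(1:4, nrow(df), replace = TRUE)
  df$ordinal[runif(nrow(df)) < p_na] <- NA_integer_
  df$parsed <- triage_label(df$ordinal)
  df$raw_response <- ifelse(is.na(df$parsed), "", df$parsed)
  class(df) <- c("trial_table", "data.frame")
  attr(df, "design") <- list(n_appraisers = k, n_parts = n,
                             n_replicates = r)
  df
}

# small convenience: identity appraiser
identity_appraiser <- function(id = "exact")
  make_confusion_appraiser(diag(4), invalid_rate = 0, appraiser_id = id)

# expected pooled accuracy (percent, over valid trials) of a set of
# confusion appraisers on a cohort: trial-weighted mean of diagonal mass
expected_accuracy <- function(appraisers, cohort) {
  w <- table(factor(cohort$reference_code, levels = triage_labels()))
  w <- as.numeric(w) / sum(w)
  100 * mean(vapply(appraisers, function(a)
    sum(w * diag(a$response_distribution)), numeric(1)))
}
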