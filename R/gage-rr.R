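# cache for d2 constants (numerical integration is cheap but repeated)
.d2_cache <- new.env(parent = emptyenv())

#' Expected-range constant d2
#'
#' The d2 constant is the expected range of `n` independent standard normal
#' deviates; the range method divides average ranges by d2 to convert them
#' into standard-deviation estimates.  It is computed here by numerical
#' integration of `E[range] = integral of 1 - Phi(x)^n - (1 - Phi(x))^n dx`
#' over the real line, which agrees with published control-chart tables
#' (d2(2) = 1.128, d2(10) = 3.078) and extends to arbitrary subgroup sizes
#' such as the 391 parts of the classic study.  Values are cached.
#'
#' @param n subgroup size, integer >= 2.
#' @return the d2 constant (positive real).
#' @examples
#' d2_constant(2)   # 1.128
#' d2_constant(10)  # 3.078
#' @export
d2_constant <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2")
  key <- as.character(n)
  if (!is.null(.d2_cache[[key]])) return(.d2_cache[[key]])
  val <- stats::integrate(
    function(x) 1 - stats::pnorm(x)^n - stats::pnorm(-x)^n,
    lower = -Inf, upper = Inf, abs.tol = 1e-6, rel.tol = 1e-8,
    subdivisions = 400L)$value
  .d2_cache[[key]] <- val
  val
}

#' Per-cell ranges of a trial table
#'
#' One cell is one (appraiser, part) combination; its range is max - min of
#' the valid ordinal responses over the replicates.  Cells with fewer than
#' two valid responses cannot contribute a range and are excluded, with the
#' exclusion count reported.
#'
#' @param trials a `trial_table` (see [run_crossed_study()]).
#' @return list with `cells` (data.frame appraiser_id, vignette_id, range,
#'   n_valid), and `n_excluded` (cells with < 2 valid responses).
#' @export
cell_ranges <- function(trials) {
  if (nrow(trials) == 0L) stop("trial table is empty")
  ord <- trials$ordinal
  fa <- factor(trials$appraiser_id)
  fv <- factor(trials$vignette_id)
  rng <- tapply(ord, list(fa, fv), function(x) {
    v <- x[!is.na(x)]
    if (length(v) < 2L) NA_real_ else diff(range(v))
  })
  nv <- tapply(ord, list(fa, fv), function(x) sum(!is.na(x)))
  nv[is.na(nv)] <- 0L
  grid <- expand.grid(appraiser_id = rownames(rng),
                      vignette_id = colnames(rng),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- data.frame(grid, range = as.numeric(rng),
                      n_valid = as.integer(nv),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(cells = cells[!is.na(cells$range), , drop = FALSE],
       n_excluded = sum(is.na(cells$range)))
}

#' Repeatability (equipment variation) by the range method
#'
#' EV = R-bar / d2(r), where R-bar is the mean of the per-cell ranges over
#' replicates and r is the number of replicates per cell.
#'
#' @param trials a `trial_table`.
#' @param n_replicates replicates per cell; defaults to the table's design
#'   attribute.
#' @return list with `EV`, `mean_range_overall`, `cell_range_frequency`
#'   (data.frame range/n/percent) and `n_excluded`.
#' @export
repeatability_ev <- function(trials, n_replicates = NULL) {
  cr <- cell_ranges(trials)
  if (nrow(cr$cells) == 0L)
    stop("no cell has >= 2 valid responses; EV is undefined")
  r <- n_replicates %||% attr(trials, "design")$n_replicates %||%
    max(trials$replicate)
  rbar <- mean(cr$cells$range)
  freq <- as.data.frame(table(range = cr$cells$range),
                        stringsAsFactors = FALSE)
  names(freq) <- c("range", "n")
  freq$range <- as.numeric(freq$range)
  freq$percent <- 100 * freq$n / sum(freq$n)
  list(EV = rbar / d2_constant(r), mean_range_overall = rbar,
       cell_range_frequency = freq, n_excluded = cr$n_excluded)
}

#' Reproducibility (appraiser variation) by the range method
#'
#' The appraiser range R_A is the spread (max - min) of the per-appraiser
#' mean ordinals over all their valid trials.  AV is R_A / d2(k) (k
#' appraisers) with the standard bias correction for repeatability leaking
#' into the appraiser means: AV = sqrt(max(0, (R_A/d2(k))^2 - EV^2/(n r))),
#' n parts and r replicates; the subtraction is clipped at zero.
#'
#' @param trials a `trial_table`.
#' @param EV repeatability, from [repeatability_ev()].
#' @return list with `AV`, `appraiser_range`, and `mean_range_by_appraiser`
#'   (data.frame appraiser_id, mean_range, sd_range, mean_ordinal — the
#'   per-appraiser average and SD of cell ranges plus the mean ordinal).
#' @export
reproducibility_av <- function(trials, EV) {
  k <- length(unique(trials$appraiser_id))
  if (k < 2L) stop("reproducibility requires >= 2 appraisers")
  n <- length(unique(trials$vignette_id))
  r <- attr(trials, "design")$n_replicates %||% max(trials$replicate)
  valid <- trials[!is.na(trials$ordinal), ]
  means <- tapply(valid$ordinal, valid$appraiser_id, mean)
  R_A <- max(means) - min(means)
  AV <- sqrt(max(0, (R_A / d2_constant(k))^2 - EV^2 / (n * r)))
  cr <- cell_ranges(trials)$cells
  by_app <- data.frame(
    appraiser_id = sort(unique(trials$appraiser_id)),
    stringsAsFactors = FALSE)
  by_app$mean_range <- as.numeric(
    tapply(cr$range, cr$appraiser_id, mean)[by_app$appraiser_id])
  by_app$sd_range <- as.numeric(
    tapply(cr$range, cr$appraiser_id, stats::sd)[by_app$appraiser_id])
  by_app$mean_ordinal <- as.numeric(means[by_app$appraiser_id])
  list(AV = AV, appraiser_range = R_A, mean_range_by_appraiser = by_app)
}

#' Part variation by the range method
#'
#' PV = (max - min of per-part mean ordinals) / d2(number of parts), with
#' d2 extended to large part counts by numerical integration.  Also tallies
#' the per-part range over ALL trials (all appraisers and replicates
#' pooled).
#'
#' @param trials a `trial_table`.
#' @return list with `PV`, `part_range` and `part_range_frequency`
#'   (data.frame range/n/percent over parts).
#' @export
part_variation_pv <- function(trials) {
  n <- length(unique(trials$vignette_id))
  if (n < 2L) stop("part variation requires >= 2 parts")
  valid <- trials[!is.na(trials$ordinal), ]
  means <- tapply(valid$ordinal, valid$vignette_id, mean)
  PV <- (max(means) - min(means)) / d2_constant(n)
  pooled_rng <- tapply(valid$ordinal, valid$vignette_id,
                       function(x) diff(range(x)))
  freq <- as.data.frame(table(range = as.numeric(pooled_rng)),
                        stringsAsFactors = FALSE)
  names(freq) <- c("range", "n")
  freq$range <- as.numeric(freq$range)
  freq$percent <- 100 * freq$n / sum(freq$n)
  list(PV = PV, part_range = max(means) - min(means),
       part_range_frequency = freq)
}

#' Combined gage R&R from its components
#'
#' GRR = sqrt(EV^2 + AV^2): total measurement-system variation is the root
#' sum of squares of repeatability and reproducibility.
#'
#' @param EV,AV non-negative repeatability and reproducibility estimates.
#' @return the combined GRR (same units as EV/AV).
#' @examples
#' combined_grr(0.17, 0.091)  # 0.19 to two decimals
#' @export
combined_grr <- function(EV, AV) {
  if (EV < 0 || AV < 0) stop("EV and AV must be non-negative")
  sqrt(EV^2 + AV^2)
}

#' Percent variance contributions
#'
#' Total variation TV satisfies TV^2 = EV^2 + AV^2 + PV^2; each component's
#' percent contribution is its squared share of TV^2, so the three shares
#' sum to 100 and pct_GRR = pct_EV + pct_AV.
#'
#' @param EV,AV,PV non-negative components (not all zero).
#' @return list with `TV`, `pct_EV`, `pct_AV`, `pct_GRR`, `pct_PV`.
#' @export
percent_contributions <- function(EV, AV, PV) {
  if (any(c(EV, AV, PV) < 0)) stop("components must be non-negative")
  tv2 <- EV^2 + AV^2 + PV^2
  if (tv2 == 0)
    stop("percent contributions are undefined when EV = AV = PV = 0")
  list(TV = sqrt(tv2),
       pct_EV = 100 * EV^2 / tv2,
       pct_AV = 100 * AV^2 / tv2,
       pct_GRR = 100 * (EV^2 + AV^2) / tv2,
       pct_PV = 100 * PV^2 / tv2)
}

#' Usability band for a measurement system
#'
#' Standard guideline bands on the percent gage R&R: under 10% the system is
#' adequate for general use, 10% to 30% adequate for low-risk use only,
#' and over 30% inadequate.
#'
#' @param pct_GRR percent gage R&R in `[0, 100]`.
#' @return one of `"adequate_general"`, `"adequate_low_risk"`,
#'   `"inadequate"`.
#' @export
usability_rating <- function(pct_GRR) {
  if (is.na(pct_GRR) || pct_GRR < 0 || pct_GRR > 100)
    stop("'pct_GRR' must lie in [0, 100]")
  if (pct_GRR < 10) "adequate_general"
  else if (pct_GRR <= 30) "adequate_low_risk"
  else "inadequate"
}

#' Range-method gage repeatability & reproducibility
#'
#' Fits the full range-method gage R&R decomposition to a crossed trial
#' table of ordinal triage scores: repeatability (equipment variation, EV),
#' reproducibility (appraiser variation, AV), combined GRR, part variation
#' (PV), total variation (TV), percent variance contributions, and the
#' range summaries practitioners tabulate (per-cell range frequencies,
#' per-appraiser mean ranges, per-part pooled range frequencies).
#'
#' @param trials a `trial_table` from [run_crossed_study()] or
#'   [read_trial_table()].
#' @return an object of class `gage_rr`; see [print.gage_rr()] and
#'   [summary.gage_rr()].
#' @examples
#' cohort <- generate_cohort(cohort_spec(2, 3, 3, 2, seed = 42))
#' apps <- preset_appraisers()[1:3]
#' design <- study_design(cohort, vapply(apps, `[[`, "", "appraiser_id"),
#'                        n_replicates = 5, seed = 99)
#' fit <- gage_rr(run_crossed_study(design, apps))
#' fit
#' @export
gage_rr <- function(trials) {
  ev <- repeatability_ev(trials)
  av <- reproducibility_av(trials, ev$EV)
  pv <- part_variation_pv(trials)
  GRR <- combined_grr(ev$EV, av$AV)
  pct <- percent_contributions(ev$EV, av$AV, pv$PV)
  structure(list(
    EV = ev$EV, AV = av$AV, GRR = GRR, PV = pv$PV, TV = pct$TV,
    pct_EV = pct$pct_EV, pct_AV = pct$pct_AV, pct_GRR = pct$pct_GRR,
    pct_PV = pct$pct_PV,
    usability = usability_rating(pct$pct_GRR),
    mean_range_overall = ev$mean_range_overall,
    cell_range_frequency = ev$cell_range_frequency,
    mean_range_by_appraiser = av$mean_range_by_appraiser,
    part_range_frequency = pv$part_range_frequency,
    n_excluded_cells = ev$n_excluded,
    design = attr(trials, "design")
  ), class = "gage_rr")
}

#' @rdname gage_rr
#' @param x,object a `gage_rr` fit.
#' @param ... unused.
#' @export
print.gage_rr <- function(x, ...) {
  d <- x$design
  cat("Range-method gage R&R (crossed design",
      if (!is.null(d)) sprintf("%d appraisers x %d parts x %d replicates",
                               d$n_appraisers, d$n_parts, d$n_replicates),
      ")\n", sep = " ")
  cat(sprintf("  repeatability  EV  = %.4f  (%5.1f%% of variance)\n",
              x$EV, x$pct_EV))
  cat(sprintf("  reproducibility AV = %.4f  (%5.1f%% of variance)\n",
              x$AV, x$pct_AV))
  cat(sprintf("  combined       GRR = %.4f  (%5.1f%% of variance)\n",
              x$GRR, x$pct_GRR))
  cat(sprintf("  part variation PV  = %.4f  (%5.1f%% of variance)\n",
              x$PV, x$pct_PV))
  cat(sprintf("  total variation TV = %.4f\n", x$TV))
  cat("  usability band:", x$usability, "\n")
  if (x$n_excluded_cells > 0)
    cat("  (", x$n_excluded_cells,
        "cell(s) with < 2 valid responses excluded )\n")
  invisible(x)
}

#' @rdname gage_rr
#' @export
summary.gage_rr <- function(object, ...) {
  out <- object
  class(out) <- c("summary.gage_rr", "gage_rr")
  out
}

#' @rdname gage_rr
#' @export
print.summary.gage_rr <- function(x, ...) {
  print.gage_rr(x)
  cat("\nPer-cell range frequencies (replicates within appraiser x part):\n")
  print(x$cell_range_frequency, row.names = FALSE, digits = 3)
  cat("\nMean range by appraiser:\n")
  print(x$mean_range_by_appraiser, row.names = FALSE, digits = 3)
  cat("\nPer-part pooled range frequencies (all appraisers and replicates):\n")
  print(x$part_range_frequency, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @rdname gage_rr
#' @export
plot.gage_rr <- function(x, ...) {
  comp <- c(EV = x$pct_EV, AV = x$pct_AV, GRR = x$pct_GRR, PV = x$pct_PV)
  graphics::barplot(comp, ylab = "% of total variance",
                    main = "Gage R&R variance contributions",
                    ylim = c(0, 100), ...)
  graphics::abline(h = c(10, 30), lty = 2, col = "grey40")
  invisible(x)
}

#' Coefficients of a gage R&R fit
#'
#' @param object a `gage_rr` fit.
#' @param ... unused.
#' @return named numeric vector of EV, AV, GRR, PV, TV and the percent
#'   contributions.
#' @export
coef.gage_rr <- function(object, ...) {
  c(EV = object$EV, AV = object$AV, GRR = object$GRR, PV = object$PV,
    TV = object$TV, pct_EV = object$pct_EV, pct_AV = object$pct_AV,
    pct_GRR = object$pct_GRR, pct_PV = object$pct_PV)
}
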