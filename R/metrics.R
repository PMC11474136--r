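#' Direction of a triage error
#'
#' On the ordinal scale (red = 1 ... black = 4), overtriage means assigning
#' a lower ordinal (higher acuity) than the reference; undertriage a higher
#' ordinal (lower acuity).  Because black holds the highest ordinal, any
#' live code assigned to a black-reference patient counts as overtriage.
#'
#' @param assigned,reference triage labels (vectors recycle).
#' @return character vector: `"match"`, `"overtriage"` or `"undertriage"`.
#' @examples
#' classify_direction("red", "yellow")    # overtriage
#' classify_direction("yellow", "black")  # overtriage
#' classify_direction("green", "red")     # undertriage
#' @export
classify_direction <- function(assigned, reference) {
  a <- triage_ordinal(assigned)
  r <- triage_ordinal(reference)
  if (anyNA(a) || anyNA(r)) stop("codes must be valid triage labels")
  ifelse(a == r, "match", ifelse(a < r, "overtriage", "undertriage"))
}

#' Confusion matrix of assigned versus reference codes
#'
#' Tallies every trial once: a 4x5 count matrix with reference codes in
#' rows (red/yellow/green/black) and assigned codes in columns, plus an
#' `invalid` column for unparseable responses.
#'
#' @param trials a `trial_table`.
#' @param reference named vector vignette_id -> triage label (see
#'   [cohort_reference()]); must cover every vignette in the table.
#' @return matrix of class `triage_confusion`.
#' @export
build_confusion <- function(trials, reference) {
  miss <- setdiff(unique(trials$vignette_id), names(reference))
  if (length(miss))
    stop("reference standard missing for vignette(s): ",
         paste(miss, collapse = ", "))
  lv <- triage_labels()
  ref <- factor(reference[trials$vignette_id], levels = lv)
  assigned <- factor(ifelse(is.na(trials$parsed), "invalid", trials$parsed),
                     levels = c(lv, "invalid"))
  m <- table(reference = ref, assigned = assigned)
  m <- unclass(m)
  class(m) <- c("triage_confusion", class(m))
  m
}

#' Triage accuracy report against the reference standard
#'
#' Accuracy is the percentage of *valid* responses that match the reference
#' standard; invalid responses are excluded from the denominator.  Also
#' reports overtriage and undertriage rates over valid responses, per
#' reference-class match/over/under breakdowns, and per-appraiser accuracy
#' (mean with the SD of the per-replicate accuracy proportions).
#'
#' @param trials a `trial_table`.
#' @param reference named vector vignette_id -> triage label.
#' @return an object of class `triage_accuracy` with elements
#'   `overall_accuracy`, `overtriage_rate`, `undertriage_rate` (percent of
#'   valid trials), `per_class` (data.frame with match/over/under percent
#'   per reference class), `per_appraiser` (data.frame appraiser_id,
#'   accuracy, sd, n_valid), `confusion`, `n_valid`, `n_total`,
#'   `percent_valid`.
#' @export
triage_accuracy <- function(trials, reference) {
  confusion <- build_confusion(trials, reference)
  valid <- trials[!is.na(trials$parsed), , drop = FALSE]
  if (nrow(valid) == 0L) stop("no valid trials: accuracy is undefined")
  dir <- classify_direction(valid$parsed, reference[valid$vignette_id])
  overall <- 100 * mean(dir == "match")
  over <- 100 * mean(dir == "overtriage")
  under <- 100 * mean(dir == "undertriage")

  ref_class <- reference[valid$vignette_id]
  per_class <- do.call(rbind, lapply(triage_labels(), function(cl) {
    d <- dir[ref_class == cl]
    if (!length(d))
      return(data.frame(reference = cl, n_valid = 0L, match = NA_real_,
                        overtriage = NA_real_, undertriage = NA_real_))
    data.frame(reference = cl, n_valid = length(d),
               match = 100 * mean(d == "match"),
               overtriage = 100 * mean(d == "overtriage"),
               undertriage = 100 * mean(d == "undertriage"))
  }))

  acc_by <- function(sub) 100 * mean(
    classify_direction(sub$parsed, reference[sub$vignette_id]) == "match")
  per_appraiser <- do.call(rbind, lapply(
    sort(unique(trials$appraiser_id)), function(a) {
      sub <- valid[valid$appraiser_id == a, , drop = FALSE]
      if (nrow(sub) == 0L)
        return(data.frame(appraiser_id = a, accuracy = NA_real_,
                          sd = NA_real_, n_valid = 0L))
      by_rep <- vapply(sort(unique(sub$replicate)), function(k)
        acc_by(sub[sub$replicate == k, , drop = FALSE]), numeric(1))
      data.frame(appraiser_id = a, accuracy = acc_by(sub),
                 sd = stats::sd(by_rep), n_valid = nrow(sub))
    }))

  structure(list(
    overall_accuracy = overall, overtriage_rate = over,
    undertriage_rate = under, per_class = per_class,
    per_appraiser = per_appraiser, confusion = confusion,
    n_valid = nrow(valid), n_total = nrow(trials),
    percent_valid = 100 * nrow(valid) / nrow(trials)
  ), class = "triage_accuracy")
}

#' @rdname triage_accuracy
#' @param x a `triage_accuracy` object.
#' @param ... unused.
#' @export
print.triage_accuracy <- function(x, ...) {
  cat(sprintf("Triage accuracy over %d valid of %d trials (%.1f%% valid)\n",
              x$n_valid, x$n_total, x$percent_valid))
  cat(sprintf("  overall accuracy: %.1f%%   overtriage: %.1f%%   undertriage: %.1f%%\n",
              x$overall_accuracy, x$overtriage_rate, x$undertriage_rate))
  cat("\nBy reference class (% of valid trials):\n")
  print(x$per_class, row.names = FALSE, digits = 3)
  cat("\nBy appraiser:\n")
  print(x$per_appraiser, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a confusion matrix as CSV
#'
#' Rows are the reference classes, columns the four assigned codes plus
#' `invalid`.
#'
#' @param confusion a `triage_confusion` matrix.
#' @param path CSV file path.
#' @export
write_confusion <- function(confusion, path) {
  df <- data.frame(reference = rownames(confusion),
                   as.data.frame.matrix(unclass(confusion)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Heat-map of a confusion matrix
#'
#' @param x a `triage_confusion` matrix.
#' @param ... passed to [graphics::image()].
#' @export
plot.triage_confusion <- function(x, ...) {
  m <- unclass(x)
  rowp <- m / pmax(rowSums(m), 1)
  nr <- nrow(m); nc <- ncol(m)
  graphics::image(seq_len(nc), seq_len(nr), t(rowp[nr:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "assigned", ylab = "reference",
                  main = "Assigned vs reference triage code", ...)
  graphics::axis(1, at = seq_len(nc), labels = colnames(m))
  graphics::axis(2, at = seq_len(nr), labels = rev(rownames(m)), las = 1)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    graphics::text(j, nr - i + 1, m[i, j], cex = 0.8)
  invisible(x)
}
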