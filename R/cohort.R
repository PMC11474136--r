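#' @title Patient vignette cohorts
#' @description A cohort is a data.frame with one row per simulated patient:
#'   `vignette_id`, `age` (years), `sex` ("male"/"female"), the structured
#'   physiology fields (`ambulatory`, `spontaneous_breathing`,
#'   `breathing_after_airway_reposition`, `respiratory_rate`,
#'   `radial_pulse_present`, `capillary_refill`, `obeys_commands`), a
#'   rendered free-text `narrative` and the engine-assigned `reference_code`.
#' @name cohort
NULL

physiology_fields <- c("ambulatory", "spontaneous_breathing",
                       "breathing_after_airway_reposition",
                       "respiratory_rate", "radial_pulse_present",
                       "capillary_refill", "obeys_commands")

# internal: physiology object from one cohort row
row_physiology <- function(row) {
  physiology(
    ambulatory = row$ambulatory,
    spontaneous_breathing = row$spontaneous_breathing,
    breathing_after_airway_reposition = row$breathing_after_airway_reposition,
    respiratory_rate = row$respiratory_rate,
    radial_pulse_present = row$radial_pulse_present,
    capillary_refill = row$capillary_refill,
    obeys_commands = row$obeys_commands
  )
}

#' Render a deterministic narrative for a vignette
#'
#' Produces the free text an appraiser is shown.  The template is chosen
#' deterministically from the vignette id so surface form varies across the
#' cohort while the narrative stays a pure function of the structured fields.
#'
#' @param vignette_id unique identifier (drives template choice).
#' @param age years.
#' @param sex "male" or "female".
#' @param p a [physiology()] object or compatible list.
#' @return a single character string.
#' @export
render_narrative <- function(vignette_id, age, sex, p) {
  walk <- if (isTRUE(p$ambulatory)) "is walking around the scene"
          else "is found lying on the ground, unable to walk"
  breath <- if (isTRUE(p$spontaneous_breathing)) {
    sprintf("Breathing is spontaneous at %d breaths per minute.",
            as.integer(p$respiratory_rate))
  } else if (isTRUE(p$breathing_after_airway_reposition)) {
    "There is no spontaneous breathing, but breathing resumes after the airway is repositioned."
  } else {
    "There is no breathing, even after the airway is repositioned."
  }
  perf <- character(0)
  if (!is.na(p$radial_pulse_present)) {
    perf <- c(perf, if (isTRUE(p$radial_pulse_present))
      "The radial pulse is palpable." else "No radial pulse can be felt.")
  }
  if (!is.na(p$capillary_refill)) {
    perf <- c(perf, sprintf("Capillary refill takes %.1f seconds.",
                            p$capillary_refill))
  }
  mental <- if (isTRUE(p$obeys_commands)) "The patient follows simple commands."
            else "The patient does not respond to simple commands."
  body <- paste(c(breath, perf, mental), collapse = " ")

  templates <- c(
    "A %d-year-old %s %s. %s",
    "Rescuers find a %d-year-old %s who %s. %s",
    "Casualty report: %s patient, %d years old, %s. %s"
  )
  k <- (sum(utf8ToInt(as.character(vignette_id))) %% length(templates)) + 1L
  if (k == 3L) {
    sprintf(templates[k], sex, as.integer(age), walk, body)
  } else {
    sprintf(templates[k], as.integer(age), sex, walk, body)
  }
}

# internal: validate a cohort data.frame
validate_cohort <- function(cohort) {
  need <- c("vignette_id", "age", "sex", physiology_fields,
            "narrative", "reference_code")
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(cohort$vignette_id))
    stop("duplicate vignette_id values in cohort")
  bad <- !cohort$reference_code %in% triage_labels()
  if (any(bad))
    stop("invalid reference_code for vignette(s): ",
         paste(cohort$vignette_id[bad], collapse = ", "))
  invisible(cohort)
}

#' Read and write vignette cohorts as JSON Lines
#'
#' One vignette per line; physiology fields are nested under `physiology`.
#' The writer is byte-stable given a fixed row order, so a cohort written
#' twice from the same data.frame produces identical files.
#'
#' @param cohort a cohort data.frame (see [cohort]).
#' @param path file path.
#' @return `read_cohort()` returns the cohort data.frame; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  lines <- vapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    phys <- lapply(physiology_fields, function(f) row[[f]])
    names(phys) <- physiology_fields
    jsonlite::toJSON(list(
      vignette_id = row$vignette_id, age = row$age, sex = row$sex,
      physiology = phys, narrative = row$narrative,
      reference_code = row$reference_code
    ), auto_unbox = TRUE, na = "null", digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    phys <- x$physiology
    null2na <- function(v, na) if (is.null(v)) na else v
    data.frame(
      vignette_id = x$vignette_id, age = x$age, sex = x$sex,
      ambulatory = phys$ambulatory,
      spontaneous_breathing = phys$spontaneous_breathing,
      breathing_after_airway_reposition = phys$breathing_after_airway_reposition,
      respiratory_rate = null2na(phys$respiratory_rate, NA_integer_),
      radial_pulse_present = null2na(phys$radial_pulse_present, NA),
      capillary_refill = null2na(phys$capillary_refill, NA_real_),
      obeys_commands = phys$obeys_commands,
      narrative = x$narrative, reference_code = x$reference_code,
      stringsAsFactors = FALSE
    )
  })
  cohort <- do.call(rbind, rows)
  validate_cohort(cohort)
  cohort
}

#' Read and write rater assignments
#'
#' A rater assignment maps every vignette in a cohort to one triage code.
#' The file format is CSV with header `vignette_id,code`.
#'
#' @param rater_id identifier for the rater.
#' @param codes named character vector (names = vignette ids, values =
#'   triage labels).
#' @return a `rater_assignment` object.
#' @export
rater_assignment <- function(rater_id, codes) {
  if (is.null(names(codes)) || any(!nzchar(names(codes))))
    stop("'codes' must be a named vector keyed by vignette_id")
  if (anyDuplicated(names(codes)))
    stop("duplicate vignette_id in rater assignment")
  bad <- !codes %in% triage_labels()
  if (any(bad))
    stop("invalid code(s) for vignette(s): ",
         paste(names(codes)[bad], collapse = ", "))
  structure(list(rater_id = rater_id, codes = codes),
            class = "rater_assignment")
}

#' @rdname rater_assignment
#' @param path CSV file path.
#' @export
write_rater_assignment <- function(x, path) {
  stopifnot(inherits(x, "rater_assignment"))
  utils::write.csv(
    data.frame(vignette_id = names(x$codes), code = unname(x$codes)),
    path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname rater_assignment
#' @param x a `rater_assignment` (for writing).
#' @export
read_rater_assignment <- function(path, rater_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("vignette_id", "code") %in% names(df)))
    stop("rater CSV must have columns vignette_id,code")
  rater_assignment(rater_id, stats::setNames(df$code, df$vignette_id))
}

# internal: check two assignments cover the same cohort
same_cohort <- function(a, b) {
  miss_b <- setdiff(names(a$codes), names(b$codes))
  miss_a <- setdiff(names(b$codes), names(a$codes))
  if (length(miss_a) || length(miss_b))
    stop("rater assignments cover different cohorts; missing vignette_ids: ",
         paste(unique(c(miss_a, miss_b)), collapse = ", "))
  invisible(TRUE)
}

#' Adjudicate a reference standard from two raters plus a tiebreaker
#'
#' Where the first two raters agree their code stands and the tiebreaker is
#' ignored.  Where they disagree, the code matching the tiebreaker (a 2-of-3
#' majority) is used.  Where all three differ the vignette is marked
#' `unresolved` — it is flagged with a warning rather than silently
#' assigned, and should be excluded from accuracy denominators downstream.
#'
#' @param r1,r2,tiebreaker [rater_assignment()] objects over the same cohort.
#' @return a list of class `adjudication` with elements `final` (named code
#'   vector, `NA` where unresolved), `provenance` (per vignette, one of
#'   `two_rater_agreement`, `tiebreaker_majority`, `unresolved`),
#'   `n_agreed`, `percent_agreement` and `kappa` (the two primary raters'
#'   agreement statistics).
#' @export
adjudicate_reference <- function(r1, r2, tiebreaker) {
  same_cohort(r1, r2); same_cohort(r1, tiebreaker)
  ids <- names(r1$codes)
  a <- r1$codes[ids]; b <- r2$codes[ids]; t <- tiebreaker$codes[ids]
  final <- ifelse(a == b, a, ifelse(t == a, a, ifelse(t == b, b, NA)))
  provenance <- ifelse(a == b, "two_rater_agreement",
                       ifelse(t == a | t == b, "tiebreaker_majority",
                              "unresolved"))
  names(final) <- names(provenance) <- ids
  if (any(provenance == "unresolved"))
    warning(sum(provenance == "unresolved"),
            " vignette(s) unresolved (all three raters differ): ",
            paste(ids[provenance == "unresolved"], collapse = ", "))
  agr <- percent_agreement(r1, r2)
  kap <- tryCatch(cohen_kappa(rater_cross_table(r1, r2)),
                  error = function(e) NULL)
  structure(list(final = final, provenance = provenance,
                 n_agreed = agr$n_agreed,
                 percent_agreement = agr$percent_agreement,
                 kappa = kap),
            class = "adjudication")
}

#' Raw agreement between two raters
#'
#' @inheritParams adjudicate_reference
#' @return list with `n_agreed`, `n_total` and `percent_agreement` (percent,
#'   0-100).
#' @export
percent_agreement <- function(r1, r2) {
  same_cohort(r1, r2)
  ids <- names(r1$codes)
  n_agreed <- sum(r1$codes[ids] == r2$codes[ids])
  list(n_agreed = n_agreed, n_total = length(ids),
       percent_agreement = 100 * n_agreed / length(ids))
}

#' Cross-tabulate two raters' codes
#'
#' @inheritParams adjudicate_reference
#' @return a 4x4 count matrix (rows = rater 1, columns = rater 2) in ordinal
#'   order red/yellow/green/black.
#' @export
rater_cross_table <- function(r1, r2) {
  same_cohort(r1, r2)
  ids <- names(r1$codes)
  lv <- triage_labels()
  table(factor(r1$codes[ids], levels = lv),
        factor(r2$codes[ids], levels = lv))
}

#' Unweighted Cohen's kappa with an asymptotic 95% CI
#'
#' Chance-corrected agreement for a square contingency table:
#' kappa = (p_o - p_e) / (1 - p_e), with observed agreement p_o the diagonal
#' fraction and expected agreement p_e the sum of products of the marginal
#' fractions.  The confidence interval uses the large-sample normal
#' approximation with Cohen's standard error
#' sqrt(p_o (1 - p_o) / (N (1 - p_e)^2)).
#'
#' @param cross_table square matrix of non-negative counts (rater 1 in rows,
#'   rater 2 in columns).
#' @return list with `kappa`, `se`, `ci` (length-2 vector), `p_o`, `p_e`,
#'   `n`.
#' @export
cohen_kappa <- function(cross_table) {
  m <- as.matrix(cross_table)
  if (nrow(m) != ncol(m)) stop("cross_table must be square")
  if (any(m < 0)) stop("counts must be non-negative")
  n <- sum(m)
  if (n <= 0) stop("cross_table must contain at least one observation")
  p <- m / n
  p_o <- sum(diag(p))
  p_e <- sum(rowSums(p) * colSums(p))
  if (1 - p_e < .Machine$double.eps^0.5)
    stop("kappa is undefined: expected agreement is 1 ",
         "(degenerate single-category table)")
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  list(kappa = kappa, se = se,
       ci = kappa + c(-1, 1) * stats::qnorm(0.975) * se,
       p_o = p_o, p_e = p_e, n = n)
}
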