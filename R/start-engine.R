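#' Structured physiology snapshot for START triage
#'
#' Captures the minimal physiological observations the START flowchart
#' consumes.  All gates operate on these structured fields; free-text
#' understanding is deliberately out of scope.
#'
#' @param ambulatory logical; can the patient walk?
#' @param spontaneous_breathing logical; is the patient breathing without
#'   intervention?
#' @param breathing_after_airway_reposition logical; does breathing resume
#'   after the airway is repositioned?  Only consulted when
#'   `spontaneous_breathing` is `FALSE`.
#' @param respiratory_rate breaths per minute, non-negative integer.  Must be
#'   positive when `spontaneous_breathing` is `TRUE`.
#' @param radial_pulse_present logical or `NA`; radial pulse check.  One of
#'   the two perfusion indicators.
#' @param capillary_refill seconds, non-negative, or `NA`; the alternative
#'   perfusion indicator.  At least one indicator must be non-missing if the
#'   perfusion gate is reached.
#' @param obeys_commands logical; does the patient follow simple commands?
#'
#' @return an object of class `physiology` (a named list of the validated
#'   fields).
#' @examples
#' p <- physiology(ambulatory = FALSE, spontaneous_breathing = TRUE,
#'                 respiratory_rate = 24, radial_pulse_present = TRUE,
#'                 obeys_commands = TRUE)
#' triage_start(p)
#' @export
physiology <- function(ambulatory,
                       spontaneous_breathing = TRUE,
                       breathing_after_airway_reposition = FALSE,
                       respiratory_rate = NA_integer_,
                       radial_pulse_present = NA,
                       capillary_refill = NA_real_,
                       obeys_commands = TRUE) {
  chk_flag <- function(x, nm, na_ok = FALSE) {
    if (length(x) != 1L || (!na_ok && is.na(x)) || (!is.na(x) && !is.logical(x)))
      stop("'", nm, "' must be a single ", if (na_ok) "logical or NA" else "TRUE/FALSE")
    x
  }
  p <- list(
    ambulatory = chk_flag(ambulatory, "ambulatory"),
    spontaneous_breathing = chk_flag(spontaneous_breathing, "spontaneous_breathing"),
    breathing_after_airway_reposition =
      chk_flag(breathing_after_airway_reposition, "breathing_after_airway_reposition"),
    respiratory_rate = respiratory_rate,
    radial_pulse_present = chk_flag(radial_pulse_present, "radial_pulse_present",
                                    na_ok = TRUE),
    capillary_refill = capillary_refill,
    obeys_commands = chk_flag(obeys_commands, "obeys_commands")
  )
  rr <- p$respiratory_rate
  if (!is.na(rr) && (rr < 0 || rr != round(rr)))
    stop("'respiratory_rate' must be a non-negative integer (breaths/minute)")
  if (isTRUE(p$spontaneous_breathing) && !is.na(rr) && rr == 0)
    stop("'respiratory_rate' must be > 0 when breathing is spontaneous")
  cr <- p$capillary_refill
  if (!is.na(cr) && cr < 0)
    stop("'capillary_refill' must be non-negative (seconds)")
  structure(p, class = "physiology")
}

#' Deterministic START triage of a structured patient snapshot
#'
#' Applies the canonical START gates in order: (1) ambulatory patients are
#' green; (2) a patient not breathing spontaneously, and not after airway
#' repositioning, is black, while breathing only after repositioning is red;
#' (3) respiratory rate strictly over 30/min is red; (4) failed perfusion
#' (absent radial pulse, or capillary refill strictly over 2 s) is red;
#' (5) not obeying simple commands is red; (6) otherwise yellow.  Pediatric
#' patients are triaged with the same adult gates.
#'
#' `decision_trace()` returns the gates actually evaluated, in order, each
#' with its outcome ("pass" for a gate that did not decide, otherwise the
#' assigned colour); the final entry's outcome is the triage code.
#'
#' @param p a [physiology()] object (or a plain list with the same fields).
#' @return `triage_start()`: a single triage colour label (see
#'   [triage_labels()]).  `decision_trace()`: a data.frame with columns
#'   `rule` and `outcome`.
#' @examples
#' triage_start(physiology(ambulatory = TRUE))   # "green"
#' decision_trace(physiology(ambulatory = FALSE, spontaneous_breathing = TRUE,
#'                           respiratory_rate = 32))
#' @export
triage_start <- function(p) {
  tr <- decision_trace(p)
  tr$outcome[nrow(tr)]
}

#' @rdname triage_start
#' @export
decision_trace <- function(p) {
  if (!is.list(p)) stop("'p' must be a physiology snapshot")
  step <- function(rule, outcome) data.frame(rule = rule, outcome = outcome,
                                             stringsAsFactors = FALSE)
  trace <- list()

  # gate 1: ambulatory -> green
  if (isTRUE(p$ambulatory)) {
    return(step("ambulatory", "green"))
  }
  trace[[1L]] <- step("ambulatory", "pass")

  # gate 2: airway/breathing
  if (!isTRUE(p$spontaneous_breathing)) {
    out <- if (isTRUE(p$breathing_after_airway_reposition)) "red" else "black"
    trace[[length(trace) + 1L]] <- step("breathing", out)
    return(do.call(rbind, trace))
  }
  trace[[length(trace) + 1L]] <- step("breathing", "pass")

  # gate 3: respiratory rate > 30 -> red (30 itself passes)
  rr <- p$respiratory_rate
  if (is.na(rr))
    stop("respiratory_rate is required at the respiratory-rate gate")
  if (rr > 30) {
    trace[[length(trace) + 1L]] <- step("respiratory_rate", "red")
    return(do.call(rbind, trace))
  }
  trace[[length(trace) + 1L]] <- step("respiratory_rate", "pass")

  # gate 4: perfusion; either failing indicator -> red
  pulse <- p$radial_pulse_present
  cr <- p$capillary_refill
  if (is.na(pulse) && is.na(cr))
    stop("no perfusion indicator (radial pulse or capillary refill) ",
         "available at the perfusion gate")
  if (identical(pulse, FALSE) || (!is.na(cr) && cr > 2)) {
    trace[[length(trace) + 1L]] <- step("perfusion", "red")
    return(do.call(rbind, trace))
  }
  trace[[length(trace) + 1L]] <- step("perfusion", "pass")

  # gate 5: mental status
  out <- if (isTRUE(p$obeys_commands)) "yellow" else "red"
  trace[[length(trace) + 1L]] <- step("obeys_commands", out)
  do.call(rbind, trace)
}
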