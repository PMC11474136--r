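#' START triage codes and their ordinal encoding
#'
#' The START protocol classifies casualties as red (immediate), yellow
#' (delayed), green (ambulatory/minor) or black (expectant).  To preserve
#' ordinality the codes are rescored as integers by acuity priority:
#' red = 1, yellow = 2, green = 3, black = 4.
#'
#' @return `triage_labels()` returns the four colour labels in ordinal
#'   order (red, yellow, green, black).
#' @examples
#' triage_labels()
#' triage_ordinal(c("red", "black"))
#' triage_label(1:4)
#' @export
triage_labels <- function() c("red", "yellow", "green", "black")

#' @rdname triage_labels
#' @param label character vector of colour labels.
#' @return `triage_ordinal()` returns the integer encoding (1-4).
#' @export
triage_ordinal <- function(label) {
  idx <- match(label, triage_labels())
  if (anyNA(idx) && !anyNA(label)) {
    bad <- unique(label[is.na(idx) & !is.na(label)])
    stop("unknown triage label(s): ", paste(bad, collapse = ", "))
  }
  as.integer(idx)
}

#' @rdname triage_labels
#' @param ordinal integer vector in 1..4.
#' @return `triage_label()` returns the colour labels for an ordinal vector.
#' @export
triage_label <- function(ordinal) {
  ok <- is.na(ordinal) | (ordinal %in% 1:4)
  if (!all(ok)) {
    stop("triage ordinals must be integers in 1..4; got: ",
         paste(unique(ordinal[!ok]), collapse = ", "))
  }
  triage_labels()[as.integer(ordinal)]
}

# internal: validate a scalar triage label
assert_triage_code <- function(code, what = "code") {
  if (length(code) != 1L || is.na(code) || !code %in% triage_labels()) {
    stop(what, " must be one of ", paste(triage_labels(), collapse = "/"),
         "; got ", deparse(code))
  }
  invisible(code)
}
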