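#' Crossed study design
#'
#' Describes a crossed gage R&R layout: every appraiser measures every part
#' (vignette) the same number of times.  The classic study evaluated 9
#' appraisers x 391 parts x 10 replicates = 35,190 trials.
#'
#' @param cohort a cohort data.frame (see [cohort]).
#' @param appraiser_ids ordered character vector of appraiser identifiers.
#' @param n_replicates positive integer, replicate queries per
#'   appraiser-vignette combination (default 10).
#' @param seed integer RNG seed for the synthetic responses.
#' @return a `study_design` object.
#' @export
study_design <- function(cohort, appraiser_ids, n_replicates = 10L,
                         seed = 1L) {
  validate_cohort(cohort)
  if (length(appraiser_ids) < 1L) stop("at least one appraiser is required")
  if (anyDuplicated(appraiser_ids)) stop("duplicate appraiser ids")
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L)
    stop("'n_replicates' must be a positive integer")
  structure(list(cohort = cohort, appraiser_ids = appraiser_ids,
                 n_replicates = n_replicates, seed = as.integer(seed),
                 n_trials = length(appraiser_ids) * nrow(cohort) *
                   n_replicates),
            class = "study_design")
}

#' Assemble the query text for one trial
#'
#' The query is the prompt, the vignette narrative, and the fixed
#' restriction "Answer only with the color code and no other text", in that
#' order, separated by blank lines.
#'
#' @param prompt_text the appraiser's prompt (non-empty).
#' @param narrative the vignette narrative (non-empty).
#' @return a single string.
#' @export
build_query <- function(prompt_text, narrative) {
  if (!is.character(prompt_text) || length(prompt_text) != 1L ||
      !nzchar(prompt_text))
    stop("'prompt_text' must be a non-empty string")
  if (!is.character(narrative) || length(narrative) != 1L ||
      !nzchar(narrative))
    stop("'narrative' must be a non-empty string")
  paste(prompt_text, narrative,
        "Answer only with the color code and no other text", sep = "\n\n")
}

#' Parse a response text into a triage code
#'
#' Scans case-insensitively for the four colour words as standalone tokens
#' (so "RED." parses but "hundred" does not).  A response is valid if and
#' only if exactly one distinct colour word occurs, any number of times;
#' empty text, text without a colour word, and text with two or more
#' distinct colour words are invalid and parse to `NA`.
#'
#' @param text character vector of raw responses.
#' @return character vector of triage labels, `NA` where invalid.
#' @examples
#' parse_response(c("Red", "The code is: YELLOW.", "red or yellow", ""))
#' @export
parse_response <- function(text) {
  vapply(text, function(t) {
    if (is.na(t) || !nzchar(t)) return(NA_character_)
    low <- tolower(t)
    hits <- regmatches(low, gregexpr("\\b(red|yellow|green|black)\\b",
                                     low, perl = TRUE))[[1]]
    found <- unique(hits)
    if (length(found) == 1L) found else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Run the crossed appraiser-by-part-by-replicate study
#'
#' Loops appraiser-outermost, then vignette, then replicate (the canonical
#' order), builds each query, obtains a raw response, and parses it.  Each
#' appraiser is either an `appraiser_model` (sampled synthetically; fully
#' reproducible from `design$seed`) or a callback `function(query)`
#' returning text — the hook where a live LLM client would plug in.  A
#' callback that keeps erroring after `retries` further attempts yields an
#' invalid record; the run continues.
#'
#' @param design a [study_design()].
#' @param appraisers list of `appraiser_model` objects and/or callbacks, in
#'   the order of `design$appraiser_ids`.
#' @param retries attempts after the first failure of a callback (default 2).
#' @param verbose log per-appraiser progress to stderr.
#' @return a `trial_table`: a data.frame with one row per planned trial and
#'   columns `appraiser_id`, `vignette_id`, `replicate`, `raw_response`,
#'   `parsed` (label or `NA`), `ordinal` (1-4 or `NA`).
#' @examples
#' cohort <- generate_cohort(cohort_spec(2, 2, 2, 2, seed = 7))
#' ident <- make_confusion_appraiser(diag(4), 0, "exact")
#' trials <- run_crossed_study(study_design(cohort, "exact", 2), list(ident))
#' nrow(trials)  # 8 vignettes x 1 appraiser x 2 replicates
#' @export
run_crossed_study <- function(design, appraisers, retries = 2L,
                              verbose = FALSE) {
  stopifnot(inherits(design, "study_design"))
  if (length(appraisers) != length(design$appraiser_ids))
    stop("'appraisers' must match design$appraiser_ids (",
         length(design$appraiser_ids), " expected)")
  cohort <- design$cohort
  r <- design$n_replicates
  ref <- cohort_reference(cohort)
  with_local_seed(design$seed, {
    per_appraiser <- lapply(seq_along(appraisers), function(ai) {
      app <- appraisers[[ai]]
      aid <- design$appraiser_ids[ai]
      if (verbose)
        message(sprintf("appraiser %s (%d/%d): %d queries",
                        aid, ai, length(appraisers), nrow(cohort) * r))
      raw <- character(nrow(cohort) * r)
      for (vi in seq_len(nrow(cohort))) {
        idx <- (vi - 1L) * r + seq_len(r)
        if (inherits(app, "appraiser_model")) {
          raw[idx] <- sample_response(app, ref[[vi]], n = r)
        } else if (is.function(app)) {
          query <- build_query(attr(app, "prompt_text") %||%
                                 "Assign a START triage colour to this patient.",
                               cohort$narrative[vi])
          raw[idx] <- vapply(seq_len(r), function(k)
            call_with_retries(app, query, retries), character(1))
        } else stop("appraiser #", ai,
                    " is neither an appraiser_model nor a function")
      }
      data.frame(
        appraiser_id = aid,
        vignette_id = rep(cohort$vignette_id, each = r),
        replicate = rep(seq_len(r), times = nrow(cohort)),
        raw_response = raw,
        stringsAsFactors = FALSE
      )
    })
    trials <- do.call(rbind, per_appraiser)
    trials$parsed <- parse_response(trials$raw_response)
    trials$ordinal <- triage_ordinal(trials$parsed)
    class(trials) <- c("trial_table", "data.frame")
    attr(trials, "design") <- list(
      n_appraisers = length(appraisers), n_parts = nrow(cohort),
      n_replicates = r, seed = design$seed)
    trials
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: call an external appraiser with bounded retries; failures after
# the last retry become an empty (invalid) response.
call_with_retries <- function(fun, query, retries) {
  for (attempt in seq_len(retries + 1L)) {
    out <- tryCatch(fun(query), error = function(e) e)
    if (!inherits(out, "error")) return(as.character(out)[1])
  }
  ""
}

#' Valid-response rate of a trial table
#'
#' @param trials a `trial_table`.
#' @return list with `n_valid`, `n_total` and `percent_valid` (0-100).
#' @export
valid_rate <- function(trials) {
  if (nrow(trials) == 0L) stop("trial table is empty")
  n_valid <- sum(!is.na(trials$parsed))
  list(n_valid = n_valid, n_total = nrow(trials),
       percent_valid = 100 * n_valid / nrow(trials))
}

#' Read and write trial tables as CSV
#'
#' Columns `appraiser_id,vignette_id,replicate,raw_response,parsed,ordinal`;
#' invalid parses are written as the literal token `NA`; fields are quoted
#' per RFC 4180 so embedded newlines round-trip.
#'
#' @param trials a `trial_table`.
#' @param path CSV file path.
#' @return `read_trial_table()` returns a `trial_table`.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(as.data.frame(trials)[, c("appraiser_id", "vignette_id",
                                             "replicate", "raw_response",
                                             "parsed", "ordinal")],
                   path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  need <- c("appraiser_id", "vignette_id", "replicate", "raw_response",
            "parsed", "ordinal")
  header <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  missing <- setdiff(need, header)
  if (length(missing))
    stop("trial CSV is missing column(s): ", paste(missing, collapse = ", "))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(appraiser_id = "character",
                                       vignette_id = "character",
                                       replicate = "integer",
                                       raw_response = "character",
                                       parsed = "character",
                                       ordinal = "integer"))
  df$raw_response[is.na(df$raw_response)] <- ""
  class(df) <- c("trial_table", "data.frame")
  attr(df, "design") <- list(
    n_appraisers = length(unique(df$appraiser_id)),
    n_parts = length(unique(df$vignette_id)),
    n_replicates = max(df$replicate))
  df
}
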