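# Eligibility filters and complete-case samples --------------------------

.log_step <- function(log, reason, removed, remaining) {
  rbind(log, data.frame(reason = reason, n_removed = removed,
                        n_remaining = remaining, stringsAsFactors = FALSE))
}

#' Exclude withdrawn participants and prevalent/early-incident dementia
#'
#' Removes participants who withdrew, who had prevalent dementia at
#' baseline, or whose first dementia diagnosis fell within the first
#' `window_years` of follow-up (strict `<`), to avoid reverse causality:
#' prodromal disease close to diagnosis is no longer the "pre-clinical"
#' exposure the instruments proxy.
#'
#' @param cohort Cohort data.frame with `withdrawn`, `prevalent_dementia`
#'   and `incident_dementia_years` columns.
#' @param window_years Exclusion window in years (default 5).
#' @return The retained subset, with an exclusion log data.frame
#'   (`reason`, `n_removed`, `n_remaining`) as attribute
#'   `"exclusion_log"`.
#' @export
apply_dementia_exclusions <- function(cohort, window_years = 5) {
  log <- data.frame(reason = character(), n_removed = integer(),
                    n_remaining = integer(), stringsAsFactors = FALSE)
  out <- cohort
  drop1 <- !is.na(out$withdrawn) & out$withdrawn == 1
  out <- out[!drop1, , drop = FALSE]
  log <- .log_step(log, "withdrawn", sum(drop1), nrow(out))
  drop2 <- !is.na(out$prevalent_dementia) & out$prevalent_dementia == 1
  out <- out[!drop2, , drop = FALSE]
  log <- .log_step(log, "prevalent_dementia", sum(drop2), nrow(out))
  drop3 <- !is.na(out$incident_dementia_years) &
    out$incident_dementia_years < window_years
  out <- out[!drop3, , drop = FALSE]
  log <- .log_step(log, sprintf("incident_dementia_lt_%gy", window_years),
                   sum(drop3), nrow(out))
  attr(out, "exclusion_log") <- log
  out
}

#' Restrict to the genetic analysis sample
#'
#' Keeps participants who passed genotyping quality control, are in the
#' European ancestry group (self-declared ethnicity; restriction guards
#' against population stratification) and have a valid weighted allele
#' score.
#'
#' @param cohort Cohort data.frame with `qc_fail`, `ethnic_group` and
#'   `pgis_valid` columns.
#' @return Retained subset with an `"exclusion_log"` attribute.
#' @export
genetic_analysis_sample <- function(cohort) {
  log <- data.frame(reason = character(), n_removed = integer(),
                    n_remaining = integer(), stringsAsFactors = FALSE)
  out <- cohort
  drop1 <- is.na(out$qc_fail) | out$qc_fail == 1
  out <- out[!drop1, , drop = FALSE]
  log <- .log_step(log, "qc_fail", sum(drop1), nrow(out))
  drop2 <- is.na(out$ethnic_group) | out$ethnic_group != "European"
  out <- out[!drop2, , drop = FALSE]
  log <- .log_step(log, "non_european", sum(drop2), nrow(out))
  drop3 <- is.na(out$pgis_valid) | !out$pgis_valid
  out <- out[!drop3, , drop = FALSE]
  log <- .log_step(log, "pgis_invalid", sum(drop3), nrow(out))
  attr(out, "exclusion_log") <- log
  out
}

#' Complete-case restriction
#'
#' Keeps rows with no missing value in any of `required_fields` and
#' attaches a per-field missingness table (counts over the input rows).
#'
#' @param cohort Cohort data.frame.
#' @param required_fields Character vector of column names that must be
#'   non-missing.  Unknown names are a structural error.
#' @return Retained subset with attribute `"missingness"` (data.frame
#'   `field`, `n_missing`, `prop_missing`).
#' @export
complete_case <- function(cohort, required_fields) {
  unknown <- setdiff(required_fields, names(cohort))
  if (length(unknown))
    stop("unknown field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!length(required_fields)) {
    attr(cohort, "missingness") <-
      data.frame(field = character(), n_missing = integer(),
                 prop_missing = numeric(), stringsAsFactors = FALSE)
    return(cohort)
  }
  sub <- cohort[, required_fields, drop = FALSE]
  n_miss <- vapply(sub, function(x) sum(is.na(x)), integer(1))
  keep <- stats::complete.cases(sub)
  out <- cohort[keep, , drop = FALSE]
  attr(out, "missingness") <- data.frame(
    field = required_fields, n_missing = unname(n_miss),
    prop_missing = unname(n_miss) / nrow(cohort),
    stringsAsFactors = FALSE
  )
  out
}
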