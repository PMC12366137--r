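# Blood-pressure outcome derivation --------------------------------------

.plausible_bp <- function(x, lo = 40, hi = 300) {
  # device-error guard: readings outside (40, 300) mmHg are set missing
  x[!is.na(x) & (x <= lo | x >= hi)] <- NA_real_
  x
}

.visit_mean <- function(a, b) {
  both <- !is.na(a) & !is.na(b)
  one <- xor(is.na(a), is.na(b))
  out <- rep(NA_real_, length(a))
  out[both] <- (a[both] + b[both]) / 2
  out[one] <- ifelse(is.na(a[one]), b[one], a[one])
  out
}

#' Mean blood pressure from per-visit reading pairs
#'
#' Per pressure type independently: the mean of the two baseline readings
#' if both are present; the single reading if only one was recorded; and if
#' both baseline readings are missing, the same rule applied to the first
#' subsequent visit with any reading.  Automated readings are preferred
#' over manual ones within a visit.  Participants with no reading at any
#' visit get a missing outcome (flagged for complete-case handling), not an
#' error.
#'
#' @param visits A list of visits in visit order; each visit is a list with
#'   elements `sbp` (numeric length <= 2), `dbp` (numeric length <= 2) and
#'   optionally `sbp_manual`/`dbp_manual` fallback readings.  Readings
#'   outside (40, 300) mmHg are treated as missing.
#' @return A list with `sbp_mean`, `dbp_mean`, `sbp_source_visit`,
#'   `dbp_source_visit` (0-based visit index, `NA` when unresolved).
#' @export
#' @examples
#' derive_mean_bp(list(list(sbp = c(120, 130), dbp = c(80, 84))))
derive_mean_bp <- function(visits) {
  stopifnot(is.list(visits), length(visits) >= 1)
  pick <- function(type) {
    for (i in seq_along(visits)) {
      v <- visits[[i]]
      auto <- .plausible_bp(as.numeric(v[[type]] %||% c(NA, NA)))
      man <- .plausible_bp(as.numeric(v[[paste0(type, "_manual")]] %||% c(NA, NA)))
      r <- if (any(!is.na(auto))) auto else man
      m <- .visit_mean(r[1], if (length(r) > 1) r[2] else NA_real_)
      if (!is.na(m)) return(list(mean = m, visit = i - 1L))
    }
    list(mean = NA_real_, visit = NA_integer_)
  }
  s <- pick("sbp"); d <- pick("dbp")
  list(sbp_mean = s$mean, dbp_mean = d$mean,
       sbp_source_visit = s$visit, dbp_source_visit = d$visit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correct measured blood pressure for antihypertensive treatment
#'
#' Adds the conventional +15 mmHg to SBP and +10 mmHg to DBP for
#' participants on BP-lowering medication (antihypertensives, or drugs
#' prescribed for other indications that also lower BP), conservative
#' estimates of average treatment lowering.  Untreated participants are
#' unchanged.  The returned data.frame carries a `corrected` column and
#' the function refuses inputs already flagged corrected, so the shift can
#' never be applied twice.
#'
#' @param sbp_mean,dbp_mean Measured mean BP, mmHg.
#' @param on_bp_med 0/1 indicator of BP-lowering medication use.
#' @param sbp_add,dbp_add Correction constants (defaults 15 and 10 mmHg).
#' @return data.frame with `sbp`, `dbp`, `corrected` (logical), of class
#'   `adbp_bp_corrected`.
#' @export
#' @examples
#' correct_for_medication(130, 80, 1)  # 145 / 90
correct_for_medication <- function(sbp_mean, dbp_mean, on_bp_med,
                                   sbp_add = 15, dbp_add = 10) {
  if (inherits(sbp_mean, "adbp_bp_corrected") ||
      isTRUE(attr(sbp_mean, "bp_corrected")))
    stop("blood pressure has already been medication-corrected", call. = FALSE)
  med <- as.integer(on_bp_med)
  out <- data.frame(sbp = sbp_mean + sbp_add * (med == 1L & !is.na(med)),
                    dbp = dbp_mean + dbp_add * (med == 1L & !is.na(med)),
                    corrected = !is.na(med))
  out$sbp[is.na(med)] <- NA_real_
  out$dbp[is.na(med)] <- NA_real_
  class(out) <- c("adbp_bp_corrected", class(out))
  out
}

#' Composite hypertension indicator
#'
#' A participant is hypertensive if any of the following holds:
#' self-reported essential hypertension, use of antihypertensive
#' medication, measured SBP above 140 mmHg, or measured DBP above
#' 90 mmHg.  Thresholds are strict (boundary values are normotensive) and
#' are applied to measured, uncorrected BP: medication already enters the
#' composite directly, so correcting BP as well would double-count
#' treatment.  Three-valued logic: any satisfied criterion gives `TRUE`;
#' all criteria resolvably unsatisfied gives `FALSE`; otherwise `NA`.
#'
#' @param self_report_htn,on_antihypertensive 0/1 indicators.
#' @param sbp_measured,dbp_measured Measured mean BP, mmHg.
#' @param sbp_threshold,dbp_threshold Strict cutoffs, mmHg (defaults 140
#'   and 90).
#' @return Integer vector (1/0/`NA`).
#' @export
#' @examples
#' derive_hypertension(0, 0, 140, 90)  # 0: boundary values are normotensive
derive_hypertension <- function(self_report_htn, on_antihypertensive,
                                sbp_measured, dbp_measured,
                                sbp_threshold = 140, dbp_threshold = 90) {
  res <- (self_report_htn == 1) | (on_antihypertensive == 1) |
    (sbp_measured > sbp_threshold) | (dbp_measured > dbp_threshold)
  as.integer(res)
}

#' Derive all blood-pressure outcomes for a cohort table
#'
#' Applies [derive_mean_bp()], [correct_for_medication()] and
#' [derive_hypertension()] across a cohort table whose reading columns
#' follow the `sbp_<visit><a|b>` / `dbp_<visit><a|b>` convention.
#'
#' @param cohort Cohort data.frame.
#' @param visits Integer visit indices to consider, in order (default 0:1).
#' @return data.frame keyed by `id` with `sbp_measured`, `dbp_measured`,
#'   `sbp_corrected`, `dbp_corrected`, `corrected`, `hypertension`,
#'   `sbp_source_visit`, `dbp_source_visit`.
#' @export
derive_outcomes <- function(cohort, visits = 0:1) {
  n <- nrow(cohort)
  get_col <- function(nm) if (nm %in% names(cohort)) .plausible_bp(cohort[[nm]]) else rep(NA_real_, n)
  sbp <- rep(NA_real_, n); dbp <- rep(NA_real_, n)
  sv <- rep(NA_integer_, n); dv <- rep(NA_integer_, n)
  for (v in visits) {
    ms <- .visit_mean(get_col(sprintf("sbp_%d%s", v, "a")),
                      get_col(sprintf("sbp_%d%s", v, "b")))
    md <- .visit_mean(get_col(sprintf("dbp_%d%s", v, "a")),
                      get_col(sprintf("dbp_%d%s", v, "b")))
    fill_s <- is.na(sbp) & !is.na(ms)
    fill_d <- is.na(dbp) & !is.na(md)
    sbp[fill_s] <- ms[fill_s]; sv[fill_s] <- v
    dbp[fill_d] <- md[fill_d]; dv[fill_d] <- v
  }
  corr <- correct_for_medication(sbp, dbp, cohort$bp_med)
  data.frame(
    id = cohort$id,
    sbp_measured = sbp, dbp_measured = dbp,
    sbp_corrected = corr$sbp, dbp_corrected = corr$dbp,
    corrected = corr$corrected,
    hypertension = derive_hypertension(cohort$self_report_htn, cohort$bp_med,
                                       sbp, dbp),
    sbp_source_visit = sv, dbp_source_visit = dv,
    stringsAsFactors = FALSE
  )
}
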