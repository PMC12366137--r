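# The model ladder: crude -> fully adjusted ------------------------------

#' One rung of the model ladder
#'
#' @param outcome One of `"SBP"`, `"DBP"`, `"hypertension"`.
#' @param instrument `"PDIS"` or `"PGIS"`.
#' @param covariates Character vector of cohort field names (may be empty
#'   for a crude model).
#' @param bp_correction Use medication-corrected BP as the outcome?
#'   Ignored for the hypertension outcome, which always uses the measured
#'   composite.
#' @param label Rung name, e.g. `"M1 crude"`.
#' @return An `adbp_model_spec` list.
#' @export
model_spec <- function(outcome, instrument, covariates = character(0),
                       bp_correction = TRUE, label = "model") {
  outcome <- match.arg(outcome, c("SBP", "DBP", "hypertension"))
  instrument <- match.arg(instrument, c("PDIS", "PGIS"))
  structure(list(outcome = outcome, instrument = instrument,
                 covariates = covariates,
                 bp_correction = isTRUE(bp_correction), label = label),
            class = "adbp_model_spec")
}

#' Default model ladders for each instrument
#'
#' The parental-score (PDIS) ladder runs from a crude uncorrected model to
#' the pre-specified final model — fully confounder-adjusted with the
#' +15/+10 medication correction: M1 crude/uncorrected, M2
#' crude/corrected, M3 adds sex, M4 adds age, M5 adds the full confounder
#' roster (education, ethnic group, smoking, BMI, physical activity, salt
#' intake, alcohol use, deprivation).  The allele-score (PGIS) ladder is
#' M1 crude, M2 adds genetic principal components, M3 adds sex, M4 adds
#' age, all medication-corrected, reflecting that the external GWAS
#' weights were age- and sex-adjusted and that confounding of a genetic
#' score is implausible beyond population structure.
#'
#' @param instrument `"PDIS"` or `"PGIS"`.
#' @param outcome Outcome label applied to every rung.
#' @param n_pcs Number of principal-component columns (`pc1`..) for the
#'   PGIS ladder.
#' @return List of [model_spec()] rungs, crude first.
#' @export
default_ladder <- function(instrument, outcome = "SBP", n_pcs = 4L) {
  instrument <- match.arg(instrument, c("PDIS", "PGIS"))
  full_confounders <- c("sex", "age", "education", "ethnic_group", "smoking",
                        "bmi", "activity", "salt", "alcohol", "townsend")
  if (instrument == "PDIS") {
    list(
      model_spec(outcome, "PDIS", character(0), FALSE, "M1 crude"),
      model_spec(outcome, "PDIS", character(0), TRUE, "M2 crude corrected"),
      model_spec(outcome, "PDIS", "sex", TRUE, "M3 + sex"),
      model_spec(outcome, "PDIS", c("sex", "age"), TRUE, "M4 + age"),
      model_spec(outcome, "PDIS", full_confounders, TRUE, "M5 fully adjusted")
    )
  } else {
    pcs <- paste0("pc", seq_len(n_pcs))
    list(
      model_spec(outcome, "PGIS", character(0), TRUE, "M1 crude"),
      model_spec(outcome, "PGIS", pcs, TRUE, "M2 + PCs"),
      model_spec(outcome, "PGIS", c(pcs, "sex"), TRUE, "M3 + sex"),
      model_spec(outcome, "PGIS", c(pcs, "sex", "age"), TRUE, "M4 + age")
    )
  }
}

.outcome_column <- function(spec) {
  switch(spec$outcome,
         SBP = if (spec$bp_correction) "sbp_corrected" else "sbp_measured",
         DBP = if (spec$bp_correction) "dbp_corrected" else "dbp_measured",
         hypertension = "hypertension")
}

.score_columns <- function(instrument) {
  if (instrument == "PDIS") c(raw = "pdis_raw", valid = "pdis_valid")
  else c(raw = "pgis_raw", valid = "pgis_valid")
}

#' Fit a model ladder for one instrument-outcome pair
#'
#' Fits every rung of the ladder on one fixed analysis sample: the maximal
#' complete-case sample for the *full* ladder (all rungs' covariates, the
#' outcome and a valid instrument score), so that rung-to-rung changes
#' reflect adjustment rather than sample shift.  The instrument is
#' standardized on that same sample, making every estimate "per 1 SD
#' higher score" in the reporting sample.  SBP and DBP rungs are linear
#' models ([fit_linear()]); hypertension rungs are logistic
#' ([fit_logistic()]).
#'
#' @param data Analysis data.frame containing the score columns
#'   (`pdis_raw`/`pdis_valid` or `pgis_raw`/`pgis_valid`), derived outcome
#'   columns (`sbp_measured`, `sbp_corrected`, `dbp_measured`,
#'   `dbp_corrected`, `hypertension`) and all covariates — typically built
#'   with [assemble_analysis()] and filtered with
#'   [apply_dementia_exclusions()] (and [genetic_analysis_sample()] for
#'   the PGIS).
#' @param instrument `"PDIS"` or `"PGIS"`.
#' @param outcome `"SBP"`, `"DBP"` or `"hypertension"`.
#' @param ladder List of [model_spec()] rungs, crude first; defaults to
#'   [default_ladder()].
#' @return An object of class `adbp_ladder` with `print`, `summary`,
#'   `coef`, `as.data.frame` and `plot` (forest) methods.
#' @export
run_model_ladder <- function(data, instrument = c("PDIS", "PGIS"),
                             outcome = c("SBP", "DBP", "hypertension"),
                             ladder = NULL) {
  instrument <- match.arg(instrument)
  outcome <- match.arg(outcome)
  if (is.null(ladder)) ladder <- default_ladder(instrument, outcome)
  for (spec in ladder) {
    if (spec$instrument != instrument || spec$outcome != outcome)
      stop("ladder rung '", spec$label, "' does not match instrument '",
           instrument, "' / outcome '", outcome, "'", call. = FALSE)
  }
  sc <- .score_columns(instrument)
  all_cov <- unique(unlist(lapply(ladder, `[[`, "covariates")))
  out_cols <- unique(vapply(ladder, .outcome_column, character(1)))
  need <- c(sc[["raw"]], all_cov, out_cols)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("analysis data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  data <- data[data[[sc[["valid"]]]] %in% TRUE,
               unique(c(need, sc[["valid"]])), drop = FALSE]
  cc <- complete_case(data, need)
  z <- standardize_score(cc[[sc[["raw"]]]])
  results <- vector("list", length(ladder))
  for (i in seq_along(ladder)) {
    spec <- ladder[[i]]
    y <- cc[[.outcome_column(spec)]]
    covs <- if (length(spec$covariates))
      cc[, spec$covariates, drop = FALSE] else NULL
    results[[i]] <- if (outcome == "hypertension")
      fit_logistic(y, z, covs, spec$label)
    else
      fit_linear(y, z, covs, spec$label)
  }
  structure(list(results = results, instrument = instrument,
                 outcome = outcome, ladder = ladder, n = nrow(cc),
                 score_center = attr(z, "center"),
                 score_scale = attr(z, "scale"),
                 missingness = attr(cc, "missingness")),
            class = "adbp_ladder")
}

#' @export
print.adbp_ladder <- function(x, ...) {
  cat(sprintf("Model ladder: %s -> %s (n = %d, score SD = %.4g)\n",
              x$instrument, x$outcome, x$n, x$score_scale))
  print(as.data.frame(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.adbp_ladder <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("Instrument %s on %s, one fixed complete-case sample (n = %d)\n",
              object$instrument, object$outcome, object$n))
  cat(sprintf("Effects per 1 SD of raw score (SD = %.4g)\n\n",
              object$score_scale))
  print(df, digits = 4, row.names = FALSE)
  invisible(df)
}

#' @export
as.data.frame.adbp_ladder <- function(x, ...) {
  out <- do.call(rbind, lapply(x$results, as.data.frame))
  cbind(instrument = x$instrument, outcome = x$outcome, out,
        stringsAsFactors = FALSE)
}

#' @export
coef.adbp_ladder <- function(object, ...) {
  stats::setNames(vapply(object$results, `[[`, numeric(1), "estimate"),
                  vapply(object$results, `[[`, character(1), "model_label"))
}

#' Forest plot of ladder rungs
#'
#' @param x An `adbp_ladder` object.
#' @param ... Further graphical arguments (unused).
#' @export
plot.adbp_ladder <- function(x, ...) {
  df <- as.data.frame(x)
  k <- nrow(df)
  null_at <- if (x$outcome == "hypertension") 1 else 0
  xlim <- range(c(df$ci_low, df$ci_high, null_at))
  ys <- rev(seq_len(k))
  op <- graphics::par(mar = c(4, 10, 3, 2))
  on.exit(graphics::par(op))
  graphics::plot(df$estimate, ys, xlim = xlim, ylim = c(0.5, k + 0.5),
                 pch = 15, yaxt = "n", xlab = df$scale[1], ylab = "",
                 main = sprintf("%s -> %s", x$instrument, x$outcome))
  graphics::segments(df$ci_low, ys, df$ci_high, ys)
  graphics::abline(v = null_at, lty = 2, col = "grey40")
  graphics::axis(2, at = ys, labels = df$model_label, las = 1, cex.axis = 0.8)
  invisible(x)
}
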