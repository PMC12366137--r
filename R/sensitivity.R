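# Sensitivity analyses: leave-one-out, extended adjustment, complete-case

# fit one model spec on an already complete-case sample, standardising the
# given raw score over that sample
.fit_spec_on <- function(cc, spec, raw) {
  z <- standardize_score(raw)
  covs <- if (length(spec$covariates)) cc[, spec$covariates, drop = FALSE]
  y <- cc[[.outcome_column(spec)]]
  if (spec$outcome == "hypertension") fit_logistic(y, z, covs, spec$label)
  else fit_linear(y, z, covs, spec$label)
}

#' Leave-one-variant-out analysis of the weighted allele score
#'
#' Recomputes the allele score with each variant removed in turn,
#' re-standardises it over the same fixed analysis sample, and refits the
#' main model, to surface influential outliers such as a variant acting on
#' blood pressure through a pathway other than Alzheimer's liability
#' (horizontal pleiotropy).  Each row reports the shift from the
#' full-panel estimate in units of the full-panel standard error
#' (`delta_se_units`); rows with `|delta| >` `influence_threshold` are
#' flagged influential.
#'
#' @param data Analysis data.frame (after eligibility filtering) whose
#'   `id` column matches `rownames(dosages)`; must contain the outcome and
#'   covariate columns of `spec`.
#' @param dosages Dosage matrix (participants x variants).
#' @param weights Harmonised weight table.
#' @param spec A [model_spec()] for the main PGIS model.
#' @param influence_threshold Influence flag cutoff in SE units
#'   (default 2, a repository convention — no published numeric criterion
#'   for "influential" exists).
#' @return An `adbp_loo` data.frame: `variant_id` (`"(full score)"` first),
#'   `estimate`, `se`, `ci_low`, `ci_high`, `n`, `delta_se_units`,
#'   `influential`.
#' @export
leave_one_out <- function(data, dosages, weights, spec,
                          influence_threshold = 2) {
  if (nrow(weights) < 2)
    stop("leave-one-out needs at least 2 variants", call. = FALSE)
  dos <- dosages[match(data$id, rownames(dosages)), weights$variant_id,
                 drop = FALSE]
  full <- compute_pgis(dos, weights)
  data$pgis_raw <- full$raw
  keep <- full$valid
  need <- unique(c("pgis_raw", spec$covariates, .outcome_column(spec)))
  cc <- complete_case(data[keep, , drop = FALSE], need)
  dos_cc <- dos[match(cc$id, rownames(dos)), , drop = FALSE]

  ref <- .fit_spec_on(cc, spec, cc$pgis_raw)
  rows <- vector("list", nrow(weights) + 1L)
  rows[[1]] <- data.frame(variant_id = "(full score)",
                          estimate = ref$estimate, se = ref$se,
                          ci_low = ref$ci_low, ci_high = ref$ci_high,
                          n = ref$n, delta_se_units = 0,
                          influential = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(weights))) {
    raw_j <- cc$pgis_raw - dos_cc[, j] * weights$beta[j]
    fit <- tryCatch(.fit_spec_on(cc, spec, raw_j), error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[j + 1L]] <- data.frame(variant_id = weights$variant_id[j],
                                   estimate = NA_real_, se = NA_real_,
                                   ci_low = NA_real_, ci_high = NA_real_,
                                   n = NA_integer_, delta_se_units = NA_real_,
                                   influential = NA, stringsAsFactors = FALSE)
      next
    }
    scale_ref <- if (spec$outcome == "hypertension") ref$beta else ref$estimate
    scale_fit <- if (spec$outcome == "hypertension") fit$beta else fit$estimate
    delta <- (scale_fit - scale_ref) / ref$se
    rows[[j + 1L]] <- data.frame(variant_id = weights$variant_id[j],
                                 estimate = fit$estimate, se = fit$se,
                                 ci_low = fit$ci_low, ci_high = fit$ci_high,
                                 n = fit$n, delta_se_units = delta,
                                 influential = abs(delta) > influence_threshold,
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("adbp_loo", class(out))
  attr(out, "spec") <- spec
  out
}

#' Forest-style plot of leave-one-out results
#'
#' @param x An `adbp_loo` data.frame from [leave_one_out()].
#' @param ... Unused.
#' @export
plot.adbp_loo <- function(x, ...) {
  df <- as.data.frame(x)
  k <- nrow(df)
  ys <- rev(seq_len(k))
  op <- graphics::par(mar = c(4, 9, 3, 2))
  on.exit(graphics::par(op))
  graphics::plot(df$estimate, ys, xlim = range(c(df$ci_low, df$ci_high),
                                               na.rm = TRUE),
                 ylim = c(0.5, k + 0.5), pch = 15, yaxt = "n",
                 xlab = "estimate per 1 SD", ylab = "",
                 main = "Leave-one-variant-out")
  graphics::segments(df$ci_low, ys, df$ci_high, ys)
  graphics::abline(v = df$estimate[1], lty = 2, col = "grey40")
  flagged <- which(isTRUE(df$influential) | df$influential %in% TRUE)
  if (length(flagged))
    graphics::points(df$estimate[flagged], ys[flagged], pch = 15, col = "red")
  graphics::axis(2, at = ys, labels = df$variant_id, las = 1, cex.axis = 0.6)
  invisible(x)
}

#' Extended confounder adjustment on a common restricted sample
#'
#' Refits the main parental-score model adding metabolic and inflammatory
#' covariates (HbA1c, total cholesterol, HDL and LDL cholesterol,
#' triglycerides, C-reactive protein).  Both the base and the extended
#' model are fitted on the complete-case sample for base *plus* extra
#' fields, so the pair is directly comparable: any difference reflects
#' adjustment, not sample composition.
#'
#' @param data Analysis data.frame with score, outcome, covariate and
#'   biomarker columns.
#' @param base_spec [model_spec()] of the main model.
#' @param extra_fields Additional covariate columns (defaults to the six
#'   biomarkers above).
#' @return List with `base` and `extended` `adbp_assoc` results and the
#'   shared `n`.
#' @export
extended_adjustment <- function(data, base_spec,
                                extra_fields = c("hba1c", "chol_total", "hdl",
                                                 "ldl", "trig", "crp")) {
  sc <- .score_columns(base_spec$instrument)
  data <- data[data[[sc[["valid"]]]] %in% TRUE, , drop = FALSE]
  need <- unique(c(sc[["raw"]], base_spec$covariates, extra_fields,
                   .outcome_column(base_spec)))
  cc <- complete_case(data, need)
  raw <- cc[[sc[["raw"]]]]
  base <- .fit_spec_on(cc, base_spec, raw)
  ext_spec <- base_spec
  ext_spec$covariates <- c(base_spec$covariates, extra_fields)
  ext_spec$label <- paste(base_spec$label, "+ extended confounders")
  extended <- .fit_spec_on(cc, ext_spec, raw)
  list(base = base, extended = extended, n = nrow(cc))
}

#' Complete-case comparison: main sample versus a stricter sample
#'
#' Fits the main model on its own complete-case sample and again on the
#' stricter complete-case sample defined by `strict_fields` (a superset of
#' the main model's fields).  Divergence between the two estimates is
#' evidence of selection bias from informative missingness in the extra
#' fields.
#'
#' @param data Analysis data.frame.
#' @param spec [model_spec()] of the main model.
#' @param strict_fields Fields whose completeness defines the stricter
#'   sample; must contain the main model's fields.
#' @return List with `main` and `strict` `adbp_assoc` results and both
#'   sample sizes.
#' @export
complete_case_comparison <- function(data, spec, strict_fields) {
  sc <- .score_columns(spec$instrument)
  main_fields <- unique(c(sc[["raw"]], spec$covariates, .outcome_column(spec)))
  if (!all(spec$covariates %in% strict_fields))
    stop("strict_fields must contain the main model's covariates", call. = FALSE)
  strict_all <- unique(c(main_fields, strict_fields))
  data <- data[data[[sc[["valid"]]]] %in% TRUE, , drop = FALSE]
  cc_main <- complete_case(data, main_fields)
  cc_strict <- complete_case(data, strict_all)
  main <- .fit_spec_on(cc_main, spec, cc_main[[sc[["raw"]]]])
  strict_spec <- spec
  strict_spec$label <- paste(spec$label, "(strict complete case)")
  strict <- .fit_spec_on(cc_strict, strict_spec, cc_strict[[sc[["raw"]]]])
  list(main = main, strict = strict,
       n_main = nrow(cc_main), n_strict = nrow(cc_strict))
}
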