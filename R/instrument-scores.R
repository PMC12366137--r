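# Instrumental variables: parental dementia score and weighted allele score

#' Age-weighted contribution of one parent to the parental dementia score
#'
#' A parent diagnosed with dementia contributes one full unit.  A parent
#' without a dementia diagnosis contributes a weight inversely proportional
#' to their attained age (current age if alive, age at death otherwise),
#' `(100 - age)/100`, reflecting confidence that they will not develop
#' dementia: age 100 is about the 95th percentile of life expectancy, so a
#' non-demented centenarian contributes 0, and ages above 100 are clamped
#' to 0.  Because dementia incidence is very low below age 68, all
#' non-demented parents aged 68 or younger contribute the same capped
#' weight, `(100 - 68)/100 = 0.32`.
#'
#' @param dementia_reported Integer/logical vector; 1 if the parent has a
#'   reported dementia diagnosis, `NA` if unknown.
#' @param age_years Parent's current age or age at death, years.  Ignored
#'   for demented parents; required for non-demented parents.
#' @return Numeric vector of weights in `[0, 1]`; `NA` where the weight is
#'   undefined (unknown dementia status, or missing age for a non-demented
#'   parent).
#' @export
#' @examples
#' parental_weight(c(1, 0, 0, 0), c(NA, 100, 68, 80))  # 1, 0, 0.32, 0.20
parental_weight <- function(dementia_reported, age_years) {
  dem <- as.integer(dementia_reported)
  age <- as.numeric(age_years)
  if (length(age) == 1L) age <- rep(age, length(dem))
  if (length(dem) != length(age))
    stop("'dementia_reported' and 'age_years' lengths differ", call. = FALSE)
  if (any(!is.na(age) & (age <= 0 | age >= 120)))
    stop("'age_years' must lie in (0, 120)", call. = FALSE)
  eff_age <- pmax(pmin(age, 100), 68)
  w <- ifelse(is.na(dem), NA_real_,
              ifelse(dem == 1L, 1,
                     ifelse(is.na(age), NA_real_, (100 - eff_age) / 100)))
  w
}

#' Parental dementia instrument score (PDIS)
#'
#' Sums the [parental_weight()] of both parents (biological or adoptive),
#' giving a raw score in `[0, 2]`.  The score is valid only when both
#' parental weights are defined; participants with any missing or unknown
#' parental field are flagged invalid and excluded from PDIS analyses.
#'
#' @param mother_dementia,mother_age,father_dementia,father_age Vectors of
#'   parental dementia reports (1/0/`NA`) and attained ages.
#' @return A data.frame with columns `raw` (numeric, `NA` when invalid) and
#'   `valid` (logical).
#' @export
#' @examples
#' compute_pdis(1, NA, 0, 90)  # raw 1.10
compute_pdis <- function(mother_dementia, mother_age,
                         father_dementia, father_age) {
  wm <- parental_weight(mother_dementia, mother_age)
  wf <- parental_weight(father_dementia, father_age)
  raw <- wm + wf
  data.frame(raw = raw, valid = !is.na(raw))
}

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonise GWAS weights onto a genotype panel's dosage orientation
#'
#' Aligns each external GWAS weight with the allele the dosage matrix
#' counts.  If the GWAS effect allele is the panel's counted allele the
#' weight is kept; if the alleles are swapped the effect size changes sign
#' and the effect-allele frequency becomes its complement; if neither
#' orientation matches the variant is dropped.  Palindromic (A/T or C/G)
#' variants are dropped when their frequency is uninformative about strand
#' (within `palindromic_tol` of 0.5 in either the GWAS or the sample).
#' A per-variant report comparing GWAS and sample effect-allele frequencies
#' is attached for the harmonisation check.
#'
#' @param weights data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `eaf` (GWAS effect-allele frequency).
#' @param panel_alleles data.frame with columns `variant_id`, `allele_a`
#'   (the allele the dosage counts), `allele_b`, `eaf` (sample frequency of
#'   `allele_a`).  Every weight's variant must appear here.
#' @param palindromic_tol Half-width around 0.5 inside which a palindromic
#'   variant's frequency is considered ambiguous (default 0.08, standard
#'   harmonisation practice).
#' @return data.frame of harmonised weights (possibly fewer rows), with the
#'   report as attribute `"report"`: columns `variant_id`, `action` in
#'   `kept`/`flipped`/`dropped_mismatch`/`dropped_palindromic`, `gwas_eaf`,
#'   `sample_eaf`.
#' @export
harmonize_weights <- function(weights, panel_alleles, palindromic_tol = 0.08) {
  stopifnot(is.data.frame(weights), is.data.frame(panel_alleles))
  miss <- setdiff(weights$variant_id, panel_alleles$variant_id)
  if (length(miss))
    stop("variants missing from panel: ", paste(miss, collapse = ", "),
         call. = FALSE)
  idx <- match(weights$variant_id, panel_alleles$variant_id)
  pa <- panel_alleles$allele_a[idx]
  pb <- panel_alleles$allele_b[idx]
  sample_eaf <- panel_alleles$eaf[idx]

  aligned <- weights$effect_allele == pa & weights$other_allele == pb
  swapped <- weights$effect_allele == pb & weights$other_allele == pa
  pal <- .is_palindromic(weights$effect_allele, weights$other_allele)
  ambiguous <- pal & (abs(weights$eaf - 0.5) < palindromic_tol |
                        abs(sample_eaf - 0.5) < palindromic_tol)

  action <- rep("dropped_mismatch", nrow(weights))
  action[aligned] <- "kept"
  action[swapped] <- "flipped"
  # a palindromic variant matches under both strand readings, so only an
  # unambiguous frequency can resolve its orientation
  action[(aligned | swapped) & ambiguous] <- "dropped_palindromic"

  report <- data.frame(variant_id = weights$variant_id, action = action,
                       gwas_eaf = weights$eaf, sample_eaf = sample_eaf,
                       stringsAsFactors = FALSE)

  out <- weights
  fl <- action == "flipped"
  # express the weight on the panel's counted allele
  out$effect_allele[fl] <- pa[fl]
  out$other_allele[fl] <- pb[fl]
  out$beta[fl] <- -out$beta[fl]
  out$eaf[fl] <- 1 - out$eaf[fl]
  out <- out[action %in% c("kept", "flipped"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

#' Weighted allele score (PGIS)
#'
#' Multiplies each participant's effect-allele dosage by the variant's
#' (harmonised) GWAS weight and sums across variants.  By default a
#' participant with any missing dosage gets an invalid score; optionally
#' missing dosages are imputed with the expected dosage `2 * eaf`.
#'
#' @param dosages Numeric matrix (participants x variants) of effect-allele
#'   dosages in `[0, 2]`; columns named by `variant_id` or given in the
#'   order of `weights`.
#' @param weights Harmonised weight table (see [harmonize_weights()]).
#' @param impute_missing If `TRUE`, replace missing dosages with
#'   `2 * eaf`; default `FALSE`.
#' @return data.frame with columns `raw` and `valid`.
#' @export
compute_pgis <- function(dosages, weights, impute_missing = FALSE) {
  if (is.null(dim(dosages))) dosages <- matrix(dosages, nrow = 1)
  if (!is.null(colnames(dosages))) {
    if (!identical(colnames(dosages), weights$variant_id)) {
      miss <- setdiff(weights$variant_id, colnames(dosages))
      if (length(miss))
        stop("dosage matrix lacks variants: ", paste(miss, collapse = ", "),
             call. = FALSE)
      dosages <- dosages[, weights$variant_id, drop = FALSE]
    }
  } else if (ncol(dosages) != nrow(weights)) {
    stop("dosage matrix has ", ncol(dosages), " columns but ", nrow(weights),
         " weights were supplied", call. = FALSE)
  }
  any_na <- rowSums(is.na(dosages)) > 0
  if (impute_missing && any(any_na)) {
    for (jj in which(colSums(is.na(dosages)) > 0)) {
      nas <- is.na(dosages[, jj])
      dosages[nas, jj] <- 2 * weights$eaf[jj]
    }
    raw <- as.vector(dosages %*% weights$beta)
    valid <- rep(TRUE, length(raw))
  } else {
    raw <- as.vector(dosages %*% weights$beta)
    valid <- !any_na
    raw[!valid] <- NA_real_
  }
  data.frame(raw = raw, valid = valid)
}

#' Standardise an instrument score over an analysis sample
#'
#' Converts raw scores to z-units using the mean and SD of the valid scores
#' inside the analysis mask, so reported effects are "per 1 SD higher
#' score" on the same sample that contributes to the model.
#'
#' @param raw Numeric vector of raw scores (`NA` where invalid).
#' @param mask Logical vector flagging the analysis sample (default: all).
#' @return Numeric vector of standardized scores (`NA` outside the valid
#'   mask), with attributes `"center"` and `"scale"`.
#' @export
standardize_score <- function(raw, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(raw))
  mask <- mask & !is.na(raw)
  if (sum(mask) < 2)
    stop("need at least 2 valid scores to standardise", call. = FALSE)
  mu <- mean(raw[mask])
  sdv <- stats::sd(raw[mask])
  if (!is.finite(sdv) || sdv == 0)
    stop("degenerate instrument: score SD is zero over the analysis sample",
         call. = FALSE)
  z <- (raw - mu) / sdv
  z[!mask] <- NA_real_
  attr(z, "center") <- mu
  attr(z, "scale") <- sdv
  z
}

#' Instrument relevance: association with diagnosed all-cause dementia
#'
#' The latent exposure (pre-clinical Alzheimer's disease) cannot be
#' measured, so instrument strength cannot be computed directly.  As a
#' relevance check, each standardized instrument is regressed on the
#' participant's own diagnosed all-cause dementia (before the reverse-
#' causality exclusions): a relevant instrument should carry a higher odds
#' of diagnosed dementia.
#'
#' @param score_z Standardized instrument score.
#' @param dementia_dx 0/1 indicator of diagnosed all-cause dementia.
#' @param covariates Optional data.frame of covariates.
#' @return An `adbp_assoc` object on the odds-ratio scale (see
#'   [fit_logistic()]).
#' @export
instrument_relevance <- function(score_z, dementia_dx, covariates = NULL) {
  keep <- !is.na(score_z) & !is.na(dementia_dx)
  fit_logistic(dementia_dx[keep], score_z[keep],
               covariates = if (!is.null(covariates)) covariates[keep, , drop = FALSE],
               label = "instrument relevance")
}
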