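# Simulation configuration -----------------------------------------------

#' Synthetic Alzheimer's-risk variant panel
#'
#' Builds a deterministic panel of biallelic variants standing in for the
#' genome-wide-significant Alzheimer's disease SNPs that make up the weighted
#' allele score (PGIS).  Effect sizes are log odds ratios on Alzheimer's
#' disease with a GWAS-like decay in magnitude; allele pairs are chosen
#' non-palindromic so the default panel never triggers the ambiguity drop in
#' [harmonize_weights()].  The panel is a pure function of `n_variants` —
#' no randomness — so cohorts simulated under different seeds share it.
#'
#' @param n_variants Number of variants in the panel (default 32, the size
#'   of the published score).
#' @return A data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta` (log OR per effect allele), `eaf` (effect-allele
#'   frequency) and `p`.
#' @export
#' @examples
#' head(synthetic_snp_panel())
synthetic_snp_panel <- function(n_variants = 32L) {
  stopifnot(is.numeric(n_variants), n_variants >= 1)
  n_variants <- as.integer(n_variants)
  j <- seq_len(n_variants)
  pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2, byrow = TRUE)
  idx <- ((j - 1L) %% 4L) + 1L
  # magnitudes decay like a ranked GWAS hit list; every 5th effect is
  # protective so both weight signs are exercised downstream
  beta <- round(0.28 * exp(-(j - 1) / 14) + 0.03, 4)
  beta <- ifelse(j %% 5L == 0L, -beta, beta)
  eaf <- round(seq(0.10, 0.90, length.out = n_variants), 4)
  data.frame(
    variant_id = sprintf("rs%07d", 1000003L + 37L * j),
    effect_allele = pairs[idx, 1],
    other_allele = pairs[idx, 2],
    beta = beta,
    eaf = eaf,
    p = signif(5e-8 / j, 3),
    stringsAsFactors = FALSE
  )
}

# numeric confounders that may carry simulated confounding effects,
# with the marginal mean/sd used to put effects on a per-SD scale
.conf_scale <- list(
  townsend = c(mean = -1.3, sd = 3.0),
  bmi      = c(mean = 27.4, sd = 4.8),
  activity = c(mean = 30.0, sd = 15.0)
)

.chk_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop("configuration error: '", field, "' must be a probability in [0, 1]",
         call. = FALSE)
  x
}

.chk_num <- function(x, field, n = 1) {
  if (!is.numeric(x) || length(x) != n || anyNA(x))
    stop("configuration error: '", field, "' must be numeric of length ", n,
         call. = FALSE)
  x
}

#' Simulation configuration for the two-generation synthetic cohort
#'
#' Collects and validates every free parameter of [simulate_cohort()].  The
#' defaults describe the bias-free ("clean") study condition: a mid-life
#' cohort aged 40-69 with two parents each, Mendelian transmission of the
#' panel alleles, a liability-threshold pre-clinical Alzheimer's exposure
#' raising systolic blood pressure by `beta_sbp` mmHg, and no confounding,
#' pleiotropy or differential parental survival.  Bias mechanisms are
#' switched on through `confounder_effects`, `pleiotropy` and
#' `survival_bp_hazard` (see [scenario_library()]).
#'
#' @param n_participants Cohort size (>= 1).
#' @param seed Integer seed; fully determines the cohort.
#' @param snp_panel Variant weight table as from [synthetic_snp_panel()].
#' @param liability_h2 Share of pre-clinical AD liability variance carried by
#'   the weighted allele score, in `[0, 1]`.
#' @param familial_env_sd SD of the shared parent-offspring environmental
#'   liability component (enters parental dementia log-odds and offspring
#'   liability with unit coefficient).
#' @param beta_sbp,beta_dbp Causal effect of pre-clinical AD on systolic /
#'   diastolic blood pressure, mmHg.
#' @param confounder_effects Named list mapping a numeric confounder
#'   (`townsend`, `bmi`, `activity`) to `c(dementia_logodds, bp_mmHg)`:
#'   the per-SD effect on parental dementia log-odds and on offspring BP.
#'   Non-empty values open a confounding path between the parental score
#'   and blood pressure.
#' @param pleiotropy Named numeric vector mapping `variant_id` to a direct
#'   mmHg effect on SBP per effect allele (horizontal pleiotropy).
#' @param survival_bp_hazard Log-hazard of parental death per mmHg of the
#'   parent's blood pressure above 140; positive values make high-BP parents
#'   die younger (survivor bias).
#' @param dementia_age_curve `c(baseline, slope)`: parental dementia
#'   log-odds at or below age 68, and the per-year log-odds increase above
#'   68.
#' @param med_threshold,med_prob Underlying SBP above which antihypertensive
#'   use is assigned with probability `med_prob`.
#' @param preclinical_prevalence Target prevalence of the pre-clinical AD
#'   indicator (sets the liability threshold).
#' @param parent_genetic_logodds Parental dementia log-odds per SD of the
#'   parent's own weighted allele score.
#' @param bp_age_slope,dbp_age_slope mmHg of SBP / DBP per year of
#'   participant age (0 in the clean condition, so crude and age-adjusted
#'   models coincide by construction).
#' @param sbp_sex_effect,dbp_sex_effect mmHg added for male participants.
#' @param person_bp_sd SD of the person-level (heritable) BP component.
#' @param reading_sd Measurement SD of a single BP reading, mmHg.
#' @param sbp_mean,dbp_mean Population baseline means, mmHg.
#' @param med_sbp_reduction,med_dbp_reduction mmHg by which treatment lowers
#'   measured SBP / DBP; the analysis-side medication correction adds the
#'   conventional +15/+10 back, so with the defaults corrected BP recovers
#'   the untreated value exactly.
#' @param missing_rates Named list of completely-at-random missingness rates:
#'   `default` (confounders), `education`, `parent` (per parental field),
#'   `reading` (per BP reading), `biomarker` (extended-adjustment fields),
#'   `dosage` (per genotype call).
#' @param prevalent_rate,withdrawn_rate,qc_fail_rate,european_prob Rates for
#'   the eligibility flags so every downstream filter has work to do.
#' @param n_pcs Number of (noise) genetic principal components to emit.
#' @return An object of class `adbp_sim_config` (a validated list).
#' @seealso [simulate_cohort()], [scenario_library()]
#' @export
sim_config <- function(n_participants = 10000L,
                       seed = 1L,
                       snp_panel = synthetic_snp_panel(),
                       liability_h2 = 0.45,
                       familial_env_sd = 0.7,
                       beta_sbp = 1.5,
                       beta_dbp = 0,
                       confounder_effects = list(),
                       pleiotropy = numeric(0),
                       survival_bp_hazard = 0,
                       dementia_age_curve = c(baseline = -3.4, slope = 0.07),
                       med_threshold = 140,
                       med_prob = 0.6,
                       preclinical_prevalence = 0.10,
                       parent_genetic_logodds = 1.8,
                       bp_age_slope = 0,
                       dbp_age_slope = 0,
                       sbp_sex_effect = 4,
                       dbp_sex_effect = 2,
                       person_bp_sd = 8,
                       reading_sd = 4,
                       sbp_mean = 125,
                       dbp_mean = 78,
                       med_sbp_reduction = 15,
                       med_dbp_reduction = 10,
                       missing_rates = list(default = 0.005, education = 0.015,
                                            parent = 0.02, reading = 0.01,
                                            biomarker = 0.04, dosage = 5e-4),
                       prevalent_rate = 0.002,
                       withdrawn_rate = 0.002,
                       qc_fail_rate = 0.03,
                       european_prob = 0.95,
                       n_pcs = 4L) {
  if (!is.numeric(n_participants) || length(n_participants) != 1 ||
      is.na(n_participants) || n_participants < 1)
    stop("configuration error: 'n_participants' must be >= 1", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("configuration error: 'seed' must be a single integer", call. = FALSE)
  stopifnot(is.data.frame(snp_panel))
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "eaf")
  if (!all(need %in% names(snp_panel)))
    stop("configuration error: 'snp_panel' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(snp_panel$eaf <= 0 | snp_panel$eaf >= 1))
    stop("configuration error: 'snp_panel' allele frequencies must lie in (0, 1)",
         call. = FALSE)
  if (anyDuplicated(snp_panel$variant_id))
    stop("configuration error: 'snp_panel' variant ids must be unique",
         call. = FALSE)
  .chk_prob(liability_h2, "liability_h2")
  .chk_num(familial_env_sd, "familial_env_sd")
  if (familial_env_sd < 0)
    stop("configuration error: 'familial_env_sd' must be nonnegative", call. = FALSE)
  if (liability_h2 + familial_env_sd^2 > 0.95)
    stop("configuration error: 'liability_h2' + 'familial_env_sd'^2 must be <= 0.95 ",
         "to leave room for individual liability noise", call. = FALSE)
  .chk_num(beta_sbp, "beta_sbp"); .chk_num(beta_dbp, "beta_dbp")
  if (length(confounder_effects)) {
    bad <- setdiff(names(confounder_effects), names(.conf_scale))
    if (is.null(names(confounder_effects)) || length(bad))
      stop("configuration error: 'confounder_effects' names must be among ",
           paste(names(.conf_scale), collapse = ", "), call. = FALSE)
    for (nm in names(confounder_effects))
      .chk_num(confounder_effects[[nm]], paste0("confounder_effects$", nm), 2)
  }
  if (length(pleiotropy)) {
    if (is.null(names(pleiotropy)) ||
        !all(names(pleiotropy) %in% snp_panel$variant_id))
      stop("configuration error: 'pleiotropy' must be named by panel variant ids",
         call. = FALSE)
    .chk_num(unname(pleiotropy), "pleiotropy", length(pleiotropy))
  }
  .chk_num(survival_bp_hazard, "survival_bp_hazard")
  .chk_num(dementia_age_curve, "dementia_age_curve", 2)
  .chk_num(med_threshold, "med_threshold")
  .chk_prob(med_prob, "med_prob")
  .chk_prob(preclinical_prevalence, "preclinical_prevalence")
  if (preclinical_prevalence <= 0 || preclinical_prevalence >= 1)
    stop("configuration error: 'preclinical_prevalence' must be in (0, 1)",
         call. = FALSE)
  .chk_prob(european_prob, "european_prob")
  .chk_prob(qc_fail_rate, "qc_fail_rate")
  .chk_prob(prevalent_rate, "prevalent_rate")
  .chk_prob(withdrawn_rate, "withdrawn_rate")
  for (nm in names(missing_rates)) .chk_prob(missing_rates[[nm]], paste0("missing_rates$", nm))
  for (nm in c("default", "education", "parent", "reading", "biomarker", "dosage"))
    if (is.null(missing_rates[[nm]]))
      stop("configuration error: 'missing_rates$", nm, "' is required", call. = FALSE)
  stopifnot(person_bp_sd >= 0, reading_sd >= 0, n_pcs >= 1)

  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    snp_panel = snp_panel, liability_h2 = liability_h2,
    familial_env_sd = familial_env_sd, beta_sbp = beta_sbp, beta_dbp = beta_dbp,
    confounder_effects = confounder_effects, pleiotropy = pleiotropy,
    survival_bp_hazard = survival_bp_hazard,
    dementia_age_curve = unname(dementia_age_curve),
    med_threshold = med_threshold, med_prob = med_prob,
    preclinical_prevalence = preclinical_prevalence,
    parent_genetic_logodds = parent_genetic_logodds,
    bp_age_slope = bp_age_slope, dbp_age_slope = dbp_age_slope,
    sbp_sex_effect = sbp_sex_effect, dbp_sex_effect = dbp_sex_effect,
    person_bp_sd = person_bp_sd, reading_sd = reading_sd,
    sbp_mean = sbp_mean, dbp_mean = dbp_mean,
    med_sbp_reduction = med_sbp_reduction, med_dbp_reduction = med_dbp_reduction,
    missing_rates = missing_rates, prevalent_rate = prevalent_rate,
    withdrawn_rate = withdrawn_rate, qc_fail_rate = qc_fail_rate,
    european_prob = european_prob, n_pcs = as.integer(n_pcs)
  )
  class(cfg) <- "adbp_sim_config"
  cfg
}

#' @export
print.adbp_sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  participants:", x$n_participants, " seed:", x$seed,
      " variants:", nrow(x$snp_panel), "\n")
  cat("  causal effects: SBP", x$beta_sbp, "mmHg, DBP", x$beta_dbp, "mmHg;",
      "liability h2:", x$liability_h2, "\n")
  mech <- c(
    if (length(x$confounder_effects)) "confounding",
    if (length(x$pleiotropy)) "pleiotropy",
    if (x$survival_bp_hazard != 0) "survivor bias"
  )
  cat("  bias mechanisms:", if (length(mech)) paste(mech, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Library of named study conditions
#'
#' Pre-specified simulation scenarios encoding the bias structures the
#' two-instrument triangulation design is built to distinguish:
#' \describe{
#'   \item{clean}{No confounding, no pleiotropy, no differential parental
#'     survival, no age/sex trend in BP: both instruments are valid and
#'     every model rung targets the same estimand.}
#'   \item{confounded}{Shared (familial) deprivation and adiposity raise
#'     parental dementia odds and offspring BP, opening a confounding path
#'     for the parental score that full adjustment closes.}
#'   \item{survivor}{Parental death hazard rises with parental BP and
#'     participant BP rises with age; together with the age weighting of
#'     the parental score this reproduces the crude-negative /
#'     age-adjusted-positive sign flip.}
#'   \item{pleiotropic}{One panel variant has a direct effect on SBP not
#'     mediated by pre-clinical AD, the key bias threat to the allele
#'     score; leave-one-out analysis should isolate it.}
#' }
#'
#' @param n_participants,seed Passed to every scenario's [sim_config()].
#' @return Named list of `adbp_sim_config` objects.
#' @export
#' @examples
#' names(scenario_library(1000, seed = 1))
scenario_library <- function(n_participants = 10000L, seed = 1L) {
  panel <- synthetic_snp_panel()
  planted <- panel$variant_id[16]  # mid-frequency variant, decent weight
  list(
    clean = sim_config(n_participants, seed),
    confounded = sim_config(
      n_participants, seed,
      confounder_effects = list(townsend = c(0.25, 1.5), bmi = c(0.20, 1.0))
    ),
    survivor = sim_config(
      n_participants, seed,
      survival_bp_hazard = 0.002, bp_age_slope = 0.7, dbp_age_slope = 0.35
    ),
    pleiotropic = sim_config(
      n_participants, seed,
      pleiotropy = stats::setNames(1.5, planted)
    )
  )
}
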