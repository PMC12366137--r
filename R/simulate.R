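# Two-generation synthetic cohort generator ------------------------------

# standardized genetic score implied by the panel under Hardy-Weinberg
.score_scale <- function(panel) {
  mu <- sum(panel$beta * 2 * panel$eaf)
  v <- sum(panel$beta^2 * 2 * panel$eaf * (1 - panel$eaf))
  list(mean = mu, sd = sqrt(v))
}

.z_conf <- function(values, field) {
  sc <- .conf_scale[[field]]
  (values - sc[["mean"]]) / sc[["sd"]]
}

.punch_na <- function(x, rate) {
  if (rate <= 0) return(x)
  x[stats::runif(length(x)) < rate] <- NA
  x
}

#' Simulate a two-generation cohort with known ground truth
#'
#' Generates a mid-life cohort (ages 40-69) together with both simulated
#' parents, under the causal structure the instrumental-variable analysis
#' assumes plus whichever bias mechanisms the configuration switches on:
#'
#' * parental genotypes are Hardy-Weinberg at the panel allele frequencies
#'   and each offspring dosage is the sum of one allele transmitted from
#'   each parent (Mendelian transmission);
#' * parental dementia is Bernoulli with log-odds = age curve + the
#'   parent's own standardized allele score + shared familial environment
#'   + any configured confounder effects;
#' * parental age at death depends on parental blood pressure through
#'   `survival_bp_hazard`, so under survivor bias high-BP parents are
#'   observed younger and with less opportunity for a dementia diagnosis;
#' * offspring pre-clinical AD follows a liability threshold mixing the
#'   allele score (share `liability_h2`), the familial environment and
#'   individual noise, calibrated to `preclinical_prevalence`;
#' * two SBP and two DBP readings per visit equal an age/sex/confounder
#'   baseline + `beta_sbp`/`beta_dbp` times the pre-clinical indicator +
#'   any direct (pleiotropic) variant effects + a heritable person-level
#'   component + reading noise; antihypertensive treatment is assigned
#'   above `med_threshold` and lowers measured BP by the treatment effect
#'   that the downstream +15/+10 correction is designed to undo;
#' * eligibility flags (withdrawal, prevalent and early-incident dementia,
#'   genotyping QC failure, ancestry group) and completely-at-random
#'   missingness give every downstream filter work to do.
#'
#' @param config An [sim_config()] object.
#' @return An object of class `adbp_cohort`: a list with elements
#'   `cohort` (participant-level data.frame, parental fields as paired
#'   columns), `dosages` (participants x variants matrix of 0/1/2),
#'   `truth` (ground-truth list: `beta_sbp`, `beta_dbp`,
#'   `preclinical_status`, `parental_liability`, plus the latent BP and
#'   familial components used by recovery tests) and `config`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(500, seed = 42))
#' table(sim$truth$preclinical_status)
simulate_cohort <- function(config) {
  if (!inherits(config, "adbp_sim_config"))
    stop("'config' must be created by sim_config()", call. = FALSE)
  withr::with_seed(config$seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_participants
  panel <- cfg$snp_panel
  k <- nrow(panel)
  eafs <- rep(panel$eaf, each = n)

  age <- stats::runif(n, 40, 69)
  sex <- factor(c("male", "female")[(stats::runif(n) < 0.54) + 1L],
                levels = c("female", "male"))

  education <- factor(sample(c("none", "secondary", "vocational", "degree"),
                             n, TRUE, prob = c(0.20, 0.45, 0.20, 0.15)),
                      levels = c("none", "secondary", "vocational", "degree"))
  ethnic_group <- factor(c("Other", "European")[(stats::runif(n) < cfg$european_prob) + 1L],
                         levels = c("European", "Other"))
  smoking <- factor(sample(c("never", "former", "current"), n, TRUE,
                           prob = c(0.55, 0.33, 0.12)),
                    levels = c("never", "former", "current"))
  salt <- factor(sample(c("never_rarely", "sometimes", "usually", "always"),
                        n, TRUE, prob = c(0.55, 0.28, 0.12, 0.05)),
                 levels = c("never_rarely", "sometimes", "usually", "always"))
  alcohol <- factor(sample(c("never", "occasional", "weekly", "daily"),
                           n, TRUE, prob = c(0.12, 0.25, 0.43, 0.20)),
                    levels = c("never", "occasional", "weekly", "daily"))
  activity <- pmax(0, stats::rnorm(n, 30, 15))
  townsend <- stats::rnorm(n, -1.3, 3)
  bmi <- pmax(15, stats::rnorm(n, 27.4, 4.8))
  conf <- list(townsend = townsend, bmi = bmi, activity = activity)

  # --- genotypes: Hardy-Weinberg parents, Mendelian transmission ---------
  hwe_genotype <- function() {
    # one uniform per genotype via the binomial(2, f) quantile:
    # P(g >= 1) = 1 - (1-f)^2, P(g = 2) = f^2
    u <- stats::runif(n * k)
    g <- (u > (1 - eafs)^2) + (u > 1 - eafs^2)
    dim(g) <- c(n, k)
    storage.mode(g) <- "integer"
    g
  }
  g_mother <- hwe_genotype()
  g_father <- hwe_genotype()
  transmit <- function(g) {
    h <- stats::runif(n * k) < as.vector(g) / 2  # pick one of two alleles
    dim(h) <- c(n, k)
    h
  }
  dosages <- transmit(g_mother) + transmit(g_father)
  colnames(dosages) <- panel$variant_id

  sc <- .score_scale(panel)
  gz_o <- (as.vector(dosages %*% panel$beta) - sc$mean) / sc$sd
  gz_m <- (as.vector(g_mother %*% panel$beta) - sc$mean) / sc$sd
  gz_f <- (as.vector(g_father %*% panel$beta) - sc$mean) / sc$sd

  fam_env <- stats::rnorm(n, 0, cfg$familial_env_sd)

  # --- parental survival and attained age --------------------------------
  u_mother <- stats::rnorm(n, 0, cfg$person_bp_sd)
  u_father <- stats::rnorm(n, 0, cfg$person_bp_sd)
  parent_bp <- function(u) cfg$sbp_mean + 12 + u  # parents are a generation older
  natural_age <- function() pmin(pmax(age + stats::rnorm(n, 28, 4), age + 16), 105)
  age_at_death <- function(u) {
    t0 <- stats::rnorm(n, 82, 9)
    40 + pmax(t0 - 40, 1) * exp(-cfg$survival_bp_hazard * (parent_bp(u) - 140))
  }
  obs_parent <- function(u) {
    nat <- natural_age()
    death <- age_at_death(u)
    pmin(nat, death)
  }
  page_m <- obs_parent(u_mother)
  page_f <- obs_parent(u_father)

  # --- parental dementia -------------------------------------------------
  conf_dem <- rep(0, n)
  for (nm in names(cfg$confounder_effects))
    conf_dem <- conf_dem + cfg$confounder_effects[[nm]][1] * .z_conf(conf[[nm]], nm)
  dem_logit <- function(page, gz) {
    cfg$dementia_age_curve[1] + cfg$dementia_age_curve[2] * pmax(0, page - 68) +
      cfg$parent_genetic_logodds * gz + fam_env + conf_dem
  }
  dem_m <- stats::rbinom(n, 1L, stats::plogis(dem_logit(page_m, gz_m)))
  dem_f <- stats::rbinom(n, 1L, stats::plogis(dem_logit(page_f, gz_f)))

  # --- offspring pre-clinical AD (liability threshold) -------------------
  e_var <- max(0.05, 1 - cfg$liability_h2 - cfg$familial_env_sd^2)
  liab <- sqrt(cfg$liability_h2) * gz_o + fam_env + stats::rnorm(n, 0, sqrt(e_var))
  total_sd <- sqrt(cfg$liability_h2 + cfg$familial_env_sd^2 + e_var)
  thr <- stats::qnorm(1 - cfg$preclinical_prevalence, sd = total_sd)
  preclin <- as.integer(liab > thr)

  # --- blood pressure ----------------------------------------------------
  conf_bp <- rep(0, n)
  for (nm in names(cfg$confounder_effects))
    conf_bp <- conf_bp + cfg$confounder_effects[[nm]][2] * .z_conf(conf[[nm]], nm)
  pleio <- rep(0, n)
  if (length(cfg$pleiotropy)) {
    for (v in names(cfg$pleiotropy)) {
      f <- panel$eaf[panel$variant_id == v]
      pleio <- pleio + cfg$pleiotropy[[v]] * (dosages[, v] - 2 * f)
    }
  }
  u_o <- 0.5 * (u_mother + u_father) + stats::rnorm(n, 0, cfg$person_bp_sd * sqrt(0.5))
  sbp_true <- cfg$sbp_mean + cfg$bp_age_slope * (age - 55) +
    cfg$sbp_sex_effect * (sex == "male") + conf_bp +
    cfg$beta_sbp * preclin + pleio + u_o
  dbp_true <- cfg$dbp_mean + cfg$dbp_age_slope * (age - 55) +
    cfg$dbp_sex_effect * (sex == "male") + 0.5 * conf_bp +
    cfg$beta_dbp * preclin + 0.55 * u_o +
    stats::rnorm(n, 0, cfg$person_bp_sd * 0.5)

  on_med <- as.integer(sbp_true > cfg$med_threshold &
                         stats::runif(n) < cfg$med_prob)
  sbp_base <- sbp_true - cfg$med_sbp_reduction * on_med
  dbp_base <- dbp_true - cfg$med_dbp_reduction * on_med

  reading <- function(base) base + stats::rnorm(n, 0, cfg$reading_sd)
  mr <- cfg$missing_rates
  sbp_0a <- .punch_na(reading(sbp_base), mr$reading)
  sbp_0b <- .punch_na(reading(sbp_base), mr$reading)
  dbp_0a <- .punch_na(reading(dbp_base), mr$reading)
  dbp_0b <- .punch_na(reading(dbp_base), mr$reading)
  # a small slice loses the whole baseline visit, exercising the
  # subsequent-visit fallback
  lost0 <- stats::runif(n) < 0.003
  sbp_0a[lost0] <- sbp_0b[lost0] <- dbp_0a[lost0] <- dbp_0b[lost0] <- NA
  device_0 <- factor(c("manual", "automated")[(stats::runif(n) < 0.97) + 1L],
                     levels = c("automated", "manual"))
  has_v1 <- lost0 | stats::runif(n) < 0.02
  blank <- function(x) { x[!has_v1] <- NA; x }
  sbp_1a <- blank(reading(sbp_base)); sbp_1b <- blank(reading(sbp_base))
  dbp_1a <- blank(reading(dbp_base)); dbp_1b <- blank(reading(dbp_base))
  device_1 <- factor(c("manual", "automated")[(has_v1 & stats::runif(n) < 0.97) + 1L],
                     levels = c("automated", "manual"))

  high_bp <- sbp_true > 140 | dbp_true > 90 | on_med == 1L
  self_report_htn <- stats::rbinom(n, 1L, 0.02 + 0.43 * high_bp)

  # --- participant dementia diagnoses and eligibility flags --------------
  dx_p <- stats::plogis(-4.6 + 2.0 * preclin + 0.06 * (age - 55))
  dementia_dx <- stats::rbinom(n, 1L, dx_p)
  prevalent_dementia <- as.integer(dementia_dx == 1L &
                                     stats::runif(n) < cfg$prevalent_rate / 0.02)
  incident_dementia_years <- rep(NA_real_, n)
  inc <- dementia_dx == 1L & prevalent_dementia == 0L
  incident_dementia_years[inc] <- stats::runif(sum(inc), 0.5, 15)
  withdrawn <- stats::rbinom(n, 1L, cfg$withdrawn_rate)
  qc_fail <- stats::rbinom(n, 1L, cfg$qc_fail_rate)

  pcs <- matrix(stats::rnorm(n * cfg$n_pcs), n, cfg$n_pcs,
                dimnames = list(NULL, paste0("pc", seq_len(cfg$n_pcs))))

  # --- extended-adjustment biomarkers (correlates of adiposity and BP) ---
  z_bmi <- .z_conf(bmi, "bmi")
  z_sbp <- (sbp_true - cfg$sbp_mean) / max(cfg$person_bp_sd, 1)
  hba1c <- 36 + 1.0 * z_bmi + 0.5 * z_sbp + stats::rnorm(n, 0, 5)
  chol_total <- 5.7 + 0.1 * z_bmi + stats::rnorm(n, 0, 1.1)
  hdl <- pmax(0.4, 1.45 - 0.15 * z_bmi + stats::rnorm(n, 0, 0.25))
  ldl <- pmax(0.5, 3.6 + 0.1 * z_bmi + stats::rnorm(n, 0, 0.8))
  trig <- pmax(0.2, 1.7 + 0.3 * z_bmi + stats::rnorm(n, 0, 0.7))
  crp <- exp(stats::rnorm(n, 0.3 + 0.15 * z_bmi, 0.9))

  cohort <- data.frame(
    id = sprintf("P%06d", seq_len(n)),
    age = age, sex = sex, education = education, ethnic_group = ethnic_group,
    smoking = smoking, salt = salt, alcohol = alcohol, activity = activity,
    townsend = townsend, bmi = bmi,
    mother_dementia = dem_m, mother_age = page_m,
    father_dementia = dem_f, father_age = page_f,
    sbp_0a = sbp_0a, sbp_0b = sbp_0b, dbp_0a = dbp_0a, dbp_0b = dbp_0b,
    device_0 = device_0,
    sbp_1a = sbp_1a, sbp_1b = sbp_1b, dbp_1a = dbp_1a, dbp_1b = dbp_1b,
    device_1 = device_1,
    bp_med = on_med, self_report_htn = self_report_htn,
    dementia_dx = dementia_dx, prevalent_dementia = prevalent_dementia,
    incident_dementia_years = incident_dementia_years,
    withdrawn = withdrawn, qc_fail = qc_fail,
    pcs,
    hba1c = hba1c, chol_total = chol_total, hdl = hdl, ldl = ldl,
    trig = trig, crp = crp,
    stringsAsFactors = FALSE
  )

  # --- completely-at-random missingness ----------------------------------
  for (fld in c("smoking", "salt", "alcohol", "activity", "townsend", "bmi"))
    cohort[[fld]] <- .punch_na(cohort[[fld]], mr$default)
  cohort$education <- .punch_na(cohort$education, mr$education)
  for (fld in c("mother_dementia", "mother_age", "father_dementia", "father_age"))
    cohort[[fld]] <- .punch_na(cohort[[fld]], mr$parent)
  for (fld in c("hba1c", "chol_total", "hdl", "ldl", "trig", "crp"))
    cohort[[fld]] <- .punch_na(cohort[[fld]], mr$biomarker)
  if (mr$dosage > 0)
    dosages[stats::runif(length(dosages)) < mr$dosage] <- NA_integer_
  rownames(dosages) <- cohort$id

  truth <- list(
    beta_sbp = cfg$beta_sbp, beta_dbp = cfg$beta_dbp,
    preclinical_status = preclin,
    parental_liability = cbind(mother = gz_m, father = gz_f),
    familial_env = fam_env, liability = liab,
    sbp_true = sbp_true, dbp_true = dbp_true, on_med = on_med,
    parent_genotypes = list(mother = g_mother, father = g_father)
  )

  structure(list(cohort = cohort, dosages = dosages, truth = truth,
                 config = cfg),
            class = "adbp_cohort")
}

#' @export
print.adbp_cohort <- function(x, ...) {
  cat("Synthetic two-generation cohort:", nrow(x$cohort), "participants,",
      ncol(x$dosages), "variants\n")
  cat("  pre-clinical AD prevalence:",
      round(mean(x$truth$preclinical_status), 3),
      " parental dementia (either):",
      round(mean(x$cohort$mother_dementia == 1 | x$cohort$father_dementia == 1,
                 na.rm = TRUE), 3), "\n")
  invisible(x)
}
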