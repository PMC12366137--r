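test_that("configuration validation names the offending field", {
  expect_error(sim_config(0), "n_participants")
  expect_error(sim_config(100, med_prob = 1.5), "med_prob")
  expect_error(sim_config(100, liability_h2 = -0.1), "liability_h2")
  expect_error(sim_config(100, liability_h2 = 0.6, familial_env_sd = 0.8),
               "familial_env_sd")
  bad_panel <- synthetic_snp_panel(4); bad_panel$eaf[2] <- 1.2
  expect_error(sim_config(100, snp_panel = bad_panel), "frequencies")
  expect_error(sim_config(100, pleiotropy = c(rsX = 1)), "pleiotropy")
  expect_error(sim_config(100, confounder_effects = list(age = c(1, 1))),
               "confounder_effects")
})

test_that("the same configuration and seed reproduce the cohort exactly", {
  cfg <- sim_config(2000, seed = 7)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$dosages, s2$dosages)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(sim_config(2000, seed = 8))
  expect_false(identical(s1$cohort, s3$cohort))
})

test_that("offspring dosages are 0/1/2 and Mendelian given parental genotypes", {
  panel <- synthetic_snp_panel(1)
  panel$eaf <- 0.4
  sim <- simulate_cohort(sim_config(12000, seed = 9, snp_panel = panel,
                                    missing_rates = list(default = 0, education = 0,
                                                         parent = 0, reading = 0,
                                                         biomarker = 0, dosage = 0)))
  d <- sim$dosages[, 1]
  expect_true(all(d %in% 0:2))
  gm <- sim$truth$parent_genotypes$mother[, 1]
  gf <- sim$truth$parent_genotypes$father[, 1]
  # enumeration oracle: offspring = Bern(gm/2) + Bern(gf/2)
  offspring_probs <- function(a, b) {
    pa <- a / 2; pb <- b / 2
    c((1 - pa) * (1 - pb), pa * (1 - pb) + (1 - pa) * pb, pa * pb)
  }
  chis <- c()
  for (a in 0:2) for (b in 0:2) {
    idx <- gm == a & gf == b
    if (sum(idx) < 50) next
    obs <- tabulate(d[idx] + 1L, 3)
    exp_p <- offspring_probs(a, b)
    keep <- exp_p > 0
    chi <- sum((obs[keep] - sum(obs) * exp_p[keep])^2 / (sum(obs) * exp_p[keep]))
    chis <- c(chis, stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE))
  }
  expect_true(all(chis > 0.001))  # goodness-of-fit not rejected at alpha = 0.001
})

test_that("mean offspring dosage matches the binomial oracle at frequency 0.5", {
  panel <- synthetic_snp_panel(1)
  panel$eaf <- 0.5
  sim <- simulate_cohort(sim_config(100000, seed = 10, snp_panel = panel))
  m <- mean(sim$dosages[, 1], na.rm = TRUE)
  se <- sqrt(2 * 0.5 * 0.5 / sum(!is.na(sim$dosages[, 1])))
  expect_lt(abs(m - 1.0), 3 * se)
})

test_that("with no causal effect the allele score is uncorrelated with corrected SBP", {
  cfg <- sim_config(50000, seed = 11, beta_sbp = 0, beta_dbp = 0)
  sim <- simulate_cohort(cfg)
  adat <- assemble_analysis(sim$cohort, sim$dosages, cfg$snp_panel)
  ok <- adat$pgis_valid & !is.na(adat$sbp_corrected)
  r <- cor(adat$pgis_raw[ok], adat$sbp_corrected[ok])
  expect_lt(abs(r), 3 / sqrt(sum(ok)))
})

test_that("the clean scenario plants the stated SBP effect", {
  cfg <- scenario_library(50000, seed = 12)$clean
  sim <- simulate_cohort(cfg)
  out <- derive_outcomes(sim$cohort)
  pre <- sim$truth$preclinical_status
  diff <- mean(out$sbp_corrected[pre == 1], na.rm = TRUE) -
    mean(out$sbp_corrected[pre == 0], na.rm = TRUE)
  expect_lt(abs(diff - cfg$beta_sbp), 0.55)  # ~4 MC standard errors
})

test_that("parental dementia prevalence rises with attained parental age", {
  sim <- simulate_cohort(sim_config(40000, seed = 13))
  ages <- c(sim$cohort$mother_age, sim$cohort$father_age)
  dem <- c(sim$cohort$mother_dementia, sim$cohort$father_dementia)
  ok <- !is.na(ages) & !is.na(dem)
  qs <- quantile(ages[ok], c(0.25, 0.5, 0.75))
  bin <- cut(ages[ok], c(-Inf, qs, Inf))
  prev <- tapply(dem[ok], bin, mean)
  expect_true(all(diff(prev) > 0))
})

test_that("the scenario library encodes the four designed bias structures", {
  lib <- scenario_library(1000, seed = 1)
  expect_true(all(c("clean", "confounded", "survivor", "pleiotropic") %in%
                    names(lib)))
  cl <- lib$clean
  expect_length(cl$confounder_effects, 0)
  expect_length(cl$pleiotropy, 0)
  expect_identical(cl$survival_bp_hazard, 0)
  expect_gt(length(lib$confounded$confounder_effects), 0)
  expect_gt(lib$survivor$survival_bp_hazard, 0)
  expect_length(lib$survivor$confounder_effects, 0)
  expect_equal(sum(lib$pleiotropic$pleiotropy != 0), 1)
})
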