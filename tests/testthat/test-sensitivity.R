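test_that("leave-one-out returns one row per variant plus the reference", {
  s <- sim_analysis("clean", 6000, seed = 340)
  gen <- genetic_analysis_sample(apply_dementia_exclusions(s$adat))
  w <- attr(s$adat, "weights")
  spec <- default_ladder("PGIS", "SBP")[[4]]
  loo <- leave_one_out(gen, s$sim$dosages, w, spec)
  expect_equal(nrow(loo), nrow(w) + 1)
  expect_equal(loo$variant_id[1], "(full score)")
  expect_setequal(loo$variant_id[-1], w$variant_id)
  expect_error(leave_one_out(gen, s$sim$dosages, w[1, , drop = FALSE], spec),
               "at least 2")
})

test_that("removing a zero-weight variant reproduces the full-panel estimate", {
  s <- sim_analysis("clean", 5000, seed = 341)
  w <- attr(s$adat, "weights")
  w$beta[3] <- 0
  gen <- genetic_analysis_sample(apply_dementia_exclusions(s$adat))
  spec <- default_ladder("PGIS", "SBP")[[4]]
  loo <- leave_one_out(gen, s$sim$dosages, w, spec)
  ref <- loo[loo$variant_id == "(full score)", ]
  zero <- loo[loo$variant_id == w$variant_id[3], ]
  expect_equal(zero$estimate, ref$estimate, tolerance = 1e-10)
  expect_equal(zero$delta_se_units, 0, tolerance = 1e-8)
})

test_that("a planted pleiotropic variant is the unique influential row", {
  s <- sim_analysis("pleiotropic", 25000, seed = 342)
  gen <- genetic_analysis_sample(apply_dementia_exclusions(s$adat))
  w <- attr(s$adat, "weights")
  loo <- leave_one_out(gen, s$sim$dosages, w, default_ladder("PGIS", "SBP")[[4]])
  planted <- names(s$cfg$pleiotropy)
  flagged <- loo$variant_id[loo$influential %in% TRUE]
  expect_identical(flagged, planted)
  # excluding it moves the estimate toward the undistorted coupling
  ref <- loo$estimate[loo$variant_id == "(full score)"]
  drop <- loo$estimate[loo$variant_id == planted]
  expect_lt(drop, ref)
})

test_that("covariates orthogonal to the design leave the estimate unchanged", {
  withr::with_seed(343, {
    n <- 800
    dat <- data.frame(
      id = sprintf("S%04d", 1:n),
      pdis_raw = runif(n, 0, 2), pdis_valid = TRUE,
      age = runif(n, 40, 69), sex = factor(sample(c("female", "male"), n, TRUE))
    )
    dat$sbp_corrected <- 120 + 0.8 * scale(dat$pdis_raw)[, 1] +
      0.2 * dat$age + 3 * (dat$sex == "male") + rnorm(n, 0, 6)
    e1 <- rnorm(n); e2 <- rnorm(n)
  })
  spec <- model_spec("SBP", "PDIS", c("sex", "age"), TRUE, "main")
  # orthogonalise the extras against the full base design (Frisch-Waugh)
  X <- model.matrix(~ scale(dat$pdis_raw) + sex + age, data = dat)
  dat$b1 <- resid(lm(e1 ~ X - 1))
  dat$b2 <- resid(lm(e2 ~ X - 1))
  res <- extended_adjustment(dat, spec, extra_fields = c("b1", "b2"))
  expect_equal(res$extended$estimate, res$base$estimate, tolerance = 1e-8)
})

test_that("extras collinear with an existing covariate raise a rank error", {
  s <- sim_analysis("clean", 2000, seed = 344)
  base <- apply_dementia_exclusions(s$adat)
  base$bmi_twin <- 2 * base$bmi
  spec <- default_ladder("PDIS", "SBP")[[5]]
  expect_error(extended_adjustment(base, spec, extra_fields = "bmi_twin"),
               "collinear")
})

test_that("irrelevant extended covariates barely move the estimate", {
  s <- sim_analysis("clean", 20000, seed = 345)
  base <- apply_dementia_exclusions(s$adat)
  withr::with_seed(346, {
    base$noise1 <- rnorm(nrow(base)); base$noise2 <- rnorm(nrow(base))
  })
  spec <- default_ladder("PDIS", "SBP")[[5]]
  res <- extended_adjustment(base, spec, extra_fields = c("noise1", "noise2"))
  expect_lt(abs(res$extended$estimate - res$base$estimate), 0.2 * res$base$se)
})

test_that("complete-case comparison is the identity without extra missingness", {
  s <- sim_analysis("clean", 4000, seed = 347)
  base <- apply_dementia_exclusions(s$adat)
  spec <- default_ladder("PDIS", "SBP")[[5]]
  base$allpresent <- 1
  res <- complete_case_comparison(base, spec,
                                  strict_fields = c(spec$covariates, "allpresent"))
  expect_equal(res$main$estimate, res$strict$estimate, tolerance = 1e-12)
  expect_equal(res$n_main, res$n_strict)
  expect_error(complete_case_comparison(base, spec, strict_fields = "age"),
               "must contain")
})

test_that("random missingness leaves estimates concordant; informative missingness does not", {
  spec <- model_spec("SBP", "PDIS", c("sex", "age"), TRUE, "main")
  run_pair <- function(seed, informative) {
    s <- sim_analysis("clean", 10000, seed = seed)
    base <- apply_dementia_exclusions(s$adat)
    base$extra <- base$hba1c
    drop <- if (informative) {
      # missingness driven by the outcome itself: classic selection bias.
      # Truncating the top 60% of SBP attenuates the slope strongly
      # (outcome truncation), so the planted divergence dominates the
      # per-replicate noise at this n
      !is.na(base$sbp_corrected) &
        base$sbp_corrected > quantile(base$sbp_corrected, 0.4, na.rm = TRUE)
    } else {
      withr::with_seed(seed + 5000, runif(nrow(base)) < 0.6)
    }
    base$extra[drop] <- NA
    res <- complete_case_comparison(base, spec,
                                    strict_fields = c(spec$covariates, "extra"))
    res$strict$estimate - res$main$estimate
  }
  mcar <- vapply(1:30, function(r) run_pair(400 + r, FALSE), numeric(1))
  inf <- vapply(1:30, function(r) run_pair(450 + r, TRUE), numeric(1))
  se_m <- sd(mcar) / sqrt(length(mcar))
  expect_lt(abs(mean(mcar)), 3.5 * se_m)  # concordant under MCAR
  # outcome-driven missingness attenuates the estimate systematically
  expect_lt(mean(inf), mean(mcar) - 2 * sd(inf) / sqrt(length(inf)))
})
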