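test_that("mean BP uses both baseline readings, one if single, later visit if none", {
  expect_equal(derive_mean_bp(list(list(sbp = c(120, 130),
                                        dbp = c(80, 84))))$sbp_mean, 125)
  one <- derive_mean_bp(list(list(sbp = c(NA, 118), dbp = c(NA, 76))))
  expect_equal(one$sbp_mean, 118)
  expect_equal(one$sbp_source_visit, 0L)
  fall <- derive_mean_bp(list(list(sbp = c(NA, NA), dbp = c(NA, NA)),
                              list(sbp = c(140, 150), dbp = c(88, 92))))
  expect_equal(fall$sbp_mean, 145)
  expect_equal(fall$dbp_mean, 90)
  expect_equal(fall$sbp_source_visit, 1L)
  # the two pressure types resolve independently
  mix <- derive_mean_bp(list(list(sbp = c(121, 123), dbp = c(NA, NA)),
                             list(sbp = c(999, NA), dbp = c(70, 74))))
  expect_equal(mix$sbp_mean, 122)
  expect_equal(mix$sbp_source_visit, 0L)
  expect_equal(mix$dbp_mean, 72)
  expect_equal(mix$dbp_source_visit, 1L)
})

test_that("mean BP is order-invariant, guards implausible readings, prefers automated", {
  a <- derive_mean_bp(list(list(sbp = c(118, 132), dbp = c(78, 86))))
  b <- derive_mean_bp(list(list(sbp = c(132, 118), dbp = c(86, 78))))
  expect_equal(a, b)
  # readings outside (40, 300) mmHg are device errors, treated missing
  g <- derive_mean_bp(list(list(sbp = c(900, 120), dbp = c(30, 82))))
  expect_equal(g$sbp_mean, 120)
  expect_equal(g$dbp_mean, 82)
  # automated preferred over manual within a visit, manual as fallback
  m <- derive_mean_bp(list(list(sbp = c(NA, NA), sbp_manual = c(100, 110),
                                dbp = c(80, 82), dbp_manual = c(60, 62))))
  expect_equal(m$sbp_mean, 105)
  expect_equal(m$dbp_mean, 81)
  none <- derive_mean_bp(list(list(sbp = c(NA, NA), dbp = c(NA, NA))))
  expect_true(is.na(none$sbp_mean) && is.na(none$sbp_source_visit))
})

test_that("cohort-level outcome derivation agrees with the per-participant rule", {
  s <- sim_analysis("clean", 400, seed = 310)
  co <- s$sim$cohort
  out <- derive_outcomes(co)
  for (i in sample(nrow(co), 60)) {
    ref <- derive_mean_bp(list(
      list(sbp = c(co$sbp_0a[i], co$sbp_0b[i]), dbp = c(co$dbp_0a[i], co$dbp_0b[i])),
      list(sbp = c(co$sbp_1a[i], co$sbp_1b[i]), dbp = c(co$dbp_1a[i], co$dbp_1b[i]))
    ))
    expect_equal(out$sbp_measured[i], ref$sbp_mean)
    expect_equal(out$dbp_measured[i], ref$dbp_mean)
  }
})

test_that("medication correction adds +15/+10 for treated participants only", {
  c1 <- correct_for_medication(130, 80, 1)
  expect_equal(c(c1$sbp, c1$dbp), c(145, 90))
  c0 <- correct_for_medication(130, 80, 0)
  expect_equal(c(c0$sbp, c0$dbp), c(130, 80))
  # the corrected flag blocks double application
  expect_error(correct_for_medication(c1, 80, 1), "already")
  # unknown medication status cannot be corrected
  cna <- correct_for_medication(c(120, 125), c(70, 75), c(NA, 1))
  expect_true(is.na(cna$sbp[1]) && cna$sbp[2] == 140)
})

test_that("correction shifts the population mean by 15 x treated fraction", {
  withr::with_seed(311, {
    sbp <- rnorm(5000, 135, 15); dbp <- rnorm(5000, 82, 9)
    med <- rbinom(5000, 1, 0.3)
  })
  corr <- correct_for_medication(sbp, dbp, med)
  expect_equal(mean(corr$sbp) - mean(sbp), 15 * mean(med), tolerance = 1e-12)
  expect_equal(mean(corr$dbp) - mean(dbp), 10 * mean(med), tolerance = 1e-12)
})

test_that("hypertension composite uses strict 140/90 thresholds and any criterion", {
  expect_equal(derive_hypertension(0, 0, 140, 90), 0L)  # boundary normotensive
  expect_equal(derive_hypertension(0, 0, 141, 70), 1L)
  expect_equal(derive_hypertension(0, 0, 120, 90.5), 1L)
  expect_equal(derive_hypertension(0, 1, 110, 70), 1L)
  expect_equal(derive_hypertension(1, 0, 110, 70), 1L)
  # three-valued logic: a TRUE criterion decides despite missing inputs
  expect_equal(derive_hypertension(0, 0, NA, 95), 1L)
  expect_true(is.na(derive_hypertension(NA, 0, 120, 80)))
  expect_true(is.na(derive_hypertension(NA, NA, NA, NA)))
})

test_that("hypertension indicator is monotone in blood pressure", {
  withr::with_seed(312, {
    for (r in 1:200) {
      sr <- rbinom(1, 1, 0.2); med <- rbinom(1, 1, 0.2)
      sbp <- runif(1, 90, 200); dbp <- runif(1, 50, 110)
      base <- derive_hypertension(sr, med, sbp, dbp)
      up <- derive_hypertension(sr, med, sbp + runif(1, 0, 40),
                                dbp + runif(1, 0, 20))
      expect_gte(up, base)
    }
  })
})
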