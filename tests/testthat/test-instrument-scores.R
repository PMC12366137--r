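test_that("parental weight follows the age-weighting rule with cap at 68", {
  # demented parents contribute one full unit regardless of age
  expect_identical(parental_weight(1, 75), 1)
  expect_identical(parental_weight(1, NA), 1)
  # non-demented: (100 - age)/100, capped below at 68, clamped above at 100
  expect_equal(parental_weight(0, 100), 0)
  expect_equal(parental_weight(0, 68), 0.32)
  expect_equal(parental_weight(0, 60), 0.32)
  expect_equal(parental_weight(0, 80), 0.20)
  expect_equal(parental_weight(0, 105), 0)  # beyond 100 clamps to zero
  # undefined cases invalidate rather than guess
  expect_true(is.na(parental_weight(NA, 80)))
  expect_true(is.na(parental_weight(0, NA)))
  expect_error(parental_weight(0, 130), "age_years")
})

test_that("parental weight is constant below the cap and non-increasing above", {
  ages <- seq(1, 100, by = 0.5)
  w <- parental_weight(rep(0L, length(ages)), ages)
  expect_true(all(w[ages <= 68] == 0.32))
  above <- w[ages >= 68]
  expect_true(all(diff(above) <= 0))
  expect_true(all(w >= 0 & w <= 1))
})

test_that("PDIS sums two parental weights and tracks validity", {
  expect_equal(compute_pdis(1, NA, 1, NA)$raw, 2)
  expect_equal(compute_pdis(0, 100, 0, 100)$raw, 0)
  expect_equal(compute_pdis(1, 70, 0, 90)$raw, 1.10)
  out <- compute_pdis(c(1, 0, NA), c(NA, NA, 80), c(0, 0, 0), c(75, 75, 75))
  expect_equal(out$valid, c(TRUE, FALSE, FALSE))
  expect_true(all(out$raw[out$valid] >= 0 & out$raw[out$valid] <= 2))
  expect_true(all(is.na(out$raw[!out$valid])))
})

test_that("harmonisation flips swapped alleles and reports actions", {
  w <- data.frame(variant_id = c("v1", "v2"),
                  effect_allele = c("A", "C"), other_allele = c("G", "T"),
                  beta = c(0.1, -0.2), eaf = c(0.3, 0.6),
                  stringsAsFactors = FALSE)
  panel <- data.frame(variant_id = c("v1", "v2"),
                      allele_a = c("G", "C"), allele_b = c("A", "T"),
                      eaf = c(0.72, 0.61), stringsAsFactors = FALSE)
  h <- harmonize_weights(w, panel)
  rep <- attr(h, "report")
  # v1 swapped: sign flips, frequency complements
  expect_equal(rep$action, c("flipped", "kept"))
  expect_equal(h$beta, c(-0.1, -0.2))
  expect_equal(h$eaf, c(0.7, 0.6))
  expect_equal(h$effect_allele, c("G", "C"))
})

test_that("harmonisation drops mismatches and ambiguous palindromes", {
  w <- data.frame(variant_id = c("p1", "p2", "m1"),
                  effect_allele = c("A", "A", "A"),
                  other_allele = c("T", "T", "G"),
                  beta = c(0.1, 0.1, 0.1), eaf = c(0.50, 0.10, 0.3),
                  stringsAsFactors = FALSE)
  panel <- data.frame(variant_id = c("p1", "p2", "m1"),
                      allele_a = c("A", "A", "C"),
                      allele_b = c("T", "T", "T"),
                      eaf = c(0.5, 0.11, 0.3), stringsAsFactors = FALSE)
  h <- harmonize_weights(w, panel)
  rep <- attr(h, "report")
  # p1: palindromic with frequency at 0.5 -> uninformative, dropped
  expect_equal(rep$action[rep$variant_id == "p1"], "dropped_palindromic")
  # p2: palindromic but frequency far from 0.5 -> resolvable, kept
  expect_equal(rep$action[rep$variant_id == "p2"], "kept")
  # m1: neither orientation matches -> dropped
  expect_equal(rep$action[rep$variant_id == "m1"], "dropped_mismatch")
  expect_equal(h$variant_id, "p2")
  expect_error(harmonize_weights(w, panel[1:2, ]), "missing from panel")
})

test_that("harmonising back onto the GWAS orientation is an involution", {
  w <- synthetic_snp_panel(8)
  panel <- data.frame(variant_id = w$variant_id,
                      allele_a = w$other_allele,  # every variant swapped
                      allele_b = w$effect_allele,
                      eaf = 1 - w$eaf, stringsAsFactors = FALSE)
  h <- harmonize_weights(w, panel)
  back_panel <- data.frame(variant_id = w$variant_id,
                           allele_a = w$effect_allele,
                           allele_b = w$other_allele,
                           eaf = w$eaf, stringsAsFactors = FALSE)
  w2 <- harmonize_weights(h, back_panel)
  expect_equal(w2$beta, w$beta)
  expect_equal(w2$eaf, w$eaf)
  expect_equal(w2$effect_allele, w$effect_allele)
})

test_that("PGIS is the dosage-weight dot product", {
  w3 <- data.frame(variant_id = c("a", "b", "c"),
                   effect_allele = "A", other_allele = "G",
                   beta = c(0.1, -0.2, 0.5), eaf = c(0.2, 0.5, 0.8),
                   stringsAsFactors = FALSE)
  expect_equal(compute_pgis(matrix(0, 1, 3), w3)$raw, 0)
  w1 <- data.frame(variant_id = "a", effect_allele = "A", other_allele = "G",
                   beta = 0.15, eaf = 0.2, stringsAsFactors = FALSE)
  expect_equal(compute_pgis(matrix(2, 1, 1), w1)$raw, 0.30)
  expect_equal(compute_pgis(matrix(c(1, 2, 0), 1, 3), w3)$raw, -0.30)

  # brute-force double-loop oracle on random instances
  withr::with_seed(404, {
    for (r in 1:20) {
      n <- sample(1:40, 1); k <- sample(1:12, 1)
      dos <- matrix(sample(0:2, n * k, TRUE), n, k)
      wt <- data.frame(variant_id = paste0("v", 1:k),
                       effect_allele = "A", other_allele = "G",
                       beta = rnorm(k), eaf = runif(k, 0.05, 0.95),
                       stringsAsFactors = FALSE)
      oracle <- numeric(n)
      for (i in 1:n) for (j in 1:k) oracle[i] <- oracle[i] + dos[i, j] * wt$beta[j]
      expect_equal(compute_pgis(dos, wt)$raw, oracle, tolerance = 1e-12)
    }
  })
})

test_that("missing dosages invalidate the PGIS unless imputation is requested", {
  wt <- data.frame(variant_id = c("v1", "v2"), effect_allele = "A",
                   other_allele = "G", beta = c(0.2, 0.4), eaf = c(0.25, 0.5),
                   stringsAsFactors = FALSE)
  dos <- matrix(c(1, NA, 2, 2), 2, 2)
  out <- compute_pgis(dos, wt)
  expect_equal(out$valid, c(TRUE, FALSE))
  expect_true(is.na(out$raw[2]))
  imp <- compute_pgis(dos, wt, impute_missing = TRUE)
  expect_true(all(imp$valid))
  expect_equal(imp$raw[2], 2 * 0.25 * 0.2 + 2 * 0.4)
  expect_error(compute_pgis(matrix(0, 2, 3), wt), "3 columns")
})

test_that("standardisation matches a two-pass z-score oracle and respects masks", {
  expect_equal(as.numeric(standardize_score(c(0, 1, 2))), c(-1, 0, 1))
  raws <- c(0.32, 0.64, 1.0, 2.0)
  mu <- sum(raws) / 4
  sdv <- sqrt(sum((raws - mu)^2) / 3)
  expect_equal(as.numeric(standardize_score(raws)), (raws - mu) / sdv,
               tolerance = 1e-12)
  expect_error(standardize_score(rep(1.4, 5)), "degenerate")
  # masked rows neither contribute to the moments nor receive a value
  z <- standardize_score(c(0, 1, 2, 50), mask = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(as.numeric(z)[1:3], c(-1, 0, 1))
  expect_true(is.na(z[4]))
  mz <- standardize_score(c(0, 1, 2), mask = rep(TRUE, 3))
  expect_equal(mean(mz, na.rm = TRUE), 0)
  expect_equal(sd(mz, na.rm = TRUE), 1)
})

test_that("instrument relevance detects the designed dementia association", {
  s <- sim_analysis("clean", 20000, seed = 301)
  z <- standardize_score(s$adat$pgis_raw)
  rel <- instrument_relevance(z, s$adat$dementia_dx)
  expect_gt(rel$estimate, 1)
  expect_lt(rel$p, 0.05)
  expect_true(rel$ci_low <= rel$estimate && rel$estimate <= rel$ci_high)
  # degenerate inputs fail loudly
  expect_error(instrument_relevance(z, rep(1L, length(z))), "classes")
  ysep <- rep(c(0L, 1L), each = 40)
  zsep <- ifelse(ysep == 1, 5 + seq_along(ysep) / 100, -5 - seq_along(ysep) / 100)
  expect_error(instrument_relevance(zsep, ysep), "separation|converge")
})

test_that("a permuted instrument is null-calibrated", {
  # n chosen for several hundred dementia cases per fit: Wald intervals on
  # a logistic coefficient are liberal with few events, and the property
  # under test is the calibration of the procedure, not that artefact
  s <- sim_analysis("clean", 40000, seed = 302)
  z <- as.numeric(standardize_score(s$adat$pgis_raw))
  y <- s$adat$dementia_dx
  covered <- withr::with_seed(303, {
    vapply(1:200, function(r) {
      fit <- instrument_relevance(sample(z), y)
      fit$ci_low <= 1 && 1 <= fit$ci_high
    }, logical(1))
  })
  expect_gte(mean(covered), 0.93)
})

test_that("PDIS and PGIS are positively correlated under the clean scenario", {
  s <- sim_analysis("clean", 20000, seed = 304)
  ok <- s$adat$pdis_valid & s$adat$pgis_valid
  expect_gt(cor(s$adat$pdis_raw[ok], s$adat$pgis_raw[ok]), 0)
})
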