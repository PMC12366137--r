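# End-to-end orchestration: simulate -> score -> outcomes -> models ------

#' Assemble the analysis table: scores, outcomes and validity flags
#'
#' Harmonises the GWAS weights onto the dosage panel, computes both
#' instrument scores and the derived blood-pressure outcomes, and joins
#' everything onto the cohort table.  No eligibility filtering happens
#' here; apply [apply_dementia_exclusions()] (and
#' [genetic_analysis_sample()] for allele-score analyses) downstream.
#'
#' @param cohort Cohort data.frame.
#' @param dosages Dosage matrix with rownames matching `cohort$id`.
#' @param weights GWAS weight table ([read_snp_weights()] format).
#' @param panel_alleles Optional panel orientation table for
#'   [harmonize_weights()]; by default the dosage matrix is taken to count
#'   the weight table's effect allele and sample frequencies are estimated
#'   from the dosages (harmonisation is then an identity with a frequency
#'   comparison report).
#' @param impute_missing Passed to [compute_pgis()].
#' @return The cohort with added columns `pdis_raw`, `pdis_valid`,
#'   `pgis_raw`, `pgis_valid` and the [derive_outcomes()] columns;
#'   harmonisation report and harmonised weights attached as attributes
#'   `"harmonisation_report"` and `"weights"`.
#' @export
assemble_analysis <- function(cohort, dosages, weights,
                              panel_alleles = NULL, impute_missing = FALSE) {
  if (is.null(panel_alleles)) {
    sample_eaf <- colMeans(dosages[, weights$variant_id, drop = FALSE],
                           na.rm = TRUE) / 2
    panel_alleles <- data.frame(variant_id = weights$variant_id,
                                allele_a = weights$effect_allele,
                                allele_b = weights$other_allele,
                                eaf = unname(sample_eaf),
                                stringsAsFactors = FALSE)
  }
  hw <- harmonize_weights(weights, panel_alleles)
  report <- attr(hw, "report")

  pdis <- compute_pdis(cohort$mother_dementia, cohort$mother_age,
                       cohort$father_dementia, cohort$father_age)
  dos <- if (identical(rownames(dosages), cohort$id))
    dosages
  else
    dosages[match(cohort$id, rownames(dosages)), , drop = FALSE]
  pgis <- compute_pgis(dos, hw, impute_missing = impute_missing)
  out <- derive_outcomes(cohort)

  res <- cbind(cohort,
               pdis_raw = pdis$raw, pdis_valid = pdis$valid,
               pgis_raw = pgis$raw, pgis_valid = pgis$valid,
               out[, setdiff(names(out), "id"), drop = FALSE])
  attr(res, "harmonisation_report") <- report
  attr(res, "weights") <- hw
  res
}

.known_scenarios <- function() names(scenario_library(10, 1))

#' Simulate a scenario cohort and write it to disk
#'
#' @param scenario Scenario name from [scenario_library()].
#' @param n Number of participants (>= 1).
#' @param seed Integer seed.
#' @param outdir Output directory.
#' @param vcf Also write a VCF of the genotypes?
#' @return Character vector of files written, invisibly.
#' @export
cmd_simulate <- function(scenario, n, seed, outdir, vcf = FALSE) {
  if (!is.character(scenario) || !(scenario %in% .known_scenarios()))
    stop("unknown scenario '", scenario, "'; available: ",
         paste(.known_scenarios(), collapse = ", "), call. = FALSE)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1)
    stop("usage error: 'n' must be a positive integer", call. = FALSE)
  cfg <- scenario_library(as.integer(n), as.integer(seed))[[scenario]]
  sim <- simulate_cohort(cfg)
  paths <- write_cohort_files(sim, outdir, vcf = vcf)
  message("wrote ", length(paths), " files to ", outdir)
  invisible(paths)
}

.result_row <- function(instrument, outcome, assoc) {
  cbind(instrument = instrument, outcome = outcome, as.data.frame(assoc),
        stringsAsFactors = FALSE)
}

#' Run the full two-instrument analysis pipeline
#'
#' Orchestrates scoring, outcome derivation, eligibility filtering, the
#' model ladders for both instruments across the three outcomes, the
#' instrument relevance check, and the sensitivity suite, writing all
#' results as delimited text under `outdir`:
#' `results.tsv` (all ladder rungs), `relevance.tsv`,
#' `exclusion_log.tsv`, `harmonisation_report.tsv`,
#' `loo_<outcome>.tsv` (leave-one-variant-out for the PGIS main model)
#' and `sensitivity_summary.tsv` (extended adjustment and complete-case
#' comparison for the PDIS main model).
#'
#' @param cohort Cohort data.frame, or `NULL` to simulate `scenario`.
#' @param dosages,weights Genotype dosages and GWAS weight table
#'   (required when `cohort` is given).
#' @param scenario,n,seed Simulation request used when `cohort` is `NULL`
#'   (exactly one of cohort paths or scenario must be supplied).
#' @param outdir Output directory.
#' @param instruments,outcomes Subsets to run (defaults: both instruments,
#'   all three outcomes).
#' @param sensitivity Run the sensitivity suite?
#' @return Invisibly, a list with the ladders, relevance fits, sensitivity
#'   results and the result table.
#' @export
cmd_analyze <- function(cohort = NULL, dosages = NULL, weights = NULL,
                        scenario = NULL, n = 20000L, seed = 1L,
                        outdir = NULL,
                        instruments = c("PDIS", "PGIS"),
                        outcomes = c("SBP", "DBP", "hypertension"),
                        sensitivity = TRUE) {
  if (is.null(cohort) == is.null(scenario))
    stop("supply exactly one of 'cohort' (+dosages+weights) or 'scenario'",
         call. = FALSE)
  cfg_hash <- NA_character_
  if (!is.null(scenario)) {
    if (!(scenario %in% .known_scenarios()))
      stop("unknown scenario '", scenario, "'; available: ",
           paste(.known_scenarios(), collapse = ", "), call. = FALSE)
    cfg <- scenario_library(as.integer(n), as.integer(seed))[[scenario]]
    sim <- simulate_cohort(cfg)
    cohort <- sim$cohort; dosages <- sim$dosages
    weights <- cfg$snp_panel
    cfg_hash <- .config_hash(cfg)
  } else if (is.null(dosages) || is.null(weights)) {
    stop("'dosages' and 'weights' are required with 'cohort'", call. = FALSE)
  }

  adat <- assemble_analysis(cohort, dosages, weights)
  relevance <- list(
    PDIS = instrument_relevance(
      standardize_score(adat$pdis_raw), adat$dementia_dx),
    PGIS = instrument_relevance(
      standardize_score(adat$pgis_raw), adat$dementia_dx)
  )

  base <- apply_dementia_exclusions(adat)
  excl_log <- attr(base, "exclusion_log")
  gen <- genetic_analysis_sample(base)
  excl_log <- rbind(
    cbind(sample = "all", attr(base, "exclusion_log")),
    cbind(sample = "genetic", attr(gen, "exclusion_log"))
  )

  ladders <- list()
  rows <- list()
  for (ins in instruments) {
    dat <- if (ins == "PGIS") gen else base
    for (oc in outcomes) {
      lad <- run_model_ladder(dat, ins, oc)
      ladders[[paste(ins, oc, sep = "_")]] <- lad
      rows[[length(rows) + 1L]] <- as.data.frame(lad)
    }
  }
  results <- do.call(rbind, rows)

  sens <- NULL
  if (sensitivity) {
    w <- attr(adat, "weights")
    loo <- list()
    if ("PGIS" %in% instruments) {
      for (oc in intersect(outcomes, c("SBP", "DBP", "hypertension"))) {
        spec <- default_ladder("PGIS", oc)[[4]]
        loo[[oc]] <- leave_one_out(gen, dosages, w, spec)
      }
    }
    ext <- cc_cmp <- NULL
    if ("PDIS" %in% instruments && "SBP" %in% outcomes) {
      main_spec <- default_ladder("PDIS", "SBP")[[5]]
      ext <- extended_adjustment(base, main_spec)
      cc_cmp <- complete_case_comparison(
        base, main_spec,
        strict_fields = c(main_spec$covariates,
                          c("hba1c", "chol_total", "hdl", "ldl", "trig", "crp")))
    }
    sens <- list(loo = loo, extended = ext, complete_case = cc_cmp)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_table(results, file.path(outdir, "results.tsv"), cfg_hash)
    rel_df <- rbind(.result_row("PDIS", "dementia_dx", relevance$PDIS),
                    .result_row("PGIS", "dementia_dx", relevance$PGIS))
    write_table(rel_df, file.path(outdir, "relevance.tsv"), cfg_hash)
    write_table(excl_log, file.path(outdir, "exclusion_log.tsv"), cfg_hash)
    write_table(attr(adat, "harmonisation_report"),
                file.path(outdir, "harmonisation_report.tsv"), cfg_hash)
    if (!is.null(sens)) {
      for (oc in names(sens$loo))
        write_table(sens$loo[[oc]],
                    file.path(outdir, sprintf("loo_%s.tsv", tolower(oc))),
                    cfg_hash)
      if (!is.null(sens$extended)) {
        ss <- rbind(
          .result_row("PDIS", "SBP", sens$extended$base),
          .result_row("PDIS", "SBP", sens$extended$extended),
          .result_row("PDIS", "SBP", sens$complete_case$main),
          .result_row("PDIS", "SBP", sens$complete_case$strict)
        )
        write_table(ss, file.path(outdir, "sensitivity_summary.tsv"), cfg_hash)
      }
    }
  }

  invisible(list(results = results, ladders = ladders, relevance = relevance,
                 sensitivity = sens, exclusion_log = excl_log,
                 harmonisation_report = attr(adat, "harmonisation_report")))
}

#' Render forest plots and a text summary from a results directory
#'
#' @param results_dir Directory written by [cmd_analyze()].
#' @param plot_dir Where to write the per-rung forest plots (PDF); defaults
#'   to `results_dir`.
#' @return Invisibly, the results table.
#' @export
cmd_report <- function(results_dir, plot_dir = results_dir) {
  f_results <- file.path(results_dir, "results.tsv")
  f_log <- file.path(results_dir, "exclusion_log.tsv")
  missing <- c(f_results, f_log)[!file.exists(c(f_results, f_log))]
  if (length(missing))
    stop("missing expected results file(s): ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  results <- utils::read.delim(f_results, stringsAsFactors = FALSE)
  excl <- utils::read.delim(f_log, stringsAsFactors = FALSE)

  dir.create(plot_dir, showWarnings = FALSE, recursive = TRUE)
  combos <- unique(results[, c("instrument", "outcome")])
  for (i in seq_len(nrow(combos))) {
    sub <- results[results$instrument == combos$instrument[i] &
                     results$outcome == combos$outcome[i], ]
    pdf_path <- file.path(plot_dir, sprintf("forest_%s_%s.pdf",
                                            tolower(combos$instrument[i]),
                                            tolower(combos$outcome[i])))
    grDevices::pdf(pdf_path, width = 7, height = 4)
    null_at <- if (combos$outcome[i] == "hypertension") 1 else 0
    ys <- rev(seq_len(nrow(sub)))
    op <- graphics::par(mar = c(4, 10, 3, 2))
    graphics::plot(sub$estimate, ys,
                   xlim = range(c(sub$ci_low, sub$ci_high, null_at)),
                   ylim = c(0.5, nrow(sub) + 0.5), pch = 15, yaxt = "n",
                   xlab = sub$scale[1], ylab = "",
                   main = sprintf("%s -> %s", combos$instrument[i],
                                  combos$outcome[i]))
    graphics::segments(sub$ci_low, ys, sub$ci_high, ys)
    graphics::abline(v = null_at, lty = 2, col = "grey40")
    graphics::axis(2, at = ys, labels = sub$model_label, las = 1,
                   cex.axis = 0.8)
    graphics::par(op)
    grDevices::dev.off()
  }

  cat("Analysis summary\n================\n")
  cat("Exclusions:\n")
  print(excl, row.names = FALSE)
  cat("\nFinal-rung estimates:\n")
  last <- do.call(rbind, lapply(split(results, list(results$instrument,
                                                    results$outcome),
                                      drop = TRUE),
                                function(d) d[nrow(d), ]))
  print(last[, c("instrument", "outcome", "model_label", "n", "estimate",
                 "ci_low", "ci_high", "p")], row.names = FALSE, digits = 4)
  invisible(results)
}
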