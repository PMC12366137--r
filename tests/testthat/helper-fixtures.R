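# Shared fixtures, all built in code.

# deterministic miniature cohort for filter tests
toy_cohort <- function(n = 10) {
  data.frame(
    id = sprintf("T%03d", seq_len(n)),
    withdrawn = rep(0L, n),
    prevalent_dementia = rep(0L, n),
    incident_dementia_years = rep(NA_real_, n),
    qc_fail = rep(0L, n),
    ethnic_group = factor(rep("European", n), levels = c("European", "Other")),
    pgis_valid = rep(TRUE, n),
    education = factor(rep("secondary", n),
                       levels = c("none", "secondary", "vocational", "degree")),
    age = seq(40, 69, length.out = n),
    stringsAsFactors = FALSE
  )
}

# simulate a scenario and assemble the analysis table in one step
sim_analysis <- function(scenario, n, seed) {
  cfg <- scenario_library(n, seed)[[scenario]]
  sim <- simulate_cohort(cfg)
  adat <- assemble_analysis(sim$cohort, sim$dosages, cfg$snp_panel)
  list(sim = sim, adat = adat, cfg = cfg)
}

# independent brute-force complete-case oracle: plain row scan
brute_force_complete <- function(df, fields) {
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (f in fields) if (is.na(df[[f]][i])) ok <- FALSE
    keep[i] <- ok
  }
  keep
}
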