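# Delimited-text readers and writers -------------------------------------

.round6 <- function(df) {
  for (nm in names(df)) if (is.double(df[[nm]])) df[[nm]] <- round(df[[nm]], 6)
  df
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

# sidecar metadata record; no timestamps, so outputs are byte-reproducible
.write_sidecar <- function(path, config_hash = NA_character_) {
  meta <- list(file = basename(path), config_hash = config_hash,
               package = "adbpiv",
               package_version = as.character(utils::packageVersion("adbpiv")),
               r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
}

#' Write a delimited results/cohort table with metadata sidecar
#'
#' Tab-delimited, header row, floats rounded at 6 decimals, missing values
#' as `NA`; a `<file>.meta.json` sidecar records the package version and
#' (optionally) the simulation config hash.
#'
#' @param df data.frame to write.
#' @param path Output file path.
#' @param config_hash Optional hash linking the file to its configuration.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, config_hash = NA_character_) {
  utils::write.table(.round6(as.data.frame(df)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  .write_sidecar(path, config_hash)
  invisible(path)
}

.cohort_dictionary <- function() {
  d <- c(
    id = "participant identifier",
    age = "age at baseline assessment, years (40-69)",
    sex = "participant sex (female/male); female is the reference level",
    education = "highest education band (none/secondary/vocational/degree)",
    ethnic_group = "self-declared ethnicity group (European/Other)",
    smoking = "smoking status (never/former/current)",
    salt = "added-salt frequency (never_rarely/sometimes/usually/always)",
    alcohol = "alcohol intake frequency (never/occasional/weekly/daily)",
    activity = "physical activity, MET-h/week",
    townsend = "Townsend-style deprivation index",
    bmi = "body mass index, kg/m2",
    mother_dementia = "mother ever diagnosed with all-cause dementia (1/0, NA unknown)",
    mother_age = "mother's current age if alive, age at death otherwise, years",
    father_dementia = "father ever diagnosed with all-cause dementia (1/0, NA unknown)",
    father_age = "father's current age if alive, age at death otherwise, years",
    sbp_0a = "systolic BP, baseline visit, first reading, mmHg",
    sbp_0b = "systolic BP, baseline visit, second reading, mmHg",
    dbp_0a = "diastolic BP, baseline visit, first reading, mmHg",
    dbp_0b = "diastolic BP, baseline visit, second reading, mmHg",
    device_0 = "measurement device at baseline (automated/manual)",
    sbp_1a = "systolic BP, repeat visit, first reading, mmHg",
    sbp_1b = "systolic BP, repeat visit, second reading, mmHg",
    dbp_1a = "diastolic BP, repeat visit, first reading, mmHg",
    dbp_1b = "diastolic BP, repeat visit, second reading, mmHg",
    device_1 = "measurement device at repeat visit (automated/manual)",
    bp_med = "on blood-pressure-lowering medication (1/0)",
    self_report_htn = "self-reported essential hypertension (1/0)",
    dementia_dx = "participant's own diagnosed all-cause dementia (1/0)",
    prevalent_dementia = "dementia diagnosed before baseline (1/0)",
    incident_dementia_years = "years from baseline to first dementia code (NA if none)",
    withdrawn = "participant withdrew from the study (1/0)",
    qc_fail = "failed genotyping quality control (1/0)",
    hba1c = "glycated haemoglobin, mmol/mol",
    chol_total = "total cholesterol, mmol/L",
    hdl = "HDL cholesterol, mmol/L",
    ldl = "LDL cholesterol, mmol/L",
    trig = "triglycerides, mmol/L",
    crp = "C-reactive protein, mg/L"
  )
  data.frame(column = names(d), description = unname(d),
             stringsAsFactors = FALSE)
}

#' Write a simulated cohort to delimited text files
#'
#' Emits `cohort.tsv` (one row per participant, parental fields as paired
#' columns), `dosages.tsv` (participants x variants, 0/1/2),
#' `ground_truth.tsv` (per-participant latent state) and
#' `data_dictionary.tsv`, each with a metadata sidecar carrying the
#' configuration hash.  Optionally also a minimal VCF of the genotypes
#' (requires the vcfR package).
#'
#' @param sim An `adbp_cohort` from [simulate_cohort()].
#' @param outdir Output directory (created if needed).
#' @param vcf Also write `dosages.vcf.gz`?
#' @return Character vector of the files written.
#' @export
write_cohort_files <- function(sim, outdir, vcf = FALSE) {
  stopifnot(inherits(sim, "adbp_cohort"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  h <- .config_hash(sim$config)
  paths <- character(0)

  p <- file.path(outdir, "cohort.tsv")
  write_table(sim$cohort, p, h); paths <- c(paths, p)

  p <- file.path(outdir, "dosages.tsv")
  dos <- data.frame(id = rownames(sim$dosages), sim$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_table(dos, p, h); paths <- c(paths, p)

  p <- file.path(outdir, "ground_truth.tsv")
  gt <- data.frame(
    id = sim$cohort$id,
    preclinical_status = sim$truth$preclinical_status,
    mother_liability = sim$truth$parental_liability[, "mother"],
    father_liability = sim$truth$parental_liability[, "father"],
    familial_env = sim$truth$familial_env,
    sbp_true = sim$truth$sbp_true, dbp_true = sim$truth$dbp_true,
    beta_sbp = sim$truth$beta_sbp, beta_dbp = sim$truth$beta_dbp,
    stringsAsFactors = FALSE
  )
  write_table(gt, p, h); paths <- c(paths, p)

  p <- file.path(outdir, "data_dictionary.tsv")
  write_table(.cohort_dictionary(), p, h); paths <- c(paths, p)

  p <- file.path(outdir, "snp_weights.tsv")
  write_table(sim$config$snp_panel, p, h); paths <- c(paths, p)

  if (vcf) {
    p <- file.path(outdir, "dosages.vcf.gz")
    write_dosages_vcf(sim$dosages, sim$config$snp_panel, p)
    paths <- c(paths, p)
  }
  paths
}

#' Read a cohort table written by [write_cohort_files()]
#'
#' Restores the documented factor levels (reference level first).
#'
#' @param path Path to `cohort.tsv`.
#' @return Cohort data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lv <- list(
    sex = c("female", "male"),
    education = c("none", "secondary", "vocational", "degree"),
    ethnic_group = c("European", "Other"),
    smoking = c("never", "former", "current"),
    salt = c("never_rarely", "sometimes", "usually", "always"),
    alcohol = c("never", "occasional", "weekly", "daily"),
    device_0 = c("automated", "manual"),
    device_1 = c("automated", "manual")
  )
  for (nm in names(lv))
    if (nm %in% names(df)) df[[nm]] <- factor(df[[nm]], levels = lv[[nm]])
  df
}

#' Read a dosage matrix from delimited text
#'
#' @param path Path to `dosages.tsv` (first column `id`).
#' @return Numeric matrix with participant rownames and variant colnames.
#' @export
read_dosages <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a GWAS weight table
#'
#' Tab-delimited with header columns `variant_id`, `effect_allele`,
#' `other_allele`, `beta`, `eaf` (and optionally `p`).
#'
#' @param path File path.
#' @return data.frame of weights.
#' @export
read_snp_weights <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "eaf")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("weight table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Write genotypes as a minimal VCF
#'
#' Diploid unphased GT records; ALT is the effect (dosage-counted) allele,
#' so dosage = ALT allele count.  Requires the vcfR package.
#'
#' @param dosages Dosage matrix (participants x variants).
#' @param panel Variant table with `variant_id`, `effect_allele`,
#'   `other_allele`.
#' @param path Output path (written gzipped by vcfR).
#' @return `path`, invisibly.
#' @export
write_dosages_vcf <- function(dosages, panel, path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required for VCF output", call. = FALSE)
  panel <- panel[match(colnames(dosages), panel$variant_id), ]
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- apply(dosages, 1, function(d) gt_code[d + 1L])  # variants x participants
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = ncol(dosages))
  fix <- cbind(CHROM = "1", POS = as.character(seq_len(nrow(panel)) * 1000L),
               ID = panel$variant_id, REF = panel$other_allele,
               ALT = panel$effect_allele, QUAL = ".", FILTER = "PASS",
               INFO = ".")
  gt <- cbind(FORMAT = "GT", gt)
  colnames(gt) <- c("FORMAT", rownames(dosages))
  v <- methods::new("vcfR",
                    meta = c("##fileformat=VCFv4.2",
                             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                    fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read effect-allele dosages from a VCF
#'
#' Counts ALT alleles in the GT field (diploid, unphased or phased).
#'
#' @param path VCF path (plain or gzipped).
#' @return Numeric dosage matrix (participants x variants).
#' @export
read_dosages_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required for VCF input", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  m <- apply(gt, 2, count_alt)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(rownames(gt), names(m)))
  out <- t(m)
  colnames(out) <- rownames(gt)
  out
}
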