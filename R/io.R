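#' Write a simulated cohort to the pipeline's on-disk formats
#'
#' Emits the exact external file set [run_pipeline()] consumes: an instrument
#' weight TSV (PGS-catalog-style columns), a dosage matrix TSV plus a variant
#' sites TSV carrying the counted-allele orientation, a covariate CSV,
#' longitudinal height and weight measurement CSVs, a long-format ICD event
#' CSV, the ICD-to-phecode map CSV, and a JSON sidecar recording the seed.
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_cohort_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) abort(sprintf("Cannot create directory '%s'.", dir))
  paths <- c(
    weights = file.path(dir, "weights.tsv"),
    dosages = file.path(dir, "dosages.tsv"),
    sites = file.path(dir, "sites.tsv"),
    covariates = file.path(dir, "covariates.csv"),
    height_measurements = file.path(dir, "height_measurements.csv"),
    weight_measurements = file.path(dir, "weight_measurements.csv"),
    icd_events = file.path(dir, "icd_events.csv"),
    phecode_map = file.path(dir, "phecode_map.csv"),
    meta = file.path(dir, "sim_meta.json")
  )
  readr::write_tsv(sim$weights, paths[["weights"]])
  dos <- tibble::as_tibble(sim$dosages$matrix)
  dos <- dplyr::bind_cols(
    tibble::tibble(person_id = rownames(sim$dosages$matrix) %||% character(0)),
    dos
  )
  readr::write_tsv(dos, paths[["dosages"]])
  readr::write_tsv(sim$dosages$variants, paths[["sites"]])
  covars <- dplyr::select(sim$cohort, "person_id", "population", "age", "sex",
                          dplyr::starts_with("PC"), "enrollment_date")
  readr::write_csv(covars, paths[["covariates"]])
  readr::write_csv(sim$height_measurements, paths[["height_measurements"]])
  readr::write_csv(sim$weight_measurements, paths[["weight_measurements"]])
  readr::write_csv(sim$icd_events, paths[["icd_events"]])
  readr::write_csv(sim$phecode_map, paths[["phecode_map"]])
  writeLines(jsonlite::toJSON(list(
    seed = sim$config$seed,
    n_individuals = sim$config$n_individuals,
    n_variants = sim$config$n_variants,
    n_phecodes = sim$config$n_phecodes,
    target_r2 = sim$config$target_r2
  ), auto_unbox = TRUE, pretty = TRUE), paths[["meta"]])
  invisible(paths)
}

#' Read an instrument weight table
#'
#' @param path TSV with columns rsid, chrom (or chr), pos, effect_allele,
#'   other_allele, beta.
#' @return A tibble.
#' @export
read_weights <- function(path) {
  w <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("chr" %in% names(w) && !"chrom" %in% names(w)) {
    w <- dplyr::rename(w, chrom = "chr")
  }
  need <- c("rsid", "effect_allele", "other_allele", "beta")
  if (!all(need %in% names(w))) {
    abort(paste("Weight table must contain columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(w$rsid)) abort("Weight table variant ids must be unique.")
  if (any(!is.finite(w$beta))) abort("Weight table betas must be finite.")
  w
}

#' Read a dosage matrix TSV plus its variant sites TSV
#'
#' @param dosage_path TSV whose first column is `person_id` and remaining
#'   columns are per-variant dosages of the counted allele.
#' @param sites_path TSV with columns id, counted_allele, other_allele
#'   (chrom/pos optional) describing each dosage column.
#' @return A [dosage_set()].
#' @export
read_dosages <- function(dosage_path, sites_path) {
  d <- readr::read_tsv(dosage_path, show_col_types = FALSE, progress = FALSE)
  sites <- readr::read_tsv(sites_path, show_col_types = FALSE, progress = FALSE)
  if (names(d)[1] != "person_id") abort("First dosage column must be `person_id`.")
  mat <- as.matrix(d[, -1, drop = FALSE])
  rownames(mat) <- as.character(d$person_id)
  sites <- sites[match(colnames(mat), as.character(sites$id)), , drop = FALSE]
  if (anyNA(sites$id)) abort("Every dosage column needs a row in the sites table.")
  dosage_set(mat, sites)
}

#' Read genotype dosages from a VCF with a DS FORMAT field
#'
#' The ALT allele is taken as the counted allele and REF as the other allele,
#' the convention of imputation-server VCF output.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return A [dosage_set()].
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Reading VCF dosages requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- tibble::as_tibble(vcfR::getFIX(v))
  mat <- t(ds)
  colnames(mat) <- fix$ID
  variants <- tibble::tibble(
    id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    counted_allele = fix$ALT,
    other_allele = fix$REF
  )
  dosage_set(mat, variants)
}
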