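#' Read a pipeline run configuration from YAML or JSON
#'
#' @param path Path to a YAML or JSON file; its fields are the arguments of
#'   [run_pipeline()]'s config (see that help page).
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file '%s' does not exist.", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

pipeline_require_file <- function(path, stage, what) {
  if (is.null(path) || !file.exists(path)) {
    abort(sprintf("[%s] required input '%s' not found: %s",
                  stage, what, path %||% "<missing>"))
  }
  path
}

#' Run the full PheWAS / MR-PheWAS pipeline
#'
#' Orchestrates the stages: anthropometric QC, phecode assignment and
#' filtering, genetic risk score construction, per-population measured-height
#' PheWAS and two-stage least squares MR-PheWAS (optionally the BMI-adjusted
#' sensitivity model), and cross-population fixed-effects meta-analysis.
#' Writes one TSV per result table plus a JSON manifest recording thresholds,
#' per-filter counts and the seed, so a re-run on identical inputs is
#' byte-identical. Per-phecode model failures are flagged in the outputs;
#' only missing inputs or degenerate whole-stage states abort, with the
#' stage named in the error.
#'
#' @param config A named list (or path to a YAML/JSON file, see
#'   [read_run_config()]) with elements:
#'   \describe{
#'     \item{paths}{named list: weights, dosages, sites, covariates,
#'       height_measurements, weight_measurements, icd_events, phecode_map.}
#'     \item{populations}{labels to analyze (default: all in the covariate
#'       table).}
#'     \item{covariates}{second-stage covariate columns (default age, sex,
#'       PC1..PC10).}
#'     \item{min_cases, min_controls}{phecode filter (default 200/200).}
#'     \item{add_bmi}{also fit the BMI-adjusted MR model (default FALSE).}
#'     \item{out_dir}{output directory.}
#'     \item{seed}{recorded in the manifest (the pipeline itself is
#'       deterministic).}
#'   }
#' @return Invisibly, a list: `results` (per population: measured, genetic,
#'   optional genetic_bmi sweeps, stage1 fit, threshold), `meta`, `manifest`,
#'   `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  paths <- config$paths
  p_cov <- pipeline_require_file(paths$covariates, "cohort", "covariates")
  p_hgt <- pipeline_require_file(paths$height_measurements, "pheno_qc",
                                 "height measurements")
  p_wgt <- pipeline_require_file(paths$weight_measurements, "pheno_qc",
                                 "weight measurements")
  p_icd <- pipeline_require_file(paths$icd_events, "pheno_qc", "ICD events")
  p_map <- pipeline_require_file(paths$phecode_map, "pheno_qc", "phecode map")
  p_wts <- pipeline_require_file(paths$weights, "grs_instrument", "weights")
  p_dos <- pipeline_require_file(paths$dosages, "grs_instrument", "dosages")
  p_sit <- pipeline_require_file(paths$sites, "grs_instrument", "sites")
  out_dir <- config$out_dir %||% abort("config$out_dir is required.")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  covariate_names <- config$covariates %||% default_covariates()
  min_cases <- config$min_cases %||% 200
  min_controls <- config$min_controls %||% 200
  add_bmi <- isTRUE(config$add_bmi)

  ## --- cohort assembly -------------------------------------------------
  covars <- readr::read_csv(p_cov, show_col_types = FALSE, progress = FALSE)
  heights <- clean_height(readr::read_csv(p_hgt, show_col_types = FALSE,
                                          progress = FALSE))
  bmi <- clean_bmi(readr::read_csv(p_wgt, show_col_types = FALSE,
                                   progress = FALSE),
                   heights, covars)
  cohort <- covars |>
    dplyr::inner_join(dplyr::filter(heights, !.data$excluded) |>
                        dplyr::select("person_id", "height_cm"),
                      by = "person_id") |>
    dplyr::left_join(dplyr::select(bmi, "person_id", "bmi"), by = "person_id")
  populations <- config$populations %||% sort(unique(cohort$population))
  missing_pops <- setdiff(populations, unique(cohort$population))
  if (length(missing_pops)) {
    abort(sprintf("[cohort] populations not present in covariate table: %s",
                  paste(missing_pops, collapse = ", ")))
  }

  ## --- instrument ------------------------------------------------------
  weights <- read_weights(p_wts)
  dosages <- read_dosages(p_dos, p_sit)
  grs <- compute_grs(dosages, weights)
  match_log <- attr(grs, "match_log")
  cohort <- dplyr::inner_join(cohort, grs, by = "person_id")

  ## --- phenotypes ------------------------------------------------------
  icd <- readr::read_csv(p_icd, show_col_types = FALSE, progress = FALSE)
  map <- readr::read_csv(p_map, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           phecode = readr::col_character()))
  pm_all <- suppressMessages(
    assign_phecodes(icd, map, persons = cohort$person_id)
  )

  ## --- per-population sweeps ------------------------------------------
  results <- list()
  files <- character(0)
  manifest_pops <- list()
  for (pop in populations) {
    sub <- dplyr::filter(cohort, .data$population == pop)
    pm_pop <- subset_persons(pm_all, sub$person_id)
    pm_f <- suppressWarnings(filter_phecodes(pm_pop, min_cases, min_controls))
    n_tested <- nrow(pm_f$counts)
    threshold <- if (n_tested > 0) bonferroni_threshold(n_tested) else NA_real_
    if (n_tested == 0) {
      warn(sprintf("[assoc_engine] no phecodes pass the %d/%d filter in %s; skipping.",
                   min_cases, min_controls, pop))
      next
    }
    measured <- phewas_measured(sub, pm_f, covariates = covariate_names)
    s1 <- stage1_predict(sub, dplyr::select(sub, "person_id", "grs"))
    genetic <- mr_phewas(s1, sub, pm_f, covariates = covariate_names)
    res <- list(measured = measured, genetic = genetic, stage1 = s1,
                threshold = threshold, n_phecodes_tested = n_tested)
    if (add_bmi) {
      res$genetic_bmi <- mr_phewas(s1, sub, pm_f,
                                   covariates = covariate_names,
                                   add_bmi = TRUE)
    }
    results[[pop]] <- res
    for (tag in intersect(c("measured", "genetic", "genetic_bmi"), names(res))) {
      f <- file.path(out_dir, sprintf("%s_%s.tsv", tag, pop))
      readr::write_tsv(res[[tag]], f)
      files <- c(files, f)
    }
    manifest_pops[[pop]] <- list(
      n_persons = nrow(sub),
      n_phecodes_input = nrow(pm_pop$counts),
      n_phecodes_tested = n_tested,
      n_phecodes_filtered = nrow(pm_pop$counts) - n_tested,
      significance_threshold = threshold,
      first_stage_f = s1$f_statistic,
      instrument_r2 = s1$r_squared,
      weak_instrument = s1$weak_instrument
    )
  }
  if (length(results) == 0) abort("[assoc_engine] no population produced results.")

  ## --- meta-analysis ---------------------------------------------------
  meta <- NULL
  if (length(results) > 1) {
    meta <- meta_phewas(purrr::map(results, "genetic"))
    f <- file.path(out_dir, "meta_genetic.tsv")
    readr::write_tsv(meta, f)
    files <- c(files, f)
  }

  ## --- manifest --------------------------------------------------------
  n_h_excluded <- sum(heights$excluded)
  manifest <- list(
    package_version = as.character(utils::packageVersion("heightphewas")),
    seed = config$seed %||% NA,
    counts = list(
      persons_covariate_table = nrow(covars),
      persons_height_input = nrow(heights),
      persons_height_excluded = n_h_excluded,
      persons_height_retained = nrow(heights) - n_h_excluded,
      persons_analyzed = nrow(cohort),
      variants_weight_table = nrow(weights),
      variants_matched = sum(match_log$status == "matched"),
      variants_flipped = sum(match_log$status == "flipped"),
      variants_dropped = sum(match_log$status == "dropped"),
      icd_events_unmapped = pm_all$n_unmapped_events
    ),
    filters = list(min_cases = min_cases, min_controls = min_controls),
    populations = manifest_pops
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             manifest_path)
  files <- c(files, manifest_path)
  excl_path <- file.path(out_dir, "height_exclusions.tsv")
  readr::write_tsv(dplyr::filter(heights, .data$excluded), excl_path)
  files <- c(files, excl_path)

  invisible(list(results = results, meta = meta, manifest = manifest,
                 files = files))
}
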