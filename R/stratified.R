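#' Define a stratification by presence of a phecode set
#'
#' A stratum specification names a condition (e.g. coronary heart disease)
#' and the phecodes whose case status defines membership. The conventional
#' CHD and diabetes sets are available via [chd_stratum()] and
#' [diabetes_stratum()].
#'
#' @param name Stratum label.
#' @param phecodes Character vector of defining phecodes.
#' @return A `stratum_spec`.
#' @export
stratum_spec <- function(name, phecodes) {
  stopifnot(is.character(name), length(name) == 1, length(phecodes) >= 1)
  structure(list(name = name, phecodes = as.character(phecodes)),
            class = "stratum_spec")
}

#' @rdname stratum_spec
#' @export
chd_stratum <- function() {
  stratum_spec("CHD", c("411", "411.1", "411.2", "411.3", "411.4",
                        "411.41", "411.8", "411.9"))
}

#' @rdname stratum_spec
#' @export
diabetes_stratum <- function() {
  stratum_spec("diabetes", c("250", "250.1", "250.11", "250.12", "250.13",
                             "250.14", "250.15", "250.2", "250.21", "250.22",
                             "250.23", "250.24", "250.25", "250.6", "249"))
}

#' MR-PheWAS stratified by presence of a condition, with heterogeneity
#'
#' Splits the cohort into members (case for any defining phecode, by the
#' usual two-code rule) and non-members (everyone else, including persons
#' with a single qualifying code), refits the first stage within each
#' stratum, runs the MR-PheWAS on the outcome phecodes — the defining
#' phecodes are excluded from the outcome list — applying the case/control
#' minimums within each stratum, and tests between-stratum heterogeneity per
#' phecode shared by both sweeps.
#'
#' @param cohort One population stratum, as for [mr_phewas()].
#' @param grs Tibble `person_id`, `grs`.
#' @param pm A `phecode_matrix` (unfiltered; filtering happens per stratum).
#' @param stratum A [stratum_spec()].
#' @param covariates Second-stage covariates.
#' @param stage1_covariates First-stage covariates.
#' @param min_cases,min_controls Per-stratum phecode filter.
#' @return A list of class `mr_stratified`: `stratum` (the spec), `results`
#'   (combined `phewas_result` rows with a `stratum` column of
#'   `"with"`/`"without"`), and `heterogeneity` (per-phecode z and p).
#' @export
stratified_mr <- function(cohort, grs, pm, stratum,
                          covariates = default_covariates(),
                          stage1_covariates = paste0("PC", 1:10),
                          min_cases = 200, min_controls = 200) {
  stopifnot(inherits(stratum, "stratum_spec"), inherits(pm, "phecode_matrix"))
  cohort <- tibble::as_tibble(cohort)
  member_ids <- pm$calls |>
    dplyr::filter(.data$phecode %in% stratum$phecodes,
                  .data$status == "case") |>
    dplyr::pull(.data$person_id) |>
    unique()
  groups <- list(
    with = dplyr::filter(cohort, .data$person_id %in% member_ids),
    without = dplyr::filter(cohort, !.data$person_id %in% member_ids)
  )
  empty <- names(groups)[vapply(groups, nrow, 0L) == 0]
  if (length(empty)) {
    abort(sprintf("Stratum '%s' (%s) has zero members.",
                  stratum$name, paste(empty, collapse = ", ")))
  }
  res <- purrr::imap(groups, function(g, nm) {
    pm_g <- subset_persons(pm, g$person_id)
    pm_g$counts <- dplyr::filter(pm_g$counts,
                                 !.data$phecode %in% stratum$phecodes)
    pm_g <- suppressWarnings(
      filter_phecodes(pm_g, min_cases = min_cases, min_controls = min_controls)
    )
    if (nrow(pm_g$counts) == 0) {
      return(tibble::tibble())
    }
    s1 <- stage1_predict(g, grs, covariates = stage1_covariates)
    out <- mr_phewas(s1, g, pm_g, covariates = covariates)
    dplyr::mutate(out, stratum = nm, .before = 1)
  })
  results <- dplyr::bind_rows(res)
  het <- results |>
    dplyr::filter(.data$converged) |>
    dplyr::select("stratum", "phecode", "beta", "se") |>
    tidyr::pivot_wider(names_from = "stratum",
                       values_from = c("beta", "se")) |>
    dplyr::filter(!is.na(.data$beta_with) & !is.na(.data$beta_without))
  het <- if (nrow(het)) {
    dplyr::bind_cols(
      het["phecode"],
      heterogeneity_two_strata(het$beta_with, het$se_with,
                               het$beta_without, het$se_without)
    )
  } else {
    tibble::tibble(phecode = character(0), z = numeric(0),
                   p_value = numeric(0))
  }
  structure(list(stratum = stratum, results = results, heterogeneity = het),
            class = "mr_stratified")
}

#' @export
print.mr_stratified <- function(x, ...) {
  cat("<mr_stratified> by", x$stratum$name, "status:",
      nrow(x$results), "stratum-phecode results,",
      nrow(x$heterogeneity), "heterogeneity tests\n")
  invisible(x)
}

#' Cross-population concordance of phenome sweeps
#'
#' Joins two result sets on phecode, counts the phenome-wide-significant sets
#' (Venn counts for A-only, B-only, both), tests direction concordance among
#' the union of significant phecodes (chi-square goodness-of-fit against
#' one half), and compares standardized effects: Z-prime values via
#' [zprime()] and their best-fit slope via [effect_slope()] (A on B).
#'
#' @param results_a,results_b `phewas_result` tibbles.
#' @param alpha_a,alpha_b Significance thresholds for each set (e.g. from
#'   [bonferroni_threshold()]).
#' @return A list of class `concordance_summary`: `venn` (named counts),
#'   `concordance` (tibble from [direction_concordance()]), `slope` (tibble
#'   from [effect_slope()]), and `data` (the joined per-phecode table).
#' @export
concordance_summary <- function(results_a, results_b, alpha_a, alpha_b) {
  a <- tibble::as_tibble(results_a) |> dplyr::filter(.data$converged)
  b <- tibble::as_tibble(results_b) |> dplyr::filter(.data$converged)
  joined <- dplyr::inner_join(a, b, by = "phecode",
                              suffix = c("_a", "_b"))
  if (nrow(joined) == 0) abort("No phecodes shared between the two result sets.")
  joined <- joined |>
    dplyr::mutate(
      sig_a = .data$p_value_a < alpha_a,
      sig_b = .data$p_value_b < alpha_b,
      zprime_a = zprime(.data$beta_a, .data$se_a,
                        .data$n_case_a + .data$n_control_a),
      zprime_b = zprime(.data$beta_b, .data$se_b,
                        .data$n_case_b + .data$n_control_b)
    )
  venn <- c(a_only = sum(joined$sig_a & !joined$sig_b),
            b_only = sum(!joined$sig_a & joined$sig_b),
            both = sum(joined$sig_a & joined$sig_b))
  union_sig <- dplyr::filter(joined, .data$sig_a | .data$sig_b)
  conc <- if (nrow(union_sig) >= 2) {
    direction_concordance(union_sig$beta_a, union_sig$beta_b)
  } else {
    tibble::tibble(n_pairs = nrow(union_sig), n_concordant = NA_integer_,
                   proportion = NA_real_, statistic = NA_real_,
                   p_value = NA_real_)
  }
  slope <- if (nrow(union_sig) >= 3) {
    effect_slope(union_sig$zprime_a, union_sig$zprime_b)
  } else {
    tibble::tibble(slope = NA_real_, conf_low = NA_real_,
                   conf_high = NA_real_, r = NA_real_, n = nrow(union_sig))
  }
  structure(list(venn = venn, concordance = conc, slope = slope,
                 data = joined),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("<concordance_summary>\n")
  cat("  significant: A-only", x$venn[["a_only"]],
      "| B-only", x$venn[["b_only"]], "| both", x$venn[["both"]], "\n")
  if (!is.na(x$concordance$proportion)) {
    cat(sprintf("  direction concordance %.1f%% (%d/%d), p = %.3g\n",
                100 * x$concordance$proportion, x$concordance$n_concordant,
                x$concordance$n_pairs, x$concordance$p_value))
  }
  if (!is.na(x$slope$slope)) {
    cat(sprintf("  Z' slope %.2f [%.2f, %.2f], r = %.2f\n", x$slope$slope,
                x$slope$conf_low, x$slope$conf_high, x$slope$r))
  }
  invisible(x)
}
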