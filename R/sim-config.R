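#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set that [simulate_cohort()] consumes.
#' The defaults emulate the statistical structure of a large multi-population
#' EHR biobank in which a European-ancestry-derived height instrument explains
#' about 18% of height variance in the majority population and is attenuated
#' in a second population (attenuation factor 0.52, giving a realized R\eqn{^2}
#' near 4.8%).
#'
#' Phecode liabilities follow a logistic model
#' \deqn{\mathrm{logit}\, p_{ik} = \alpha_k + \gamma_k z(H_i) + \delta_k z(U_i)
#'   + \beta_{age}(age_i - 60) + \beta_{sex} sex_i}
#' where \eqn{H} is height, \eqn{U} a latent non-genetic confounder shared
#' with height, and \eqn{z(\cdot)} a within-population z-score. Phecodes are
#' split into three classes: *causal* (\eqn{\gamma_k} = `gamma_scale`,
#' \eqn{\delta_k = 0}), *confounded* (\eqn{\gamma_k = 0}, \eqn{\delta_k} =
#' `confounder_scale`) and *null* (both zero).
#'
#' @param n_individuals Number of individuals.
#' @param n_variants Number of instrument variants.
#' @param allele_freq_range Range (length-2, in (0,1)) from which effect-allele
#'   frequencies are drawn uniformly.
#' @param target_r2 Fraction of covariate-adjusted height variance explained by
#'   the true genetic score in the reference (least attenuated) population.
#' @param n_phecodes Number of simulated phecodes.
#' @param effect_classes Named proportions over `c(causal, confounded, null)`;
#'   must sum to 1.
#' @param gamma_scale Log-odds per SD of height for causal phecodes.
#' @param confounder_scale Log-odds per SD of the confounder for confounded
#'   phecodes.
#' @param confounder_height_sd SD (cm) of the confounder's contribution to
#'   height; links the confounder to measured height.
#' @param baseline_prevalence_range Range of baseline phecode prevalences.
#' @param populations Data frame with columns `label`, `fraction` (sampling
#'   fractions summing to 1) and `attenuation` (scalar multiplier
#'   \eqn{a \in (0,1]} on the true per-allele effects).
#' @param one_code_fraction Fraction of non-cases that emit exactly one
#'   qualifying diagnosis code (exercising the two-code case rule).
#' @param seed Integer seed; every downstream draw derives from it.
#'
#' @return A `sim_config` list.
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 500, n_variants = 20, seed = 7)
sim_config <- function(n_individuals = 1000,
                       n_variants = 100,
                       allele_freq_range = c(0.05, 0.95),
                       target_r2 = 0.18,
                       n_phecodes = 60,
                       effect_classes = c(causal = 1 / 3, confounded = 1 / 3, null = 1 / 3),
                       gamma_scale = 0.3,
                       confounder_scale = 0.3,
                       confounder_height_sd = 2,
                       baseline_prevalence_range = c(0.05, 0.25),
                       populations = data.frame(
                         label = c("EA", "AA"),
                         fraction = c(0.79, 0.21),
                         attenuation = c(1.0, 0.52)
                       ),
                       one_code_fraction = 0.05,
                       seed = 1L) {
  stopifnot(n_individuals >= 0, n_variants >= 1, n_phecodes >= 0)
  if (length(allele_freq_range) != 2 || any(allele_freq_range <= 0) ||
      any(allele_freq_range >= 1) || diff(allele_freq_range) < 0) {
    abort("`allele_freq_range` must be an increasing pair inside (0, 1).")
  }
  if (!(target_r2 > 0 && target_r2 < 1)) {
    abort("`target_r2` must lie in (0, 1).")
  }
  if (!all(c("causal", "confounded", "null") %in% names(effect_classes))) {
    abort("`effect_classes` needs named entries causal, confounded, null.")
  }
  if (abs(sum(effect_classes) - 1) > 1e-8) {
    abort("`effect_classes` proportions must sum to 1.")
  }
  if (any(effect_classes < 0)) abort("`effect_classes` proportions must be >= 0.")
  populations <- tibble::as_tibble(populations)
  stopifnot(all(c("label", "fraction", "attenuation") %in% names(populations)))
  if (abs(sum(populations$fraction) - 1) > 1e-8) {
    abort("Population sampling fractions must sum to 1.")
  }
  if (any(populations$attenuation <= 0) || any(populations$attenuation > 1)) {
    abort("Attenuation factors must lie in (0, 1].")
  }
  if (length(baseline_prevalence_range) != 2 ||
      any(baseline_prevalence_range <= 0) || any(baseline_prevalence_range >= 1)) {
    abort("`baseline_prevalence_range` must be a pair inside (0, 1).")
  }
  stopifnot(one_code_fraction >= 0, one_code_fraction < 1)
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    allele_freq_range = as.numeric(allele_freq_range),
    target_r2 = as.numeric(target_r2),
    n_phecodes = as.integer(n_phecodes),
    effect_classes = effect_classes[c("causal", "confounded", "null")],
    gamma_scale = as.numeric(gamma_scale),
    confounder_scale = as.numeric(confounder_scale),
    confounder_height_sd = as.numeric(confounder_height_sd),
    baseline_prevalence_range = as.numeric(baseline_prevalence_range),
    populations = populations,
    one_code_fraction = as.numeric(one_code_fraction),
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  individuals:", x$n_individuals, " variants:", x$n_variants,
      " phecodes:", x$n_phecodes, "\n")
  cat("  target R2:", x$target_r2, " gamma:", x$gamma_scale,
      " delta:", x$confounder_scale, "\n")
  cat("  populations:", paste(sprintf("%s (%.0f%%, a=%.2f)", x$populations$label,
      100 * x$populations$fraction, x$populations$attenuation), collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
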