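#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the first-stage instrumental regression
#'
#' @param x A `stage1_fit`.
#' @param ... Unused.
#' @return Tibble of first-stage terms: `term`, `estimate`, `std_error`.
#' @exportS3Method generics::tidy
tidy.stage1_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of the first-stage fit
#'
#' @param x A `stage1_fit`.
#' @param ... Unused.
#' @return Tibble: `n`, `f_statistic`, `r_squared`, `sd_height`,
#'   `weak_instrument`.
#' @exportS3Method generics::glance
glance.stage1_fit <- function(x, ...) {
  tibble::tibble(n = x$n, f_statistic = x$f_statistic,
                 r_squared = x$r_squared, sd_height = x$sd_height,
                 weak_instrument = x$weak_instrument)
}

#' One-row summary of a phenome sweep
#'
#' @param x A `phewas_result`.
#' @param ... Unused.
#' @return Tibble: `model`, `n_phecodes`, `n_converged`,
#'   `bonferroni_threshold`.
#' @exportS3Method generics::glance
glance.phewas_result <- function(x, ...) {
  tibble::tibble(
    model = attr(x, "model") %||% x$model[1],
    n_phecodes = nrow(x),
    n_converged = sum(x$converged),
    bonferroni_threshold = bonferroni_threshold(max(1, nrow(x)))
  )
}

#' Tidy a stratified MR analysis into its heterogeneity table
#'
#' @param x An `mr_stratified`.
#' @param ... Unused.
#' @return Tibble: `phecode`, `z`, `p_value`.
#' @exportS3Method generics::tidy
tidy.mr_stratified <- function(x, ...) {
  x$heterogeneity
}

#' One-row summary of a cross-population concordance analysis
#'
#' @param x A `concordance_summary`.
#' @param ... Unused.
#' @return Tibble combining Venn counts, direction concordance and the
#'   Z-prime slope.
#' @exportS3Method generics::glance
glance.concordance_summary <- function(x, ...) {
  tibble::tibble(
    n_a_only = x$venn[["a_only"]], n_b_only = x$venn[["b_only"]],
    n_both = x$venn[["both"]],
    concordance = x$concordance$proportion,
    concordance_p = x$concordance$p_value,
    zprime_slope = x$slope$slope,
    zprime_slope_low = x$slope$conf_low,
    zprime_slope_high = x$slope$conf_high
  )
}
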