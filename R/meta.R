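#' Reconstruct a standard error from an estimate and its p-value
#'
#' Inverts the two-sided normal test: `se = |beta| / z` where
#' `z` is the upper `p/2` standard normal quantile, evaluated with
#' `qnorm(..., lower.tail = FALSE)` so the far tail is accurate; p-values
#' below the smallest representable double can be supplied on the log scale.
#' Used to rebuild summary statistics (e.g. meta-analysis inputs) from
#' printed odds ratios and p-values.
#'
#' @param beta Nonzero effect estimate(s).
#' @param p Two-sided p-value(s) in (0, 1), or log p-values if
#'   `log_p = TRUE`.
#' @param log_p Interpret `p` as `log(p)`.
#' @return Standard error(s).
#' @seealso [p_from_estimate()] for the inverse.
#' @export
#' @examples
#' se_from_p(1, 0.3173105) # z = 1, se = 1
#' se_from_p(log(1.47), 2.0e-41)
se_from_p <- function(beta, p, log_p = FALSE) {
  if (any(beta == 0)) abort("`beta` must be nonzero (z undefined at 0).")
  if (log_p) {
    if (any(p >= 0)) abort("log p-values must be negative.")
    z <- qnorm(p - log(2), lower.tail = FALSE, log.p = TRUE)
  } else {
    if (any(p <= 0 | p >= 1)) abort("`p` must lie strictly in (0, 1).")
    z <- qnorm(p / 2, lower.tail = FALSE)
  }
  abs(beta) / z
}

#' Two-sided normal p-value from an estimate and standard error
#'
#' @param beta,se Numeric vectors; `se > 0`.
#' @param log_p Return `log(p)` (accurate far past 1e-300).
#' @return Two-sided p-value(s), or their logs.
#' @export
p_from_estimate <- function(beta, se, log_p = FALSE) {
  if (any(se <= 0)) abort("`se` must be positive.")
  if (log_p) {
    log(2) + pnorm(abs(beta) / se, lower.tail = FALSE, log.p = TRUE)
  } else {
    2 * pnorm(-abs(beta) / se)
  }
}

#' Inverse-variance weighted fixed-effects meta-analysis
#'
#' Combines per-stratum estimates with weights \eqn{w_i = 1/se_i^2}:
#' \eqn{\beta = \sum w_i \beta_i / \sum w_i}, \eqn{se = 1/\sqrt{\sum w_i}},
#' with Cochran's Q heterogeneity statistic
#' \eqn{Q = \sum w_i (\beta_i - \beta)^2} referred to chi-square on
#' \eqn{k - 1} degrees of freedom. With a single stratum the input is
#' returned unchanged (Q = 0, heterogeneity p = 1 by convention).
#'
#' @param estimates Data frame with columns `beta` and `se` (one row per
#'   stratum; an optional `stratum` column is echoed in the output).
#' @return A one-row `meta_result` tibble: `beta`, `se`, `or`, `p_value`,
#'   `k`, `q_statistic`, `het_p_value`, plus a `strata` attribute echoing the
#'   inputs.
#' @export
#' @examples
#' ivw_meta(data.frame(beta = c(0.2, 0.4), se = c(0.1, 0.1)))
ivw_meta <- function(estimates) {
  estimates <- tibble::as_tibble(estimates)
  stopifnot(all(c("beta", "se") %in% names(estimates)))
  if (nrow(estimates) < 1) abort("At least one stratum is required.")
  if (any(!is.finite(estimates$se)) || any(estimates$se <= 0)) {
    abort("All standard errors must be positive and finite.")
  }
  w <- 1 / estimates$se^2
  k <- nrow(estimates)
  beta <- sum(w * estimates$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (estimates$beta - beta)^2)
  het_p <- if (k > 1) pchisq(q, df = k - 1, lower.tail = FALSE) else 1
  out <- tibble::tibble(
    beta = beta, se = se, or = exp(beta),
    p_value = p_from_estimate(beta, se),
    k = k, q_statistic = q, het_p_value = het_p
  )
  class(out) <- c("meta_result", class(out))
  attr(out, "strata") <- estimates
  out
}

#' Heterogeneity test between two strata
#'
#' Two-sample z test on the difference of estimates,
#' \eqn{z = (\beta_1 - \beta_2)/\sqrt{se_1^2 + se_2^2}}, whose squared value
#' equals Cochran's Q with one degree of freedom on the same inputs.
#'
#' @param beta1,se1,beta2,se2 Estimates and standard errors for the two
#'   strata.
#' @return A tibble `z`, `p_value`.
#' @export
#' @examples
#' heterogeneity_two_strata(0, 1, 2.771, 1) # z = -1.96, p = 0.05
heterogeneity_two_strata <- function(beta1, se1, beta2, se2) {
  if (any(c(se1, se2) <= 0)) abort("Standard errors must be positive.")
  z <- (beta1 - beta2) / sqrt(se1^2 + se2^2)
  tibble::tibble(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Meta-analyse two phenome sweeps phecode by phecode
#'
#' Joins two (or more) `phewas_result` tables on phecode and runs
#' [ivw_meta()] per phecode over the converged strata. METAL-style behaviour:
#' a phecode present in only one stratum is carried through with k = 1.
#'
#' @param ... Named `phewas_result` tibbles (names become stratum labels), or
#'   a single list of them.
#' @return A tibble: `phecode`, `beta`, `se`, `or`, `p_value`, `k`,
#'   `q_statistic`, `het_p_value`.
#' @export
meta_phewas <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1 && is.list(inputs[[1]]) &&
      !is.data.frame(inputs[[1]])) {
    inputs <- inputs[[1]]
  }
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    names(inputs) <- paste0("stratum", seq_along(inputs))
  }
  long <- purrr::imap(inputs, function(res, nm) {
    dplyr::transmute(tibble::as_tibble(res),
                     phecode = .data$phecode, stratum = nm,
                     beta = .data$beta, se = .data$se,
                     converged = .data$converged)
  }) |>
    dplyr::bind_rows() |>
    dplyr::filter(.data$converged, is.finite(.data$beta), is.finite(.data$se))
  if (nrow(long) == 0) abort("No converged results to meta-analyse.")
  long |>
    dplyr::group_by(phecode = .data$phecode) |>
    dplyr::group_modify(~ ivw_meta(.x[, c("stratum", "beta", "se")])) |>
    dplyr::ungroup()
}
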