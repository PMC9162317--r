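#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit (via the binomial IRLS of
#' `stats::glm.fit`) with a convergence tolerance of 1e-8 on the deviance
#' scale, at most 25 iterations, Wald standard errors from the inverse
#' observed information at the final iterate, and two-sided normal p-values.
#' Rows with any missing value are dropped (listwise deletion). Complete or
#' quasi-complete separation (any fitted probability numerically at 0 or 1
#' with a diverging coefficient) flags the fit as not converged; sweeps skip
#' such results rather than aborting.
#'
#' @param y Binary 0/1 response.
#' @param x Numeric design matrix. An intercept column is *not* added
#'   automatically.
#' @return A tibble with one row per column of `x`: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`; attributes `converged` (logical)
#'   and `n` (rows used).
#' @export
#' @examples
#' # saturated 2x2 table: log-odds ratio ln(40*80/(60*20))
#' y <- rep(c(1, 0, 1, 0), c(40, 60, 20, 80))
#' x <- cbind(intercept = 1, x = rep(c(1, 0), c(100, 100)))
#' fit_logistic(y, x)
fit_logistic <- function(y, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  ok <- complete.cases(x) & !is.na(y)
  y <- y[ok]
  x <- x[ok, , drop = FALSE]
  if (!all(y %in% c(0, 1))) abort("`y` must be binary 0/1.")
  if (qr(x)$rank < ncol(x)) {
    abort("Design matrix is rank deficient (constant or collinear columns).")
  }
  fit <- suppressWarnings(stats::glm.fit(
    x, y,
    family = binomial(),
    control = glm.control(epsilon = 1e-8, maxit = 25)
  ))
  eps <- 1e-10
  separated <- (any(fit$fitted.values < eps) || any(fit$fitted.values > 1 - eps)) &&
    max(abs(fit$coefficients), na.rm = TRUE) > 15
  converged <- isTRUE(fit$converged) && !fit$boundary && !separated
  p1 <- seq_len(fit$rank)
  cov_unscaled <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  se <- sqrt(diag(cov_unscaled))
  est <- fit$coefficients
  z <- est / se
  out <- tibble::tibble(
    term = colnames(x),
    estimate = unname(est),
    std_error = unname(se),
    statistic = unname(z),
    p_value = 2 * pnorm(-abs(unname(z)))
  )
  attr(out, "converged") <- converged
  attr(out, "n") <- length(y)
  out
}
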