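#' Compute a weighted genetic risk score
#'
#' Scores each individual as the weighted sum of effect-allele dosages,
#' \eqn{GRS_i = \sum_j \beta_j d_{ij}}. Variants are matched to the weight
#' table by id and verified against the allele pair: when the stored counted
#' allele is the weight table's *other* allele the dosage is flipped to
#' \eqn{2 - d}; when neither orientation matches the variant is dropped and
#' logged. Missing dosages are mean-imputed as twice the cohort effect-allele
#' frequency, which preserves the score mean.
#'
#' @param dosages A [dosage_set()].
#' @param weights Weight table with `rsid`, `effect_allele`, `other_allele`,
#'   `beta` (see [read_weights()]).
#' @param max_unmatched Fraction of weight variants allowed to go unmatched
#'   before a hard error (default 0.5).
#' @return A tibble `person_id`, `grs`, with a `match_log` attribute: one row
#'   per weight variant with `status` in matched / flipped / dropped and the
#'   drop reason.
#' @export
#' @examples
#' ds <- dosage_set(matrix(c(2, 1, 0, 1), 2, 2,
#'                         dimnames = list(c("a", "b"), c("v1", "v2"))),
#'                  data.frame(id = c("v1", "v2"), counted_allele = c("A", "C"),
#'                             other_allele = c("G", "T")))
#' w <- data.frame(rsid = c("v1", "v2"), effect_allele = c("A", "T"),
#'                 other_allele = c("G", "C"), beta = c(0.1, -0.2))
#' compute_grs(ds, w)
compute_grs <- function(dosages, weights, max_unmatched = 0.5) {
  stopifnot(inherits(dosages, "dosage_set"))
  weights <- tibble::as_tibble(weights)
  stopifnot(all(c("rsid", "effect_allele", "other_allele", "beta") %in%
                  names(weights)))
  v <- dosages$variants
  idx <- match(weights$rsid, v$id)
  status <- rep("dropped", nrow(weights))
  reason <- ifelse(is.na(idx), "absent from dosage data", NA_character_)
  found <- !is.na(idx)
  same <- found & v$counted_allele[idx] == weights$effect_allele &
    v$other_allele[idx] == weights$other_allele
  swap <- found & v$counted_allele[idx] == weights$other_allele &
    v$other_allele[idx] == weights$effect_allele
  status[same] <- "matched"
  status[swap] <- "flipped"
  mism <- found & !same & !swap
  reason[mism] <- "allele pair mismatch"
  match_log <- tibble::tibble(rsid = weights$rsid, status = status,
                              reason = reason)

  n_unmatched <- sum(status == "dropped")
  if (nrow(weights) > 0 && n_unmatched / nrow(weights) > max_unmatched) {
    abort(sprintf("%d of %d weight variants could not be matched (> %.0f%%).",
                  n_unmatched, nrow(weights), 100 * max_unmatched))
  }

  use <- which(status != "dropped")
  mat <- dosages$matrix[, idx[use], drop = FALSE]
  flip_col <- status[use] == "flipped"
  if (any(flip_col)) {
    mat[, flip_col] <- 2 - mat[, flip_col, drop = FALSE]
  }
  # mean imputation of missing effect-allele dosages
  if (anyNA(mat)) {
    cm <- colMeans(mat, na.rm = TRUE)
    cm[is.nan(cm)] <- 0
    na_idx <- which(is.na(mat), arr.ind = TRUE)
    mat[na_idx] <- cm[na_idx[, 2]]
  }
  grs <- unname(drop(mat %*% weights$beta[use]))
  out <- tibble::tibble(
    person_id = rownames(dosages$matrix) %||% as.character(seq_len(nrow(dosages$matrix))),
    grs = if (length(use)) grs else rep(0, nrow(dosages$matrix))
  )
  attr(out, "match_log") <- match_log
  out
}

#' Variance in a trait explained by a score
#'
#' Least-squares \eqn{R^2} of the trait on the score; with covariates, the
#' partial \eqn{R^2} of the score given the covariates (both trait and score
#' residualized on the covariates first). The F statistic is
#' \eqn{R^2 (n-2) / (1-R^2)} for the single-predictor case.
#'
#' @param score,trait Numeric vectors (pairs with `NA` are dropped).
#' @param covariates Optional numeric matrix or data frame of covariates.
#' @return A tibble with `r_squared`, `f_statistic`, `n`.
#' @export
variance_explained <- function(score, trait, covariates = NULL) {
  ok <- is.finite(score) & is.finite(trait)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & complete.cases(covariates)
  }
  score <- score[ok]; trait <- trait[ok]
  n <- length(score)
  if (n < 3) abort("At least 3 complete observations are required.")
  if (sd(score) == 0) {
    abort("Zero-variance score: R^2 undefined (weak/degenerate instrument).")
  }
  if (!is.null(covariates)) {
    cv <- cbind(1, covariates[ok, , drop = FALSE])
    score <- stats::lm.fit(cv, score)$residuals
    trait <- stats::lm.fit(cv, trait)$residuals
    if (sd(score) == 0) {
      abort("Score is collinear with the covariates: partial R^2 undefined.")
    }
  }
  r2 <- stats::cor(score, trait)^2
  tibble::tibble(r_squared = r2,
                 f_statistic = r2 * (n - 2) / (1 - r2),
                 n = n)
}

#' Direction concordance between two sets of effect estimates
#'
#' Proportion of paired estimates with the same sign (pairs where either
#' estimate is exactly zero are excluded) and a 1-df chi-square
#' goodness-of-fit p-value of the concordant count against the null
#' expectation of one half. An exact binomial test is available as an
#' alternative.
#'
#' @param beta_a,beta_b Paired numeric vectors.
#' @param method `"chisq"` (default, goodness-of-fit) or `"binomial"`
#'   (exact).
#' @return A tibble `n_pairs`, `n_concordant`, `proportion`, `statistic`
#'   (`NA` for the binomial method), `p_value`.
#' @export
direction_concordance <- function(beta_a, beta_b, method = c("chisq", "binomial")) {
  method <- match.arg(method)
  stopifnot(length(beta_a) == length(beta_b))
  use <- is.finite(beta_a) & is.finite(beta_b) & beta_a != 0 & beta_b != 0
  n <- sum(use)
  if (n < 2) abort("Fewer than 2 usable (nonzero, finite) pairs.")
  conc <- sum(sign(beta_a[use]) == sign(beta_b[use]))
  if (method == "chisq") {
    expd <- n / 2
    stat <- (conc - expd)^2 / expd + ((n - conc) - expd)^2 / expd
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stat <- NA_real_
    p <- stats::binom.test(conc, n, 0.5)$p.value
  }
  tibble::tibble(n_pairs = n, n_concordant = conc, proportion = conc / n,
                 statistic = stat, p_value = p)
}

#' Standardized effect size Z-prime
#'
#' Standardizes a beta coefficient to its standard error and the square root
#' of the sample size: \eqn{Z' = \beta / (se \sqrt{n})}. Used to compare
#' effect sizes across samples of different size.
#'
#' @param beta,se,n Numeric vectors (recycled).
#' @return Numeric vector of Z' values.
#' @export
zprime <- function(beta, se, n) {
  if (any(se <= 0)) abort("Standard errors must be positive.")
  if (any(n <= 0)) abort("Sample sizes must be positive.")
  beta / (se * sqrt(n))
}

#' Slope of the best-fit line between two sets of effect sizes
#'
#' Ordinary least squares of `y_effects` on `x_effects` *with* intercept;
#' returns the slope, its Wald 95% confidence interval, and the Pearson
#' correlation.
#'
#' @param y_effects,x_effects Paired numeric vectors (at least 3 pairs).
#' @return A tibble `slope`, `conf_low`, `conf_high`, `r`, `n`.
#' @export
effect_slope <- function(y_effects, x_effects) {
  use <- is.finite(y_effects) & is.finite(x_effects)
  y <- y_effects[use]; x <- x_effects[use]
  if (length(x) < 3) abort("At least 3 complete pairs are required.")
  if (sd(x) == 0) abort("Zero variance in `x_effects`: slope undefined.")
  fit <- lm(y ~ x)
  est <- coef(fit)[["x"]]
  # direct Wald se (avoids summary.lm's perfect-fit warning on exact data)
  sigma2 <- sum(fit$residuals^2) / (length(x) - 2)
  se <- sqrt(sigma2 / sum((x - mean(x))^2))
  zq <- qnorm(0.975)
  tibble::tibble(slope = est, conf_low = est - zq * se,
                 conf_high = est + zq * se,
                 r = stats::cor(x, y), n = length(x))
}
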