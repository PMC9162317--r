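default_covariates <- function() c("age", "sex", paste0("PC", 1:10))

# Shared phenome-sweep engine: logistic regression of each phecode on an
# exposure plus covariates. Zero-variance covariate columns (e.g. sex in a
# sex-stratified run) are dropped automatically; a failing phecode never
# aborts the sweep.
sweep_logistic <- function(cohort, pm, exposure, covariates, model_tag) {
  stopifnot(inherits(pm, "phecode_matrix"))
  cohort <- tibble::as_tibble(cohort)
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) {
    abort(paste("Cohort is missing covariate columns:", paste(miss, collapse = ", ")))
  }
  cv <- as.matrix(cohort[, covariates, drop = FALSE])
  cc <- if (ncol(cv)) complete.cases(cv) else rep(TRUE, nrow(cohort))
  ok <- is.finite(exposure) & cc & cohort$person_id %in% pm$persons
  persons <- cohort$person_id[ok]
  xb <- cbind(intercept = 1, exposure = exposure[ok], cv[ok, , drop = FALSE])
  keep_col <- c(TRUE, TRUE, apply(cv[ok, , drop = FALSE], 2, function(z) {
    isTRUE(sd(z) > 0)
  }))
  xb <- xb[, keep_col, drop = FALSE]

  calls <- pm$calls[pm$calls$person_id %in% persons, , drop = FALSE]
  pos <- match(calls$person_id, persons)
  groups <- split(seq_len(nrow(calls)), calls$phecode)
  n <- length(persons)

  res <- purrr::map(pm$counts$phecode, function(code) {
    y <- rep(0L, n)
    g <- groups[[code]]
    if (!is.null(g)) {
      st <- calls$status[g]
      y[pos[g][st == "case"]] <- 1L
      y[pos[g][st == "missing"]] <- NA_integer_
    }
    use <- !is.na(y)
    row <- tibble::tibble(
      phecode = code, model = model_tag,
      n_case = sum(y[use] == 1L), n_control = sum(y[use] == 0L),
      beta = NA_real_, se = NA_real_, or = NA_real_, p_value = NA_real_,
      converged = FALSE, note = NA_character_
    )
    fit <- tryCatch(
      fit_logistic(y[use], xb[use, , drop = FALSE]),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      row$note <- conditionMessage(fit)
      return(row)
    }
    b <- fit[fit$term == "exposure", ]
    row$beta <- b$estimate
    row$se <- b$std_error
    row$or <- exp(b$estimate)
    row$p_value <- b$p_value
    row$converged <- isTRUE(attr(fit, "converged"))
    if (!row$converged) row$note <- "did not converge or separated"
    row
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("phewas_result", class(out))
  attr(out, "model") <- model_tag
  attr(out, "n_persons") <- n
  out
}

#' Phenome-wide association study of measured height
#'
#' Logistic regression of each retained phecode on the within-stratum height
#' Z-score, adjusting for age, sex and 10 principal components (the default
#' covariate set). The cohort passed in should be a single analysis stratum
#' (one population, optionally one sex); height is standardized to mean 0,
#' SD 1 within it, so effects are log-odds per SD of measured height.
#'
#' @param cohort Tibble with `person_id`, `height_cm` and the covariate
#'   columns.
#' @param pm A (filtered) `phecode_matrix`.
#' @param covariates Character vector of covariate column names.
#' @return A `phewas_result` tibble: `phecode`, `model`, `n_case`,
#'   `n_control`, `beta`, `se`, `or`, `p_value`, `converged`, `note`.
#'   Non-converged phecodes are flagged, not dropped, and never abort the
#'   sweep.
#' @export
phewas_measured <- function(cohort, pm, covariates = default_covariates()) {
  cohort <- tibble::as_tibble(cohort)
  stopifnot("height_cm" %in% names(cohort))
  h <- cohort$height_cm
  z <- (h - mean(h, na.rm = TRUE)) / sd(h, na.rm = TRUE)
  sweep_logistic(cohort, pm, z, covariates, "measured")
}

#' First stage of the two-stage least squares MR model
#'
#' Ordinary least squares of measured height on the genetic risk score,
#' adjusting for principal components (by default; age/sex can be added via
#' `covariates`). Genetically-predicted height is the fitted value,
#' standardized by centring and dividing by the SD of *measured* height, so
#' that one unit of predicted height corresponds to one measured-height
#' Z-score unit and PheWAS and MR-PheWAS effects share a per-SD scale.
#'
#' @param cohort Tibble with `person_id`, `height_cm` and covariate columns.
#' @param grs Tibble `person_id`, `grs` (e.g. from [compute_grs()]) or a
#'   numeric vector aligned with `cohort`.
#' @param covariates Covariates for the first-stage regression (default the
#'   10 PCs).
#' @return A `stage1_fit`: coefficients, first-stage F statistic for the
#'   score, partial R-squared, SD of measured height, and per-person
#'   standardized predictions. A first-stage F below 10 attaches a
#'   weak-instrument warning that propagates to downstream results.
#' @export
stage1_predict <- function(cohort, grs, covariates = paste0("PC", 1:10)) {
  cohort <- tibble::as_tibble(cohort)
  stopifnot("height_cm" %in% names(cohort))
  if (is.data.frame(grs)) {
    stopifnot(all(c("person_id", "grs") %in% names(grs)))
    g <- grs$grs[match(cohort$person_id, grs$person_id)]
  } else {
    stopifnot(length(grs) == nrow(cohort))
    g <- as.numeric(grs)
  }
  cv <- as.matrix(cohort[, covariates, drop = FALSE])
  cc <- if (ncol(cv)) complete.cases(cv) else rep(TRUE, nrow(cohort))
  ok <- is.finite(g) & is.finite(cohort$height_cm) & cc
  if (sum(ok) < 3) abort("Too few complete observations for the first stage.")
  g_ok <- g[ok]
  if (sd(g_ok) == 0) abort("Zero-variance genetic score: instrument degenerate.")
  x <- cbind(intercept = 1, grs = g_ok, cv[ok, , drop = FALSE])
  h <- cohort$height_cm[ok]
  fit <- stats::lm.fit(x, h)
  p1 <- seq_len(fit$rank)
  sigma2 <- sum(fit$residuals^2) / (length(h) - fit$rank)
  cov_un <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  se <- sqrt(diag(cov_un) * sigma2)
  f_stat <- (fit$coefficients[["grs"]] / se[[which(colnames(x) == "grs")]])^2
  sd_h <- sd(h)
  fitted <- h - fit$residuals
  hhat <- (fitted - mean(fitted)) / sd_h
  r2 <- variance_explained(g_ok, h,
                           covariates = if (ncol(cv)) cv[ok, , drop = FALSE])
  weak <- f_stat < 10
  if (weak) {
    warn(sprintf("Weak instrument: first-stage F = %.2f (< 10).", f_stat))
  }
  structure(list(
    coefficients = tibble::tibble(term = colnames(x),
                                  estimate = unname(fit$coefficients),
                                  std_error = unname(se)),
    f_statistic = unname(f_stat),
    r_squared = r2$r_squared,
    sd_height = sd_h,
    predicted = tibble::tibble(person_id = cohort$person_id[ok], hhat = hhat),
    n = sum(ok),
    weak_instrument = weak
  ), class = "stage1_fit")
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat("<stage1_fit> n = ", x$n, ", first-stage F = ", round(x$f_statistic, 1),
      ", partial R^2 = ", signif(x$r_squared, 3),
      if (x$weak_instrument) " [WEAK INSTRUMENT]", "\n", sep = "")
  invisible(x)
}

#' MR-PheWAS of genetically-predicted height (two-stage least squares)
#'
#' Second stage of the 2SLS model: logistic regression of each phecode on the
#' standardized genetically-predicted height from [stage1_predict()], plus
#' covariates. Effects are log-odds per SD of measured height, directly
#' comparable with [phewas_measured()]. With `add_bmi = TRUE` the model is
#' the BMI-adjusted sensitivity analysis (tag `"genetic+BMI"`; the cohort
#' must carry a `bmi` column). Standard errors are the naive second-stage
#' Wald errors with no first-stage correction, which is anti-conservative
#' when the instrument is weak — hence the propagated weak-instrument flag.
#'
#' @param stage1 A `stage1_fit` for the same stratum.
#' @param cohort,pm,covariates As in [phewas_measured()].
#' @param add_bmi Add BMI as a covariate (sensitivity model).
#' @return A `phewas_result` tibble (model `"genetic"` or `"genetic+BMI"`),
#'   with attribute `weak_instrument` echoed from the first stage.
#' @export
mr_phewas <- function(stage1, cohort, pm, covariates = default_covariates(),
                      add_bmi = FALSE) {
  stopifnot(inherits(stage1, "stage1_fit"))
  cohort <- tibble::as_tibble(cohort)
  hhat <- stage1$predicted$hhat[match(cohort$person_id,
                                      stage1$predicted$person_id)]
  if (add_bmi) {
    if (!"bmi" %in% names(cohort)) abort("`add_bmi = TRUE` needs a `bmi` column.")
    covariates <- union(covariates, "bmi")
  }
  tag <- if (add_bmi) "genetic+BMI" else "genetic"
  out <- sweep_logistic(cohort, pm, hhat, covariates, tag)
  attr(out, "weak_instrument") <- stage1$weak_instrument
  out
}

#' Bonferroni phenome-wide significance threshold
#'
#' `0.05 / n` for `n` phecodes actually tested in an analysis subset;
#' recompute it per population or sex stratum.
#'
#' @param n_phecodes_tested Positive count.
#' @param alpha Family-wise error rate (default 0.05).
#' @return The corrected threshold.
#' @export
#' @examples
#' bonferroni_threshold(1378) # 3.6e-5
bonferroni_threshold <- function(n_phecodes_tested, alpha = 0.05) {
  if (length(n_phecodes_tested) != 1 || is.na(n_phecodes_tested) ||
      n_phecodes_tested < 1) {
    abort("`n_phecodes_tested` must be a single count >= 1.")
  }
  alpha / n_phecodes_tested
}
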