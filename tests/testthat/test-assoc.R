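test_that("logistic engine matches the closed-form saturated 2x2 fit", {
  y <- rep(c(1, 0, 1, 0), c(40, 60, 20, 80))
  x <- cbind(intercept = 1, x = rep(c(1, 0), c(100, 100)))
  fit <- fit_logistic(y, x)
  b <- fit[fit$term == "x", ]
  expect_equal(b$estimate, log(40 * 80 / (60 * 20)), tolerance = 1e-6)
  expect_equal(b$std_error, sqrt(1 / 40 + 1 / 60 + 1 / 20 + 1 / 80),
               tolerance = 1e-6)
  expect_true(attr(fit, "converged"))
})

test_that("degenerate designs error and separation is flagged", {
  y <- rbinom(50, 1, 0.5)
  expect_error(fit_logistic(y, cbind(intercept = 1, x = rep(2, 50))),
               "rank deficient")
  # perfectly separating predictor: flagged, not an error
  ys <- rep(c(0, 1), each = 25)
  xs <- cbind(intercept = 1, x = ys * 2 - 1)
  fit <- fit_logistic(ys, xs)
  expect_false(attr(fit, "converged"))
})

test_that("null covariate effects are calibrated", {
  # y independent of x: estimate within +-3 se in the bulk of seeds
  inside <- vapply(1:20, function(s) {
    set.seed(s)
    x <- cbind(intercept = 1, x = rnorm(2000))
    y <- rbinom(2000, 1, 0.3)
    fit <- fit_logistic(y, x)
    b <- fit[fit$term == "x", ]
    abs(b$estimate) < 3 * b$std_error
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})

test_that("bonferroni thresholds reproduce the phenome-wide cutoffs", {
  expect_equal(signif(bonferroni_threshold(1378), 2), 3.6e-5)
  expect_equal(signif(bonferroni_threshold(997), 2), 5.0e-5)
  expect_equal(signif(bonferroni_threshold(1308), 2), 3.8e-5)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_error(bonferroni_threshold(0), "count")
})

test_that("a perfect instrument makes MR-PheWAS equal the measured PheWAS", {
  sim <- small_sim()
  ea <- dplyr::filter(sim$cohort, population == "EA")
  pm <- suppressMessages(assign_phecodes(sim$icd_events, sim$phecode_map,
                                         persons = sim$cohort$person_id))
  pmf <- suppressWarnings(filter_phecodes(subset_persons(pm, ea$person_id),
                                          50, 50))
  meas <- phewas_measured(ea, pmf)
  # GRS identical to height: first stage fits height exactly
  s1 <- stage1_predict(ea, tibble::tibble(person_id = ea$person_id,
                                          grs = ea$height_cm))
  mr <- mr_phewas(s1, ea, pmf)
  expect_equal(mr$beta, meas$beta, tolerance = 1e-6)
  expect_equal(mr$se, meas$se, tolerance = 1e-6)
  expect_equal(mr$or, exp(mr$beta))
})

test_that("first-stage predictions are on the measured-height SD scale", {
  sim <- small_sim()
  ea <- dplyr::filter(sim$cohort, population == "EA")
  grs <- compute_grs(sim$dosages, sim$weights)
  s1 <- stage1_predict(ea, grs)
  expect_equal(mean(s1$predicted$hhat), 0, tolerance = 1e-10)
  # one unit of predicted height is one measured-height SD, so the
  # variance of the predictions is the share of height variance captured
  expect_lt(abs(sd(s1$predicted$hhat)^2 - s1$r_squared), 0.01)
  expect_gt(s1$f_statistic, 10)
  expect_false(s1$weak_instrument)
  # zero-variance score errors
  expect_error(
    stage1_predict(ea, tibble::tibble(person_id = ea$person_id, grs = 0)),
    "Zero-variance"
  )
})

test_that("the 2SLS slope equals the Wald ratio on continuous outcomes", {
  cfg <- sim_config(n_individuals = 1000, n_variants = 30, n_phecodes = 0,
                    seed = 77)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  g <- co$score_true
  h <- co$height_cm
  set.seed(78)
  y <- 0.25 * h + rnorm(nrow(co), 0, 5) # continuous outcome
  s1 <- stage1_predict(co, g, covariates = character(0))
  xhat <- s1$predicted$hhat * s1$sd_height
  slope_2sls <- coef(lm(y ~ xhat))[["xhat"]]
  wald <- cov(y, g) / cov(h, g)
  expect_equal(slope_2sls, wald, tolerance = 1e-10)
})

test_that("negating the weights leaves MR estimates unchanged", {
  sim <- small_sim()
  ea <- dplyr::filter(sim$cohort, population == "EA")
  pm <- suppressMessages(assign_phecodes(sim$icd_events, sim$phecode_map,
                                         persons = sim$cohort$person_id))
  pmf <- suppressWarnings(filter_phecodes(subset_persons(pm, ea$person_id),
                                          50, 50))
  grs <- compute_grs(sim$dosages, sim$weights)
  s1 <- stage1_predict(ea, grs)
  neg <- dplyr::mutate(grs, grs = -grs)
  s1n <- stage1_predict(ea, neg)
  expect_equal(s1n$coefficients$estimate[s1n$coefficients$term == "grs"],
               -s1$coefficients$estimate[s1$coefficients$term == "grs"])
  mr <- mr_phewas(s1, ea, pmf)
  mrn <- mr_phewas(s1n, ea, pmf)
  expect_equal(mrn$beta, mr$beta, tolerance = 1e-8)
})

test_that("one pathological phecode never aborts the sweep", {
  sim <- small_sim()
  ea <- dplyr::filter(sim$cohort, population == "EA")
  pm <- suppressMessages(assign_phecodes(sim$icd_events, sim$phecode_map,
                                         persons = sim$cohort$person_id))
  pm <- subset_persons(pm, ea$person_id)
  # inject a phecode with a single case: glm still fits but the count is tiny;
  # and one with zero cases among analyzable persons, which errors inside
  pm$counts <- dplyr::bind_rows(
    pm$counts,
    tibble::tibble(phecode = "9999", n_case = 0L,
                   n_control = length(pm$persons), n_missing = 0L)
  )
  out <- phewas_measured(ea, pm)
  expect_equal(nrow(out), nrow(pm$counts))
  bad <- out[out$phecode == "9999", ]
  expect_false(bad$converged)
  expect_true(all(out$or[out$converged] ==
                    exp(out$beta[out$converged])))
})

test_that("BMI adjustment under a null BMI effect barely moves estimates", {
  sim <- small_sim()
  ea <- dplyr::filter(sim$cohort, population == "EA")
  set.seed(9)
  ea$bmi <- rnorm(nrow(ea), 30, 5) # BMI unrelated to the phenotypes
  pm <- suppressMessages(assign_phecodes(sim$icd_events, sim$phecode_map,
                                         persons = sim$cohort$person_id))
  pmf <- suppressWarnings(filter_phecodes(subset_persons(pm, ea$person_id),
                                          50, 50))
  grs <- compute_grs(sim$dosages, sim$weights)
  s1 <- stage1_predict(ea, grs)
  mr <- mr_phewas(s1, ea, pmf)
  mrb <- mr_phewas(s1, ea, pmf, add_bmi = TRUE)
  expect_equal(mrb$model[1], "genetic+BMI")
  expect_lt(max(abs(mrb$beta - mr$beta)), 0.02)
})
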