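test_that("manhattan table applies the sign, label and parent-level rules", {
  res <- fake_results(
    c("427.2", "427.21", "427.22", "411", "250.1"),
    beta = c(0.3, 0.31, -0.2, -0.25, 0.1),
    p = c(1e-8, 1e-6, 1e-5, 1e-4, 1e-3)
  )
  d <- manhattan_data(res)
  # signed -log10 p: negative beta below the axis
  expect_equal(d$signed_log10_p[d$phecode == "427.22"], -5)
  expect_equal(d$signed_log10_p[d$phecode == "427.2"], 8)
  # one label per group, at the lowest p
  circ <- d[d$group == "circulatory system", ]
  expect_equal(sum(circ$label), 1L)
  expect_equal(circ$phecode[circ$label], "427.2")
  # parent-level filter keeps 427.2 but drops 427.21 / 427.22
  dp <- manhattan_data(res, parent_only = TRUE)
  expect_true("427.2" %in% dp$phecode)
  expect_false(any(c("427.21", "427.22") %in% dp$phecode))
  # p = 0 is clamped with a warning
  res0 <- fake_results("100", beta = 1, p = 1e-10)
  res0$p_value <- 0
  expect_warning(d0 <- manhattan_data(res0), "clamped")
  expect_true(is.finite(d0$signed_log10_p))
})

test_that("non-converged fits never reach the plot tables", {
  res <- fake_results(c("100", "200"), beta = c(0.2, 0.4), p = c(0.01, 0.02))
  res$converged[2] <- FALSE
  expect_false("200" %in% manhattan_data(res)$phecode)
})

test_that("comparison scatter classifies significance categories", {
  a <- fake_results(1:6, beta = 0.4, p = c(1e-8, 1e-8, 1e-8, 0.5, 0.5, 0.5))
  b <- fake_results(1:6, beta = 0.4, p = c(1e-8, 0.5, 1e-8, 1e-8, 0.5, 0.5))
  sc <- comparison_scatter(a, b, 1e-5, 1e-5)
  expect_equal(sc$category,
               c("both", "a_only", "both", "b_only", "neither", "neither"))
  expect_equal(unname(attr(sc, "venn")), c(1, 1, 2))
  # identical inputs: everything on the diagonal, no one-sided sets
  sc2 <- comparison_scatter(a, a, 1e-5, 1e-5)
  expect_equal(sc2$or_a, sc2$or_b)
  expect_equal(unname(attr(sc2, "venn")[c("a_only", "b_only")]), c(0, 0))
  expect_error(comparison_scatter(a, fake_results(10:12, 0.1, 0.5),
                                  1e-5, 1e-5), "shared")
})

test_that("plot builders return ggplot objects", {
  res <- fake_results(c("427.2", "250.1", "707"), beta = c(0.3, -0.2, 0.15),
                      p = c(1e-8, 1e-4, 0.02))
  expect_s3_class(plot_manhattan(res, threshold = 1e-5), "ggplot")
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(
    plot_or_comparison(res, fake_results(c("427.2", "250.1", "707"),
                                         beta = c(0.2, -0.1, 0.1),
                                         p = c(1e-6, 0.03, 0.2)),
                       1e-5, 1e-5),
    "ggplot"
  )
})

test_that("the pipeline runs end to end, deterministically, with a manifest", {
  cfg <- sim_config(n_individuals = 2500, n_variants = 30, n_phecodes = 8,
                    baseline_prevalence_range = c(0.12, 0.25), seed = 19)
  sim <- simulate_cohort(cfg)
  fix <- withr::local_tempdir()
  paths <- write_cohort_fixture(sim, fix)
  run_cfg <- list(
    paths = as.list(paths[c("weights", "dosages", "sites", "covariates",
                            "height_measurements", "weight_measurements",
                            "icd_events", "phecode_map")]),
    min_cases = 30, min_controls = 30,
    add_bmi = TRUE,
    seed = 19,
    out_dir = file.path(fix, "out1")
  )
  out1 <- suppressWarnings(run_pipeline(run_cfg))
  expect_true(all(c("EA", "AA") %in% names(out1$results)))
  man <- out1$manifest
  # manifest arithmetic: input = retained + excluded at the height filter
  expect_equal(man$counts$persons_height_input,
               man$counts$persons_height_retained +
                 man$counts$persons_height_excluded)
  for (pop in names(man$populations)) {
    p <- man$populations[[pop]]
    expect_equal(p$n_phecodes_input,
                 p$n_phecodes_tested + p$n_phecodes_filtered)
    expect_equal(p$significance_threshold, 0.05 / p$n_phecodes_tested)
  }
  # variant accounting covers the whole weight table
  expect_equal(man$counts$variants_matched + man$counts$variants_flipped +
                 man$counts$variants_dropped, nrow(sim$weights))
  # meta present (two populations) and BMI sensitivity model written
  expect_false(is.null(out1$meta))
  expect_true(file.exists(file.path(fix, "out1", "genetic_bmi_EA.tsv")))
  # byte-identical re-run
  run_cfg$out_dir <- file.path(fix, "out2")
  out2 <- suppressWarnings(run_pipeline(run_cfg))
  for (f1 in out1$files) {
    f2 <- sub("out1", "out2", f1, fixed = TRUE)
    expect_identical(readLines(f1), readLines(f2), info = basename(f1))
  }
})

test_that("a missing ICD file aborts naming the phenotype-QC stage", {
  cfg <- sim_config(n_individuals = 50, n_variants = 5, n_phecodes = 2,
                    seed = 23)
  sim <- simulate_cohort(cfg)
  fix <- withr::local_tempdir()
  paths <- write_cohort_fixture(sim, fix)
  file.remove(paths[["icd_events"]])
  run_cfg <- list(
    paths = as.list(paths[c("weights", "dosages", "sites", "covariates",
                            "height_measurements", "weight_measurements",
                            "icd_events", "phecode_map")]),
    out_dir = file.path(fix, "out")
  )
  expect_error(run_pipeline(run_cfg), "pheno_qc")
})

test_that("run configs load from YAML and JSON", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("out_dir: /tmp/x", "min_cases: 100", "add_bmi: true"), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$min_cases, 100)
  expect_true(cfg$add_bmi)
  j <- withr::local_tempfile(fileext = ".json")
  writeLines('{"out_dir": "/tmp/x", "min_cases": 100}', j)
  expect_equal(read_run_config(j)$min_cases, 100)
  expect_error(read_run_config("/nonexistent/path.yaml"), "does not exist")
})

test_that("phecode groups map numeric ranges to body systems", {
  expect_equal(phecode_group(c("427.2", "250.1", "710", "008")),
               c("circulatory system", "endocrine/metabolic",
                 "musculoskeletal", "infectious diseases"))
  expect_equal(phecode_group("not-a-code"), "other")
})

test_that("tidy and glance methods summarise fitted objects", {
  sim <- small_sim()
  ea <- dplyr::filter(sim$cohort, population == "EA")
  grs <- compute_grs(sim$dosages, sim$weights)
  s1 <- stage1_predict(ea, grs)
  td <- tidy(s1)
  expect_true(all(c("term", "estimate", "std_error") %in% names(td)))
  expect_true("grs" %in% td$term)
  gl <- glance(s1)
  expect_equal(gl$n, s1$n)
  expect_false(gl$weak_instrument)
})
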