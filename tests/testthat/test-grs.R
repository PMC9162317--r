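test_that("scores are the weighted sum of effect-allele dosages", {
  # beta {0.1, -0.2, 0.05} with dosages {2, 1, 0}: 0.2 - 0.2 + 0 = 0
  g <- compute_grs(toy_dosages(), toy_weights())
  expect_equal(g$grs[g$person_id == "p1"], 0)
  expect_equal(g$grs[g$person_id == "p2"], 0.1 - 0.2 + 0.1)
  # zero weights give zero scores
  g0 <- compute_grs(toy_dosages(), toy_weights(beta = c(0, 0, 0)))
  expect_true(all(g0$grs == 0))
})

test_that("swapped alleles flip the dosage to 2 - d", {
  ds <- dosage_set(matrix(0.5, 1, 1, dimnames = list("p1", "v1")),
                   data.frame(id = "v1", counted_allele = "G",
                              other_allele = "A"))
  w <- data.frame(rsid = "v1", effect_allele = "A", other_allele = "G",
                  beta = 0.1)
  g <- compute_grs(ds, w)
  expect_equal(g$grs, 0.1 * (2 - 0.5))
  expect_equal(attr(g, "match_log")$status, "flipped")
})

test_that("allele-flip involution and weight linearity hold", {
  sim <- small_sim()
  base <- compute_grs(sim$dosages, sim$weights)
  # flip every stored column: counted <-> other, d -> 2 - d
  flipped <- sim$dosages
  flipped$matrix <- 2 - flipped$matrix
  tmp <- flipped$variants$counted_allele
  flipped$variants$counted_allele <- flipped$variants$other_allele
  flipped$variants$other_allele <- tmp
  g2 <- compute_grs(flipped, sim$weights)
  expect_equal(g2$grs, base$grs, tolerance = 1e-12)
  # scaling all weights scales every score
  w3 <- sim$weights
  w3$beta <- w3$beta * 3
  g3 <- compute_grs(sim$dosages, w3)
  expect_equal(g3$grs, 3 * base$grs, tolerance = 1e-12)
  # permuting weight rows leaves scores unchanged
  g4 <- compute_grs(sim$dosages, sim$weights[rev(seq_len(nrow(sim$weights))), ])
  expect_equal(g4$grs, base$grs, tolerance = 1e-12)
})

test_that("mismatched variants are dropped and excess triggers an error", {
  w <- toy_weights()
  w$effect_allele[3] <- "T"
  w$other_allele[3] <- "C" # neither orientation matches v3 (G/A)
  g <- compute_grs(toy_dosages(), w)
  log <- attr(g, "match_log")
  expect_equal(log$status[3], "dropped")
  expect_equal(log$reason[3], "allele pair mismatch")
  # > 50% unmatched is a hard error
  w2 <- toy_weights()
  w2$rsid <- c("v1", "zz1", "zz2")
  expect_error(compute_grs(toy_dosages(), w2), "could not be matched")
})

test_that("missing dosages are imputed at twice the effect-allele frequency", {
  mat <- matrix(c(2, 0, NA, 1, 1, 1), 3, 2,
                dimnames = list(c("p1", "p2", "p3"), c("v1", "v2")))
  ds <- dosage_set(mat, data.frame(id = c("v1", "v2"),
                                   counted_allele = c("A", "A"),
                                   other_allele = c("G", "G")))
  w <- data.frame(rsid = c("v1", "v2"), effect_allele = "A",
                  other_allele = "G", beta = c(1, 0))
  g <- compute_grs(ds, w)
  expect_equal(g$grs[3], mean(c(2, 0))) # imputed as the observed mean dosage
})

test_that("variance explained matches squared correlation and its F", {
  set.seed(1)
  x <- rnorm(200)
  y <- x + rnorm(200)
  ve <- variance_explained(x, y)
  expect_equal(ve$r_squared, cor(x, y)^2, tolerance = 1e-12)
  expect_equal(ve$f_statistic, ve$r_squared * (200 - 2) / (1 - ve$r_squared))
  # identity gives R^2 = 1; independence, near 0
  expect_equal(variance_explained(y, y)$r_squared, 1)
  expect_lt(variance_explained(rnorm(5000), rnorm(5000))$r_squared, 0.01)
  expect_error(variance_explained(rep(1, 10), rnorm(10)), "Zero-variance")
})

test_that("direction concordance reproduces the chi-square tail", {
  # 50 of 100: no signal
  d <- direction_concordance(c(rep(1, 50), rep(-1, 50)), rep(1, 100))
  expect_equal(d$proportion, 0.5)
  expect_equal(d$p_value, 1)
  # 100 of 100: chi-square = 100, far past genome-wide certainty
  d2 <- direction_concordance(rep(1, 100), rep(1, 100))
  expect_equal(d2$statistic, 100)
  expect_equal(d2$p_value, pchisq(100, 1, lower.tail = FALSE))
  expect_lt(d2$p_value, 2e-16)
  # 18 of 20 concordant: chi-square 12.8
  d3 <- direction_concordance(c(rep(1, 18), rep(-1, 2)), rep(1, 20))
  expect_equal(d3$statistic, 12.8)
  expect_equal(d3$p_value, 3.5e-4, tolerance = 0.01)
  # zeros are excluded; all-zero input errors
  expect_error(direction_concordance(rep(0, 10), rep(1, 10)), "usable")
})

test_that("Z-prime standardizes by the SE and the root sample size", {
  expect_equal(zprime(2, 1, 100), 0.2)
  expect_equal(zprime(0, 0.5, 10), 0)
  expect_equal(zprime(0.385, 0.0286, 134534), 0.0367, tolerance = 1e-3)
  expect_error(zprime(1, 0, 10), "positive")
  # invariant to rescaling beta and se together
  expect_equal(zprime(0.3, 0.1, 50), zprime(3, 1, 50))
})

test_that("effect-size slope equals the closed-form OLS estimate", {
  x <- c(0.12, -0.55, 0.31, 0.77, -0.20, 0.05, 0.42, -0.91, 0.66, 0.08)
  y <- c(0.10, -0.60, 0.25, 0.80, -0.15, 0.00, 0.39, -0.85, 0.70, 0.12)
  s <- effect_slope(y, x)
  expect_equal(s$slope, sum((x - mean(x)) * (y - mean(y))) /
                 sum((x - mean(x))^2), tolerance = 1e-12)
  # identity: slope 1, zero-width CI
  id <- effect_slope(x, x)
  expect_equal(id$slope, 1)
  expect_equal(id$conf_high - id$conf_low, 0, tolerance = 1e-10)
  expect_equal(id$r, 1)
  expect_error(effect_slope(y, rep(1, 10)), "Zero variance")
})

test_that("VCF dosages read into the same scores as the TSV matrix", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tp1\tp2",
    "1\t100\tv1\tG\tA\t.\tPASS\t.\tDS\t2.0\t1.0",
    "1\t200\tv2\tT\tC\t.\tPASS\t.\tDS\t0.5\t1.5"
  )
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  ds <- read_dosage_vcf(f)
  expect_equal(unname(ds$matrix["p1", ]), c(2, 0.5))
  expect_equal(ds$variants$counted_allele, c("A", "C"))
  w <- data.frame(rsid = c("v1", "v2"), effect_allele = c("A", "C"),
                  other_allele = c("G", "T"), beta = c(0.1, 0.2))
  g <- compute_grs(ds, w)
  expect_equal(g$grs[g$person_id == "p1"], 0.1 * 2 + 0.2 * 0.5)
})
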