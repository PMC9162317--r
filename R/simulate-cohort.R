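#' A set of genotype dosages with variant annotation
#'
#' Minimal container pairing an individual-by-variant dosage matrix with the
#' allele orientation of each stored column. `counted_allele` is the allele
#' whose copies the matrix counts; scoring functions flip to the weight
#' table's effect allele when required.
#'
#' @param mat Numeric matrix, individuals in rows (rownames = person ids),
#'   variants in columns (colnames = variant ids). Values in \[0, 2\] or `NA`.
#' @param variants Data frame with columns `id`, `chrom`, `pos`,
#'   `counted_allele`, `other_allele`.
#' @return A `dosage_set` object.
#' @export
dosage_set <- function(mat, variants) {
  variants <- tibble::as_tibble(variants)
  stopifnot(is.matrix(mat),
            all(c("id", "counted_allele", "other_allele") %in% names(variants)))
  if (!identical(colnames(mat), as.character(variants$id))) {
    abort("Column names of the dosage matrix must equal `variants$id` in order.")
  }
  if (length(mat) && !all(is.na(mat))) {
    rng <- range(mat, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) abort("Dosages must lie in [0, 2].")
  }
  structure(list(matrix = mat, variants = variants), class = "dosage_set")
}

#' @export
print.dosage_set <- function(x, ...) {
  cat("<dosage_set> ", nrow(x$matrix), " individuals x ", ncol(x$matrix),
      " variants\n", sep = "")
  invisible(x)
}

#' Generate a seeded synthetic cohort with known truth
#'
#' Draws a cohort whose statistical structure matches the assumptions of a
#' height MR-PheWAS: independent biallelic variants, a weighted true genetic
#' score, height composed of genetics, age, sex, a latent confounder and
#' calibrated residual noise, and binary phecodes from a logistic liability
#' model with causal, confounded and null classes. Cases emit at least two
#' qualifying ICD codes; a configurable fraction of non-cases emit exactly
#' one, so the two-code case rule is exercised end to end.
#'
#' Residual height variance is solved per population in closed form so that
#' the variance share of the genetic component, after removing age and sex,
#' equals `target_r2 * a^2 / a_ref^2` where `a` is the population's
#' attenuation and `a_ref` the largest attenuation in the configuration. The
#' confounder is independent of genotype by construction, so instrumented
#' estimates of confounded phecodes are centred on zero while measured-height
#' associations are not.
#'
#' @param config A [sim_config()].
#' @return A `cohort_sim` list with elements
#'   \describe{
#'     \item{cohort}{tibble: person_id, population, age, sex (1 = male),
#'       PC1..PC10, enrollment_date, height_cm (latent true height),
#'       score_true, u_confounder.}
#'     \item{weights}{instrument weight table (rsid, chrom, pos,
#'       effect_allele, other_allele, beta in cm per allele).}
#'     \item{dosages}{a [dosage_set()]; a fraction of columns is stored
#'       counted on the other allele, and a small fraction of entries is
#'       missing, exercising harmonisation and mean imputation.}
#'     \item{height_measurements, weight_measurements}{longitudinal tables
#'       (person_id, date, value) in inches / pounds, with injected outliers.}
#'     \item{icd_events}{long table person_id, date, vocabulary, code.}
#'     \item{phecode_map}{vocabulary, code, phecode.}
#'     \item{truth}{per phecode: class, gamma (log-odds per SD height),
#'       delta (log-odds per SD confounder), baseline prevalence.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_individuals = 300, n_variants = 20,
#'                                   n_phecodes = 6, seed = 42))
#' sim$truth
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_variants

  ## --- instrument -----------------------------------------------------
  freq <- runif(m, config$allele_freq_range[1], config$allele_freq_range[2])
  # scale per-allele effects so the true score variance is ~10.8 cm^2
  # (18% of a ~60 cm^2 covariate-adjusted height variance, i.e. SD ~7.7 cm),
  # independent of how many variants carry the signal
  beta_sd <- sqrt(10.8 / (m * 2 * mean(freq * (1 - freq))))
  beta <- rnorm(m, 0, beta_sd) # cm per effect allele
  alleles <- replicate(m, sample(c("A", "C", "G", "T"), 2))
  weights <- tibble::tibble(
    rsid = sprintf("rs%06d", seq_len(m)),
    chrom = sample(1:22, m, replace = TRUE),
    pos = sample.int(1e8, m),
    effect_allele = alleles[1, ],
    other_allele = alleles[2, ],
    beta = beta
  )

  ## --- individuals ----------------------------------------------------
  person_id <- sprintf("P%06d", seq_len(n))
  population <- if (n > 0) {
    sample(config$populations$label, n, replace = TRUE,
           prob = config$populations$fraction)
  } else {
    character(0)
  }
  age <- runif(n, 40, 80)
  sex <- rbinom(n, 1, 0.9) # 1 = male
  pcs <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("PC", 1:10)))
  u <- rnorm(n)
  enrollment <- as.Date("2011-01-01") + sample.int(2550, n, replace = TRUE)

  geno <- matrix(rbinom(n * m, 2L, rep(freq, each = n)), n, m,
                 dimnames = list(person_id, weights$rsid))
  score <- drop(geno %*% beta)

  ## --- height with closed-form noise calibration ----------------------
  a_ref <- max(config$populations$attenuation)
  c_conf <- config$confounder_height_sd
  atten <- setNames(config$populations$attenuation, config$populations$label)
  a_i <- unname(atten[population])
  height <- numeric(n)
  for (pop in config$populations$label) {
    idx <- which(population == pop)
    if (!length(idx)) next
    a <- atten[[pop]]
    v_s <- var(score[idx])
    if (!is.finite(v_s) || v_s <= 0) v_s <- sum(beta^2 * 2 * freq * (1 - freq))
    sigma2 <- v_s * (a_ref^2 / config$target_r2 - a^2) - c_conf^2
    if (sigma2 < 0) {
      r2_max <- a_ref^2 * v_s / (a^2 * v_s + c_conf^2)
      abort(sprintf(
        paste0("target_r2 = %.3f is unreachable in population '%s': ",
               "maximum attainable R^2 with this weight/frequency ",
               "configuration is %.4f."),
        config$target_r2, pop, r2_max
      ))
    }
    height[idx] <- 169 + 10 * sex[idx] - 0.03 * (age[idx] - 60) +
      a * score[idx] + c_conf * u[idx] + rnorm(length(idx), 0, sqrt(sigma2))
  }

  cohort <- tibble::tibble(
    person_id = person_id,
    population = population,
    age = age,
    sex = sex,
    tibble::as_tibble(pcs),
    enrollment_date = enrollment,
    height_cm = height,
    score_true = score,
    u_confounder = u
  )

  ## --- phecode truth and case status ----------------------------------
  k <- config$n_phecodes
  n_causal <- round(config$effect_classes[["causal"]] * k)
  n_conf <- round(config$effect_classes[["confounded"]] * k)
  n_null <- k - n_causal - n_conf
  if (n_null < 0) { n_conf <- n_conf + n_null; n_null <- 0 }
  class <- rep(c("causal", "confounded", "null"), c(n_causal, n_conf, n_null))
  phecode <- as.character(100 + seq_len(k))
  gamma <- ifelse(class == "causal", config$gamma_scale, 0)
  delta <- ifelse(class == "confounded", config$confounder_scale, 0)
  prev0 <- runif(k, config$baseline_prevalence_range[1],
                 config$baseline_prevalence_range[2])
  truth <- tibble::tibble(phecode = phecode, class = class,
                          gamma = gamma, delta = delta,
                          baseline_prevalence = prev0)

  # within-population height z-score, as used by the analysis
  z_h <- numeric(n)
  for (pop in unique(population)) {
    idx <- which(population == pop)
    z_h[idx] <- (height[idx] - mean(height[idx])) / sd(height[idx])
  }

  status <- matrix(0L, n, k, dimnames = list(person_id, phecode))
  if (n > 0 && k > 0) {
    base_lin <- 0.02 * (age - 60) + 0.2 * sex
    for (j in seq_len(k)) {
      eta <- qlogis(prev0[j]) + gamma[j] * z_h + delta[j] * u + base_lin
      status[, j] <- rbinom(n, 1L, plogis(eta))
    }
  }

  ## --- ICD emission ----------------------------------------------------
  phecode_map <- tibble::tibble(
    vocabulary = rep(c("ICD9", "ICD10"), each = k),
    code = c(sprintf("Z%04d.9", seq_len(k)), sprintf("X%04d", seq_len(k))),
    phecode = rep(phecode, 2)
  )
  day0 <- as.Date("2003-01-01")
  nday <- as.integer(as.Date("2018-12-31") - day0)
  ev_person <- ev_code_idx <- list()
  for (j in seq_len(k)) {
    cases <- which(status[, j] == 1L)
    nc <- 2L + rpois(length(cases), 2)
    noncase <- which(status[, j] == 0L)
    one <- noncase[rbinom(length(noncase), 1, config$one_code_fraction) == 1L]
    ev_person[[j]] <- c(rep(cases, nc), one)
    ev_code_idx[[j]] <- rep(j, sum(nc) + length(one))
  }
  ev_person <- unlist(ev_person)
  ev_code_idx <- unlist(ev_code_idx)
  n_ev <- length(ev_person)
  vocab <- sample(c("ICD9", "ICD10"), n_ev, replace = TRUE)
  code <- ifelse(vocab == "ICD9", sprintf("Z%04d.9", ev_code_idx),
                 sprintf("X%04d", ev_code_idx))
  icd_events <- tibble::tibble(
    person_id = person_id[ev_person],
    date = day0 + sample.int(nday, n_ev, replace = TRUE),
    vocabulary = vocab,
    code = code
  )
  # de-duplicate the rare same-person/date/code collision so fixtures are clean
  icd_events <- dplyr::distinct(icd_events, .data$person_id, .data$date,
                                .data$code, .keep_all = TRUE)
  icd_events <- dplyr::arrange(icd_events, .data$person_id, .data$date, .data$code)

  ## --- measurement tables ----------------------------------------------
  n_hm <- if (n > 0) sample(1:3, n, replace = TRUE) else integer(0)
  hm_person <- rep(seq_len(n), n_hm)
  hm_val <- height[hm_person] / 2.54 + rnorm(length(hm_person), 0, 0.2)
  # inject >3-inch outlier measurements for some persons with >= 3 readings
  out_person <- which(n_hm >= 3 & runif(n) < 0.02)
  hm_person <- c(hm_person, out_person)
  hm_val <- c(hm_val, height[out_person] / 2.54 +
                sample(c(-8, 8), length(out_person), replace = TRUE))
  height_measurements <- tibble::tibble(
    person_id = person_id[hm_person],
    date = day0 + sample.int(nday, length(hm_person), replace = TRUE),
    value = round(hm_val, 2)
  )
  height_measurements <- dplyr::arrange(height_measurements, .data$person_id,
                                        .data$date)

  bmi <- pmax(rnorm(n, 30, 5), 16)
  wt_kg <- bmi * (height / 100)^2
  n_wm <- if (n > 0) sample(1:3, n, replace = TRUE) else integer(0)
  wm_person <- rep(seq_len(n), n_wm)
  wm_off <- sample.int(1095, length(wm_person), replace = TRUE) - 548L # +-1.5y
  weight_measurements <- tibble::tibble(
    person_id = person_id[wm_person],
    date = enrollment[wm_person] + wm_off,
    value = round(wt_kg[wm_person] / 0.45359237 +
                    rnorm(length(wm_person), 0, 2), 1)
  )
  weight_measurements <- dplyr::arrange(weight_measurements, .data$person_id,
                                        .data$date)

  ## --- stored dosage orientation and missingness -----------------------
  flip <- rbinom(m, 1, 0.1) == 1L
  stored <- geno
  stored[, flip] <- 2L - stored[, flip]
  miss_rate <- 0.01
  if (n > 0 && miss_rate > 0) {
    nmiss <- rbinom(1, n * m, miss_rate)
    if (nmiss > 0) stored[sample.int(n * m, nmiss)] <- NA
  }
  variants <- tibble::tibble(
    id = weights$rsid,
    chrom = weights$chrom,
    pos = weights$pos,
    counted_allele = ifelse(flip, weights$other_allele, weights$effect_allele),
    other_allele = ifelse(flip, weights$effect_allele, weights$other_allele)
  )

  structure(list(
    cohort = cohort,
    weights = weights,
    dosages = dosage_set(`storage.mode<-`(stored, "double"), variants),
    height_measurements = height_measurements,
    weight_measurements = weight_measurements,
    icd_events = icd_events,
    phecode_map = phecode_map,
    truth = truth,
    status = status,
    config = config
  ), class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim> ", nrow(x$cohort), " individuals, ",
      nrow(x$weights), " variants, ", nrow(x$truth), " phecodes (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}
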