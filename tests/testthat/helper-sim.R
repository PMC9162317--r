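# Shared small simulated cohort, built once per test run.
.sim_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_cohort(sim_config(
      n_individuals = 4000, n_variants = 50, n_phecodes = 12, seed = 101
    ))
  }
  .sim_cache$sim
}

# A tiny hand-checkable dosage set: 3 persons x 3 variants.
toy_dosages <- function() {
  mat <- matrix(c(2, 1, 0,
                  1, 1, 2,
                  0, 2, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("p1", "p2", "p3"), c("v1", "v2", "v3")))
  dosage_set(mat, data.frame(
    id = c("v1", "v2", "v3"),
    chrom = 1:3, pos = 1:3,
    counted_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A")
  ))
}

toy_weights <- function(beta = c(0.1, -0.2, 0.05)) {
  data.frame(rsid = c("v1", "v2", "v3"),
             effect_allele = c("A", "C", "G"),
             other_allele = c("G", "T", "A"),
             beta = beta)
}

# Minimal phewas_result-shaped tibble for report-layer tests.
fake_results <- function(phecode, beta, p, n_case = 500, n_control = 5000) {
  out <- tibble::tibble(
    phecode = as.character(phecode), model = "genetic",
    n_case = n_case, n_control = n_control,
    beta = beta, se = abs(beta) / stats::qnorm(1 - p / 2),
    or = exp(beta), p_value = p, converged = TRUE, note = NA_character_
  )
  class(out) <- c("phewas_result", class(out))
  out
}
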