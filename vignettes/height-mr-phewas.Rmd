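---
title: "Methods: PheWAS and MR-PheWAS of height from EHR-style data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PheWAS and MR-PheWAS of height from EHR-style data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical methods: the
models fitted, the data-cleaning rules, the decisions taken where a
published analysis protocol leaves details open, and what the synthetic
cohort generator does and does not emulate.

## The two analyses and why both are run

A phenome-wide association study (PheWAS) regresses every phecode — a
case/control phenotype built from ICD billing codes — on measured height.
Those associations mix any true effect of height with confounding: adult
height also reflects childhood nutrition, socioeconomic environment and
secular trends, all of which independently shape disease risk.

The Mendelian-randomization PheWAS (MR-PheWAS) replaces measured height
with *genetically-predicted* height, using a weighted genetic risk score
(GRS) as the instrument in a one-sample two-stage least squares (2SLS)
design:

1. **Stage 1.** Within each population, ordinary least squares of measured
   height $H_i$ (cm) on the GRS $G_i$, adjusting for 10 genetic principal
   components. Predicted values are centred and divided by the SD of
   *measured* height, giving $\hat H_i$ with the property that one unit of
   $\hat H$ equals one height Z-score unit.
2. **Stage 2.** Per phecode, logistic regression of case status on
   $\hat H_i$ plus age, sex and the 10 PCs (optionally BMI). The
   coefficient is the log-odds per SD of height and is directly comparable
   with the measured-height PheWAS coefficient, which uses the
   within-stratum height Z-score as its exposure.

Because genotype is fixed at conception, the instrumented estimate is
immune to confounders of the height–disease association that do not act
through the variants — the property the synthetic generator encodes and the
test suite verifies.

Key identifying assumptions, stated plainly: the GRS is a strong predictor
of height (checked: first-stage F, with a warning below 10); the GRS
affects outcomes only through height (horizontal pleiotropy is *not*
interrogated — no MR-Egger or median estimators are provided, because the
design uses a single aggregate instrument); and confounders of
genotype–outcome (population structure) are controlled by the PCs and the
population-stratified design.

## Phenotype construction rules

* **Height.** All measurements (inches) are averaged; measurements
  deviating strictly more than 3 inches from that provisional mean are
  dropped; the mean is recomputed once. Persons with final means ≤ 50 or
  ≥ 100 inches are excluded. The deviation pass deliberately runs exactly
  once: iterating to a fixed point can cascade (each recomputed mean
  exposes new "outliers") and is harder to reason about. Thresholds are
  strict (`> 3`) and bounds inclusive (`≤ 50`, `≥ 100`), following the
  printed symbols of the protocol being implemented. QC happens in native
  units and converts to cm once at the end.
* **BMI.** Weights (pounds) within ±1.5 years of enrollment are averaged
  after dropping weights deviating strictly more than 60 lb from the
  in-window mean (one pass). The 60-lb rule is read as
  *deviation-from-person-mean*: an absolute 60-lb floor would exclude
  almost nobody plausible and cannot be what such a rule intends. BMI is
  mean weight (kg) over height (m) squared — weight is averaged first and
  divided once, rather than averaging per-visit BMIs; with a fixed height
  the two differ only when visit sets differ, and weight-first is simpler.
* **Phecodes.** At least two mapped diagnosis events → case; zero →
  control; exactly one → missing (excluded for that phecode), the standard
  phecode-PheWAS convention for "possible" cases. Events are counted as
  distinct (person, date, code) records regardless of date spacing.
  Mapping is exact-string on (vocabulary, code); no hierarchy expansion.
  Phecode exclusion ranges (dropping controls with related codes) are not
  applied; `phecode_outcome()` is the hook where such a map would plug in.
  Analyses keep phecodes with ≥ 200 cases *and* ≥ 200 controls, and the
  Bonferroni threshold 0.05/n is recomputed from the phecodes actually
  tested in each analysis stratum.

## Instrument handling

Variants are matched by id and verified against the allele pair. When the
dosage file counts the *other* allele, the dosage is flipped to $2-d$; when
neither orientation matches, the variant is dropped and logged; more than
half the weight table unmatched is a hard error. Palindromic (A/T, C/G)
variants are retained — dosage files are assumed strand-consistent with the
weight table — and the match log makes the policy auditable; this mirrors
scoring-file practice where strand flips, not allele flips, are the rare
case. Missing dosages are mean-imputed at twice the cohort effect-allele
frequency, which preserves the score mean and is the default of standard
scoring tools.

## Numerical choices

* **Logistic fits** use binomial IRLS (`stats::glm.fit`) with convergence
  tolerance $10^{-8}$ and at most 25 iterations; Wald standard errors come
  from the inverse observed information at the final iterate and p-values
  from the normal approximation, the convention of PheWAS software.
  Separation is detected as any fitted probability within $10^{-10}$ of 0
  or 1 together with a coefficient exceeding 15 in absolute value; such
  fits are flagged `converged = FALSE` and skipped by report surfaces. No
  Firth correction is applied: the 200-case minimum makes separation rare.
  A failing phecode never aborts a phenome sweep.
* **Second-stage standard errors are naive**: no correction for first-stage
  estimation uncertainty. With tens of thousands of individuals and a
  strong instrument the correction is negligible; in the weak-instrument
  regime it is anti-conservative, which is why a first-stage F below 10
  attaches a warning to every downstream result.
* **Far-tail inverse normal.** `se_from_p()` evaluates
  `qnorm(p/2, lower.tail = FALSE)` so that p-values such as $10^{-90}$
  round-trip exactly; below the smallest representable double, p-values are
  accepted on the log scale (`log_p = TRUE`). This is what makes
  meta-analysis inputs reconstructible from printed odds ratios and
  p-values.
* **Meta-analysis** is fixed-effects inverse-variance weighting with
  Cochran's Q on $k-1$ df; the two-stratum heterogeneity test is the
  equivalent z-test $(\beta_1-\beta_2)/\sqrt{se_1^2+se_2^2}$, whose square
  is the 1-df Q — the natural reading of an unnamed "test of heterogeneity
  between strata". Meta-analysis significance uses the threshold of the
  stratum with more phecodes tested (the larger sample).
* **Direction concordance** uses a 1-df chi-square goodness-of-fit of the
  concordant count against expectation one half, zeros excluded; an exact
  binomial is available behind `method = "binomial"`. The chi-square is the
  default because "chi-square test" is the conventional description of this
  comparison.
* **Degenerate inputs** error early and informatively: zero-variance
  scores, rank-deficient designs, empty joins, non-positive standard
  errors, p-values outside (0,1). Empty *results* (no phecodes passing the
  filter) are permitted with a warning so sweeps no-op rather than fail.
* **Stratified analyses** define membership as *case* on any defining
  phecode (one-code persons count as non-members, consistent with the
  case-rule reading of "presence"); defining phecodes are excluded from the
  outcome list; the first stage is refit within each stratum; the 200/200
  filter applies within stratum. Sex is dropped automatically as a
  covariate in sex-stratified runs (zero variance).
* The first stage adjusts for PCs only, matching the stratified design it
  implements; age and sex can be added through `covariates` if a user
  prefers the fuller model. Height Z-scores are computed within the
  analysis stratum.

## What the synthetic cohort emulates

`simulate_cohort()` draws independent biallelic variants
($g_{ij}\sim\mathrm{Bin}(2,f_j)$), per-allele weights scaled so the true
score variance is ~10.8 cm² (an instrument explaining 18% of a ~60 cm²
covariate-adjusted height variance, i.e. residual SD ≈ 7.7 cm, the scale of
adult male height), and height

$$H_i = 169 + 10\,\mathrm{male}_i - 0.03(\mathrm{age}_i-60)
        + a\,S_i + c\,U_i + \varepsilon_i,$$

where $S_i$ is the true score, $a$ a population-specific attenuation factor
on the per-allele effects, $U_i\sim N(0,1)$ a latent confounder with
$c = 2$ cm, and $\varepsilon_i$ Gaussian noise whose variance is solved in
closed form *per population* so that the genetic share of
covariate-adjusted height variance equals
$\mathrm{target\_r2}\cdot a^2/a_\mathrm{ref}^2$. With the defaults
(target 0.18; attenuations 1.0 and 0.52) the two populations realize
R² ≈ 18% and ≈ 4.8% — the transferability contrast of a
European-ancestry-derived instrument applied to an African-ancestry
population — and their R² ratio is $a^2 \approx 0.27$. An unreachable
target (too much confounder variance for the requested R²) errors with the
maximum attainable value.

Phecodes are drawn from a logistic model
$\mathrm{logit}\,p_{ik} = \alpha_k + \gamma_k z(H_i) + \delta_k z(U_i) +
0.02(\mathrm{age}_i-60) + 0.2\,\mathrm{male}_i$, with three classes:
causal ($\gamma_k = 0.3$, the scale of the strongest replicated
height–disease odds ratios, ~1.35 per SD), confounded ($\gamma_k = 0$,
$\delta_k = 0.3$), and null. Binary traits come directly from the logistic
(not a probit liability) so that downstream logistic regression recovers
$\gamma_k$ without link mismatch, making parameter recovery an exact
testing surface; the residual non-collapsibility attenuation at these
effect sizes is below 2%. Because $U$ is independent of genotype by
construction, measured-height associations of confounded phecodes are
biased away from zero while instrumented ones are centred on it — the
discriminating property of the whole design.

Cases emit $2+\mathrm{Poisson}(2)$ qualifying ICD codes (split between an
ICD9 and an ICD10 synonym) and 5% of non-cases emit exactly one, so the
two-code rule, the one-code exclusion and vocabulary mapping are exercised
end to end. Ages are uniform 40–80, sex is Bernoulli(0.9) male (the skew of
a veteran cohort), PCs are independent standard normals, baseline phecode
prevalences are uniform on (0.05, 0.25) — common EHR conditions; prevalence
distributions are a free choice, as no target exists for them. About 10% of
stored dosage columns are flipped to the other allele and 1% of entries are
missing, exercising harmonisation and imputation. Height measurement tables
add 0.2-inch reading noise and inject >3-inch outliers for ~2% of persons
with enough readings (only where ≥3 readings exist: with two symmetric
readings the deviation rule cannot identify which is real and correctly
excludes the person).

What it does **not** emulate: linkage disequilibrium (attenuation is a
single scalar, a deliberate simplification of LD/frequency transferability),
imputation uncertainty, relatedness, ancestry inference, care-utilisation
patterns (ICD dates are uniform), phecode hierarchies, or pleiotropy.
Passing tests therefore demonstrate the *estimators* are correct and
calibrated under the stated model, not that real EHR data meet the model's
assumptions.

## Problem sizes used by the test suite

The simulation-based checks run at n = 50,000 individuals with 100 variants
and 60 phecodes over 10 seeds for parameter recovery (mean causal MR
estimate within ±0.02 of 0.3; type-I error on confounded phecodes within
binomial bounds of 0.05 while the measured PheWAS rejects most of them);
20 replicates at n = 50,000 for the R² calibration (mean within ±0.01 of
target); and 4 seeds × 500 null phecodes at n = 10,000 for the uniformity
of MR p-values. 100 variants rather than thousands carry the instrument:
the calibration closed form is variant-count-free, so this changes nothing
statistically while keeping the suite fast.

## Known limitations

Naive 2SLS standard errors (see above); no pleiotropy-robust estimators; no
phecode exclusion ranges by default; exact-string ICD mapping; fixed-effects
meta-analysis only (the heterogeneity statistics are reported precisely so
users can judge when fixed effects are inappropriate); and the synthetic
generator's independence assumptions listed above. The `genetic+BMI`
sensitivity model conditions on a potential collider (BMI contains height);
it is provided for comparability with standard practice, and interpreted
accordingly.
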