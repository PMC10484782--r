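---
title: "Methods: burden testing, weighted meta-analysis and FRR decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burden testing, weighted meta-analysis and FRR decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomeburden)
```

This vignette is the package's own account of the statistical machinery it
implements, the choices made where the design was genuinely open, and what
the simulation-based tests do and do not establish.

## 1. Variant classes and the NMD-escape rule

Burden categories are built from VEP-style annotations against a single
transcript per gene (transcript choice — MANE/RefSeq Select — is an input
contract, not something the package decides).

* **PTV**: stop-gained, frameshift, splice-donor or splice-acceptor.
  Splice-region and start-lost variants are deliberately *not* PTVs; the
  four classes above are the conventional loss-of-function set.
* **NMD escape**: a PTV in the last exon, or within the last 50 bases of
  the penultimate exon, generally lies downstream of the final
  exon-junction complex, escapes nonsense-mediated decay, and may yield a
  functional truncated protein, so it is excluded from the PTV category.
  Two conventions had to be fixed here. First, the boundary is
  **inclusive**: the distance is counted in bases from the variant to the
  exon's 3' end *including the variant base* (the exon's last base is at
  distance 1), and distance ≤ 50 escapes — matching the usual "within 50
  nt" phrasing of the NMD heuristic. The window is exposed as
  `nmd_window` for sensitivity analyses. Second, distances are measured in
  transcript-forward exon coordinates, not CDS coordinates; for the exon
  structures involved the two differ only when a penultimate exon contains
  the stop-proximal UTR, which the toy data do not model.
  Single-exon transcripts have no exon junction, so every PTV escapes.
* **Rare missense**: allele frequency strictly below `af_max = 0.001` in
  *both* the reference panel and the analysis cohort. The dual filter is
  strict (`<`), so AF exactly 0.001 fails; `cadd_min = 20` is inclusive
  (`>= 20`) while `helix_min = 0.5` is strict (`> 0.5`) — these mirrored
  conventions are asserted by boundary tests.

Collapsing treats missing genotypes as non-carriers. That is the only
choice compatible with carrier-count data, but it can manufacture spurious
signal when missingness correlates with case status, so
`missingness_report()` tabulates per-gene missing-call fractions by case
status; genes where the fractions diverge should be dropped, as scans of
real data have had to do.

## 2. The reversed, family-history-weighted burden regression

The burden model treats the carrier indicator as the *outcome*:

logit P(G = 1) = a + b (d + ½ f) + covariates.

By odds-ratio symmetry, with no covariates and f ≡ 0 the coefficient b
equals the usual prospective log-OR of disease given carrier status
(tested to fitting tolerance). The reversed orientation is what lets
family history enter cheaply: a positive first-degree history is, for
small effects, associated with roughly half the log-OR of the disease
itself, so an unaffected individual with family history contributes d + ½f
= 0.5. The weight is a parameter (`f_weight`); setting it to 0 recovers
the plain case-control test and is how the power-gain tests isolate the
contribution of family history. Missing f is treated as 0 (conservative:
it can only dilute, not create, signal).

Numerical choices:

* Fits use `stats::glm.fit` with a warm start at the intercept-only
  solution — with carriers at frequencies of 10⁻³–10⁻² the IRLS path from
  the default start wastes most of its iterations, and the warm start
  halves the per-gene cost without changing the optimum.
* Rare carriers make complete separation routine. When the ML fit fails
  to converge, or diverges (|coef| ≥ 15, or the Wald SE of the weighted
  phenotype ≥ 20 — at that point the Wald statistic is meaningless), a
  Firth penalised fit (Jeffreys-prior score correction, step-halved
  Newton iterations) replaces it and the result is flagged
  `converged = FALSE`. P values are Wald throughout, since downstream
  meta-analysis consumes z scores.
* Covariate columns that are constant on the analysis subset (e.g.
  library prep within one study, sex after the chromosome-X restriction)
  are dropped silently; genuine collinearity is an error naming the
  offending column.

Scans test every gene with at least one carrier after restrictions.
Restrictions (`age_lt50`, `ER+`, `ER-`, `PR+`, `PR-`, `TN`) drop
non-qualifying *cases* (cases with missing subtype are dropped rather than
imputed) and never drop controls; chromosome-X genes use females only.
Skipped genes are reported with reasons rather than silently omitted.

## 3. Anchor-weighted meta-analysis

Studies are combined on the z scale, z_M = Σ w_j z_j / √(Σ w_j²). The
denominator is read as the root of the *sum* of squared weights — the only
reading under which z_M is standard normal when the z_j are — and equal
weights reduce to the classical Stouffer combination (both asserted in
tests). Because a study that oversamples family-history-positive or
early-onset cases measures a larger per-carrier effect, inverse-variance
weights would be biased; instead the weights are calibrated on an anchor
gene whose association is established and reproducible, as the ratio of
per-study anchor z scores (reference study = 1). With several anchor
genes the ratio of summed z scores is used — it reduces to the single-gene
rule and weights each gene by its evidence; the combination is invariant
to which study is the reference and to rescaling all weights. Anchor z
scores must be positive in every study; anything else means the anchor is
not doing its job and is an error, not a warning. Genes absent from a
study are combined over the remaining studies with the missing study's
weight dropped and the row flagged.

Calibration of a scan is summarised by λ = median(z²)/0.4549 (the median
of χ²₁). Rare-carrier Wald statistics are conservative at small carrier
counts, so λ somewhat below 1 is expected behaviour in real scans, and the
calibration tests therefore use sample sizes (≥ 10,000 samples, ~100
carriers per gene) where the asymptotics have set in.

## 4. Empirical-Bayes FRR decomposition

Under a rare dominant model, a gene with PTV allele frequency p and
carrier relative risk e^β contributes

λ_j = 1 + p(e^β − 1)² / (2p(e^β − 1) + 1)²

to the first-degree FRR, and contributions add on the excess scale. The
formula is validated against an independent Monte-Carlo oracle — 2×10⁶
simulated proband–relative pairs with Mendelian transmission — to within
5% at (p ≤ 0.005, OR ≤ 5).

The effect-size landscape is modelled as a spike-and-slab mixture: a gene
is associated with probability α, in which case β ~ Exponential(η)
(median OR e^{ln2/η}); otherwise β = 0. The likelihood of a gene's
carrier counts is approximated by treating the empirical 2×2-table log-OR
β̂ as normal around β with Woolf variance (0.5 continuity correction only
when a cell is zero) — the standard approximation for rare-carrier
tables. Its mixture marginal has a closed form (an exponentially modified
Gaussian tail), evaluated on the log scale for stability and cross-checked
against adaptive quadrature to 10⁻⁸ relative error. An exact binomial
conditional likelihood could replace it behind the same interface; the
`likelihood = "quadrature"` option exists so any replacement can be
validated the same way.

Fitting maximises the summed log marginal over (logit α, log η) by
L-BFGS-B from five fixed starts (α ∈ {10⁻⁴, 10⁻³, 0.01, 0.05, 0.2} crossed
with η ∈ {0.5, 1, 2, 4, 8}); the procedure is deterministic and seedless.
Per-gene posteriors follow in closed form; posterior expectations of
λ_j − 1 use 256-node Gauss–Legendre quadrature on β ∈ [0, 5] (log-OR 5 ≈
OR 150 comfortably exceeds any plausible single-gene effect).

Two quantities are configurable because no principled default exists:

* **p_j estimation** uses cases + controls combined by default
  (`controls_only = TRUE` switches to controls). The combined estimate is
  more precise but biased upward for strongly associated genes when cases
  are a large fraction of the sample; the truth-recovery test uses
  controls only for exactly that reason.
* **λ_obs**, the observed first-degree FRR that normalises
  `frr_percent()`, defaults to 2.0 — the conventional value for breast
  cancer in first-degree relatives. Percentages scale as 1/(λ_obs − 1),
  so any other disease needs its own value.

Recessive effects are ignored: PTV homozygotes are too rare to estimate,
so the decomposition reads as the contribution to offspring of affected
individuals.

## 5. What the simulator emulates — and what it does not

`simulate_cohort()` generates exactly the structure the analysis assumes:
Bernoulli carrier status per gene (carriers are simulated directly; no
diploid genotypes, since the analysis collapses to 0/1 anyway, with allele
frequency p = carrier frequency / 2 under the rare-variant
approximation); a logistic disease model with baseline K
(`baseline_risk`, default 0.10 — a round value of the order of lifetime
female breast-cancer risk; the choice only scales case yield, not effect
recovery); and one simulated first-degree relative per sample who inherits
each carried allele with probability ½ and is affected with probability
min(1, K e^{Σβ}), plus an independent background family-history rate
(default 0.05) for histories the single-relative model cannot produce.
Relative risks act multiplicatively on K and are capped at 1, matching
the relative-risk parameterisation of the FRR formula. This is the
simplest generative model that reproduces the "log-OR for family history
≈ ½ log-OR for disease" relationship the weighted phenotype relies on.

Study ascertainment is implemented as rejection sampling of cases with
acceptance probability proportional to the study's family-history and
early-onset multipliers — it mirrors oversampled recruitment without
modelling the ascertainment likelihood. Covariates (sex, age band,
country, library prep, 10 PCs, ER/PR/HER2/TN for cases) are populated as
noise with zero true effect by default; `pc_confound` can inject genuine
PC–disease confounding for robustness checks. A block-resampling cap
(10⁶ individuals per block, 30 blocks per study) turns pathological
configurations into a diagnostic simulation error instead of a hang.

Not emulated: linkage disequilibrium, per-variant effect heterogeneity
within a gene, age-at-onset hazards, polygenic background, and male
breast cancer (sex is a pure noise label). Passing tests therefore show
that the estimators are correct *under the model the methods themselves
assume* — they cannot show robustness to, e.g., within-gene effect
heterogeneity, which no burden test detects.

`simulate_annotated_variants()` builds toy transcripts whose variant
panels deliberately sit on every classification boundary (NMD distances
49/50/51, AF exactly 0.001 and either side, CADD 19/20/25, Helix
0.4/0.5/0.6...0.7), so the classification tests are exhaustive rather
than sampled.

## 6. Problem sizes and determinism

The simulation-based checks use 5,000 null genes at 20,000 samples for
type-I error and inflation; 2×10⁶ pairs for the FRR oracle; 5,000 genes
at 50,000 cases/controls (count-level simulation) for mixture recovery,
where α is recovered within ±0.02 and η within ±30% — sizes at which each
Monte-Carlo band is a few times tighter than the assertion it supports,
while the whole suite stays desk-scale.

Every stochastic function takes an explicit seed and restores the
caller's RNG state; optimisation and quadrature are seedless and
deterministic. Pipeline outputs are fixed-format at 6 significant digits,
which is what makes byte-identical reruns (asserted by checksum) a
meaningful contract: double-precision round-trip formatting would expose
platform-dependent last digits for no analytic benefit.

## 7. Known limitations

* The Woolf-variance normal approximation degrades for genes with a
  handful of carriers; the continuity correction keeps it finite but
  biased toward the null, which makes the fitted α mildly conservative.
* Anchor weighting assumes the anchor gene's true effect is identical
  across studies; if it is not, all effect sizes inherit the distortion.
* `frr_percent()` between disjoint subsets is exactly additive, but
  posterior shrinkage means a single strong gene's share is recovered to
  ~10–15%, not exactly (see the truth-based test's pilot-calibrated 25%
  band).
* The reversed regression reports the exposure coefficient as the OR "for
  carrying a PTV"; with covariates this equals the prospective estimate
  only approximately, the usual price of the genotype-as-outcome trick.
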