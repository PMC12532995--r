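---
title: "Methods: proteome-wide two-sample MR scanning with pqtlmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide two-sample MR scanning with pqtlmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqtlmr)
```

## The design and its assumptions

`pqtlmr` implements a two-sample Mendelian randomisation (MR) scan: genetic
variants associated with a plasma protein's level (pQTLs, effects in SD
units per allele from a discovery proteomics GWAS) serve as instruments for
the protein, and their effects on a case-control outcome (log-odds per
allele from an independent GWAS) identify the causal effect of the protein
on disease risk. Validity rests on the three instrumental-variable
assumptions: instruments are associated with the protein (relevance),
share no confounder with the outcome, and affect the outcome only through
the protein (exclusion restriction). The package's machinery is organised
around the ways these fail in practice:

- **Relevance** is enforced quantitatively: instruments must pass the
  discovery significance threshold (strict `p_max`, default 1.7e-11 — a
  proteome-wide Bonferroni-style discovery level) and a minimum F-statistic
  (`f_min`, default 10), with F computed as the squared GWAS z-score
  (β/se)². The r²-based form F = r²(n−2)/(1−r²) is provided for
  bookkeeping against published variance-explained figures; the two agree
  closely for the weak-to-moderate instruments where the distinction
  matters.
- **Exclusion** is probed rather than assumed: the MR-Egger intercept
  estimates average directional pleiotropy, leave-one-out re-estimation
  detects signals carried by a single (typically hub) variant, cis-only
  re-estimation replicates under reduced pleiotropy risk, and
  colocalisation checks that the protein and outcome associations share a
  causal variant rather than sitting in linkage.
- **Directionality** (protein → disease, not reverse) is checked by the
  Steiger comparison of variance explained on the two sides.

The estimators assume independent instruments; LD pruning is the pQTL
provider's responsibility (discovery studies report independent primary
signals) and the package does not re-prune.

## Harmonisation policy

Both effects must refer to the same effect allele. The resolution order for
an outcome record is: exact allele match → swapped alleles (negate the
outcome beta, complement its frequency) → strand complement → complement
plus swap → exclude with reason "allele mismatch". Palindromic variants
(A/T, C/G) are dropped outright: their strand cannot be resolved from
alleles alone, and we deliberately do not attempt frequency-based
orientation, so no intermediate-frequency threshold exists. A protein whose
instruments are all excluded is reported as `insufficient_instruments`,
never silently skipped, and exclusion accounting is exact: input variants =
surviving pairs + logged exclusions.

Variants absent from the outcome GWAS are replaced by their best LD proxy
with r² ≥ `r2_min` (default 0.8), ties broken by higher r² then
lexicographic id. Proxy effect sizes are used as-is — no r²-attenuation
correction — mirroring standard practice. Positions are 1-based; gene
regions are closed intervals; a variant is cis when it lies within
`cis_window_bp` (default 1 Mb) of the nearer gene boundary on the same
chromosome, so the classification is invariant to swapping start and end.

## Estimators and inference

- Wald ratio (1 instrument): first-order delta-method SE
  (se<sub>Y</sub>/|β<sub>X</sub>|), which ignores exposure-side noise; this is the
  standard choice and errs on the anti-conservative side only at weak
  instruments, which the F filter excludes. A second-order SE is available
  behind a flag.
- IVW (≥ 2): fixed-effect by default — appropriate for the small
  instrument counts typical per protein (median 5); multiplicative
  random effects (SE scaled by max(1, √(Q/(J−1)))) are a config switch.
- MR-Egger (≥ 3): instruments oriented to non-negative exposure effects,
  then weighted least squares with intercept; slope and intercept inference
  on t with J−2 df, a small-sample honesty choice, while Wald/IVW use the
  normal.
- Weighted median (≥ 3): ratio estimates sorted, the estimate interpolates
  the inverse-variance-weighted cumulative distribution at half weight.
- Weighted mode (≥ 3): argmax of a Gaussian-kernel weighted density of the
  ratios with the modified Silverman bandwidth
  φ · 0.9 · min(sd, IQR/1.349) · J^(−1/5), φ = 1 by default (the cited
  method's convention). If all ratios coincide the bandwidth degenerates to
  zero and the common ratio is returned directly.

Median and mode SEs come from a parametric bootstrap (default `n_boot`
1000) that resamples both betas from N(β̂, se²); the generator's seed
derivation makes them exactly reproducible and independent of protein input
order. 95% intervals use 1.96 throughout; p-values are two-sided.

## Scan classification

Benjamini–Hochberg FDR (level `fdr_alpha` = 0.05) is applied across the
pooled protein × outcome family by default — a single stated threshold
spanning outcome subtypes implies one family — with a per-outcome mode
available. Tiers, in rule order: `insufficient_instruments`;
`pleiotropy_driven` (FDR-rejected but leave-one-out finds a driver whose
removal lets the CI cross the null, judged at the same 95% level as the
headline estimates); `robust` (FDR-rejected, leave-one-out clean, Egger
intercept p > `intercept_alpha` = 0.05); `suggestive` (nominal p < 0.05
below the FDR bar, passing every evaluable pleiotropy test); otherwise
`null`. Records with fewer than 3 instruments cannot be intercept-tested
(fewer than 2, not LOO-tested); such tests are skipped, not failed, and the
record is annotated as not pleiotropy-evaluable rather than auto-promoted.

## Colocalisation

Per-variant approximate Bayes factors use Wakefield's form
0.5·log(1−r) + 0.5·z²·r with r = W/(V+W), W the squared prior effect SD
(defaults 0.15 for the quantitative trait, 0.2 for the case-control trait)
and per-hypothesis priors p1 = p2 = 1e-4, p12 = 1e-5 — the cited method's
conventional defaults, all config-exposed since the source analysis names
the method but not its priors. All accumulation is in log space via
log-sum-exp: regions of 100+ variants overflow otherwise. The H3 term is
the exact log-difference log(exp(S1+S2) − exp(S12)); for a single-variant
region H3 is impossible and its posterior is exactly 0. Band edges are
strict: PPH4 > 0.8 is "high", > 0.5 "suggestive", exactly 0.5 or 0.8 fall
to the lower band — the prose convention leaves the boundary open and we
fix it strictly. Note one identity that is *not* assumed: jointly scaling a
trait's betas and SEs preserves z but changes the ABF unless the prior SD
(same units) is scaled alongside; the package's invariance tests scale
both.

## The simulator: what it emulates and what it does not

The generator produces the statistical structure the estimators assume, at
the default study conditions: exposure discovery n = 34,557; outcome 25,509
cases / 40,941 controls (plus a 14,049-case subtype stratum in the scan
fixture); instrument count per protein drawn as 3 + Binomial(4, ½) —
median 5, range 3–7, matching a reported median of five with IQR three to
eight; allele frequencies uniform on [0.05, 0.95]; per-variant true effects
sized so the expected F-statistic hits the scenario target (default 45,
the floor reported for included pQTLs; realised F then follows a noncentral
χ²₁ with mean target + 1). SEs are the analytic forms
1/√(2p(1−p)n) (exposure) and 1/√(2p(1−p)·n_case·n_control/n) (log-odds,
effective-sample-size approximation), exactly checkable without sampling.
Simulated p-values are floored at the smallest normalised double because
published tables report denormalised minima, never exact zeros, and an
exact zero violates the record contract.

Scenarios: `null` (θ = 0), `causal` (θ = log 2.41, a published headline
effect size), `directional_pleiotropy` (direct effects
α<sub>j</sub> ~ N(0.05, 0.02²); the mean is the scenario's definition, the
dispersion a realistic spread chosen once), and `hub_pleiotropy` (the last
instrument is a shared variant with F target 4000 — about 10% of protein
variance, inside the reported 4.2–23% hub range — and a direct outcome
effect of 0.10 log-odds). Directional pleiotropy acts on the
*protein-increasing* allele (its sign follows the instrument's exposure
effect): a shared downstream pathway pushes the outcome the same way
wherever the variant raises the protein, and this is the convention under
which an Egger intercept is estimable at all — allele-coding-independent
direct effects average to zero after orientation.

The `mixed_scan` fixture (50 proteins × 2 outcomes: 3 causal, a 5-protein
hub cluster sharing one trans variant, 42 null) raises the instrument F
target to 120 so that simulated discovery p-values comfortably clear the
strict 1.7e-11 selection threshold — published pQTLs are post-selection
and sit well past their discovery bar, whereas unselected draws at F = 45
straddle it.

Deliberately **not** modelled: LD within an instrument set (hub pleiotropy
is a genuinely shared variant, not linkage), sample overlap between the two
GWAS, winner's-curse inflation of discovery effects, and assay differences
between proteomic platforms. Passing tests therefore demonstrate that the
estimators, diagnostics and classification logic behave correctly when
their assumptions hold and under the specific violations simulated — not
that real-data signals are free of the unmodelled artefacts.

## Numerical and degenerate-input choices

- Seeds: every stochastic component takes an explicit seed; scan-internal
  bootstrap seeds derive from the config seed and the protein/outcome ids,
  so results are byte-identical across runs and invariant to input order.
  The bootstrap restores the caller's RNG state.
- Perfect-fit Egger regressions (zero residual variance) give p = 0 for a
  non-zero coefficient and p = 1 for a zero one rather than NaN.
- A 0/0 Wald ratio p-value is reported as 1 (no effect, no information);
  a zero exposure effect is an error, as the ratio is undefined.
- `variance_explained` is capped just below 1; the Steiger test caps summed
  r² at 1 with a warning. Its binary-outcome r² is an observed-scale
  approximation weighted by the case fraction — the cited directionality
  method leaves the binary mapping unstated, and this approximation is
  adequate for the direction flag, which compares magnitudes across sides.
- BH q-values come from `stats::p.adjust`; the step-up threshold and
  rejection set are recomputed explicitly and cross-checked in tests
  against a naive double-loop oracle.
- Weighted-mode densities are evaluated on a 512-point grid spanning the
  ratio range ± 3 bandwidths; the grid resolution is well below the
  bootstrap SE of the estimator.

## Problem sizes used in the checks

The shipped checks run at: 2000 null replicates (type-I error), 1000
replicates each for causal-effect and Egger-intercept recovery, 500
hub-adjudication replicates, 200 + 200 colocalisation regions of 50
variants, 1000 randomised harmonisation fixtures, and one 50 × 2 scan run
twice for determinism — sizes chosen so each Monte-Carlo rate has standard
error below about 1.5% of its target while the whole suite completes on a
single CPU in a few minutes.

## Known limitations

Single-causal-variant colocalisation (no SuSiE-style multi-signal
decomposition); no MR-PRESSO/contamination-mixture/multivariable
estimators; no conditional analysis or fine-mapping to define independent
pQTLs; no LD computation from genotypes (proxies must be supplied); no
liability-scale conversion of binary-outcome effects. These are boundaries
of scope, not of the data formats: the container types accept any
summary-statistics source with the documented columns.
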