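# pqtlmr

Proteome-wide two-sample Mendelian randomisation (MR) scanning from GWAS
summary statistics.

`pqtlmr` is for analysts who have per-variant summary associations for many
plasma proteins (pQTLs from a discovery proteomics cohort) and for a
case-control disease outcome, and who want to screen every protein for a
causal effect on the disease while guarding against the failure modes that
dominate such scans: weak instruments, allele-coding mismatches between
studies, and horizontal pleiotropy concentrated at hub loci (the *ABO*
pattern, where one trans variant instruments dozens of proteins and also
affects the outcome directly).

## The model

For protein X and outcome Y, each genetic instrument j provides an exposure
effect β̂<sub>Xj</sub> (SD units of protein per allele) and an outcome effect
β̂<sub>Yj</sub> (log-odds per allele), harmonised to the same effect allele.
Under the instrumental-variable assumptions the causal effect θ (log-odds
per 1 SD higher protein) is estimated by:

- **Wald ratio** (1 instrument): θ̂ = β̂<sub>Y</sub>/β̂<sub>X</sub>, se = se<sub>Y</sub>/|β̂<sub>X</sub>|.
- **IVW** (≥ 2): θ̂ = Σ w<sub>j</sub> β̂<sub>Xj</sub> β̂<sub>Yj</sub> / Σ w<sub>j</sub> β̂<sub>Xj</sub>²
  with w<sub>j</sub> = 1/se<sub>Yj</sub>²; equivalently the weighted regression of
  β̂<sub>Y</sub> on β̂<sub>X</sub> through the origin.
- **MR-Egger, weighted median, weighted mode** (≥ 3): sensitivity estimators
  valid under progressively weaker pleiotropy assumptions; the Egger
  intercept estimates the average directional pleiotropy, and its test
  (t, J−2 df) gates the scan's classification.

Diagnostics: leave-one-out re-estimation flags "driver" variants whose
removal collapses the signal; the Steiger test checks that instruments
explain more variance in the protein than in the disease; cis-only
re-estimation replicates each signal under reduced pleiotropy risk; and
approximate-Bayes-factor colocalisation decomposes each region pair into the
five standard hypotheses (PPH0–PPH4), with PPH4 > 0.8 read as high support
for a shared causal variant and 0.5–0.8 as suggestive.

The scan applies Benjamini–Hochberg FDR across the pooled protein × outcome
family and classifies every record as `robust` (FDR-pass, clean pleiotropy
tests), `pleiotropy_driven` (FDR-pass, leave-one-out driver),
`suggestive` (nominal p < 0.05 with clean tests), `null`, or
`insufficient_instruments`.

Because consortium-scale pQTL and case-control data cannot be bundled, the
package ships a summary-statistics simulator
(`sim_scenario()`, `make_scan_fixture()`) that generates instrument sets and
outcome effects with known causal truth at realistic cohort sizes, so every
stage — and the full scan — is testable end to end.

## Worked example

Simulate one protein with a true effect of log(2.41) on the outcome at
realistic sizes (34,557 exposure samples; 25,509 cases / 40,941 controls),
harmonise, and fit:

```r
library(pqtlmr)

sc  <- sim_scenario("causal")
g   <- simulate_protein_gwas(sc, protein_id = "FSHB_like", seed = 14)
o   <- simulate_outcome_gwas(g$truth, sc, seed = 15, trait_id = "oc_subtype")
h   <- harmonise(g$table, o, gene_region = g$gene_region)
fit <- mr_fit(h$instruments, n_exp = sc$n_exp, n_case = sc$n_case,
              n_control = sc$n_control, seed = 1)
summary(fit)
```

```
Causal estimates (log-odds per 1 SD higher exposure):
          method n_snps  theta      se or_point or_low or_high    pvalue
             ivw      5 0.7738 0.09966    2.168  1.783   2.636 8.229e-15
           egger      5 1.3405 0.21417    3.821  2.511   5.814 8.230e-03
 weighted_median      5 0.8355 0.13916    2.306  1.756   3.029 1.927e-09
   weighted_mode      5 0.8568 0.18375    2.356  1.643   3.377 3.116e-06
        cis_only      1 0.8550 0.20173    2.351  1.583   3.492 2.253e-05
MR-Egger intercept: -0.0363 (se 0.0133), p = 0.0724
Leave-one-out over 5 instruments: pass (no single-variant drivers)
Steiger: r2(exposure) = 0.006406 vs r2(outcome) = 0.0009469 -> exposure-first direction supported (z = 7.45, p = 9.17e-14)
```

All five estimators agree on a risk-increasing effect (the IVW odds ratio
2.17 per SD, 95% CI 1.78–2.64, brackets the simulated truth of 2.41), no
single variant drives the signal, and the instruments explain far more
variance in the protein than in the outcome, as a forward causal structure
requires.

A full scan over a miniature proteome:

```r
fx <- make_scan_fixture(seed = 1)     # 50 proteins x 2 outcomes, known truth
s  <- run_scan(fx$exposures, fx$outcomes, fx$annotation,
               config = scan_config(seed = 1))
summary(s)
write_results(s, "scan_results.tsv")  # TSV + JSON summary
```

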