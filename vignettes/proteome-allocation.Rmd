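---
title: "A four-sector proteome allocation analysis of bacterial multi-omics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A four-sector proteome allocation analysis of bacterial multi-omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sectorAlloc)
```

## The model

Coarse-grained growth laws describe an exponentially growing bacterium as a
budget over its proteome. `sectorAlloc` implements a four-way partition of
that budget:

* **R** — ribosome-affiliated proteins (translation),
* **M** — metabolic proteins actually used under the growth condition,
* **U** — "hedging" metabolic proteins expressed but unused under the
  condition,
* **Q** — a growth-rate-independent core (replication, envelope, ...).

Conservation gives `phi_R + phi_M + phi_U + phi_Q = 1`, and the
growth-related budget is `phi_max = 1 - phi_Q`, taken as 0.43 from the
growth-law literature. Balanced growth ties the R and M sectors to the
growth rate through two phenomenological efficiencies,

```
lambda = tE * phi_R        (translational efficiency)
lambda = mE * phi_M        (metabolic efficiency)
```

so that `mE/tE = phi_R/phi_M`. A strain that must run its metabolism with a
smaller M sector at a given growth rate has a *higher* metabolic efficiency
demand and a *lower* translational efficiency; the ratio `mE/tE`, normalized
to wild type, is the headline per-strain statistic.

The three measured inputs per strain are:

1. **`phi_R`** from the total-RNA/total-protein mass ratio,
   `phi_R = (R/P) * rho` with `rho = 0.76` (an empirical conversion factor;
   most RNA is rRNA and ribosomes have a fixed RNA/protein composition).
2. **U/M** from the transcriptome. Protein-coding genes are assigned to M
   or U by mapping the union of differentially expressed genes (DEGs)
   across all mutants onto genome-scale metabolism-and-expression (ME)
   model predictions: genes with predicted protein translation flux
   `>= 1e-15` mmol/gDCW/h in *any* glucose-uptake sweep simulation are
   "utilized" (M when differentially expressed), the remainder of the ME
   scope "non-utilized" (U). DEGs outside the model's scope enter via a
   manual annotation table, except transcriptional regulators, which are
   never sector-assigned. Sector transcriptome fractions are
   `w_g = TPM_g * L_g / sum(TPM * L)` over the assigned genes — nucleotide
   fractions — and `U/M = sum_U w / sum_M w` is assumed to carry over to
   the proteome at the subsystem level (an explicit approximation: mRNA and
   protein levels correlate well at the pathway level, poorly per gene).
3. **`lambda`** from the slope of `ln(OD600)` versus time over the
   exponential window.

Given these, the partition closes in closed form:
`phi_M = (phi_max - phi_R) / (1 + U/M)`, `phi_U = phi_M * U/M`,
`phi_Q = 1 - phi_max`. The solution is rejected as infeasible when
`phi_R >= phi_max` (no budget left for metabolism).

Two derived quantities support the physiological interpretation:

* **Unused ribosomes**: treating the wild-type `tE` as the achievable
  optimum, `max(0, phi_R - lambda/tE_wt)` is ribosome capacity beyond what
  the observed growth rate requires. It is reported as a diagnostic and
  never fed back into the partition.
* **Millimolar conversion**: intracellular pools in umol/gDCW divide by the
  specific cell volume (2.3 uL/mg DCW) to give mM, e.g. for comparing an
  alpha-ketoglutarate pool with the 1.3 mM inhibition constant of the PTS
  first enzyme.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `rho` | 0.76 | — | R/P to `phi_R` conversion |
| `phi_max` | 0.43 | fraction | growth-related proteome budget |
| `cell_volume` | 2.3 | uL/mg DCW | umol/gDCW to mM |
| `dcw_factor` | 0.44 | g/L per OD600 | OD to biomass |
| cpm filter | 0.5 | cpm | gene retained iff >= 0.5 in all libraries |
| DEG call | \|log2FC\| >= 1, adj-p < 0.05 | — | FC boundary inclusive, p exclusive |
| Fisher tests | p < 0.01, >= 5 genes | — | regulon/sigma/ppGpp sets |
| pathway tests | >= 10 DEGs, BH adj-p < 0.05 | — | hypergeometric + BH |
| ME flux threshold | 1e-15 | mmol/gDCW/h | utilized vs non-utilized, inclusive |
| calibration range | 0.781–50 | uM | outside: flagged, LOQ S/N = 10 check |
| metabolite QC | S/N > 3, < 5 ppm, spike ratio in (1/5, 5) | — | quantifiability |
| metabolite test | FDR < 0.05 | — | two-sided t, BH across metabolites |
| correlations | p < 0.05 | — | Pearson on log2 values |

All cutoffs read boundaries literally: "more than 3" excludes 3.0,
">= 2-fold" includes 2.0, "< 0.05" excludes 0.05.

## The synthetic study

`truth_config()` plants a four-strain study — a wild type and three
regulator-deletion mutants (`ihf`, `fnr`, `arcA`) under anaerobic glucose
fermentation — whose defaults are the study conditions themselves:

* wild-type `phi_R = 0.130` (R/P 0.171), U/M 0.30, `lambda` 0.50 1/h;
* mutant partitions derived so the planted `mE/tE` fold changes are exactly
  3.26, 3.24 and 2.26 and growth rates fall 16–25% below wild type;
* glucose/ammonia uptake falling with growth rate, fermentation-product
  series linear in biomass so yields are constants;
* 2000 genes with 250 planted M-sector and 250 U-sector DEGs (plus manual
  outside-scope genes, excluded regulators, ppGpp target blocks);
* 20 metabolites with planted mutant accumulations, among them
  alpha-ketoglutarate at 2.99 umol/gDCW (1.3 mM) in `ihf` and `fnr`;
* 3 biological x 2 technical metabolite replicates (n = 6), RNA-seq and
  R/P in biological duplicate, phenotypes in triplicate.

Counts are negative-binomial around means proportional to the planted
nucleotide fractions (a single dispersion scalar, default 0.05 — the
simplest generative model adequate for sector sums); peak heights, R/P and
OD carry multiplicative lognormal noise with CV `noise_cv` (default 0.05,
technical replicates at half the biological CV); each modality draws from
its own seed stream, so adding one never perturbs another.

**The noise-free limit is idealized on purpose.** With `noise_cv = 0` and
`nb_dispersion = 0` the generator emits *expected* counts (real-valued)
rather than integer draws, so every downstream estimator must return the
planted truth to floating tolerance — a sharp correctness oracle that
integer rounding would blur. Integer-valued counts are guaranteed in any
stochastic mode.

What the generator does *not* emulate: per-gene mRNA-protein decoupling,
compositional/technical artifacts of library preparation, batch effects,
matrix effects or retention-time drift in LC-MS, deviations from perfectly
exponential growth. Passing recovery tests therefore demonstrates that the
estimators are correct and stable under the stated noise model, not that
the biological approximations (transcriptome-to-proteome proportionality,
literature `rho` and `phi_max`) hold for any particular real data set.

## Numerical choices

* Growth-rate and calibration fits are ordinary least squares (`lm`);
  exponential windows default to user bounds, with an automatic mode that
  takes the longest span with log-linear R^2 above a cutoff.
* Specific rates use `q = lambda * |dS/dX|` (substrate regressed on
  biomass), the standard balanced-growth form; the sign of the slope
  decides uptake versus secretion, and both are reported positive.
* The g-log transform `log2((x + sqrt(x^2 + a^2))/2)` uses the smallest
  positive observed value as the offset `a`; missing values are imputed by
  iterative rank-2 truncated SVD (tolerance 1e-6), the smallest
  structure-preserving choice for four-strain tables.
* Enrichment tests are one-sided (over-representation), run separately on
  up- and down-regulated lists against the cpm-filtered background; the
  exact hypergeometric tail is used throughout (identical to a one-sided
  Fisher test).
* Transcriptome fractions normalize over the joint M-and-U set; the U/M
  ratio is identical under per-sector normalization, only the reported
  per-sector fractions would differ.
* R/P biological duplicates are averaged before conversion to `phi_R`.
* Correlations pool all strains' replicate observations by default; a
  per-mutant-with-wild-type pairing is available through the `strains`
  argument of `correlate_with_phenotypes()`.

## Problem sizes

The test suite validates recovery at 1000–2000 genes and 4 strains;
fold-change recovery uses 20 independent studies of 2000 genes, the
enrichment oracle enumerates all ~6.4e5 hypergeometric tables with
background up to 60 and calibrates the type-I error on 1e4 null draws, the
metabolomics power estimate uses 100 two-group simulations (n = 6, CV 10%,
3-fold change) and the correlation sign-recovery 50 studies. These sizes
give Monte-Carlo standard errors well below the asserted margins.

## Known limitations

* `rho` and `phi_max` are literature constants, not fitted; systematic
  error in either shifts all partitions coherently (fold changes are less
  affected because they are ratios to wild type).
* DEG calling itself (the count model) is upstream; the package consumes a
  DEG table and only applies thresholds, so its results inherit whatever
  shrinkage or filtering the upstream tool applied.
* The ME-model flux sweep is consumed as a table; the number and spacing
  of glucose-uptake sweep points is the caller's choice, and the
  classification contract is defined for an arbitrary column set.
* Regulator-activity inference is rule-based (enrichment sign x regulator
  mode, effector sign x significance) and reports conflicts rather than
  resolving them; it does not model dose or kinetics.
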