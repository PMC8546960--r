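# sectorAlloc

Four-sector proteome allocation analysis of bacterial growth from
multi-omics measurements.

## The problem

Exponentially growing bacteria budget their proteome between ribosomes and
metabolic enzymes. When a global transcriptional regulator is deleted,
genes that are unnecessary under the growth condition are derepressed,
metabolic bottlenecks appear, intracellular metabolites accumulate, and
growth slows. `sectorAlloc` quantifies this with a four-way proteome
partition per strain,

    phi_R + phi_M + phi_U + phi_Q = 1,    phi_max = phi_R + phi_M + phi_U

(R: ribosomal, M: utilized metabolic, U: unused/hedging metabolic, Q:
growth-rate-independent core), and the balanced-growth efficiencies

    lambda = tE * phi_R,    lambda = mE * phi_M,    mE/tE = phi_R/phi_M.

The inputs are the measurements a physiology study actually produces:
RNA-seq counts plus a DEG table, total-RNA/total-protein ratios
(`phi_R = R/P x rho`, rho = 0.76), OD600 and extracellular concentration
time courses, ME-model protein translation fluxes for classifying genes as
utilized (M) or non-utilized (U), and 13C isotope-dilution metabolomics
peak tables with calibration standards. The package is aimed at systems
biologists who want the full chain — sector fractions, efficiencies,
regulon/pathway/ppGpp enrichment, absolute metabolite concentrations and
metabolite-phenotype correlations — as tested, composable functions.

A synthetic-data generator (`truth_config()`, `generate_study()`) plants a
complete four-strain study (wild type + three regulator mutants) with
known ground truth, so every stage is validated by parameter recovery.

## Worked example

```r
library(sectorAlloc)

cfg    <- truth_config(seed = 1, n_genes = 2000)  # the study conditions
bundle <- generate_study(cfg)
res    <- run_pipeline(bundle)

res$allocation[, c("strain", "phi_R", "phi_M", "phi_U", "um_ratio",
                   "lambda", "me_te_ratio", "fold_change")]
#>   strain phi_R  phi_M  phi_U um_ratio lambda me_te_ratio fold_change
#> 1     WT 0.131 0.2303 0.0684    0.297  0.497       0.571        1.00
#> 2    ihf 0.159 0.1006 0.1702    1.691  0.375       1.582        2.77
#> 3    fnr 0.157 0.0894 0.1832    2.048  0.387       1.759        3.08
#> 4   arcA 0.159 0.1222 0.1490    1.219  0.421       1.299        2.28
```

Each row is one strain's solved partition: the mutants carry a larger
ribosomal (`phi_R`) and unused (`phi_U`) sector, a smaller metabolic
sector, and hence an elevated `mE/tE` ratio; `fold_change` normalizes that
ratio to wild type (planted values 3.26, 3.24, 2.26 — a single noisy study
scatters around them; averaging over 20 seeds recovers them to within a
few percent). Downstream elements of `res` hold the enrichment table,
per-metabolite significance calls (e.g. alpha-ketoglutarate at
~2.99 umol/gDCW = 1.3 mM in the ihf/fnr mutants, matching the PTS
inhibition constant) and the pooled Pearson correlations (growth rate vs
glucose uptake r ~ +0.96, PEP vs uptake r ~ -0.92).

The `analysis/` directory holds the same workflow as numbered stage
scripts (`01_simulate.R` ... `06_correlation.R`), each writing its table
under `results/` with a short narrative of what it found.

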