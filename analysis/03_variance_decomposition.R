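#!/usr/bin/env Rscript
# Stage 3: flight-nested variance decomposition. For every temporal trait and
# both managements, fits value = mu + flight + rep(flight) + genotype(flight)
# + residual (all random), reports the percentage decomposition and temporal
# repeatability, and writes the flight-wise genotypic values (BLUPs) used as
# phenomic predictors downstream.

library(tppr)

phenomic <- read_phenomic_table("results/phenomic.tsv")
rows <- list()
for (trial in c("OM", "SM")) {
  fits <- decompose_traits(phenomic, trial = trial)
  for (tid in names(fits)) {
    f <- fits[[tid]]
    tr <- temporal_repeatability(f)
    rows[[paste(trial, tid)]] <- data.frame(
      trial = trial, trait_id = tid,
      pct_flight = f$percentages[["flight"]],
      pct_rep = f$percentages[["rep_in_flight"]],
      pct_genotype = f$percentages[["genotype_in_flight"]],
      pct_residual = f$percentages[["residual"]],
      tr = tr$tr, method = f$method)
    if (trial == "OM")
      write_blup_matrix(genotypic_values(f), sprintf("results/blups_%s.tsv", tid))
  }
}
comp <- do.call(rbind, rows)
utils::write.table(comp, "results/variance_components.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("variance decomposition (percent of total):\n")
print(comp, row.names = FALSE, digits = 3)
cat(sprintf("\nflight share spans %.0f-%.0f%%; genotype-within-flight %.1f-%.1f%%; TR %.2f-%.2f\n",
            min(comp$pct_flight), max(comp$pct_flight),
            min(comp$pct_genotype), max(comp$pct_genotype),
            min(comp$tr), max(comp$tr)))
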