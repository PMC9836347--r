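#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-management maize trial that the rest of
# the analysis runs on — 280 hybrids (230 under stress) from inbred crosses,
# RCBD with 2 replications, 15 drone flights from 27 to 144 days after
# planting, four VIs plus canopy height, and GBS-style markers. Writes the
# phenomic table, trait tables, marker matrix, layout and truth record under
# results/.

library(tppr)

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(
  n_parents = 40, n_hybrids = 280, n_hybrids_sm = 230, n_markers = 800,
  temporal_traits = list(NGRDI = list(mean = 0.30, sd = 0.15),
                         RCC   = list(mean = 0.35, sd = 0.08),
                         GLI   = list(mean = 0.20, sd = 0.10),
                         ExG   = list(mean = 0.25, sd = 0.12),
                         CHM   = list(mean = 150,  sd = 45)),
  # half of the genotype-within-flight signal is a repeatable non-marker
  # response that also enters grain yield: the regime in which temporal
  # phenomics can outpredict genome-wide markers for untested genotypes
  vi_trait_env_link = 0.5, gy_env_link = 0.8, vi_gy_genetic_corr = 0.6,
  seed = 2017)

trial <- simulate_trial(cfg)
cat(sprintf("simulated %d OM + %d SM genotypes, %d flights, %d phenomic rows\n",
            cfg$n_hybrids, cfg$n_hybrids_sm, length(cfg$flight_days),
            nrow(trial$phenomic)))

write_phenomic_table(trial$phenomic, "results/phenomic.tsv")
write_marker_table(trial$markers, "results/markers.tsv")
write_trait_table(trial$traits$OM, "results/traits_OM.tsv")
write_trait_table(trial$traits$SM, "results/traits_SM.tsv")
write_layout_geojson(trial$layout, "results/layout.geojson")
# truth record for downstream validation
truth_tab <- do.call(rbind, lapply(names(trial$truth$temporal_genetic_values),
  function(tid) {
    m <- trial$truth$temporal_genetic_values[[tid]]
    data.frame(trait_id = tid, genotype = rep(rownames(m), ncol(m)),
               flight_day = rep(colnames(m), each = nrow(m)),
               genetic_value = as.vector(m))
  }))
utils::write.table(truth_tab, "results/truth_temporal.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/phenomic.tsv, markers.tsv, traits_*.tsv, layout.geojson, truth_temporal.tsv\n")
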