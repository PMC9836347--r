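#!/usr/bin/env Rscript
# Stage 5: trait prediction. Predicts grain yield from the temporal feature
# matrix (linear, ridge, lasso, elastic net, random forest) and from markers
# (GBLUP), under the four cross-validation schemes sharing one split plan:
# CV1 tested genotypes / tested environment (resubstitution control),
# CV2 untested genotypes / tested environment, CV3 tested / untested,
# CV4 untested / untested. Writes per-iteration records and the comparison.

library(tppr)

features <- read_feature_matrix("results/features.tsv")
traits_om <- read_trait_table("results/traits_OM.tsv")
traits_sm <- read_trait_table("results/traits_SM.tsv")
markers <- read_marker_table("results/markers.tsv")

common <- Reduce(intersect, list(rownames(features), traits_om$genotype,
                                 traits_sm$genotype))
cat(sprintf("%d genotypes with complete OM + SM + feature data\n", length(common)))
y_om <- stats::setNames(traits_om$GY, traits_om$genotype)[common]
y_sm <- stats::setNames(traits_sm$GY, traits_sm$genotype)[common]
kernel <- grm_vanraden(markers$dosages[common, ])

n_iter <- 30  # shared iterations; every model consumes this one plan
plan <- make_split_plan(common, train_frac = 0.7, n_iter = n_iter, seed = 42)
write_split_plan(plan, "results/plan.json")

models <- c("linear", "ridge", "lasso", "elasticnet", "randomforest", "gblup")
schemes <- c("CV1", "CV2", "CV3", "CV4")
results <- list()
for (mod in models) for (sch in schemes) {
  dat <- if (mod == "gblup") kernel else features
  res <- run_cv_scheme(sch, model_spec(mod), dat, y_om, y_sm, plan, trait = "GY")
  results[[paste(mod, sch)]] <- res
  write_tsv <- utils::write.table
  write_tsv(res$records, sprintf("results/result_GY_%s_%s.tsv", mod, sch),
            sep = "\t", quote = FALSE, row.names = FALSE)
}

summ <- do.call(rbind, lapply(results, `[[`, "summary"))
utils::write.table(summ, "results/prediction_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("\nmean accuracy over %d shared iterations:\n", n_iter))
wide <- stats::reshape(summ[, c("scheme", "model", "mean_accuracy")],
                       idvar = "model", timevar = "scheme", direction = "wide")
names(wide) <- sub("mean_accuracy\\.", "", names(wide))
print(wide, row.names = FALSE, digits = 3)

cmp <- compare_methods(unname(results[grepl("CV2", names(results))]))
utils::write.table(cmp$pairs, "results/comparison_CV2.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\nCV2 paired differences (ridge TPP rows vs GBLUP etc.):\n")
print(cmp$pairs, row.names = FALSE, digits = 3)
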