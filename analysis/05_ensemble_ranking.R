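#!/usr/bin/env Rscript

## Stage 5: ensemble LOOCV gene ranking. A two-class cohort (marker-high
## vs marker-low) with a planted differentially expressed block is
## classified by the four-learner majority-vote ensemble inside
## leave-one-out cross-validation, with moderated-t gene selection on each
## training fold only; genes are ranked by how often they are selected.

suppressPackageStartupMessages(library(gliosig))

out_dir <- "results/ensemble"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

de_probes <- sprintf("probe_%04d", 1:15)
spec <- cohort_spec(n_samples = 60, n_probes = 200,
                    de_block = list(probes = de_probes, shift = 1.6,
                                    prop = 0.5),
                    seed = 3033)
co <- generate_cohort(spec)
classes <- ifelse(co$class_labels == 1, "high", "low")
cat(sprintf("cohort: %d genes x %d samples, %d 'high' / %d 'low'\n",
            nrow(co$expression), ncol(co$expression),
            sum(classes == "high"), sum(classes == "low")))

cv <- loocv_ensemble_classify(co$expression, classes,
                              specs = learner_specs(inner_folds = 5),
                              seed = 11)
cat(sprintf("LOOCV majority-vote accuracy: %.1f%% over %d folds (%d fallback folds)\n",
            100 * cv$accuracy, cv$n_folds, cv$n_fallback))
per_learner <- vapply(c("svm", "rf", "knn", "nsc"), function(l)
  mean(cv$predictions[[l]] == cv$predictions$truth), numeric(1))
cat("per-learner accuracy:",
    paste(sprintf("%s %.1f%%", names(per_learner), 100 * per_learner),
          collapse = ", "), "\n")

rk <- rank_genes_by_selection_frequency(cv)
cat("top 10 genes by selection frequency:\n")
print(head(rk, 10))
cat(sprintf("planted DE probes in the top 15 ranks: %d/15\n",
            sum(head(rk$gene, 15) %in% de_probes)))

write.table(rk, file.path(out_dir, "gene_ranking.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cv$predictions, file.path(out_dir, "loocv_predictions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("written to", out_dir, "\n")
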