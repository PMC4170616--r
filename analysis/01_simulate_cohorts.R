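#!/usr/bin/env Rscript

## Build the two synthetic glioblastoma-like expression cohorts used by the
## downstream analysis scripts: a smaller "test" cohort and a larger
## "validation" cohort sharing a planted five-probe prognostic signature
## (two risk probes with positive log-hazard ratios, three protective ones
## with negative), plus a gene panel mapping symbols to probes. Everything
## is written in the package's TSV formats under results/cohorts/.

suppressPackageStartupMessages(library(gliosig))

out_dir <- "results/cohorts"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

## five planted signature probes, mirroring a mixed-direction repair panel
effects <- setNames(c(0.75, 0.65, -0.70, -0.85, -0.65),
                    sprintf("probe_%04d", 1:5))

make_spec <- function(n, seed, censoring)
  cohort_spec(n_samples = n, n_probes = 300,
              prognostic_effects = effects,
              baseline = list(family = "exponential", rate = 1 / 400),
              censoring_rate = censoring, seed = seed)

test_cohort <- generate_cohort(make_spec(250, seed = 1001, censoring = 0.08))
valid_cohort <- generate_cohort(make_spec(500, seed = 1002, censoring = 0.18))

write_cohort(test_cohort, out_dir, "test")
write_cohort(valid_cohort, out_dir, "validation")

## panel: 100 probes (the 5 planted + 95 others), 2 probes per "gene"
panel_probes <- sprintf("probe_%04d", 1:100)
panel <- data.frame(gene = sprintf("GENE%03d", ceiling(seq_along(panel_probes) / 2)),
                    probe = panel_probes)
write.table(panel, file.path(out_dir, "panel.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("test cohort: %d probes x %d samples, %.0f%% events\n",
            nrow(test_cohort$expression), ncol(test_cohort$expression),
            100 * mean(test_cohort$survival$event)))
cat(sprintf("validation cohort: %d probes x %d samples, %.0f%% events\n",
            nrow(valid_cohort$expression), ncol(valid_cohort$expression),
            100 * mean(valid_cohort$survival$event)))
cat("planted signature:", paste(names(effects), sprintf("(%+.2f)", effects),
                                collapse = ", "), "\n")
cat("written to", out_dir, "\n")
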