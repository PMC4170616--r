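#!/usr/bin/env Rscript

## Stage 1: optimal-cutpoint survival screen of the gene panel in each
## cohort with BH false-discovery control, then the cross-cohort consensus
## (significant in both, same direction of association). Reads the cohorts
## written by 01_simulate_cohorts.R.

suppressPackageStartupMessages(library(gliosig))

in_dir <- "results/cohorts"
out_dir <- "results/screen"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

panel <- read_gene_panel(file.path(in_dir, "panel.tsv"))
load1 <- function(prefix) {
  al <- align_clinical(
    read_expression_matrix(file.path(in_dir, paste0(prefix, "_expression.tsv"))),
    read_clinical_table(file.path(in_dir, paste0(prefix, "_clinical.tsv"))))
  al
}
test_c <- load1("test")
valid_c <- load1("validation")

al <- intersect_probes(test_c$expression, valid_c$expression, panel)
cat(sprintf("panel probes present in both cohorts: %d\n", length(al$probes)))

sc_test <- screen_probes(al$a, test_c$surv)
sc_valid <- screen_probes(al$b, valid_c$surv)
cat(sprintf("BH-significant probes: %d (test), %d (validation)\n",
            sum(sc_test$significant), sum(sc_valid$significant)))

cons <- consensus_probes(sc_test, sc_valid)
cat(sprintf("consensus probes (both cohorts, concordant direction): %d\n",
            nrow(cons)))
print(cons[, c("probe", "direction", "p_adj_a", "p_adj_b")])

write.table(sc_test, file.path(out_dir, "screen_test.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sc_valid, file.path(out_dir, "screen_validation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cons, file.path(out_dir, "consensus.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("written to", out_dir, "\n")
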