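#!/usr/bin/env Rscript

## Stage 2-3: iterative multivariate Cox reduction of the consensus probes
## in both cohorts, construction of the beta-weighted prognostic index
## from the surviving probes (combined coefficient = mean of the two
## cohorts' log hazard ratios), stratification of the validation cohort
## into three prognostic groups, and the 1/2/3-year percent-survival
## quadratics over the group median scores.

suppressPackageStartupMessages(library(gliosig))

in_dir <- "results/cohorts"
sc_dir <- "results/screen"
out_dir <- "results/pi"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

panel <- read_gene_panel(file.path(in_dir, "panel.tsv"))
load1 <- function(prefix) align_clinical(
  read_expression_matrix(file.path(in_dir, paste0(prefix, "_expression.tsv"))),
  read_clinical_table(file.path(in_dir, paste0(prefix, "_clinical.tsv"))))
test_c <- load1("test")
valid_c <- load1("validation")
al <- intersect_probes(test_c$expression, valid_c$expression, panel)
cons <- read.delim(file.path(sc_dir, "consensus.tsv"))

z_test <- dichotomize_expression(al$a, setNames(cons$cutpoint_a, cons$probe))
z_valid <- dichotomize_expression(al$b, setNames(cons$cutpoint_b, cons$probe))
elim <- backward_eliminate(list(z_test, z_valid),
                           list(test_c$surv, valid_c$surv), cons$probe)
cat(sprintf("elimination: %d round(s) test, %d round(s) validation\n",
            elim$rounds[1], elim$rounds[2]))
cat("final cross-cohort model:", paste(elim$probes_final, collapse = ", "), "\n")

final <- elim$probes_final
gene_of <- setNames(panel$gene, panel$probe)[final]
beta_t <- setNames(elim$fits[[1]]$beta, elim$fits[[1]]$term)[final]
beta_v <- setNames(elim$fits[[2]]$beta, elim$fits[[2]]$term)[final]
model <- pi_model(gene = unname(gene_of), probe = final,
                  cutpoint = setNames(cons$cutpoint_b, cons$probe)[final],
                  direction = cons$direction[match(final, cons$probe)],
                  beta_test = unname(beta_t), beta_validation = unname(beta_v))
cat("\ncombined prognostic-index coefficients (mean of the two ln HR):\n")
print(model[, c("gene", "probe", "beta_test", "beta_validation", "beta_combined")])

expr_g <- al$b[final, , drop = FALSE]
rownames(expr_g) <- model$gene
scores <- compute_pi(model, expr_g)
rg <- assign_risk_groups(scores, valid_c$surv, k = 3)
cat(sprintf("\nrisk groups (validation cohort): sizes %s, median scores %s\n",
            paste(table(rg$group), collapse = "/"),
            paste(sprintf("%.3f", rg$medians), collapse = ", ")))
cat(sprintf("extreme-group log-rank: chisq = %.1f, p = %.3g\n",
            rg$extreme_logrank$chisq, rg$extreme_logrank$p))

curves <- lapply(c(`1` = 365, `2` = 730, `3` = 1095), function(hd)
  fit_year_survival_curve(rg, hd))
for (yr in names(curves)) {
  co <- curves[[yr]]$coef
  cat(sprintf("%s-year survival curve: %.1f x^2 + %.1f x + %.1f\n",
              yr, co[["a"]], co[["b"]], co[["c"]]))
}
ex_score <- round(stats::median(scores), 2)
p2y <- predict_survival(curves[["2"]], ex_score)
cat(sprintf("predicted 2-year survival at PI = %.2f: %.0f%%\n",
            ex_score, p2y$percent))

write.table(model, file.path(out_dir, "pi_model.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = colnames(al$b), score = scores,
                       group = rg$group),
            file.path(out_dir, "risk_groups.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, lapply(names(curves), function(yr)
  data.frame(horizon_years = yr, t(curves[[yr]]$coef)))),
  file.path(out_dir, "year_curves.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("written to", out_dir, "\n")
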