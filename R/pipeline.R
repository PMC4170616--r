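#' Configuration for the full two-cohort analysis
#'
#' Each cohort is either a [cohort_spec] (generated on the fly) or a list
#' `list(expression = <path>, clinical = <path>)` of files in the
#' package's TSV formats.
#'
#' @param cohort_a,cohort_b Cohort sources.
#' @param panel Optional gene panel (`gene_panel` data frame or TSV path);
#'   defaults to all shared probes.
#' @param alpha_screen BH-adjusted significance level of the univariate
#'   screen.
#' @param alpha_model Wald level of the multivariate elimination.
#' @param pi_groups Number of prognostic groups (default 3).
#' @param ann Either `NULL` (skip the network stage) or a list
#'   `list(config = mlp_config(), top_m =, top_edges =)`.
#' @param ensemble Either `NULL` (skip) or a list
#'   `list(specs = learner_specs(), target = <probe>)`; classes are the
#'   target probe's median split in cohort B.
#' @param treatment_strata Re-run the per-probe survival comparison within
#'   chemotherapy/radiotherapy strata of cohort B (using the already-fixed
#'   cutpoints).
#' @param out_dir Output directory for the report bundle.
#' @param seed Global seed recorded in the manifest.
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort_a, cohort_b, panel = NULL,
                       alpha_screen = 0.05, alpha_model = 0.05,
                       pi_groups = 3, ann = NULL, ensemble = NULL,
                       treatment_strata = FALSE,
                       out_dir = tempfile("gliosig_run_"), seed = 1) {
  ok_cohort <- function(x) inherits(x, "cohort_spec") ||
    (is.list(x) && all(c("expression", "clinical") %in% names(x)))
  stop_if(!ok_cohort(cohort_a) || !ok_cohort(cohort_b),
          "run_config: each cohort must be a cohort_spec or expression/clinical paths")
  structure(list(cohort_a = cohort_a, cohort_b = cohort_b, panel = panel,
                 alpha_screen = alpha_screen, alpha_model = alpha_model,
                 pi_groups = pi_groups, ann = ann, ensemble = ensemble,
                 treatment_strata = treatment_strata,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

load_cohort <- function(x) {
  if (inherits(x, "cohort_spec")) {
    co <- generate_cohort(x)
    return(align_clinical(co$expression, co$clinical))
  }
  align_clinical(read_expression_matrix(x$expression),
                 read_clinical_table(x$clinical))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full two-cohort prognostic workflow
#'
#' Stages, in order: load/generate both cohorts; align on shared (panel)
#' probes; optimal-cutpoint screen of each cohort with BH control;
#' cross-cohort consensus; iterative multivariate Cox reduction;
#' prognostic-index construction, risk-group stratification and 1/2/3-year
#' survival curves; optional treatment-stratified re-analysis; optional
#' ANN probe screening + interaction network with hub detection; optional
#' ensemble LOOCV gene ranking. All tabular results are written under
#' `config$out_dir` together with a reproducibility manifest; an identical
#' manifest implies identical outputs.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with the in-memory results of every stage
#'   that ran (`screen_a`, `screen_b`, `consensus`, `elimination`,
#'   `pi_model`, `risk_groups`, `year_curves`, `strata`, `ann`,
#'   `ensemble`, `manifest`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  ca <- stage("load_cohort_a", load_cohort(config$cohort_a))
  cb <- stage("load_cohort_b", load_cohort(config$cohort_b))
  panel <- config$panel
  if (is.character(panel)) panel <- read_gene_panel(panel)
  al <- stage("intersect", intersect_probes(ca$expression, cb$expression, panel))

  out$screen_a <- stage("screen_a",
    screen_probes(al$a, ca$surv, alpha = config$alpha_screen))
  out$screen_b <- stage("screen_b",
    screen_probes(al$b, cb$surv, alpha = config$alpha_screen))
  utils::write.table(out$screen_a, file.path(config$out_dir, "screen_a.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$screen_b, file.path(config$out_dir, "screen_b.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  out$consensus <- stage("consensus", consensus_probes(out$screen_a, out$screen_b))
  utils::write.table(out$consensus, file.path(config$out_dir, "consensus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (nrow(out$consensus) == 0) {
    message("run_full_analysis: empty consensus set; ",
            "skipping model reduction, prognostic index and network stages")
    out$manifest <- write_manifest(config, out)
    return(invisible(out))
  }

  cp_a <- stats::setNames(out$consensus$cutpoint_a, out$consensus$probe)
  cp_b <- stats::setNames(out$consensus$cutpoint_b, out$consensus$probe)
  za <- dichotomize_expression(al$a, cp_a)
  zb <- dichotomize_expression(al$b, cp_b)
  out$elimination <- stage("backward_eliminate",
    backward_eliminate(list(za, zb), list(ca$surv, cb$surv),
                       out$consensus$probe, alpha = config$alpha_model))

  if (out$elimination$empty) {
    message("run_full_analysis: no probe survived the multivariate reduction; ",
            "skipping prognostic index and network stages")
    out$manifest <- write_manifest(config, out)
    return(invisible(out))
  }

  final <- out$elimination$probes_final
  gene_of <- if (!is.null(al$panel))
    stats::setNames(al$panel$gene, al$panel$probe)[final] else final
  beta_a <- stats::setNames(out$elimination$fits[[1]]$beta,
                            out$elimination$fits[[1]]$term)[final]
  beta_b <- stats::setNames(out$elimination$fits[[2]]$beta,
                            out$elimination$fits[[2]]$term)[final]
  out$pi_model <- stage("pi_model", pi_model(
    gene = unname(gene_of), probe = final,
    cutpoint = cp_b[final],
    direction = out$consensus$direction[match(final, out$consensus$probe)],
    beta_test = unname(beta_a), beta_validation = unname(beta_b)))
  utils::write.table(out$pi_model, file.path(config$out_dir, "pi_model.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(out$pi_model),
                       file.path(config$out_dir, "pi_model.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  ## score cohort B (validation-style) with its own cutpoints
  expr_genes <- al$b[final, , drop = FALSE]
  rownames(expr_genes) <- out$pi_model$gene
  scores <- stage("compute_pi", compute_pi(out$pi_model, expr_genes))
  out$risk_groups <- stage("risk_groups",
    assign_risk_groups(scores, cb$surv, k = config$pi_groups))
  grp_tab <- data.frame(sample_id = colnames(al$b), score = scores,
                        group = out$risk_groups$group)
  utils::write.table(grp_tab, file.path(config$out_dir, "risk_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (config$pi_groups == 3) {
    out$year_curves <- lapply(c(`1y` = 365, `2y` = 730, `3y` = 1095),
      function(hd) tryCatch(fit_year_survival_curve(out$risk_groups, hd),
                            error = function(e) NULL))
    yc <- do.call(rbind, lapply(names(out$year_curves), function(nm) {
      f <- out$year_curves[[nm]]
      if (is.null(f)) return(NULL)
      data.frame(horizon = nm, a = f$coef[["a"]], b = f$coef[["b"]],
                 c = f$coef[["c"]])
    }))
    if (!is.null(yc))
      utils::write.table(yc, file.path(config$out_dir, "year_curves.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (isTRUE(config$treatment_strata)) {
    out$strata <- stage("treatment_strata",
      strata_reanalysis(al$b, zb, cb, final))
    utils::write.table(out$strata, file.path(config$out_dir, "strata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(config$ann)) {
    out$ann <- stage("ann", {
      cfg <- config$ann$config %||% mlp_config(seed = config$seed)
      lapply(stats::setNames(final, final), function(target) {
        rk <- rank_probes_by_prediction(al$b, target, cfg)
        top <- utils::head(rk$probe, config$ann$top_m %||% 20)
        net <- infer_pairwise_interactions(al$b[top, , drop = FALSE], cfg)
        pruned <- select_top_edges_and_hubs(net,
                                            top_k = config$ann$top_edges %||% 100)
        export_network(pruned$network,
                       file.path(config$out_dir, paste0("network_", target, ".sif")),
                       "sif")
        export_network(pruned$network,
                       file.path(config$out_dir, paste0("network_", target, ".graphml")),
                       "graphml")
        list(ranking = rk, pruned = pruned)
      })
    })
  }

  if (!is.null(config$ensemble)) {
    out$ensemble <- stage("ensemble", {
      target <- config$ensemble$target %||% final[1]
      classes <- ifelse(al$b[target, ] > stats::median(al$b[target, ]),
                        "high", "low")
      cvr <- loocv_ensemble_classify(
        al$b[setdiff(rownames(al$b), target), , drop = FALSE], classes,
        specs = config$ensemble$specs %||% learner_specs(),
        seed = config$seed)
      rk <- rank_genes_by_selection_frequency(cvr)
      utils::write.table(rk, file.path(config$out_dir, "gene_ranking.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(cv = cvr, ranking = rk)
    })
  }

  out$manifest <- write_manifest(config, out)
  invisible(out)
}

## KM/log-rank of each final probe within the treatment strata of cohort B,
## re-using the consensus cutpoints (no re-derivation per stratum).
strata_reanalysis <- function(expr_b, zb, cb, probes) {
  rows <- list()
  for (flag in c("chemotherapy", "radiotherapy")) {
    if (!flag %in% names(cb$clinical)) next
    for (lev in c("yes", "no")) {
      idx <- cb$clinical[[flag]] == lev
      if (sum(idx) < 10 || sum(cb$surv$event[idx]) == 0) next
      for (pr in probes) {
        g <- zb[pr, idx]
        if (length(unique(g)) < 2) next
        lr <- logrank_test(surv_data(cb$surv$time[idx], cb$surv$event[idx],
                                     ifelse(g == 1, "high", "low")))
        rows[[length(rows) + 1L]] <-
          data.frame(stratum = flag, level = lev, probe = pr, n = sum(idx),
                     chisq = lr$chisq, p = lr$p)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(stratum = character(), level = character(),
                      probe = character(), n = integer(), chisq = numeric(),
                      p = numeric()))
  do.call(rbind, rows)
}

write_manifest <- function(config, out) {
  manifest <- list(
    package = "gliosig",
    version = as.character(utils::packageVersion("gliosig")),
    seed = config$seed,
    alpha_screen = config$alpha_screen,
    alpha_model = config$alpha_model,
    pi_groups = config$pi_groups,
    stages_run = names(out),
    cohort_a = if (inherits(config$cohort_a, "cohort_spec"))
      list(synthetic = TRUE, seed = config$cohort_a$seed,
           n_samples = config$cohort_a$n_samples,
           n_probes = config$cohort_a$n_probes)
      else list(synthetic = FALSE, files = config$cohort_a),
    cohort_b = if (inherits(config$cohort_b, "cohort_spec"))
      list(synthetic = TRUE, seed = config$cohort_b$seed,
           n_samples = config$cohort_b$n_samples,
           n_probes = config$cohort_b$n_probes)
      else list(synthetic = FALSE, files = config$cohort_b))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
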