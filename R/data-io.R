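## Tab-delimited readers/writers for the cohort formats (GEO series-matrix
## style expression, clinical tables, gene panels) plus network export.

#' Read an expression matrix
#'
#' Tab-delimited text, header row of sample IDs, first column probe IDs,
#' numeric log-scale expression values. The reader is the exact inverse of
#' [write_expression_matrix].
#'
#' @param path File path.
#' @return Probes x samples numeric matrix with unique dimnames.
#' @export
read_expression_matrix <- function(path) {
  stop_if(!file.exists(path), "read_expression_matrix: no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  stop_if(length(unique(nf)) != 1,
          "read_expression_matrix: ragged rows (lines ",
          paste(utils::head(which(nf != nf[1]), 3), collapse = ", "), ")")
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           quote = "")
  probes <- tab[[1]]
  samples <- colnames(tab)[-1]
  dup_p <- probes[duplicated(probes)]
  stop_if(length(dup_p) > 0, "read_expression_matrix: duplicated probe ID(s): ",
          paste(unique(dup_p), collapse = ", "))
  dup_s <- samples[duplicated(samples)]
  stop_if(length(dup_s) > 0, "read_expression_matrix: duplicated sample ID(s): ",
          paste(unique(dup_s), collapse = ", "))
  vals <- suppressWarnings(
    vapply(tab[-1], as.numeric, numeric(length(probes))))
  if (length(probes) == 1L) vals <- matrix(vals, nrow = 1)
  bad <- which(is.na(vals), arr.ind = TRUE)
  stop_if(nrow(bad) > 0,
          "read_expression_matrix: non-numeric or blank cell at probe '",
          probes[bad[1, 1]], "', sample '", samples[bad[1, 2]], "'")
  dimnames(vals) <- list(probes, samples)
  vals
}

#' Write an expression matrix
#' @param expression Probes x samples matrix with dimnames.
#' @param path Output path (TSV; first column `probe_id`).
#' @export
write_expression_matrix <- function(expression, path) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            !is.null(colnames(expression)))
  df <- data.frame(probe_id = rownames(expression), expression,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' TSV with columns `sample_id`, `time` (days), `event` (0/1) and any
#' further covariates (age, sex, chemotherapy, radiotherapy).
#'
#' @param path File path.
#' @return Data frame, validated.
#' @export
read_clinical_table <- function(path) {
  stop_if(!file.exists(path), "read_clinical_table: no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, quote = "")
  need <- c("sample_id", "time", "event")
  stop_if(!all(need %in% names(tab)), "read_clinical_table: missing column(s): ",
          paste(setdiff(need, names(tab)), collapse = ", "))
  stop_if(anyDuplicated(tab$sample_id) > 0,
          "read_clinical_table: duplicated sample IDs")
  stop_if(any(!is.finite(tab$time)) || any(tab$time < 0),
          "read_clinical_table: survival times must be >= 0")
  stop_if(!all(tab$event %in% c(0, 1)), "read_clinical_table: 'event' must be 0/1")
  tab
}

#' Write a clinical table
#' @param clinical Data frame with at least `sample_id`, `time`, `event`.
#' @param path Output path.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene panel
#'
#' TSV mapping gene symbols to probe IDs (columns `gene`, `probe`); a gene
#' may have several probes, each probe appears once.
#'
#' @param path File path.
#' @return Data frame of class `gene_panel` (`gene`, `probe`).
#' @export
read_gene_panel <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, quote = "",
                           colClasses = "character")
  stop_if(!all(c("gene", "probe") %in% names(tab)),
          "read_gene_panel: need columns 'gene' and 'probe'")
  stop_if(nrow(tab) == 0, "read_gene_panel: empty panel")
  stop_if(anyDuplicated(tab$probe) > 0,
          "read_gene_panel: duplicated probe IDs in panel")
  class(tab) <- c("gene_panel", "data.frame")
  tab
}

#' Align two cohorts on their shared panel probes
#'
#' Restricts both expression matrices to the panel probes present in both,
#' in identical probe order; sample sets are untouched.
#'
#' @param dataset_a,dataset_b Probes x samples matrices.
#' @param panel Optional `gene_panel` (or data frame with a `probe`
#'   column) restricting the universe.
#' @return List: `a`, `b` (aligned matrices), `probes` (retained set),
#'   `panel` (retained panel rows, if a panel was given).
#' @export
intersect_probes <- function(dataset_a, dataset_b, panel = NULL) {
  stopifnot(is.matrix(dataset_a), is.matrix(dataset_b))
  stop_if(nrow(dataset_a) == 0 || nrow(dataset_b) == 0,
          "intersect_probes: empty dataset")
  common <- intersect(rownames(dataset_a), rownames(dataset_b))
  if (!is.null(panel)) common <- common[common %in% panel$probe]
  ## keep dataset A's row order
  common <- rownames(dataset_a)[rownames(dataset_a) %in% common]
  stop_if(length(common) == 0, "intersect_probes: no probes in common")
  list(a = dataset_a[common, , drop = FALSE],
       b = dataset_b[common, , drop = FALSE],
       probes = common,
       panel = if (!is.null(panel)) panel[panel$probe %in% common, , drop = FALSE])
}

#' Drop expression samples without clinical records
#'
#' Samples present in the expression matrix but missing from the clinical
#' table are dropped with a warning (cases with missing survival data);
#' the clinical table is reordered to the expression columns.
#'
#' @param expression Probes x samples matrix.
#' @param clinical Clinical data frame with `sample_id`, `time`, `event`.
#' @return List: `expression`, `clinical`, `surv` ([surv_data]).
#' @export
align_clinical <- function(expression, clinical) {
  keep <- colnames(expression) %in% clinical$sample_id
  if (!all(keep)) {
    warning("align_clinical: dropping ", sum(!keep),
            " sample(s) without clinical records", call. = FALSE)
    expression <- expression[, keep, drop = FALSE]
  }
  clinical <- clinical[match(colnames(expression), clinical$sample_id), ]
  list(expression = expression, clinical = clinical,
       surv = surv_data(clinical$time, clinical$event))
}

#' Export an interaction network
#'
#' SIF rows are `source <pos|neg> target`; GraphML carries the numeric
#' weight and sign as edge attributes and round-trips losslessly through
#' [import_network_graphml].
#'
#' @param net An [interaction_network].
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  stopifnot(inherits(net, "interaction_network"))
  format <- match.arg(format)
  e <- net$edges
  if (format == "sif") {
    lines <- if (nrow(e) > 0)
      sprintf("%s\t%s\t%s", e$source, ifelse(e$weight >= 0, "pos", "neg"),
              e$target)
    else character(0)
    writeLines(lines, path)
    return(invisible(path))
  }
  doc <- xml2::xml_new_root("graphml",
                            xmlns = "http://graphml.graphdrawing.org/xmlns")
  for (k in list(c("w", "weight", "double"), c("s", "sign", "string"))) {
    xml2::xml_add_child(doc, "key", id = k[1], `for` = "edge",
                        attr.name = k[2], attr.type = k[3])
  }
  g <- xml2::xml_add_child(doc, "graph", id = "net", edgedefault = "directed")
  for (nd in net$nodes) xml2::xml_add_child(g, "node", id = nd)
  for (i in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(g, "edge", source = e$source[i],
                              target = e$target[i])
    xml2::xml_add_child(ed, "data", key = "w",
                        sprintf("%.17g", e$weight[i]))
    xml2::xml_add_child(ed, "data", key = "s",
                        if (e$weight[i] >= 0) "pos" else "neg")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a GraphML network written by [export_network]
#' @param path GraphML file path.
#' @return An [interaction_network].
#' @export
import_network_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodes <- xml2::xml_attr(xml2::xml_find_all(doc, ".//g:node", ns), "id")
  eds <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- data.frame(
    source = xml2::xml_attr(eds, "source"),
    target = xml2::xml_attr(eds, "target"),
    weight = as.numeric(xml2::xml_text(
      xml2::xml_find_first(eds, "./g:data[@key='w']", ns))))
  if (length(eds) == 0)
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric())
  interaction_network(edges, nodes = nodes)
}

#' Write a synthetic cohort to disk
#'
#' Expression and clinical tables in the package's TSV formats, plus the
#' generating truth record as JSON.
#'
#' @param cohort A [generate_cohort] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the files written.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    expression = file.path(dir, paste0(prefix, "_expression.tsv")),
    clinical = file.path(dir, paste0(prefix, "_clinical.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_expression_matrix(cohort$expression, files[["expression"]])
  write_clinical_table(cohort$clinical, files[["clinical"]])
  truth <- unclass(cohort$truth)
  truth$probes <- NULL  # reconstructible from n_probes
  jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  files
}
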