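#' Immunohistochemistry H-score
#'
#' Intensity-weighted percentage score for a stained tumour section:
#' `H = 1 * p1 + 2 * p2 + 3 * p3`, where `p0..p3` are the percentages of
#' cells with no, weak, moderate and strong staining. Range 0-300.
#'
#' @param p0,p1,p2,p3 Percentages (0-100) per intensity category; each set
#'   must sum to 100 within `tol`. Vectorized over records.
#' @param tol Tolerance on the percentage sum (default 0.5, for rounded
#'   pathologist estimates).
#' @return Numeric H-score(s) in \[0, 300\].
#' @export
h_score <- function(p0, p1, p2, p3, tol = 0.5) {
  p <- cbind(p0, p1, p2, p3)
  stop_if(any(!is.finite(p)) || any(p < 0) || any(p > 100),
          "h_score: percentages must lie in [0, 100]")
  sums <- rowSums(p)
  bad <- abs(sums - 100) > tol
  stop_if(any(bad), "h_score: percentages do not sum to 100 (record ",
          paste(which(bad), collapse = ", "), ")")
  as.numeric(p[, 2] + 2 * p[, 3] + 3 * p[, 4])
}

#' Average H-scores over staining records
#'
#' Computes per-record H-scores and averages replicates of the same
#' sample/marker/compartment (patients with more than one specimen from
#' the same procedure receive the mean score).
#'
#' @param records Data frame with columns `sample_id`, `marker`,
#'   `compartment`, `p0`, `p1`, `p2`, `p3`.
#' @return Data frame `sample_id`, `marker`, `compartment`, `h_score`
#'   (one row per unique combination), order-independent.
#' @export
h_score_table <- function(records) {
  need <- c("sample_id", "marker", "compartment", "p0", "p1", "p2", "p3")
  stop_if(!all(need %in% names(records)), "h_score_table: missing columns: ",
          paste(setdiff(need, names(records)), collapse = ", "))
  records$h <- h_score(records$p0, records$p1, records$p2, records$p3)
  agg <- stats::aggregate(h ~ sample_id + marker + compartment,
                          data = records, FUN = mean)
  agg <- agg[order(agg$sample_id, agg$marker, agg$compartment), ]
  names(agg)[names(agg) == "h"] <- "h_score"
  rownames(agg) <- NULL
  agg
}

#' Reference H-score dichotomization thresholds
#'
#' Optimal-cutpoint-derived thresholds for the glioma protein markers:
#' scores strictly above the threshold are "high".
#'
#' @return Data frame `marker`, `compartment`, `threshold`.
#' @export
ihc_thresholds <- function() {
  data.frame(
    marker = c("APE1", "NBN", "PTEN", "PTEN", "PMS2"),
    compartment = c("nuclear", "nuclear", "nuclear", "cytoplasmic", "nuclear"),
    threshold = c(160, 85, 50, 10, 120))
}

#' Dichotomize a marker H-score
#'
#' Strictly greater than the configured threshold is "high"; at or below
#' is "low".
#'
#' @param h H-score(s).
#' @param marker Marker name (e.g. "APE1").
#' @param compartment "nuclear" (default) or "cytoplasmic".
#' @param thresholds Threshold table (default [ihc_thresholds]).
#' @return Character vector of "low"/"high".
#' @export
dichotomize_marker <- function(h, marker, compartment = "nuclear",
                               thresholds = ihc_thresholds()) {
  row <- thresholds$marker == marker & thresholds$compartment == compartment
  stop_if(sum(row) != 1, "dichotomize_marker: unknown marker/compartment: ",
          marker, "/", compartment)
  ifelse(h > thresholds$threshold[row], "high", "low")
}
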