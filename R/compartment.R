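#' Top-N transmembrane proteins labeled in one compartment
#'
#' Restricts to proteins with a transmembrane domain and ranks them in
#' descending order of the chosen abundance metric over that condition's
#' replicate channels: the mean experimental-to-control ratio (default) or
#' the mean raw intensity. Ties break lexicographically by protein id so
#' the ranking is invariant to input row order.
#'
#' @param enr an `enrichment_result` (supplies log2fc for the report).
#' @param ann an [annotation_table()].
#' @param ratios a `ratio_table` from [compute_nc_ratios()].
#' @param condition `"ENDO"` or `"SURF"`.
#' @param n ranking size (default 200); if fewer TM proteins are available
#'   the report is shorter and a warning is logged.
#' @param metric `"mean_nc_ratio"` or `"mean_intensity"`; for
#'   `"mean_intensity"` supply `table`.
#' @param table a [protein_quant_table()], required for `"mean_intensity"`.
#' @return object of class `topn_report`: list with `condition`, `n`,
#'   `metric`, and `ranking` (data frame `protein_id`, `rank`, `metric_value`,
#'   `log2fc`).
#' @export
top_n_tm <- function(enr, ann, ratios, condition = c("ENDO", "SURF"),
                     n = 200L, metric = c("mean_nc_ratio", "mean_intensity"),
                     table = NULL) {
  condition <- match.arg(condition)
  metric <- match.arg(metric)
  if (!is_count1(n) || n < 1) ep_validation_error("n must be a positive integer")
  design <- attr(ratios, "design")
  ch <- condition_channels(design, condition)
  tm_ids <- ann$protein_id[ann$has_tm_domain]
  cand <- intersect(enr$protein_id, tm_ids)
  if (metric == "mean_nc_ratio") {
    m <- ratio_matrix(ratios, ch)
  } else {
    if (is.null(table)) {
      ep_validation_error("metric 'mean_intensity' requires the quant table")
    }
    m <- intensity_matrix(table, ch)
  }
  cand <- intersect(cand, rownames(m))
  if (length(cand) < n) {
    warning(sprintf("only %d TM protein(s) available for top-%d %s ranking",
                    length(cand), n, condition), call. = FALSE)
  }
  vals <- rowMeans(m[cand, , drop = FALSE])
  ord <- order(-vals, cand)               # descending metric, id tie-break
  take <- utils::head(ord, n)
  ids <- cand[take]
  ranking <- data.frame(
    protein_id = ids,
    rank = seq_along(ids),
    metric_value = unname(vals[take]),
    log2fc = enr$log2fc[match(ids, enr$protein_id)],
    stringsAsFactors = FALSE
  )
  structure(list(condition = condition, n = as.integer(n), metric = metric,
                 ranking = ranking),
            class = "topn_report")
}

#' @export
print.topn_report <- function(x, ...) {
  cat(sprintf("Top-%d TM proteins by %s in %s (%d listed)\n",
              x$n, x$metric, x$condition, nrow(x$ranking)))
  invisible(x)
}

#' Directional overlap between two rankings
#'
#' Fraction of the first list's members also present in the second:
#' `|A intersect B| / |A|`. The denominator is the first argument, matching
#' the directional question "how many of these were also among those".
#'
#' @param a,b character vectors (or `topn_report` objects).
#' @return fraction in \[0, 1\].
#' @export
overlap_fraction <- function(a, b) {
  if (inherits(a, "topn_report")) a <- a$ranking$protein_id
  if (inherits(b, "topn_report")) b <- b$ranking$protein_id
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L) ep_validation_error("first list must be non-empty")
  length(intersect(a, b)) / length(a)
}

#' Subset enrichment results by an annotation category
#'
#' Returns the rows of the enrichment table whose proteins match the
#' requested annotation category, rank-ordered by ascending log2(surf/endo)
#' fold change (chord-plot order).
#'
#' @param enr an `enrichment_result`.
#' @param ann an [annotation_table()].
#' @param category `"secreted"`, `"tm"`, `"signal_peptide"`, or the name of
#'   any logical column in `ann` (custom tags).
#' @return subset of `enr`, rows ordered by ascending `log2fc`.
#' @export
subset_by_category <- function(enr, ann, category) {
  col <- switch(category,
    secreted = "is_secreted",
    tm = "has_tm_domain",
    signal_peptide = "has_signal_peptide",
    category
  )
  if (!col %in% names(ann) || !is.logical(ann[[col]])) {
    known <- c("secreted", "tm", "signal_peptide",
               names(ann)[vapply(ann, is.logical, logical(1))])
    ep_validation_error(paste0(
      "unknown category '", category, "'; known categories: ",
      paste(unique(known), collapse = ", ")))
  }
  ids <- ann$protein_id[ann[[col]]]
  out <- enr[enr$protein_id %in% ids, , drop = FALSE]
  out <- out[order(out$log2fc), , drop = FALSE]
  rownames(out) <- NULL
  out
}
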