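#' Unique-peptide filter
#'
#' First step of the filtering cascade: drop proteins identified by fewer
#' than `k` unique peptides (default policy: k = 2), keeping row order.
#'
#' @param table a [protein_quant_table()].
#' @param k minimum unique peptides; `k = 0` is the identity.
#' @return filtered `protein_quant` table.
#' @export
filter_min_peptides <- function(table, k = 2L) {
  if (!is_count1(k) || k < 0) ep_validation_error("k must be a non-negative integer")
  keep <- table$unique_peptides >= k
  removed <- sum(!keep)
  if (removed > 0) {
    stage_log("filter", sprintf(
      "removed %d protein(s) with < %d unique peptides", removed, k))
  }
  out <- as.data.frame(table)[keep, , drop = FALSE]
  protein_quant_table(out, quant_design(table))
}

#' True-positive / false-positive annotation for the ratiometric filter
#'
#' A protein is a true positive when it carries a signal peptide and/or a
#' transmembrane domain (it can legitimately reach the cell surface or the
#' endosomal lumen); proteins with neither are putative contaminants and
#' serve as false positives.
#'
#' @param ann an [annotation_table()].
#' @param ids character vector of protein ids to annotate; all must be
#'   present in `ann`.
#' @return named character vector (`"TP"`/`"FP"`) over `ids`.
#' @export
annotate_tp_fp <- function(ann, ids) {
  miss <- setdiff(ids, ann$protein_id)
  if (length(miss)) {
    ep_validation_error(paste0(
      "protein id(s) missing from annotations: ", paste(miss, collapse = ", ")))
  }
  idx <- match(ids, ann$protein_id)
  tp <- ann$has_signal_peptide[idx] | ann$has_tm_domain[idx]
  stats::setNames(ifelse(tp, "TP", "FP"), ids)
}

#' Ratiometric ROC cutoff (maximum TPR - FPR)
#'
#' Proteins are ranked by their experimental-to-control ratio in descending
#' order. Walking down the ranking, a cumulative true-positive rate and
#' false-positive rate are computed after each distinct ratio value (ties
#' are processed as a block), tracing a ROC curve. The cutoff is the ratio
#' maximizing TPR - FPR (the Youden index); on ties the highest (most
#' stringent) threshold wins. Retention at the threshold is inclusive by
#' default (`ratio >= cutoff`).
#'
#' @param ratios named numeric vector of ratios (names = protein ids).
#' @param labels named character vector (`"TP"`/`"FP"`) over the same ids.
#' @param channel_id label recorded in the result (the replicate channel).
#' @param inclusive retain proteins with ratio equal to the cutoff (default
#'   `TRUE`; `FALSE` retains strictly greater ratios, in which case the
#'   proteins at the maximizing rank itself are dropped).
#' @return object of class `cutoff_result`: list with `channel_id`, `curve`
#'   (data frame `threshold`, `tpr`, `fpr`), `chosen_threshold`, `youden`,
#'   and `retained` (character vector of protein ids).
#' @export
roc_cutoff <- function(ratios, labels, channel_id = NA_character_,
                       inclusive = TRUE) {
  ids <- names(ratios)
  if (is.null(ids) || is.null(names(labels))) {
    ep_validation_error("ratios and labels must be named by protein id")
  }
  labels <- labels[ids]
  if (any(is.na(labels))) {
    ep_validation_error("every ratio needs a TP/FP label")
  }
  n_tp <- sum(labels == "TP")
  n_fp <- sum(labels == "FP")
  if (n_tp == 0L || n_fp == 0L) {
    ep_degenerate_error(
      "ROC cutoff undefined: both TP and FP proteins must be present")
  }
  ord <- order(ratios, decreasing = TRUE)
  r_sorted <- ratios[ord]
  l_sorted <- labels[ord]
  thresholds <- unique(r_sorted)
  cum_tp <- cumsum(l_sorted == "TP")
  cum_fp <- cumsum(l_sorted == "FP")
  # index of the last protein in each tie block
  block_end <- length(r_sorted) - match(thresholds, rev(r_sorted)) + 1L
  tpr <- cum_tp[block_end] / n_tp
  fpr <- cum_fp[block_end] / n_fp
  youden_seq <- tpr - fpr
  best <- which.max(youden_seq)   # earliest maximizer = highest threshold
  chosen <- thresholds[best]
  retained <- if (inclusive) ids[ratios >= chosen] else ids[ratios > chosen]
  structure(
    list(
      channel_id = channel_id,
      curve = data.frame(threshold = thresholds, tpr = tpr, fpr = fpr),
      chosen_threshold = unname(chosen),
      youden = unname(youden_seq[best]),
      retained = retained
    ),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "ROC cutoff for channel %s: threshold %.4g (TPR - FPR = %.3f), %d protein(s) retained\n",
    x$channel_id, x$chosen_threshold, x$youden, length(x$retained)))
  invisible(x)
}

#' Apply the ROC cutoff to every experimental replicate
#'
#' @param ratios a `ratio_table` from [compute_nc_ratios()].
#' @param ann an [annotation_table()] covering all proteins in `ratios`.
#' @param inclusive see [roc_cutoff()].
#' @return named list of `cutoff_result`, one per experimental channel.
#' @export
roc_cutoff_per_replicate <- function(ratios, ann, inclusive = TRUE) {
  design <- attr(ratios, "design")
  labels <- annotate_tp_fp(ann, ratios$protein_id)
  out <- lapply(experimental_channels(design), function(ch) {
    r <- stats::setNames(ratios[[ch]], ratios$protein_id)
    roc_cutoff(r, labels, channel_id = ch, inclusive = inclusive)
  })
  names(out) <- experimental_channels(design)
  out
}

#' Intersect retained sets across replicates of one condition
#'
#' A protein survives a condition only when it is retained in every
#' replicate of that condition.
#'
#' @param results list of `cutoff_result` (>= 2) from one condition.
#' @return character vector of protein ids retained in all replicates.
#' @export
intersect_replicates <- function(results) {
  if (length(results) < 2L) {
    ep_validation_error("need >= 2 replicate cutoff results to intersect")
  }
  Reduce(intersect, lapply(results, function(r) r$retained))
}

#' Assemble the filtered proteome
#'
#' Combines the per-condition intersections into the final filtered protein
#' set: the per-condition sets, their union, and a per-protein provenance
#' table recording which filters each protein passed.
#'
#' @param endo character vector of proteins surviving all ENDO replicates.
#' @param surf character vector surviving all SURF replicates.
#' @param provenance optional data frame keyed by `protein_id` with filter
#'   outcomes; if `NULL` a minimal one is built from the two sets.
#' @return object of class `filtered_proteome`: list with `endo`, `surf`,
#'   `union`, `both`, `provenance`.
#' @export
assemble_filtered_proteome <- function(endo, surf, provenance = NULL) {
  endo <- unique(as.character(endo))
  surf <- unique(as.character(surf))
  uni <- union(endo, surf)
  if (is.null(provenance)) {
    provenance <- data.frame(
      protein_id = uni,
      in_endo = uni %in% endo,
      in_surf = uni %in% surf,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(endo = endo, surf = surf, union = uni,
         both = intersect(endo, surf), provenance = provenance),
    class = "filtered_proteome"
  )
}

#' @export
print.filtered_proteome <- function(x, ...) {
  cat(sprintf(
    "Filtered proteome: %d proteins (%d endosome, %d surface, %d in both)\n",
    length(x$union), length(x$endo), length(x$surf), length(x$both)))
  invisible(x)
}

#' Run the full contaminant-filtering cascade
#'
#' Chains the unique-peptide filter, per-replicate ROC cutoffs, and
#' per-condition replicate intersection, and assembles the filtered
#' proteome with full provenance.
#'
#' @param table a [protein_quant_table()] (impurity-corrected upstream).
#' @param ann an [annotation_table()].
#' @param cfg a [run_config()].
#' @return list with `table` (peptide-filtered quant table), `ratios`,
#'   `cutoffs` (per-replicate `cutoff_result`), and `proteome`
#'   (`filtered_proteome`).
#' @export
filter_cascade <- function(table, ann, cfg = run_config()) {
  design <- quant_design(table)
  kept <- filter_min_peptides(table, cfg$min_unique_peptides)
  ratios <- compute_nc_ratios(kept, cfg$nc_pseudocount)
  cutoffs <- roc_cutoff_per_replicate(ratios, ann,
                                      inclusive = cfg$inclusive_threshold)
  endo_ch <- condition_channels(design, "ENDO")
  surf_ch <- condition_channels(design, "SURF")
  endo <- intersect_replicates(cutoffs[endo_ch])
  surf <- intersect_replicates(cutoffs[surf_ch])
  prov <- data.frame(
    protein_id = table$protein_id,
    passed_peptide_filter = table$protein_id %in% kept$protein_id,
    stringsAsFactors = FALSE
  )
  for (ch in names(cutoffs)) {
    prov[[paste0("retained_", ch)]] <- prov$protein_id %in% cutoffs[[ch]]$retained
  }
  prov$in_endo <- prov$protein_id %in% endo
  prov$in_surf <- prov$protein_id %in% surf
  prov$in_union <- prov$in_endo | prov$in_surf
  proteome <- assemble_filtered_proteome(endo, surf, provenance = prov)
  list(table = kept, ratios = ratios, cutoffs = cutoffs, proteome = proteome)
}
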