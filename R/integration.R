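#' Average an expression summary over developmental time points
#'
#' The single-cell summaries bracket the profiling stage with two time
#' points; cell-type calls use their arithmetic mean, per gene and cell
#' class, for both the mean log2(CPM+1) and the fraction of expressing
#' cells. Genes lacking either time point for a class are excluded with a
#' warning.
#'
#' @param expr an [expression_summary()].
#' @param time_points the two time-point labels to average (default
#'   `c("24h", "48h")`).
#' @return data frame: `gene_id`, `cell_class`, `mean_log2cpm1`,
#'   `frac_expressing`, averaged over time points.
#' @export
average_timepoints <- function(expr, time_points = c("24h", "48h")) {
  keep <- expr$time_point %in% time_points
  e <- as.data.frame(expr)[keep, , drop = FALSE]
  key <- interaction(e$gene_id, e$cell_class, drop = TRUE)
  cnt <- tapply(e$time_point, key, function(x) length(unique(x)))
  complete <- names(cnt)[cnt == length(time_points)]
  if (length(complete) < length(cnt)) {
    bad <- unique(sub("\\..*$", "", setdiff(names(cnt), complete)))
    warning(sprintf(
      "excluding %d gene/class pair(s) missing a time point (genes: %s)",
      length(cnt) - length(complete),
      paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    e <- e[key %in% complete, , drop = FALSE]
  }
  agg <- stats::aggregate(
    e[, c("mean_log2cpm1", "frac_expressing")],
    by = list(gene_id = e$gene_id, cell_class = e$cell_class),
    FUN = mean
  )
  agg[order(agg$gene_id, agg$cell_class), , drop = FALSE] -> agg
  rownames(agg) <- NULL
  agg
}

#' Robust-expression rule for a transcript in a cell class
#'
#' A transcript counts as robustly expressed when it is expressed in more
#' than `expr_fraction_threshold` of cells (strict inequality) at a mean
#' level of at least `expr_level_threshold` log2(CPM+1) (inclusive). The
#' asymmetry (strict fraction, inclusive level) is deliberate and mirrors
#' the thresholds' definitions.
#'
#' @param mean_log2cpm1 mean log2(CPM+1) (possibly vectorized).
#' @param frac_expressing fraction of expressing cells in \[0, 1\].
#' @param cfg a [run_config()] supplying the thresholds (defaults: level 4,
#'   fraction 0.30).
#' @return logical vector.
#' @export
is_expression_enriched <- function(mean_log2cpm1, frac_expressing,
                                   cfg = run_config()) {
  frac_expressing > cfg$expr_fraction_threshold &
    mean_log2cpm1 >= cfg$expr_level_threshold
}

#' Cell-type assignment of transcripts
#'
#' Applies the robust-expression rule to the time-averaged summary of each
#' gene in both cell classes (olfactory receptor neurons, ORN, and
#' projection neurons, PN) and classifies the gene as `ORN_ONLY`,
#' `PN_ONLY`, `BOTH` or `NEITHER`. `more_abundant_in` additionally records
#' which class has the higher averaged mean when the gene is enriched
#' there, operationalizing "more abundant in PNs" as enriched-in-PN with
#' PN mean above ORN mean.
#'
#' @param avg time-averaged summary from [average_timepoints()].
#' @param cfg a [run_config()].
#' @return data frame of class `cell_type_calls`: `gene_id`, per-class
#'   averaged values, `enriched_in`, `more_abundant_in`.
#' @export
call_cell_types <- function(avg, cfg = run_config()) {
  classes <- c("ORN", "PN")
  miss <- setdiff(classes, unique(avg$cell_class))
  if (length(miss)) {
    ep_validation_error(paste0(
      "averaged summary lacks cell class(es): ", paste(miss, collapse = ", ")))
  }
  wide_mean <- stats::reshape(
    avg[, c("gene_id", "cell_class", "mean_log2cpm1")],
    idvar = "gene_id", timevar = "cell_class", direction = "wide")
  wide_frac <- stats::reshape(
    avg[, c("gene_id", "cell_class", "frac_expressing")],
    idvar = "gene_id", timevar = "cell_class", direction = "wide")
  out <- merge(wide_mean, wide_frac, by = "gene_id")
  names(out) <- sub("mean_log2cpm1\\.", "mean_", names(out))
  names(out) <- sub("frac_expressing\\.", "frac_", names(out))
  enr_orn <- is_expression_enriched(out$mean_ORN, out$frac_ORN, cfg)
  enr_pn <- is_expression_enriched(out$mean_PN, out$frac_PN, cfg)
  enr_orn[is.na(enr_orn)] <- FALSE
  enr_pn[is.na(enr_pn)] <- FALSE
  out$enriched_in <- ifelse(enr_orn & enr_pn, "BOTH",
                     ifelse(enr_orn, "ORN_ONLY",
                     ifelse(enr_pn, "PN_ONLY", "NEITHER")))
  out$more_abundant_in <- ifelse(enr_pn & out$mean_PN > out$mean_ORN, "PN",
                          ifelse(enr_orn & out$mean_ORN > out$mean_PN, "ORN",
                                 NA_character_))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cell_type_calls", "data.frame")
  out
}

#' Join endosome-enriched secreted ligands to their receptors
#'
#' For each endosome-enriched secreted protein (the candidate internalized
#' ligands), looks up its annotated receptor(s) and reports each receptor's
#' detection status in the profiled proteome: `ENDO_ENRICHED` (`*`),
#' `DUAL` (`**`, present in both compartment sets without significant
#' enrichment either way), `SURF_ENRICHED`, or `NOT_DETECTED` (absent from
#' the filtered union). The ligand's cell-type call is attached when
#' expression calls are supplied.
#'
#' @param secreted_endo enrichment rows for secreted proteins (e.g.
#'   [subset_by_category()] output); only rows with call `ENDO_ENRICHED`
#'   are used as ligands.
#' @param ann an [annotation_table()].
#' @param enr the full `enrichment_result` with calls.
#' @param proteome a `filtered_proteome`.
#' @param cell_calls optional `cell_type_calls` keyed by `gene_id`.
#' @return data frame of class `ligand_receptor_table`, one row per
#'   ligand-receptor link (ligands without receptors keep one row with
#'   empty receptor fields): `ligand_id`, `ligand_gene`, `ligand_log2fc`,
#'   `ligand_cell_type`, `receptor_id`, `receptor_status`, `receptor_mark`.
#' @export
join_ligand_receptors <- function(secreted_endo, ann, enr, proteome,
                                  cell_calls = NULL) {
  ligands <- secreted_endo[secreted_endo$call == "ENDO_ENRICHED", , drop = FALSE]
  rmap <- receptor_list(ann)
  status_of <- function(rid) {
    if (!rid %in% ann$protein_id) return("UNMATCHED")
    if (!rid %in% proteome$union) return("NOT_DETECTED")
    call <- enr$call[match(rid, enr$protein_id)]
    if (is.na(call)) return("NOT_DETECTED")
    if (call == "ENDO_ENRICHED") return("ENDO_ENRICHED")
    if (call == "SURF_ENRICHED") return("SURF_ENRICHED")
    if (rid %in% proteome$both) return("DUAL")
    if (rid %in% proteome$endo) return("ENDO_DETECTED")
    "SURF_DETECTED"
  }
  rows <- lapply(seq_len(nrow(ligands)), function(i) {
    lid <- ligands$protein_id[i]
    gene <- ann$gene_id[match(lid, ann$protein_id)]
    ct <- if (!is.null(cell_calls) && gene %in% cell_calls$gene_id) {
      cell_calls$enriched_in[match(gene, cell_calls$gene_id)]
    } else NA_character_
    receptors <- rmap[[lid]]
    if (is.null(receptors) || length(receptors) == 0L) {
      return(data.frame(
        ligand_id = lid, ligand_gene = gene, ligand_log2fc = ligands$log2fc[i],
        ligand_cell_type = ct, receptor_id = NA_character_,
        receptor_status = NA_character_, receptor_mark = "",
        stringsAsFactors = FALSE))
    }
    st <- vapply(receptors, status_of, character(1))
    data.frame(
      ligand_id = lid, ligand_gene = gene, ligand_log2fc = ligands$log2fc[i],
      ligand_cell_type = ct, receptor_id = receptors, receptor_status = st,
      receptor_mark = ifelse(st == "ENDO_ENRICHED", "*",
                      ifelse(st == "DUAL", "**", "")),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(ligand_id = character(0), ligand_gene = character(0),
                      ligand_log2fc = numeric(0), ligand_cell_type = character(0),
                      receptor_id = character(0), receptor_status = character(0),
                      receptor_mark = character(0), stringsAsFactors = FALSE)
  }
  class(out) <- c("ligand_receptor_table", "data.frame")
  out
}

#' Summarize a raw cell-by-gene count matrix into the expression summary
#'
#' Helper to exercise the integration path end-to-end from counts: each
#' cell's counts are normalized to counts-per-million, transformed to
#' log2(CPM+1), then averaged per cell class and time point; the fraction
#' of expressing cells uses count > 0.
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse) of
#'   non-negative counts with gene ids as rownames.
#' @param cell_class character vector over cells (`"ORN"`/`"PN"`).
#' @param time_point character vector over cells (`"24h"`/`"48h"`).
#' @return an [expression_summary()].
#' @export
summarize_expression_matrix <- function(counts, cell_class, time_point) {
  if (length(cell_class) != ncol(counts) || length(time_point) != ncol(counts)) {
    ep_validation_error("cell_class and time_point must have one entry per cell")
  }
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) ep_validation_error("cells with zero total counts are not allowed")
  cpm <- sweep(as.matrix(counts), 2, lib, "/") * 1e6
  lg <- log2(cpm + 1)
  expressed <- as.matrix(counts) > 0
  groups <- split(seq_len(ncol(counts)),
                  list(class = cell_class, time = time_point), drop = TRUE)
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    data.frame(
      gene_id = rownames(counts),
      cell_class = parts[1],
      time_point = parts[2],
      mean_log2cpm1 = rowMeans(lg[, idx, drop = FALSE]),
      frac_expressing = rowMeans(expressed[, idx, drop = FALSE]),
      stringsAsFactors = FALSE)
  })
  expression_summary(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
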