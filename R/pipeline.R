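#' Run the full endosome/surface profiling pipeline
#'
#' Chains every stage on in-memory inputs: isotope-impurity correction,
#' unique-peptide filter, negative-control ratios, per-replicate ROC
#' cutoffs, replicate intersection, moderated-t compartment enrichment,
#' top-N transmembrane rankings and their overlap, secreted-protein
#' subsetting, and (when an expression summary is supplied) cell-type
#' calls and the ligand-receptor join. All stage outputs plus a run
#' manifest with the filter-cascade counts are returned; with `out_dir`
#' set, every table, the manifest (JSON) and a Markdown summary are also
#' written to disk.
#'
#' @param quant a [protein_quant_table()].
#' @param ann an [annotation_table()] covering the quantified proteins.
#' @param impurity optional impurity matrix; `NULL` skips correction.
#' @param expr optional [expression_summary()].
#' @param cfg a [run_config()].
#' @param out_dir optional output directory.
#' @return list of class `endo_run`: `corrected`, `filtered` (cascade
#'   output incl. `proteome`), `enrichment`, `topn` (ENDO and SURF
#'   reports plus `overlap`), `secreted_endo`, `cell_calls`,
#'   `ligand_receptors`, `manifest`.
#' @export
run_pipeline <- function(quant, ann, impurity = NULL, expr = NULL,
                         cfg = run_config(), out_dir = NULL) {
  design <- quant_design(quant)
  assert_valid_design(design)
  stage_log("run", sprintf("%d proteins detected", nrow(quant)))

  corrected <- if (!is.null(impurity)) {
    stage_log("correct", "applying isotope-impurity correction")
    correct_impurities(quant, impurity)
  } else quant

  filtered <- filter_cascade(corrected, ann, cfg)
  proteome <- filtered$proteome
  stage_log("filter", sprintf(
    "%d proteins after peptide filter; union of retained sets: %d",
    nrow(filtered$table), length(proteome$union)))

  enrichment <- test_enrichment(filtered$ratios, ids = proteome$union, cfg = cfg)
  n_endo <- sum(enrichment$call == "ENDO_ENRICHED")
  n_surf <- sum(enrichment$call == "SURF_ENRICHED")
  stage_log("enrich", sprintf(
    "%d endosome-enriched, %d surface-enriched at alpha %.3g (%s)",
    n_endo, n_surf, cfg$significance_alpha, cfg$adjust))

  topn <- list(
    ENDO = top_n_tm(enrichment, ann, filtered$ratios, "ENDO",
                    n = cfg$top_n, metric = cfg$ranking_metric,
                    table = filtered$table),
    SURF = top_n_tm(enrichment, ann, filtered$ratios, "SURF",
                    n = cfg$top_n, metric = cfg$ranking_metric,
                    table = filtered$table)
  )
  topn$overlap <- overlap_fraction(topn$ENDO, topn$SURF)

  secreted_endo <- subset_by_category(enrichment, ann, "secreted")
  secreted_endo <- secreted_endo[secreted_endo$call == "ENDO_ENRICHED", ,
                                 drop = FALSE]

  cell_calls <- NULL
  lr <- NULL
  if (!is.null(expr)) {
    avg <- average_timepoints(expr)
    cell_calls <- call_cell_types(avg, cfg)
    lr <- join_ligand_receptors(secreted_endo, ann, enrichment, proteome,
                                cell_calls)
    stage_log("integrate", sprintf(
      "%d endosome-enriched secreted ligand(s), %d receptor link(s)",
      nrow(secreted_endo), sum(!is.na(lr$receptor_id))))
  }

  manifest <- build_manifest(quant, filtered, enrichment, secreted_endo,
                             topn, cfg)
  check_cascade_monotone(manifest)

  run <- structure(
    list(corrected = corrected, filtered = filtered, enrichment = enrichment,
         topn = topn, secreted_endo = secreted_endo, cell_calls = cell_calls,
         ligand_receptors = lr, manifest = manifest),
    class = "endo_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir, cfg)
  run
}

build_manifest <- function(quant, filtered, enrichment, secreted_endo,
                           topn, cfg) {
  proteome <- filtered$proteome
  cutoff_counts <- vapply(filtered$cutoffs,
                          function(x) length(x$retained), integer(1))
  list(
    tool = "endoprofiler",
    version = as.character(utils::packageVersion("endoprofiler")),
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    counts = list(
      detected = nrow(quant),
      after_peptide_filter = nrow(filtered$table),
      retained_per_replicate = as.list(cutoff_counts),
      endo_condition = length(proteome$endo),
      surf_condition = length(proteome$surf),
      union = length(proteome$union),
      both_conditions = length(proteome$both),
      endo_enriched = sum(enrichment$call == "ENDO_ENRICHED"),
      surf_enriched = sum(enrichment$call == "SURF_ENRICHED"),
      secreted_endo_enriched = nrow(secreted_endo)
    ),
    cutoffs = lapply(filtered$cutoffs, function(x) {
      list(channel = x$channel_id, threshold = x$chosen_threshold,
           youden = x$youden)
    }),
    topn_overlap = topn$overlap
  )
}

# digest-free stable hash: serialize the config canonically and sum bytes
config_hash <- function(cfg) {
  raw <- serialize(unclass(cfg), connection = NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw)) %% .Machine$integer.max)
}

check_cascade_monotone <- function(manifest) {
  cts <- manifest$counts
  ok <- cts$after_peptide_filter <= cts$detected &&
    cts$union <= cts$after_peptide_filter &&
    cts$endo_condition <= cts$union &&
    cts$surf_condition <= cts$union &&
    cts$endo_enriched + cts$surf_enriched <= cts$union &&
    cts$secreted_endo_enriched <= cts$endo_enriched
  if (!ok) {
    ep_validation_error("filter-cascade counts are not monotone; pipeline invariant violated")
  }
  invisible(TRUE)
}

write_run_outputs <- function(run, out_dir, cfg) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_quant_table(run$corrected, file.path(out_dir, "corrected_quant.tsv"))
  write_ratio_table(run$filtered$ratios, file.path(out_dir, "ratios.tsv"))
  for (ch in names(run$filtered$cutoffs)) {
    utils::write.table(run$filtered$cutoffs[[ch]]$curve,
                       file.path(out_dir, paste0("roc_", ch, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(run$filtered$proteome$provenance,
                     file.path(out_dir, "filtered_proteome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(run$enrichment),
                     file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cond in c("ENDO", "SURF")) {
    utils::write.table(run$topn[[cond]]$ranking,
                       file.path(out_dir, paste0("top_tm_", cond, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(as.data.frame(run$secreted_endo),
                     file.path(out_dir, "secreted_endo_enriched.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$cell_calls)) {
    utils::write.table(as.data.frame(run$cell_calls),
                       file.path(out_dir, "cell_type_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$ligand_receptors)) {
    utils::write.table(as.data.frame(run$ligand_receptors),
                       file.path(out_dir, "ligand_receptors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(summary_report(run), file.path(out_dir, "summary.md"))
  invisible(out_dir)
}

summary_report <- function(run) {
  cts <- run$manifest$counts
  lines <- c(
    "# Endosome/surface profiling run summary", "",
    sprintf("- Proteins detected: %d", cts$detected),
    sprintf("- After unique-peptide filter: %d", cts$after_peptide_filter),
    sprintf("- Retained per replicate: %s",
            paste(sprintf("%s=%d", names(cts$retained_per_replicate),
                          unlist(cts$retained_per_replicate)),
                  collapse = ", ")),
    sprintf("- In all ENDO replicates: %d; in all SURF replicates: %d",
            cts$endo_condition, cts$surf_condition),
    sprintf("- Filtered proteome (union): %d (%d in both compartments)",
            cts$union, cts$both_conditions),
    sprintf("- Endosome-enriched: %d; surface-enriched: %d",
            cts$endo_enriched, cts$surf_enriched),
    sprintf("- Endosome-enriched secreted proteins: %d",
            cts$secreted_endo_enriched),
    sprintf("- Top-N TM overlap (endo list also in surf list): %.1f%%",
            100 * run$manifest$topn_overlap)
  )
  lines
}

#' @export
print.endo_run <- function(x, ...) {
  cat(paste(summary_report(x), collapse = "\n"), "\n")
  invisible(x)
}
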