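#' Construct and validate a protein quantification table
#'
#' The main substrate of the pipeline: one row per protein, with the number
#' of unique peptides supporting its identification and one reporter-ion
#' intensity column per TMT channel (arbitrary units).
#'
#' @param df data frame with columns `protein_id`, `unique_peptides`, and one
#'   numeric column per channel in `design`.
#' @param design a [channel_design()].
#' @return The validated data frame, class `protein_quant` with the design
#'   attached as attribute `design`.
#' @export
protein_quant_table <- function(df, design) {
  assert_valid_design(design)
  required <- c("protein_id", "unique_peptides")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    ep_schema_error(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  miss_ch <- setdiff(design$channel, names(df))
  if (length(miss_ch)) {
    ep_schema_error(paste0(
      "missing intensity column(s) for channel(s): ",
      paste(miss_ch, collapse = ", ")))
  }
  dup <- unique(df$protein_id[duplicated(df$protein_id)])
  if (length(dup)) {
    ep_validation_error(paste0(
      "duplicate protein_id(s): ", paste(dup, collapse = ", ")))
  }
  if (any(is.na(df$unique_peptides)) || any(df$unique_peptides < 0)) {
    ep_validation_error("unique_peptides must be non-negative and present")
  }
  for (ch in design$channel) {
    v <- df[[ch]]
    if (!is.numeric(v)) {
      ep_schema_error(paste0("channel column ", ch, " is not numeric"))
    }
    if (any(is.na(v)) || any(!is.finite(v))) {
      ep_validation_error(paste0(
        "channel ", ch, " has missing or non-finite intensities; ",
        "missing cells are rejected, not imputed"))
    }
    if (any(v < 0)) {
      ep_validation_error(paste0("channel ", ch, " has negative intensities"))
    }
  }
  df <- df[, c(required, design$channel)]
  rownames(df) <- NULL
  attr(df, "design") <- design
  class(df) <- c("protein_quant", "data.frame")
  df
}

quant_design <- function(table) {
  d <- attr(table, "design")
  if (is.null(d)) ep_validation_error("table carries no channel design")
  d
}

#' Extract the intensity matrix of a quantification table
#'
#' @param table a [protein_quant_table()].
#' @param channels channel subset (default: all channels of the design).
#' @return numeric matrix, proteins x channels, protein ids as rownames.
#' @export
intensity_matrix <- function(table, channels = NULL) {
  design <- quant_design(table)
  if (is.null(channels)) channels <- design$channel
  m <- as.matrix(as.data.frame(table)[, channels, drop = FALSE])
  rownames(m) <- table$protein_id
  m
}

#' Read and write protein quantification tables
#'
#' Plain one-header-line TSV/CSV (delimiter chosen by extension) with
#' `protein_id` first, then `unique_peptides`, then one column per channel.
#' Reading validates against the channel design; a read of a written table
#' is the identity.
#'
#' @param path file path (`.tsv`/`.txt` tab-delimited, `.csv` comma).
#' @param design a [channel_design()].
#' @param table a [protein_quant_table()].
#' @return `read_quant_table()` returns a validated `protein_quant` table
#'   with input row order preserved.
#' @export
read_quant_table <- function(path, design) {
  if (!file.exists(path)) ep_schema_error(paste0("file not found: ", path))
  df <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  protein_quant_table(df, design)
}

#' @rdname read_quant_table
#' @export
write_quant_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = delim_for(path),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein annotation table
#'
#' Per-protein topology and pairing annotation used both as TP/FP truth for
#' the ratiometric contaminant filter (a true positive carries a signal
#' peptide and/or a transmembrane domain) and for the ligand-receptor join.
#' Columns: `protein_id`, `gene_id`, logical `has_signal_peptide`,
#' `has_tm_domain`, `is_secreted`, and `receptor_ids` (semicolon-separated
#' protein ids, empty when the protein has no annotated receptor).
#'
#' @param path TSV/CSV file path.
#' @return data frame of class `annotation_table`.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) ep_schema_error(paste0("file not found: ", path))
  df <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  annotation_table(df)
}

#' @rdname read_annotation_table
#' @param df data frame with the annotation columns.
#' @export
annotation_table <- function(df) {
  required <- c("protein_id", "gene_id", "has_signal_peptide",
                "has_tm_domain", "is_secreted", "receptor_ids")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    ep_schema_error(paste0(
      "annotation table missing column(s): ", paste(miss, collapse = ", ")))
  }
  for (col in c("has_signal_peptide", "has_tm_domain", "is_secreted")) {
    df[[col]] <- as.logical(df[[col]])
    if (any(is.na(df[[col]]))) {
      ep_validation_error(paste0("annotation column ", col, " must be logical"))
    }
  }
  if (anyDuplicated(df$protein_id)) {
    ep_validation_error("duplicate protein_id in annotation table")
  }
  bad <- df$protein_id[df$is_secreted & !df$has_signal_peptide]
  if (length(bad)) {
    ep_validation_error(paste0(
      "secreted proteins must carry a signal peptide; violated by: ",
      paste(bad, collapse = ", ")))
  }
  df$receptor_ids[is.na(df$receptor_ids)] <- ""
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' @rdname read_annotation_table
#' @param ann an `annotation_table`.
#' @export
write_annotation_table <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = delim_for(path),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

receptor_list <- function(ann) {
  out <- strsplit(ann$receptor_ids, ";", fixed = TRUE)
  out <- lapply(out, function(x) x[nzchar(x)])
  names(out) <- ann$protein_id
  out
}

#' Read and validate a TMT isotope-impurity matrix
#'
#' CSV with channel ids as both header and first column. Entry (i, j) is the
#' fraction of channel j's true signal observed in channel i (column
#' convention). Invariants: square, matching the design's channels; each
#' column sums to at most 1 (plus tolerance); diagonally dominant by column;
#' nonsingular.
#'
#' @param path CSV file path.
#' @param design a [channel_design()]; column/row order is aligned to it.
#' @param tol slack allowed on the column-sum invariant.
#' @return numeric matrix with channel dimnames.
#' @export
read_impurity_matrix <- function(path, design, tol = 1e-6) {
  if (!file.exists(path)) ep_schema_error(paste0("file not found: ", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  validate_impurity_matrix(m, design, tol = tol)
}

#' @rdname read_impurity_matrix
#' @param m numeric matrix with channel dimnames.
#' @export
validate_impurity_matrix <- function(m, design = NULL, tol = 1e-6) {
  if (nrow(m) != ncol(m)) ep_validation_error("impurity matrix must be square")
  if (!is.null(design)) {
    if (!setequal(rownames(m), design$channel) ||
        !setequal(colnames(m), design$channel)) {
      ep_schema_error("impurity matrix channels do not match the design")
    }
    m <- m[design$channel, design$channel]
  }
  if (any(colSums(m) > 1 + tol)) {
    ep_validation_error("impurity matrix columns must sum to <= 1")
  }
  for (j in seq_len(ncol(m))) {
    off <- m[-j, j]
    if (length(off) && any(off >= m[j, j])) {
      ep_validation_error(
        "impurity matrix must be diagonally dominant within each column")
    }
  }
  m
}

#' @rdname read_impurity_matrix
#' @export
write_impurity_matrix <- function(m, path) {
  df <- data.frame(channel = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pseudo-single-cell expression summary
#'
#' Long-format TSV/CSV with one row per gene x cell class x time point:
#' columns `gene_id`, `cell_class` (`ORN`/`PN`), `time_point` (`24h`/`48h`),
#' `mean_log2cpm1` (mean log2(CPM+1) over cells of that class) and
#' `frac_expressing` (fraction of cells with nonzero counts).
#'
#' @param path TSV/CSV file path.
#' @return data frame of class `expression_summary`.
#' @export
read_expression_summary <- function(path) {
  if (!file.exists(path)) ep_schema_error(paste0("file not found: ", path))
  df <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  expression_summary(df)
}

#' @rdname read_expression_summary
#' @param df data frame with the summary columns.
#' @export
expression_summary <- function(df) {
  required <- c("gene_id", "cell_class", "time_point",
                "mean_log2cpm1", "frac_expressing")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    ep_schema_error(paste0(
      "expression summary missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(df$frac_expressing < 0 | df$frac_expressing > 1, na.rm = TRUE)) {
    ep_validation_error("frac_expressing must lie in [0, 1]")
  }
  if (any(df$mean_log2cpm1 < 0, na.rm = TRUE)) {
    ep_validation_error("mean_log2cpm1 must be >= 0")
  }
  rownames(df) <- NULL
  class(df) <- c("expression_summary", "data.frame")
  df
}

#' @rdname read_expression_summary
#' @param expr an `expression_summary`.
#' @export
write_expression_summary <- function(expr, path) {
  utils::write.table(as.data.frame(expr), path, sep = delim_for(path),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
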