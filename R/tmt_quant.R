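#' Correct reporter-ion intensities for TMT isotope impurities
#'
#' Isobaric reporter channels bleed a known fraction of their signal into
#' neighboring channels. With the impurity matrix M (entry (i, j) = fraction
#' of channel j's true signal observed in channel i), the observed vector per
#' protein is `measured = M %*% true`, so the correction is the exact linear
#' solve `true = solve(M, measured)`. Any solution component driven negative
#' by noise is clamped to zero: intensities are physical quantities.
#'
#' @param table a [protein_quant_table()].
#' @param M impurity matrix as from [read_impurity_matrix()]; its dimension
#'   must equal the number of channels in the table's design.
#' @param max_kappa condition-number threshold above which the matrix is
#'   rejected as numerically singular.
#' @return A `protein_quant` table with corrected intensities.
#' @export
correct_impurities <- function(table, M, max_kappa = 1e8) {
  design <- quant_design(table)
  M <- validate_impurity_matrix(M, design)
  kappa <- kappa(M, exact = TRUE)
  if (!is.finite(kappa) || kappa > max_kappa) {
    ep_numerical_error(sprintf(
      "impurity matrix is singular or near-singular (condition number %.3g)",
      kappa))
  }
  obs <- t(intensity_matrix(table))          # channels x proteins
  corrected <- solve(M, obs)
  corrected[corrected < 0] <- 0
  out <- as.data.frame(table)
  out[, design$channel] <- t(corrected)
  protein_quant_table(out, design)
}

#' Experimental-to-negative-control TMT ratios
#'
#' For each protein, the two negative-control channel intensities are
#' averaged (arithmetic mean) and every experimental channel is expressed as
#' a ratio to that background:
#' `ratio(c) = (intensity(c) + pseudocount) / (nc_mean + pseudocount)`.
#' The pseudocount (default 1 intensity unit) keeps ratios finite and
#' positive when a channel or the controls read zero.
#'
#' @param table a [protein_quant_table()] (impurity-corrected upstream).
#' @param pseudocount non-negative intensity pseudocount; with the default
#'   1.0 all ratios are strictly positive.
#' @return data frame of class `ratio_table`: `protein_id`, `nc_mean`, one
#'   ratio column per experimental channel; design attached as attribute.
#' @export
compute_nc_ratios <- function(table, pseudocount = 1) {
  design <- quant_design(table)
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    ep_validation_error("pseudocount must be a non-negative number")
  }
  nc <- intensity_matrix(table, nc_channels(design))
  nc_mean <- rowMeans(nc)
  expt <- intensity_matrix(table, experimental_channels(design))
  ratios <- (expt + pseudocount) / (nc_mean + pseudocount)
  out <- data.frame(protein_id = table$protein_id, nc_mean = nc_mean,
                    ratios, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "design") <- design
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Extract the ratio matrix of a ratio table
#'
#' @param ratios a `ratio_table` from [compute_nc_ratios()].
#' @param channels channel subset (default: all experimental channels).
#' @return numeric matrix, proteins x channels, protein ids as rownames.
#' @export
ratio_matrix <- function(ratios, channels = NULL) {
  design <- attr(ratios, "design")
  if (is.null(channels)) channels <- experimental_channels(design)
  m <- as.matrix(as.data.frame(ratios)[, channels, drop = FALSE])
  rownames(m) <- ratios$protein_id
  m
}

#' Log2-transform a ratio table
#'
#' Elementwise log2 of the experimental-to-control ratios; the scale on
#' which fold changes and moderated t-tests are computed.
#'
#' @param ratios a `ratio_table` from [compute_nc_ratios()].
#' @return numeric matrix (proteins x experimental channels) of log2 ratios.
#' @export
log2_ratios <- function(ratios) {
  m <- ratio_matrix(ratios)
  if (any(m <= 0)) {
    ep_validation_error(
      "ratios must be strictly positive before log transform; use a positive pseudocount")
  }
  log2(m)
}

#' @rdname compute_nc_ratios
#' @param path file path.
#' @export
write_ratio_table <- function(ratios, path) {
  utils::write.table(as.data.frame(ratios), path, sep = delim_for(path),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
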