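#' Specification of a synthetic dual-compartment profiling experiment
#'
#' Defines the ground-truth structure a simulated dataset is built from:
#' how many proteins, what mixture of compartment classes, how strongly
#' labeled proteins rise above the negative controls, how strongly the two
#' compartments differ for resident proteins, and how noisy the reporter
#' intensities are. Defaults emulate a clean proximity-labeling experiment:
#' 8-fold labeling over background, 4-fold compartment preference,
#' lognormal reporter noise with sd 0.25 on the log2 scale, 10% of
#' proteins supported by a single unique peptide, and 5% isotope spillage
#' per channel.
#'
#' Classes: `SURF_RESIDENT` and `ENDO_RESIDENT` (transmembrane proteins
#' preferentially labeled at the surface or in endosomes), `DUAL`
#' (labeled equally in both compartments), `CONTAMINANT` (no signal
#' peptide or transmembrane domain, no specific labeling), and
#' `SECRETED_LIGAND` (signal-peptide-bearing secreted proteins internalized
#' into endosomes, each wired to an annotated receptor).
#'
#' @param n_proteins number of simulated proteins (default 2000).
#' @param class_mix named proportions over the five classes; must sum to 1.
#' @param labeling_effect fold enrichment of labeled proteins over the
#'   negative controls in their own compartment (default 8).
#' @param compartment_effect fold difference between a resident protein's
#'   own and opposite compartment channels (default 4).
#' @param noise_sd_log2 sd of the lognormal channel noise, log2 scale
#'   (default 0.25).
#' @param base_intensity_log2 log2 of the background reporter intensity
#'   (default 10, i.e. 1024 units).
#' @param frac_low_peptide fraction of proteins assigned a single unique
#'   peptide (default 0.10).
#' @param impurity_spill off-diagonal isotope-impurity mass per channel,
#'   split between adjacent channels (default 0.05; 0 disables mixing).
#' @param cell_type_mix named proportions of true cell-type expression
#'   patterns for secreted-ligand genes.
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return list of class `truth_spec`.
#' @export
truth_spec <- function(n_proteins = 2000L,
                       class_mix = c(SURF_RESIDENT = 0.25,
                                     ENDO_RESIDENT = 0.20,
                                     DUAL = 0.25,
                                     CONTAMINANT = 0.20,
                                     SECRETED_LIGAND = 0.10),
                       labeling_effect = 8,
                       compartment_effect = 4,
                       noise_sd_log2 = 0.25,
                       base_intensity_log2 = 10,
                       frac_low_peptide = 0.10,
                       impurity_spill = 0.05,
                       cell_type_mix = c(ORN_ONLY = 0.05, PN_ONLY = 0.30,
                                         BOTH = 0.45, NEITHER = 0.20),
                       seed = 1L) {
  classes <- c("SURF_RESIDENT", "ENDO_RESIDENT", "DUAL",
               "CONTAMINANT", "SECRETED_LIGAND")
  if (!setequal(names(class_mix), classes)) {
    ep_validation_error(paste0(
      "class_mix must name exactly: ", paste(classes, collapse = ", ")))
  }
  if (abs(sum(class_mix) - 1) > 1e-8) {
    ep_validation_error("class_mix proportions must sum to 1")
  }
  if (labeling_effect <= 1 || compartment_effect <= 1) {
    ep_validation_error("labeling_effect and compartment_effect must be > 1")
  }
  if (noise_sd_log2 < 0) ep_validation_error("noise_sd_log2 must be >= 0")
  if (frac_low_peptide < 0 || frac_low_peptide > 1) {
    ep_validation_error("frac_low_peptide must lie in [0, 1]")
  }
  if (impurity_spill < 0 || impurity_spill >= 0.5) {
    ep_validation_error("impurity_spill must lie in [0, 0.5)")
  }
  if (abs(sum(cell_type_mix) - 1) > 1e-8) {
    ep_validation_error("cell_type_mix proportions must sum to 1")
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    class_mix = class_mix[classes],
    labeling_effect = labeling_effect,
    compartment_effect = compartment_effect,
    noise_sd_log2 = noise_sd_log2,
    base_intensity_log2 = base_intensity_log2,
    frac_low_peptide = frac_low_peptide,
    impurity_spill = impurity_spill,
    cell_type_mix = cell_type_mix,
    seed = as.integer(seed)
  ), class = "truth_spec")
}

# Tridiagonal impurity matrix: each channel keeps 1 - spill of its signal
# and leaks the rest to its plex neighbors (edge channels to their single
# neighbor), so columns sum to 1 and the matrix is diagonally dominant.
make_impurity_matrix <- function(channels, spill) {
  k <- length(channels)
  M <- diag(1 - spill, k)
  if (spill > 0 && k > 1) {
    for (j in seq_len(k)) {
      nb <- c(j - 1, j + 1)
      nb <- nb[nb >= 1 & nb <= k]
      M[nb, j] <- spill / length(nb)
    }
  }
  dimnames(M) <- list(channels, channels)
  M
}

with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic proteomics dataset with ground truth
#'
#' Draws per-channel reporter intensities as lognormal noise around
#' class-determined channel means: negative-control channels at the
#' background intensity for every protein; contaminants at background in
#' all channels; resident classes raised by `labeling_effect` in their own
#' compartment's channels and by `labeling_effect / compartment_effect` in
#' the opposite compartment; `DUAL` proteins raised equally in both;
#' secreted ligands behave like endosome residents. Optional isotope
#' mixing (`impurity_spill > 0`) is applied to the true intensities so the
#' impurity correction has real work to do. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a [truth_spec()].
#' @return list of class `endo_simulation` with `quant`
#'   ([protein_quant_table()], mixed intensities), `annotations`
#'   ([annotation_table()]), `impurity` (the mixing matrix), `truth`
#'   (data frame: `protein_id`, `gene_id`, `class`, `true_call`,
#'   `expected_in_union`, `receptor_id`, `cell_type_pattern`), and
#'   `design`.
#' @export
generate_proteomics <- function(spec) {
  stopifnot(inherits(spec, "truth_spec"))
  design <- default_channel_design()
  n <- spec$n_proteins
  with_preserved_seed(spec$seed, {
    counts <- diff(c(0, round(cumsum(spec$class_mix) * n)))
    cls <- sample(rep(names(spec$class_mix), counts))
    ids <- sprintf("P%04d", seq_len(n))
    genes <- sprintf("g%04d", seq_len(n))

    b <- spec$base_intensity_log2
    hi <- b + log2(spec$labeling_effect)
    lo <- hi - log2(spec$compartment_effect)
    mu <- matrix(b, nrow = n, ncol = nrow(design),
                 dimnames = list(ids, design$channel))
    endo_ch <- condition_channels(design, "ENDO")
    surf_ch <- condition_channels(design, "SURF")
    endo_like <- cls %in% c("ENDO_RESIDENT", "SECRETED_LIGAND")
    mu[endo_like, endo_ch] <- hi
    mu[endo_like, surf_ch] <- lo
    mu[cls == "SURF_RESIDENT", surf_ch] <- hi
    mu[cls == "SURF_RESIDENT", endo_ch] <- lo
    mu[cls == "DUAL", c(endo_ch, surf_ch)] <- hi

    noise <- matrix(stats::rnorm(length(mu), sd = spec$noise_sd_log2),
                    nrow = n)
    true_int <- 2^(mu + noise)
    M <- make_impurity_matrix(design$channel, spec$impurity_spill)
    mixed <- t(M %*% t(true_int))

    low <- stats::runif(n) < spec$frac_low_peptide
    peptides <- ifelse(low, 1L, sample(2:30, n, replace = TRUE))

    quant <- protein_quant_table(
      data.frame(protein_id = ids, unique_peptides = peptides, mixed,
                 check.names = FALSE, stringsAsFactors = FALSE),
      design)

    has_tm <- cls %in% c("SURF_RESIDENT", "ENDO_RESIDENT", "DUAL")
    has_sp <- cls == "SECRETED_LIGAND" |
      (has_tm & stats::runif(n) < 0.3)   # some membrane proteins also have SPs
    secreted <- cls == "SECRETED_LIGAND"

    # wire each secreted ligand to one membrane-resident receptor
    receptor_id <- rep(NA_character_, n)
    residents <- ids[has_tm]
    lig_idx <- which(secreted)
    if (length(lig_idx) && length(residents)) {
      receptor_id[lig_idx] <- sample(residents, length(lig_idx),
                                     replace = length(residents) < length(lig_idx))
    }
    ann <- annotation_table(data.frame(
      protein_id = ids, gene_id = genes,
      has_signal_peptide = has_sp, has_tm_domain = has_tm,
      is_secreted = secreted,
      receptor_ids = ifelse(is.na(receptor_id), "", receptor_id),
      stringsAsFactors = FALSE))

    true_call <- ifelse(endo_like, "ENDO_ENRICHED",
                 ifelse(cls == "SURF_RESIDENT", "SURF_ENRICHED",
                        "NOT_SIGNIFICANT"))
    pattern <- rep(NA_character_, n)
    if (length(lig_idx)) {
      pattern[lig_idx] <- sample(names(spec$cell_type_mix), length(lig_idx),
                                 replace = TRUE, prob = spec$cell_type_mix)
    }
    truth <- data.frame(
      protein_id = ids, gene_id = genes, class = cls,
      true_call = true_call,
      expected_in_union = cls != "CONTAMINANT",
      receptor_id = receptor_id,
      cell_type_pattern = pattern,
      unique_peptides = peptides,
      stringsAsFactors = FALSE)

    structure(list(quant = quant, annotations = ann, impurity = M,
                   truth = truth, design = design, spec = spec),
              class = "endo_simulation")
  })
}

#' Generate a synthetic single-cell expression summary from ground truth
#'
#' For every secreted-ligand gene, emits mean log2(CPM+1) and fraction of
#' expressing cells for both cell classes at both time points, placed
#' clearly above or below the robust-expression thresholds (level 4,
#' fraction 0.30) according to the gene's planted pattern: enriched
#' classes at mean 6 / fraction 0.6, others at mean 2 / fraction 0.1,
#' with optional Gaussian jitter.
#'
#' @param sim an `endo_simulation` from [generate_proteomics()].
#' @param jitter sd of the jitter on the mean level (log2(CPM+1) units);
#'   fraction jitter uses `jitter / 5`, clipped to (0, 1). `jitter = 0`
#'   reproduces the planted pattern exactly (default 0.25).
#' @return an [expression_summary()] covering all ligand genes.
#' @export
generate_expression <- function(sim, jitter = 0.25) {
  stopifnot(inherits(sim, "endo_simulation"))
  truth <- sim$truth[!is.na(sim$truth$cell_type_pattern), , drop = FALSE]
  if (nrow(truth) == 0L) {
    ep_validation_error("ground truth contains no secreted-ligand genes")
  }
  with_preserved_seed(sim$spec$seed + 1L, {
    grid <- expand.grid(gene_id = truth$gene_id,
                        cell_class = c("ORN", "PN"),
                        time_point = c("24h", "48h"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pattern <- truth$cell_type_pattern[match(grid$gene_id, truth$gene_id)]
    on_target <- (grid$cell_class == "ORN" & pattern %in% c("ORN_ONLY", "BOTH")) |
                 (grid$cell_class == "PN" & pattern %in% c("PN_ONLY", "BOTH"))
    mean_val <- ifelse(on_target, 6, 2) +
      stats::rnorm(nrow(grid), sd = jitter)
    frac_val <- ifelse(on_target, 0.6, 0.1) +
      stats::rnorm(nrow(grid), sd = jitter / 5)
    grid$mean_log2cpm1 <- pmax(mean_val, 0)
    grid$frac_expressing <- pmin(pmax(frac_val, 0), 1)
    expression_summary(grid)
  })
}

#' Write all simulated inputs as the pipeline's file formats
#'
#' Emits the quantification TSV, annotation TSV, impurity CSV, expression
#' summary TSV and ground-truth TSV into a directory, exactly in the
#' formats the readers accept, so the generator doubles as the fixture
#' factory.
#'
#' @param sim an `endo_simulation`.
#' @param dir output directory (created if needed).
#' @param expr optional [expression_summary()] to include.
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, expr = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    quant = file.path(dir, "quant.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    impurity = file.path(dir, "impurity.csv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_quant_table(sim$quant, paths["quant"])
  write_annotation_table(sim$annotations, paths["annotations"])
  write_impurity_matrix(sim$impurity, paths["impurity"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(expr)) {
    paths["expression"] <- file.path(dir, "expression.tsv")
    write_expression_summary(expr, paths["expression"])
  }
  invisible(paths)
}

#' Score compartment calls against simulation ground truth
#'
#' Sensitivity is the fraction of truly compartment-enriched proteins
#' (endosome- or surface-resident, including secreted ligands) whose
#' pipeline call matches the true direction; specificity is the fraction
#' of truly non-enriched proteins (dual-localized and contaminants) not
#' called enriched (either tested and not significant, or excluded by the
#' contaminant filter). Scoring conditions on quantifiable proteins --
#' those passing the unique-peptide filter -- since single-peptide
#' proteins are removed by design before any statistics are computed.
#'
#' @param sim an `endo_simulation`.
#' @param enr an `enrichment_result` with calls.
#' @param min_unique_peptides scoring scope threshold (default 2, matching
#'   the pipeline's filter).
#' @return list with `sensitivity`, `specificity`, `n_positive`,
#'   `n_negative`, and `contaminant_union_fraction` (requires `proteome`).
#' @param proteome a `filtered_proteome` from the same run.
#' @export
score_compartment_calls <- function(sim, enr, proteome,
                                    min_unique_peptides = 2L) {
  truth <- sim$truth
  scope <- truth[truth$unique_peptides >= min_unique_peptides, , drop = FALSE]
  observed <- enr$call[match(scope$protein_id, enr$protein_id)]
  observed[is.na(observed)] <- "NOT_TESTED"
  pos <- scope$true_call %in% c("ENDO_ENRICHED", "SURF_ENRICHED")
  sens <- mean(observed[pos] == scope$true_call[pos])
  spec <- mean(observed[!pos] %in% c("NOT_SIGNIFICANT", "NOT_TESTED"))
  contam <- scope$protein_id[scope$class == "CONTAMINANT"]
  contam_frac <- if (length(contam)) {
    mean(contam %in% proteome$union)
  } else NA_real_
  list(sensitivity = sens, specificity = spec,
       n_positive = sum(pos), n_negative = sum(!pos),
       contaminant_union_fraction = contam_frac)
}
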