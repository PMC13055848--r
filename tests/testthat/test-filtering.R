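make_ann <- function(ids, sp, tm, secreted = NULL, receptors = "") {
  if (is.null(secreted)) secreted <- rep(FALSE, length(ids))
  annotation_table(data.frame(
    protein_id = ids, gene_id = paste0("g_", ids),
    has_signal_peptide = sp, has_tm_domain = tm, is_secreted = secreted,
    receptor_ids = receptors, stringsAsFactors = FALSE))
}

test_that("unique-peptide filter keeps proteins at or above the threshold", {
  tab <- tiny_quant(matrix(runif(32, 10, 100), nrow = 4),
                    peptides = c(1L, 2L, 3L, 0L))
  out <- suppressMessages(filter_min_peptides(tab, 2L))
  expect_equal(out$protein_id, c("P02", "P03"))   # 1 removed, 2 retained
  expect_equal(filter_min_peptides(tab, 0L)$protein_id, tab$protein_id)
  # raising k never adds proteins
  expect_true(all(suppressMessages(filter_min_peptides(tab, 3L))$protein_id %in%
                    out$protein_id))
})

test_that("TP/FP labels follow the signal-peptide/TM-domain rule", {
  ann <- make_ann(c("A", "B", "C", "D"),
                  sp = c(TRUE, FALSE, TRUE, FALSE),
                  tm = c(FALSE, FALSE, TRUE, TRUE))
  lab <- annotate_tp_fp(ann, c("A", "B", "C", "D"))
  expect_equal(unname(lab), c("TP", "FP", "TP", "TP"))
  expect_error(annotate_tp_fp(ann, c("A", "Z")), "Z",
               class = "ep_validation_error")
})

test_that("ROC cutoff reproduces the worked ranking example", {
  ratios <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  labels <- c(a = "TP", b = "TP", c = "FP", d = "TP", e = "FP")
  res <- roc_cutoff(ratios, labels)
  expect_equal(res$curve$tpr - res$curve$fpr,
               c(1/3, 2/3, 2/3 - 1/2, 1 - 1/2, 0))
  expect_equal(res$chosen_threshold, 4)
  expect_equal(res$youden, 2/3)
  expect_setequal(res$retained, c("a", "b"))
  # exclusive mode drops the protein at the maximizing rank
  expect_setequal(roc_cutoff(ratios, labels, inclusive = FALSE)$retained, "a")
})

test_that("perfect separation gives Youden 1 and exactly the true positives", {
  ratios <- c(p1 = 9, p2 = 8, p3 = 7, q1 = 2, q2 = 1)
  labels <- c(p1 = "TP", p2 = "TP", p3 = "TP", q1 = "FP", q2 = "FP")
  res <- roc_cutoff(ratios, labels)
  expect_equal(res$youden, 1)
  expect_setequal(res$retained, c("p1", "p2", "p3"))

  all_tp <- c(p1 = "TP", p2 = "TP", p3 = "TP", q1 = "TP", q2 = "TP")
  expect_error(roc_cutoff(ratios, all_tp), class = "ep_degenerate_error")
})

test_that("ROC cutoff matches the exhaustive oracle on random instances with ties", {
  set.seed(51)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    # coarse rounding forces plenty of tied ratios
    ratios <- stats::setNames(round(stats::rlnorm(n, 0, 1), 1),
                              paste0("p", seq_len(n)))
    labels <- stats::setNames(sample(c("TP", "FP"), n, replace = TRUE),
                              names(ratios))
    if (!all(c("TP", "FP") %in% labels)) next
    res <- roc_cutoff(ratios, labels)
    orc <- oracle_roc(ratios, labels)
    expect_equal(res$chosen_threshold, orc$threshold)
    expect_equal(res$youden, orc$youden)
    expect_equal(sort(res$retained), orc$retained)
    # curve invariants: monotone rates, endpoint at (1, 1)
    expect_true(all(diff(res$curve$tpr) >= 0))
    expect_true(all(diff(res$curve$fpr) >= 0))
    expect_equal(utils::tail(res$curve$tpr, 1), 1)
    expect_equal(utils::tail(res$curve$fpr, 1), 1)
  }
})

test_that("replicate intersection and proteome assembly are plain set algebra", {
  mk <- function(ids) structure(list(retained = ids), class = "cutoff_result")
  expect_setequal(
    intersect_replicates(list(mk(c("A", "B", "C")), mk(c("B", "C")),
                              mk(c("B", "C", "D")))),
    c("B", "C"))
  expect_length(
    intersect_replicates(list(mk(character(0)), mk(c("A", "B")))), 0)

  set.seed(61)
  for (i in 1:20) {
    sets <- replicate(3, sample(letters, sample(5:20, 1)), simplify = FALSE)
    got <- intersect_replicates(lapply(sets, mk))
    manual <- letters[vapply(letters, function(x)
      all(vapply(sets, function(s) x %in% s, logical(1))), logical(1))]
    expect_setequal(got, manual)
  }

  fp <- assemble_filtered_proteome(c("A", "B"), c("B", "C"))
  expect_setequal(fp$union, c("A", "B", "C"))
  expect_setequal(fp$both, "B")
  expect_length(assemble_filtered_proteome(c("A"), c("B"))$both, 0)
})

test_that("cascade retention is invariant to input row order", {
  set.seed(71)
  sim <- generate_proteomics(truth_spec(n_proteins = 200L, seed = 5L))
  cfg <- run_config(seed = 5L)
  res1 <- suppressMessages(filter_cascade(sim$quant, sim$annotations, cfg))
  perm <- sample(nrow(sim$quant))
  shuffled <- protein_quant_table(as.data.frame(sim$quant)[perm, ],
                                  sim$design)
  res2 <- suppressMessages(filter_cascade(shuffled, sim$annotations, cfg))
  expect_setequal(res1$proteome$union, res2$proteome$union)
  expect_setequal(res1$proteome$endo, res2$proteome$endo)
  expect_setequal(res1$proteome$surf, res2$proteome$surf)
})

test_that("zero-noise cascade recovers exactly the labeled proteins", {
  spec <- truth_spec(n_proteins = 300L, noise_sd_log2 = 0,
                     frac_low_peptide = 0, seed = 9L)
  sim <- generate_proteomics(spec)
  corrected <- correct_impurities(sim$quant, sim$impurity)
  res <- suppressMessages(filter_cascade(corrected, sim$annotations,
                                         run_config(seed = 9L)))
  truth_ids <- sim$truth$protein_id[sim$truth$expected_in_union]
  expect_setequal(res$proteome$union, truth_ids)
  contaminants <- sim$truth$protein_id[sim$truth$class == "CONTAMINANT"]
  expect_length(intersect(res$proteome$union, contaminants), 0)
  # perfect separation on every replicate
  for (co in res$cutoffs) expect_equal(co$youden, 1)
})
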