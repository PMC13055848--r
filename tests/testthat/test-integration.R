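expr_fixture <- function(rows) {
  expression_summary(do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], cell_class = r[[2]], time_point = r[[3]],
               mean_log2cpm1 = r[[4]], frac_expressing = r[[5]],
               stringsAsFactors = FALSE)
  })))
}

test_that("time-point averaging is the arithmetic mean per gene and class", {
  expr <- expr_fixture(list(
    list("g1", "ORN", "24h", 3, 0.2), list("g1", "ORN", "48h", 5, 0.4),
    list("g1", "PN", "24h", 1, 0.1), list("g1", "PN", "48h", 2, 0.3)))
  avg <- average_timepoints(expr)
  orn <- avg[avg$cell_class == "ORN", ]
  expect_equal(orn$mean_log2cpm1, 4)
  expect_equal(orn$frac_expressing, 0.3)
  expect_equal(avg[avg$cell_class == "PN", ]$mean_log2cpm1, 1.5)

  # gene missing one time point is excluded with a warning
  expr2 <- expr_fixture(list(
    list("g1", "ORN", "24h", 3, 0.2), list("g1", "ORN", "48h", 5, 0.4),
    list("g2", "ORN", "24h", 6, 0.5)))
  expect_warning(avg2 <- average_timepoints(expr2), "missing a time point")
  expect_false("g2" %in% avg2$gene_id)
})

test_that("averaging agrees with a scalar-loop oracle on random summaries", {
  set.seed(151)
  genes <- sprintf("g%02d", 1:15)
  grid <- expand.grid(gene_id = genes, cell_class = c("ORN", "PN"),
                      time_point = c("24h", "48h"), stringsAsFactors = FALSE)
  grid$mean_log2cpm1 <- runif(nrow(grid), 0, 8)
  grid$frac_expressing <- runif(nrow(grid))
  avg <- average_timepoints(expression_summary(grid))
  for (g in sample(genes, 5)) {
    for (cl in c("ORN", "PN")) {
      rows <- grid[grid$gene_id == g & grid$cell_class == cl, ]
      got <- avg[avg$gene_id == g & avg$cell_class == cl, ]
      expect_equal(got$mean_log2cpm1, mean(rows$mean_log2cpm1))
      expect_equal(got$frac_expressing, mean(rows$frac_expressing))
    }
  }
})

test_that("robust-expression rule uses a strict fraction and inclusive level", {
  cfg <- run_config()
  expect_true(is_expression_enriched(4.5, 0.40, cfg))
  expect_false(is_expression_enriched(5, 0.30, cfg))   # fraction strict >
  expect_false(is_expression_enriched(3.9, 0.50, cfg)) # level below >= 4
  expect_true(is_expression_enriched(4, 0.31, cfg))    # level inclusive
  # monotone non-decreasing in both arguments
  set.seed(161)
  m <- runif(50, 0, 8); f <- runif(50)
  base <- is_expression_enriched(m, f, cfg)
  up <- is_expression_enriched(m + 0.5, pmin(f + 0.1, 1), cfg)
  expect_true(all(up >= base))
})

test_that("cell-type calls partition genes and reproduce planted structure", {
  sim <- generate_proteomics(truth_spec(n_proteins = 400L, seed = 17L))
  expr <- generate_expression(sim, jitter = 0)
  calls <- call_cell_types(average_timepoints(expr))
  expect_equal(nrow(calls), length(unique(expr$gene_id)))
  expect_true(all(calls$enriched_in %in%
                    c("ORN_ONLY", "PN_ONLY", "BOTH", "NEITHER")))
  truth <- sim$truth[!is.na(sim$truth$cell_type_pattern), ]
  expect_equal(
    calls$enriched_in[match(truth$gene_id, calls$gene_id)],
    truth$cell_type_pattern)
  # counts over categories sum to the gene total (partition)
  expect_equal(sum(table(calls$enriched_in)), nrow(calls))
  # "more abundant in PN" requires PN enrichment plus a higher PN mean
  pn <- calls[!is.na(calls$more_abundant_in) & calls$more_abundant_in == "PN", ]
  expect_true(all(pn$mean_PN > pn$mean_ORN))
  expect_true(all(pn$enriched_in %in% c("PN_ONLY", "BOTH")))
})

test_that("ligand-receptor join reports one record set per planted ligand", {
  spec <- truth_spec(n_proteins = 300L, noise_sd_log2 = 0,
                     frac_low_peptide = 0, seed = 19L)
  sim <- generate_proteomics(spec)
  expr <- generate_expression(sim, jitter = 0)
  run <- suppressMessages(run_pipeline(sim$quant, sim$annotations,
                                       sim$impurity, expr,
                                       cfg = run_config(seed = 19L)))
  lig_truth <- sim$truth[sim$truth$class == "SECRETED_LIGAND", ]
  lr <- run$ligand_receptors
  # zero noise: every planted ligand is endosome-enriched, one row each
  expect_setequal(lr$ligand_id, lig_truth$protein_id)
  expect_equal(nrow(lr), nrow(lig_truth))
  # statuses derive from the receptor's true class
  rec_class <- sim$truth$class[match(lr$receptor_id, sim$truth$protein_id)]
  expect_true(all(lr$receptor_status[rec_class == "ENDO_RESIDENT"] ==
                    "ENDO_ENRICHED"))
  expect_true(all(lr$receptor_status[rec_class == "SURF_RESIDENT"] ==
                    "SURF_ENRICHED"))
  expect_true(all(lr$receptor_status[rec_class == "DUAL"] == "DUAL"))
  expect_true(all(lr$receptor_mark[rec_class == "ENDO_RESIDENT"] == "*"))
  expect_true(all(lr$receptor_mark[rec_class == "DUAL"] == "**"))
  # ligand cell-type call carried over from the expression integration
  expect_equal(lr$ligand_cell_type,
               lig_truth$cell_type_pattern[match(lr$ligand_id,
                                                 lig_truth$protein_id)])
})

test_that("a ligand without receptor annotation yields an empty-receptor record", {
  enr <- data.frame(protein_id = c("L1", "R1"), log2fc = c(-2, -1),
                    p = c(1e-5, 1e-4), p_adj = c(1e-4, 1e-3),
                    call = c("ENDO_ENRICHED", "ENDO_ENRICHED"),
                    stringsAsFactors = FALSE)
  ann <- annotation_table(data.frame(
    protein_id = c("L1", "R1"), gene_id = c("gL1", "gR1"),
    has_signal_peptide = c(TRUE, FALSE), has_tm_domain = c(FALSE, TRUE),
    is_secreted = c(TRUE, FALSE), receptor_ids = c("", "")))
  proteome <- assemble_filtered_proteome(c("L1", "R1"), c("R1"))
  lr <- join_ligand_receptors(enr[1, ], ann, enr, proteome)
  expect_equal(nrow(lr), 1)
  expect_true(is.na(lr$receptor_id))
  expect_equal(lr$receptor_mark, "")
})

test_that("count-matrix summarization matches a manual CPM computation", {
  counts <- matrix(c(10, 0, 90,
                     5, 5, 90,
                     0, 50, 50,
                     20, 30, 50), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("g", 1:4), NULL))
  counts <- cbind(counts, counts + 1)   # 6 cells
  classes <- c("ORN", "ORN", "ORN", "PN", "PN", "PN")
  times <- c("24h", "24h", "24h", "48h", "48h", "48h")
  # genes x cells: need cells as columns -> counts already 4 x 6
  summ <- summarize_expression_matrix(counts, classes, times)
  # manual oracle for gene 1 in ORN/24h cells (columns 1-3)
  lib <- colSums(counts[, 1:3])
  lg <- log2(counts[1, 1:3] / lib * 1e6 + 1)
  row <- summ[summ$gene_id == "g1" & summ$cell_class == "ORN", ]
  expect_equal(row$mean_log2cpm1, mean(lg))
  expect_equal(row$frac_expressing, mean(counts[1, 1:3] > 0))
  expect_s3_class(summ, "expression_summary")
})
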