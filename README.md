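# endoprofiler

Quantitative analysis of **dual-compartment proximity-labeling proteomics**:
given a protein × TMT-channel reporter-intensity table from an experiment
that tags proteins in the endosomal lumen ("endocytome") and on the cell
surface ("surfaceome") of a defined cell type, the package identifies which
proteins reside in which compartment, and which endocytosed secreted
proteins arrive there as ligands bound to detectable receptors.

It is written for proteomics analysts working with peroxidase (HRP/APEX)
proximity labeling read out by isobaric TMT quantification, with a few
biological replicates per compartment and negative-control channels
(samples lacking enzyme or peroxide) that measure non-specific background.

## What it computes

Starting from reporter-ion intensities `y` over channels (3 ENDO, 3 SURF,
2 NC by default):

1. **Isotope-impurity correction.** With impurity matrix *M* (entry
   (i, j) = fraction of channel j's signal observed in channel i), solve
   `y = M x` exactly for the true intensities `x`, clamping negative
   components to zero.
2. **Ratiometric contaminant filter.** Per experimental channel, each
   protein's ratio to the averaged negative controls,
   `r_c = (x_c + ε) / (mean(x_NC) + ε)`, is ranked in descending order.
   Using annotation as truth — true positive = protein with a signal
   peptide and/or transmembrane domain, false positive = neither — a ROC
   curve of cumulative TPR/FPR is traced down the ranking and the cutoff
   is placed at max(TPR − FPR) (the Youden index). A protein survives a
   condition only if retained in **all** of its replicates; the analysis
   set is the union of the two conditions. Proteins also need ≥ 2 unique
   peptides.
3. **Compartment enrichment.** Per protein, the log₂(SURF/ENDO) fold
   change of the log₂ control ratios is tested with an empirical-Bayes
   **moderated t-test**: the pooled residual variance s² is shrunk toward
   a prior (d₀, s₀²) estimated by moment matching on log s²,
   `s²_post = (d₀ s₀² + df s²) / (d₀ + df)`, and
   `t = log₂FC / sqrt(s²_post (1/n₁ + 1/n₂))` is referred to a t
   distribution on d₀ + df degrees of freedom. Benjamini–Hochberg-adjusted
   p < 0.05 with the sign of the fold change yields
   ENDO_ENRICHED / SURF_ENRICHED / NOT_SIGNIFICANT calls.
4. **Top-N transmembrane ranking** per compartment (default N = 200, by
   mean control ratio) and the directional overlap between the two lists.
5. **Multi-omic ligand–receptor integration.** Endosome-enriched secreted
   proteins are the candidate internalized ligands. Each ligand's
   transcript is assigned to the cell class(es) robustly expressing it —
   mean log₂(CPM+1) ≥ 4 in > 30% of cells, averaged over two
   developmental time points — and each annotated receptor is marked
   `*` (endosome-enriched), `**` (detected in both compartments without
   enrichment), surface-enriched, or not detected.

A seeded synthetic-data generator (`truth_spec()` / `generate_proteomics()`
/ `generate_expression()`) produces every input with known ground truth, so
the whole pipeline is testable offline.

## Worked example

```r
library(endoprofiler)

sim  <- generate_proteomics(truth_spec(n_proteins = 1000L, seed = 42L))
expr <- generate_expression(sim)
run  <- run_pipeline(sim$quant, sim$annotations, sim$impurity, expr,
                     cfg = run_config(seed = 42L, top_n = 100))
print(run)
```

```
# Endosome/surface profiling run summary

- Proteins detected: 1000
- After unique-peptide filter: 908
- Retained per replicate: ENDO_1=701, ENDO_2=697, ENDO_3=704, SURF_1=710, SURF_2=706, SURF_3=696
- In all ENDO replicates: 665; in all SURF replicates: 674
- Filtered proteome (union): 720 (619 in both compartments)
- Endosome-enriched: 276; surface-enriched: 228
- Endosome-enriched secreted proteins: 90
- Top-N TM overlap (endo list also in surf list): 26.0%
```

Reading the cascade: of 1,000 simulated proteins, 908 had ≥ 2 unique
peptides; the per-replicate ROC cutoffs (e.g. `ENDO_1`: threshold 1.53,
TPR − FPR = 0.96) retained ~700 each; intersecting replicates and taking
the union leaves 720 proteins, of which 276 are called endosome-enriched
and 228 surface-enriched. Most proteins are seen in both compartments —
enrichment, not mere detection, distinguishes them. The ligand–receptor
join then reports, per internalized secreted protein, its cell class of
origin and receptor status:

```r
head(run$ligand_receptors[, c("ligand_id", "ligand_cell_type",
                              "receptor_id", "receptor_status")], 3)
#   ligand_id ligand_cell_type receptor_id receptor_status
# 1     P0502          NEITHER       P0691   SURF_ENRICHED
# 2     P0845          PN_ONLY       P0876   ENDO_ENRICHED
# 3     P0954          NEITHER       P0752   ENDO_ENRICHED
```

Against the generator's ground truth this run recovers planted
compartments with sensitivity 1.000 and specificity 0.973
(`score_compartment_calls()`), with zero contaminants in the final set.

A command-line wrapper with `simulate` and `run` subcommands lives at
`inst/scripts/endoprofiler.R`.

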