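---
title: "Methods: dual-compartment proximity-labeling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-compartment proximity-labeling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(endoprofiler)
```

# The experimental design the model assumes

The pipeline analyzes a multiplexed TMT experiment in which a peroxidase is
targeted either to the endosomal lumen or to the cell surface of one cell
type, biotinylating nearby proteins; streptavidin-enriched samples are
quantified jointly with negative controls lacking enzyme or peroxide. The
default channel layout (`default_channel_design()`) is three ENDO
replicates, three SURF replicates, and two negative-control (NC) channels.
Any layout with exactly two NC channels and at least two replicates per
experimental condition validates.

Key assumptions, in the order the stages make them:

* Reporter intensities are already rolled up to protein level; one row per
  protein, intensities finite and non-negative. Missing cells are
  **rejected, not imputed** — there is no principled imputation rule for
  streptavidin-enrichment background, and silently filling values would
  bias the control ratios.
* The NC channels measure the same non-specific background for every
  protein, so an experimental-to-NC ratio is a per-protein measure of
  labeling specificity.
* On the log2 scale, replicate noise is approximately Gaussian with a
  protein-specific variance exchangeable across proteins — the premise of
  the empirical-Bayes moderation.

# Stage by stage

## Isotope-impurity correction

Isobaric labels leak a known fraction of signal into neighboring channels.
We adopt the **column convention**: entry $(i, j)$ of the impurity matrix
$M$ is the fraction of channel $j$'s true signal observed in channel $i$,
so columns sum to at most 1 and observed intensities are $y = Mx$. The
correction is the exact linear solve $x = M^{-1} y$ (`solve()`; the
classical description of this correction via determinant ratios is
mathematically the same solve, not a prescription for how to compute it).
Numerical choices:

* Matrices with exact condition number above $10^8$ are rejected with a
  numerical error rather than producing garbage intensities.
* Components driven negative by noise are clamped to 0: intensities are
  physical. Clamping is applied after the solve so the remaining channels
  keep their exact solution values.
* Validation requires column-wise diagonal dominance, which both matches
  how real impurity tables look and guarantees invertibility.

## Control ratios

For each protein, `compute_nc_ratios()` forms
$r_c = (x_c + \varepsilon)/(\bar{x}_{NC} + \varepsilon)$ where
$\bar{x}_{NC}$ is the **arithmetic mean** of the two NC intensities and
$\varepsilon$ is a pseudocount (default **1 intensity unit**). The
arithmetic mean was chosen over the geometric for symmetry and because the
two controls play interchangeable roles; the pseudocount's only job is to
keep ratios finite and strictly positive when a channel or both controls
read zero, and at realistic intensities (hundreds to thousands of units)
it perturbs ratios negligibly. No between-channel normalization is applied
before ratioing. Note the standard caveat that isobaric quantification
compresses ratios, so fold changes are best read as conservative.

## Ratiometric ROC cutoff

Contaminants (cytosolic and nuclear proteins carried through enrichment)
lack both a signal peptide and a transmembrane domain, while genuinely
labeled proteins almost always carry one — this annotation is the truth
set: TP = signal peptide OR transmembrane domain, FP = neither. Annotation
comes from a user-supplied table so runs are hermetic (no database
queries at analysis time).

Per experimental channel, proteins are sorted by ratio in descending
order; after each **distinct** ratio value the cumulative TPR and FPR are
computed (ties are processed as a block, which makes the curve
well-defined under ties), and the cutoff is the ratio maximizing
TPR − FPR. Tie-breaks on the objective take the **earliest (highest)
threshold** — the most stringent choice. Retention is **inclusive**
(ratio ≥ cutoff) by default: exclusive retention would discard the
protein at the maximizing rank itself, contradicting the ROC
construction; a config flag (`inclusive_threshold = FALSE`) switches to
strict retention for sensitivity analysis.

Cutoffs are computed **per replicate channel**, and a protein survives a
condition only when retained in all of that condition's replicates; the
analysis set is the union of the two conditions. Computing one cutoff per
replicate (rather than on condition-averaged ratios) uses the replicate
structure as an additional filter and is the stricter reading of
"per experimental group".

## Moderated compartment test

The tested quantity is the **log2 control ratio per replicate channel** —
the NC channels act as a per-protein reference, which cancels protein
loading differences; the per-protein NC term is common to all six
channels, so it shifts both groups equally and does not inflate
within-group variance. With groups $a$ (ENDO) and $b$ (SURF):

$$\log_2 FC = \bar b - \bar a, \qquad
s^2_{post} = \frac{d_0 s_0^2 + d\,s^2}{d_0 + d}, \qquad
t = \frac{\log_2 FC}{\sqrt{s^2_{post}(1/n_1 + 1/n_2)}}$$

with $d = n_1 + n_2 - 2$ pooled residual degrees of freedom and p values
from a t distribution on $d_0 + d$ df. The hyperparameters $(d_0, s_0^2)$
are estimated from all proteins by matching the mean and variance of
$\log s^2$ to the scaled-F marginal implied by a scaled inverse-chi-square
prior; the variance equation $\psi'(d_0/2) = \widehat{Var}(\log s^2) -
\psi'(d/2)$ is inverted by Newton iteration on the trigamma function
(monotone, converges in a few steps from $x_0 = 0.5 + 1/y$). Degenerate
regimes are defined rather than errored:

* observed spread of $\log s^2$ at or below the sampling contribution
  → $d_0 = \infty$ (normal-tail test with the common variance);
* exactly constant variances → $d_0 = \infty$ with $s_0^2$ equal to the
  shared value;
* all variances zero (noise-free data) → $s^2_{post} = 0$ and the test
  takes its limit: p = 0 for any nonzero fold change, p = 1 at zero.
  This is what makes exact recovery on noise-free synthetic data
  well-defined.

Tests are two-sided throughout. Significance defaults to
**Benjamini–Hochberg-adjusted p < 0.05**; the adjustment is a deliberate
default rather than the only option (`adjust = "none"` thresholds raw p),
since published ratiometric pipelines differ in whether and how they
adjust. Calls then combine significance with the sign of the fold change.
The suite cross-checks both the prior fit and the full moderated
statistics against `limma` on identical inputs, while all package results
are computed by this implementation.

## Top-N transmembrane ranking and overlap

`top_n_tm()` restricts to transmembrane proteins and ranks them by the
condition-mean **control ratio** by default; mean raw intensity is offered
as the alternative metric because "most labeled" can defensibly mean
either, and the choice is recorded in the run manifest. Ties break
lexicographically by protein id so the ranking is order-deterministic.
The overlap statistic divides by the **first** list's size, matching the
directional question "how many of the endosome list are also in the
surface list".

## Multi-omic integration

Cell-type assignment averages (arithmetically) each gene's summary across
the two developmental time points bracketing the profiling stage, per cell
class, then applies the robust-expression rule: **fraction of expressing
cells > 0.30 (strict)** and **mean log2(CPM+1) ≥ 4 (inclusive)**. The
asymmetry mirrors the rule's definition exactly and matters only on the
boundary. "Expressing" means count > 0 in the raw-matrix helper
(`summarize_expression_matrix()`); a higher per-cell cutoff is not used
because the downstream rule already demands a substantial mean level.
"More abundant in PNs" is operationalized as: enriched in PN under the
rule **and** averaged PN mean above the ORN mean (switchable in the sense
that both the calls and the raw means are returned, so any alternative
rule can be applied downstream).

Receptor status in the ligand–receptor join derives deterministically
from the enrichment calls and the filtered sets: endosome-enriched (`*`),
present in both compartment sets without significant enrichment (`**`,
"dual"), surface-enriched, detected in only one set without enrichment,
or not detected. Receptor ids absent from the annotation table are
recorded as unmatched rather than erroring, since pairing tables are
chronically incomplete.

# The synthetic-data generator

`truth_spec()` fixes the simulated study conditions; its defaults are the
conditions all recovery statements refer to:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 2000 | proteins detected |
| `class_mix` | 25/20/25/20/10% | SURF/ENDO residents, dual, contaminant, secreted ligand |
| `labeling_effect` | 8 | fold enrichment over NC in a protein's own compartment |
| `compartment_effect` | 4 | own- vs opposite-compartment fold for residents |
| `noise_sd_log2` | 0.25 | lognormal reporter noise, log2 scale |
| `base_intensity_log2` | 10 | background intensity (1024 units) |
| `frac_low_peptide` | 0.10 | proteins with a single unique peptide |
| `impurity_spill` | 0.05 | off-diagonal isotope mass per channel |

The effect sizes describe a clean proximity-labeling experiment: strong
labeling over background, a clear but not extreme compartment preference,
and channel noise typical of reporter-ion quantification. Contaminants sit
at background in all eight channels; secreted ligands behave like
endosome residents but carry a signal peptide without a transmembrane
domain, and each is wired to one membrane-resident receptor. Expression
summaries place enriched classes at mean 6 / fraction 0.6 and
non-enriched at 2 / 0.1 — far from the (4, 0.30) thresholds so that
default jitter cannot flip a call, with `jitter = 0` reproducing planted
patterns exactly.

What the generator does **not** emulate: peptide-level variation and
roll-up, abundance-dependent variance trends, missing values,
between-channel loading differences, co-isolation interference beyond the
linear impurity model, and single-cell count overdispersion. Passing the
recovery tests therefore demonstrates correctness of the algorithms under
the stated statistical model, not robustness to every artifact of real
spectra.

Scoring of end-to-end recovery conditions on proteins with ≥ 2 unique
peptides: the peptide filter is part of the design, and single-peptide
proteins are unquantifiable by construction, so they are out of scope for
sensitivity rather than counted as misses.

# Problem sizes and reproducibility

The test suite and the acceptance script use desk-scale sizes chosen to
make Monte-Carlo error small relative to the tolerances they assert:
2,000-protein pipeline runs, 5,000-protein null calibration (binomial sd
of the p < 0.05 fraction ≈ 0.003), 50,000 variances for hyperparameter
recovery, and 500-instance oracle scans for the ROC cutoff. Every source
of randomness flows from a single integer seed (`truth_spec(seed = )`,
`run_config(seed = )`); generation preserves and restores the caller's
RNG state.

The run configuration serializes to YAML with a versioned `schema` key,
and every pipeline run emits a JSON manifest (config hash, seed, cascade
counts, per-replicate cutoffs) plus a Markdown summary; the cascade-count
monotonicity is asserted at run time, not only in tests.

# Known limitations

* Two-condition designs only; no general design matrices, sample weights,
  or abundance-dependent variance trend in the moderation.
* Ratio compression inherent to isobaric labeling means fold changes are
  conservative; the package does not attempt to de-compress them.
* The contaminant filter inherits the quality of the annotation table:
  an unannotated genuinely-labeled protein counts as a false positive and
  tightens the cutoff.
* Functional enrichment, network analysis, and ortholog mapping are out
  of scope; outputs are plain TSV intended for such downstream tools.
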