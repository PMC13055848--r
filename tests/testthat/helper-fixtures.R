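# Shared fixtures and independent oracles. Oracles are deliberately naive
# (scalar loops, exhaustive scans) and never call the code paths they check.

tiny_design <- function() default_channel_design()

# quant table with explicit intensities; channels in design order
tiny_quant <- function(intensities, peptides = NULL, design = tiny_design()) {
  n <- nrow(intensities)
  if (is.null(peptides)) peptides <- rep(5L, n)
  df <- data.frame(
    protein_id = sprintf("P%02d", seq_len(n)),
    unique_peptides = peptides,
    intensities, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[-(1:2)] <- design$channel
  protein_quant_table(df, design)
}

random_quant <- function(n, design = tiny_design()) {
  m <- matrix(round(2^stats::rnorm(n * nrow(design), 10, 1), 3),
              nrow = n)
  tiny_quant(m, peptides = sample(1:20, n, replace = TRUE), design = design)
}

# exhaustive ROC-cutoff oracle: evaluate TPR - FPR at every candidate
# threshold by direct counting; ties in the objective -> largest threshold
oracle_roc <- function(ratios, labels) {
  labels <- labels[names(ratios)]
  n_tp <- sum(labels == "TP")
  n_fp <- sum(labels == "FP")
  thresholds <- sort(unique(ratios), decreasing = TRUE)
  youden <- vapply(thresholds, function(t) {
    sum(ratios >= t & labels == "TP") / n_tp -
      sum(ratios >= t & labels == "FP") / n_fp
  }, numeric(1))
  best <- which.max(youden)  # first = largest threshold among ties
  list(threshold = thresholds[best], youden = youden[best],
       retained = sort(names(ratios)[ratios >= thresholds[best]]))
}

# brute-force BH step-up: adj_(k) = min(1, min_{i >= k} p_(i) * m / i)
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    adj[k] <- min(1, min(ps[k:m] * m / (k:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# random diagonally-dominant column-stochastic-ish impurity matrix
random_impurity <- function(k, channels = NULL) {
  M <- matrix(stats::runif(k * k, 0, 0.05 / k), k, k)
  diag(M) <- 0
  diag(M) <- 0.9 + stats::runif(k, 0, 0.05)
  if (!is.null(channels)) dimnames(M) <- list(channels, channels)
  M
}
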