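#' Empirical-Bayes variance prior by moment matching on log variances
#'
#' Models per-protein residual variances as draws from a scaled
#' inverse-chi-square prior with `prior_df` (d0) degrees of freedom and
#' scale `prior_var` (s0^2); marginally s2 ~ s0^2 * F(df_resid, d0). The
#' hyperparameters are estimated by matching the first two moments of
#' log(s2): the sampling contribution trigamma(df_resid/2) is subtracted
#' from the observed variance of log(s2), and the remainder is inverted
#' through the trigamma function by Newton iteration to give d0. When the
#' observed spread of log variances does not exceed the sampling
#' contribution, the variances are essentially constant and `prior_df` is
#' the `Inf` sentinel with `prior_var` the common (geometric-mean-based)
#' variance.
#'
#' @param s2 numeric vector of residual variances (>= 10 values, all >= 0).
#'   Zero variances are admissible only when all are zero (noise-free data),
#'   in which case the prior degenerates to `(Inf, 0)`.
#' @param df_resid residual degrees of freedom each variance was computed
#'   with (n1 + n2 - 2 for a two-group comparison).
#' @return list of class `variance_prior` with `prior_df`, `prior_var`,
#'   `df_resid`.
#' @export
fit_variance_prior <- function(s2, df_resid) {
  if (length(s2) < 10L) {
    ep_validation_error("need >= 10 residual variances to fit the prior")
  }
  if (!is_count1(df_resid) || df_resid < 1) {
    ep_validation_error("df_resid must be a positive integer")
  }
  if (any(!is.finite(s2)) || any(s2 < 0)) {
    ep_validation_error("residual variances must be finite and >= 0")
  }
  if (all(s2 == 0)) {
    # noise-free degenerate case: all variance comes from the (zero) prior
    return(structure(list(prior_df = Inf, prior_var = 0, df_resid = df_resid),
                     class = "variance_prior"))
  }
  if (any(s2 == 0)) {
    ep_validation_error(
      "a mix of zero and positive residual variances cannot be moment-matched; inspect the input")
  }
  if (max(s2) == min(s2)) {
    # exactly constant: the shared value is itself the prior scale
    return(structure(
      list(prior_df = Inf, prior_var = s2[1], df_resid = df_resid),
      class = "variance_prior"))
  }
  z <- log(s2)
  # E[log s2] = log s0^2 + digamma(df/2) - log(df/2) - digamma(d0/2) + log(d0/2)
  # Var[log s2] = trigamma(df/2) + trigamma(d0/2)
  e_mean <- mean(z) - digamma(df_resid / 2) + log(df_resid / 2)
  excess <- stats::var(z) - trigamma(df_resid / 2)
  if (!is.finite(excess) || excess <= 0) {
    return(structure(
      list(prior_df = Inf, prior_var = exp(e_mean), df_resid = df_resid),
      class = "variance_prior"))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  structure(list(prior_df = d0, prior_var = s0_sq, df_resid = df_resid),
            class = "variance_prior")
}

# Solve trigamma(x) = y for x > 0 by Newton iteration on the monotone
# decreasing trigamma; converges in a handful of steps from x = 0.5 + 1/y.
trigamma_inverse <- function(y) {
  if (y <= 0) ep_validation_error("trigamma_inverse requires y > 0")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("Variance prior: d0 = %s, s0^2 = %.6g (df_resid = %d)\n",
              format(x$prior_df, digits = 4), x$prior_var, x$df_resid))
  invisible(x)
}

#' Moderated two-sample t-test for compartment enrichment
#'
#' For each protein, the surface-vs-endosome log2 fold change is
#' `mean(SURF) - mean(ENDO)` of the log2 control ratios. The pooled residual
#' variance is shrunk toward the empirical-Bayes prior,
#' `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)`, and the moderated t
#' statistic `log2fc / sqrt(s2_post * (1/n1 + 1/n2))` is referred to a
#' Student t distribution with `d0 + df` degrees of freedom (standard normal
#' when `d0 = Inf`). When the moderated variance is exactly zero (noise-free
#' data) the test degenerates to its limit: p = 0 for a nonzero fold change,
#' p = 1 otherwise.
#'
#' @param endo numeric matrix, proteins x ENDO replicate channels (log2
#'   ratios).
#' @param surf numeric matrix, proteins x SURF replicate channels, same row
#'   order.
#' @param prior a `variance_prior`; if `NULL`, fitted on the pooled residual
#'   variances of these data.
#' @return data frame of class `enrichment_result`: `protein_id`, `log2fc`,
#'   `s2_resid`, `s2_post`, `t_mod`, `df_total`, `p`. Adjusted p values and
#'   compartment calls are added by [call_compartments()].
#' @export
moderated_t <- function(endo, surf, prior = NULL) {
  if (nrow(endo) != nrow(surf)) {
    ep_validation_error("endo and surf matrices must have the same proteins")
  }
  n1 <- ncol(endo)
  n2 <- ncol(surf)
  if (n1 < 2L || n2 < 2L) {
    ep_validation_error("need >= 2 replicates per condition")
  }
  df_resid <- n1 + n2 - 2L
  m1 <- rowMeans(endo)
  m2 <- rowMeans(surf)
  ss1 <- rowSums((endo - m1)^2)
  ss2 <- rowSums((surf - m2)^2)
  s2_resid <- (ss1 + ss2) / df_resid
  if (is.null(prior)) prior <- fit_variance_prior(s2_resid, df_resid)
  d0 <- prior$prior_df
  s0_sq <- prior$prior_var
  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2_resid))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_sq + df_resid * s2_resid) / (d0 + df_resid)
    df_total <- d0 + df_resid
  }
  log2fc <- m2 - m1
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, log2fc / se,
                  ifelse(log2fc == 0, 0, sign(log2fc) * Inf))
  p <- if (is.infinite(df_total)) {
    2 * stats::pnorm(-abs(t_mod))
  } else {
    2 * stats::pt(-abs(t_mod), df = df_total)
  }
  p[is.infinite(t_mod)] <- 0
  ids <- rownames(endo)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(endo)))
  out <- data.frame(
    protein_id = ids, log2fc = log2fc, s2_resid = s2_resid,
    s2_post = s2_post, t_mod = t_mod, df_total = df_total, p = p,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "prior") <- prior
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p values controlling the false discovery rate; a thin
#' validated wrapper over [stats::p.adjust()] so every pipeline stage shares
#' the same input checks.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return adjusted p values, same order and length.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    ep_validation_error("p values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Assign compartment calls from the moderated test
#'
#' A protein is surface-enriched when significant with positive
#' log2(surf/endo) fold change, endosome-enriched when significant with
#' negative fold change, otherwise not significant. Significance uses
#' BH-adjusted p values by default; raw p thresholding is available via the
#' config.
#'
#' @param results an `enrichment_result` from [moderated_t()].
#' @param alpha significance level (default 0.05).
#' @param adjust `"BH"` (default) or `"none"`.
#' @return the `enrichment_result` with columns `p_adj` and `call`
#'   (`"ENDO_ENRICHED"`, `"SURF_ENRICHED"`, `"NOT_SIGNIFICANT"`).
#' @export
call_compartments <- function(results, alpha = 0.05, adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) ep_validation_error("alpha must lie in (0, 1)")
  results$p_adj <- if (adjust == "BH") adjust_bh(results$p) else results$p
  sig <- results$p_adj < alpha
  results$call <- ifelse(sig & results$log2fc > 0, "SURF_ENRICHED",
                  ifelse(sig & results$log2fc < 0, "ENDO_ENRICHED",
                         "NOT_SIGNIFICANT"))
  results
}

#' Full enrichment stage: log ratios, prior fit, moderated test, calls
#'
#' @param ratios a `ratio_table` restricted upstream to the filtered
#'   proteome.
#' @param ids optional protein ids to test (default: all rows).
#' @param cfg a [run_config()].
#' @return an `enrichment_result` with `p_adj` and `call` columns.
#' @export
test_enrichment <- function(ratios, ids = NULL, cfg = run_config()) {
  design <- attr(ratios, "design")
  lr <- log2_ratios(ratios)
  if (!is.null(ids)) lr <- lr[rownames(lr) %in% ids, , drop = FALSE]
  endo <- lr[, condition_channels(design, "ENDO"), drop = FALSE]
  surf <- lr[, condition_channels(design, "SURF"), drop = FALSE]
  res <- moderated_t(endo, surf)
  call_compartments(res, alpha = cfg$significance_alpha,
                    adjust = if (cfg$adjust == "BH") "BH" else "none")
}
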