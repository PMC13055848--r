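# simulate residual variances from the scaled inverse-chi-square prior:
# s2 ~ s0^2 * F(df, d0)
r_s2 <- function(G, d0, s0_sq, df) {
  s0_sq * (stats::rchisq(G, df) / df) / (stats::rchisq(G, d0) / d0)
}

test_that("variance-prior moment matching recovers known hyperparameters", {
  set.seed(81)
  s2 <- r_s2(20000, d0 = 4, s0_sq = 2, df = 4)
  pr <- fit_variance_prior(s2, 4L)
  expect_lt(abs(pr$prior_df - 4) / 4, 0.15)
  expect_lt(abs(pr$prior_var - 2) / 2, 0.1)
})

test_that("variance prior degenerates correctly", {
  expect_error(fit_variance_prior(rep(1, 5), 4L), class = "ep_validation_error")
  pr <- fit_variance_prior(rep(0.5, 50), 4L)
  expect_identical(pr$prior_df, Inf)
  expect_equal(pr$prior_var, 0.5)
  pr0 <- fit_variance_prior(rep(0, 50), 4L)
  expect_identical(pr0$prior_df, Inf)
  expect_equal(pr0$prior_var, 0)
})

test_that("variance prior agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  set.seed(91)
  s2 <- r_s2(5000, d0 = 6, s0_sq = 1.5, df = 4)
  pr <- fit_variance_prior(s2, 4L)
  ref <- limma::fitFDist(s2, df1 = 4)
  expect_equal(pr$prior_df, ref$df2, tolerance = 0.05)
  expect_equal(pr$prior_var, ref$scale, tolerance = 0.05)
})

test_that("moderated t reduces to known limits", {
  set.seed(101)
  G <- 50
  endo <- matrix(rnorm(G * 3), G, 3)
  surf <- matrix(rnorm(G * 3), G, 3)
  rownames(endo) <- rownames(surf) <- sprintf("P%02d", 1:G)

  # identical group means -> t = 0, p = 1
  same <- moderated_t(endo, endo,
                      prior = structure(list(prior_df = 4, prior_var = 1,
                                             df_resid = 4L),
                                        class = "variance_prior"))
  expect_true(all(same$t_mod == 0))
  expect_true(all(same$p == 1))

  # prior_df = 0: ordinary equal-variance two-sample t (textbook oracle)
  res0 <- moderated_t(endo, surf,
                      prior = structure(list(prior_df = 0, prior_var = 1,
                                             df_resid = 4L),
                                        class = "variance_prior"))
  for (i in c(1, 17, 42)) {
    tt <- stats::t.test(surf[i, ], endo[i, ], var.equal = TRUE)
    expect_equal(res0$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res0$p[i], tt$p.value, tolerance = 1e-10)
  }

  # prior_df = Inf: closed form z statistic with s2_post = s0^2
  resI <- moderated_t(endo, surf,
                      prior = structure(list(prior_df = Inf, prior_var = 0.7,
                                             df_resid = 4L),
                                        class = "variance_prior"))
  expect_true(all(resI$s2_post == 0.7))
  expect_equal(resI$t_mod, resI$log2fc / sqrt(0.7 * (2 / 3)), tolerance = 1e-12)
})

test_that("moderation pulls each variance toward the prior, in both directions", {
  pr <- structure(list(prior_df = 4, prior_var = 1, df_resid = 4L),
                  class = "variance_prior")
  # constructed: one protein with tiny, one with huge residual variance
  endo <- rbind(c(0, 0.001, -0.001), c(0, 3, -3))
  surf <- rbind(c(1, 1.001, 0.999), c(2, 5, -1))
  rownames(endo) <- rownames(surf) <- c("tiny", "huge")
  res <- moderated_t(endo, surf, prior = pr)
  expect_true(res$s2_post[1] > res$s2_resid[1])  # tiny variance shrunk up
  expect_true(res$s2_post[1] < pr$prior_var)
  expect_true(res$s2_post[2] < res$s2_resid[2])  # huge variance shrunk down
  expect_true(res$s2_post[2] > pr$prior_var)
  # so |t| decreases for the tiny-variance protein relative to ordinary t
  ord_t <- function(i) unname(stats::t.test(surf[i, ], endo[i, ],
                                            var.equal = TRUE)$statistic)
  expect_lt(abs(res$t_mod[1]), abs(ord_t(1)))
  expect_gt(abs(res$t_mod[2]), abs(ord_t(2)))
})

test_that("swapping groups negates the statistic and preserves p", {
  set.seed(111)
  endo <- matrix(rnorm(60), 20, 3, dimnames = list(sprintf("P%02d", 1:20), NULL))
  surf <- matrix(rnorm(60), 20, 3, dimnames = list(sprintf("P%02d", 1:20), NULL))
  a <- moderated_t(endo, surf)
  b <- moderated_t(surf, endo, prior = attr(a, "prior"))
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$t_mod, -b$t_mod)
  expect_equal(a$p, b$p)
})

test_that("moderated results match the limma pipeline on the same data", {
  skip_if_not_installed("limma")
  set.seed(121)
  G <- 500
  s2 <- r_s2(G, d0 = 5, s0_sq = 1, df = 4)
  endo <- matrix(rnorm(G * 3, sd = sqrt(s2)), G, 3)
  surf <- matrix(rnorm(G * 3, 0.5, sd = sqrt(s2)), G, 3)
  rownames(endo) <- rownames(surf) <- sprintf("P%03d", 1:G)
  res <- moderated_t(endo, surf)

  y <- cbind(endo, surf)
  dmat <- cbind(1, rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(y, dmat))
  expect_equal(res$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(res$t_mod, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-5)
})

test_that("BH adjustment matches hand-computed and brute-force values", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(adjust_bh(c(0.5, 1.2)), class = "ep_validation_error")
  set.seed(131)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- adjust_bh(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
  }
})

test_that("compartment calls combine significance and fold-change sign", {
  res <- data.frame(protein_id = c("a", "b", "c"),
                    log2fc = c(2, -2, 1.5),
                    p = c(0.0001, 0.0001, 0.5))
  out <- call_compartments(res, alpha = 0.05, adjust = "none")
  expect_equal(out$call, c("SURF_ENRICHED", "ENDO_ENRICHED", "NOT_SIGNIFICANT"))
  expect_true(all(out$p_adj >= out$p - 1e-15))
})

test_that("planted two-fold effects are detected with high sensitivity and specificity", {
  set.seed(141)
  G <- 2000
  truth <- sample(c("ENDO", "SURF", "NULL"), G, replace = TRUE,
                  prob = c(0.3, 0.3, 0.4))
  fc <- ifelse(truth == "SURF", 1, ifelse(truth == "ENDO", -1, 0))
  endo <- matrix(rnorm(G * 3, 0, 0.25), G, 3,
                 dimnames = list(sprintf("P%04d", 1:G), NULL))
  surf <- matrix(rnorm(G * 3, fc, 0.25), G, 3,
                 dimnames = list(sprintf("P%04d", 1:G), NULL))
  res <- call_compartments(moderated_t(endo, surf), alpha = 0.05)
  want <- ifelse(truth == "SURF", "SURF_ENRICHED",
          ifelse(truth == "ENDO", "ENDO_ENRICHED", "NOT_SIGNIFICANT"))
  pos <- truth != "NULL"
  expect_gte(mean(res$call[pos] == want[pos]), 0.9)
  expect_gte(mean(res$call[!pos] == "NOT_SIGNIFICANT"), 0.9)
})
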