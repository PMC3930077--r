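test_that("log-scale conversion recovers theta and se from ratio intervals", {
  le <- to_log_effect(effect_estimate("OR", 1.88, 1.65, 2.15))
  # independent arithmetic: (ln 2.15 - ln 1.65) / (2 * 1.959964)
  expect_equal(le$theta, log(1.88), tolerance = 1e-12)
  expect_equal(le$se, (log(2.15) - log(1.65)) / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(le$theta, 0.6313, tolerance = 1e-4)
  expect_equal(le$se, 0.0675, tolerance = 1e-3)

  # symmetric interval round-trips exactly
  s <- 0.37
  z <- qnorm(0.975)
  le2 <- to_log_effect(effect_estimate("OR", 1.0, exp(-z * s), exp(z * s)))
  expect_equal(le2$theta, 0, tolerance = 1e-12)
  expect_equal(le2$se, s, tolerance = 1e-12)

  # SMD converts on the identity scale
  le3 <- to_log_effect(effect_estimate("SMD", 0.5, 0.1, 0.9))
  expect_equal(le3$theta, 0.5)
  expect_equal(le3$se, 0.8 / (2 * qnorm(0.975)), tolerance = 1e-12)
  expect_equal(le3$se, 0.20408, tolerance = 1e-4)

  expect_error(to_log_effect(effect_estimate("OR", 1.5), "study-x"),
               "cannot derive precision.*study-x")
})

test_that("fixed-effect pooling matches the brute-force oracle on small grids", {
  # identical effects: no variation at all
  p0 <- pool_fixed(list(log_effect(0.5, 0.1), log_effect(0.5, 0.1)))
  expect_equal(p0$Q, 0)
  expect_equal(p0$i_squared, 0)
  expect_equal(p0$theta_hat, 0.5)

  # frozen worked case: equal weights 100, symmetric deviations 0.4
  p <- pool_fixed(list(log_effect(0.2, 0.1), log_effect(1.0, 0.1)))
  expect_equal(p$Q, 32, tolerance = 1e-12)
  expect_equal(p$i_squared, 96.875, tolerance = 1e-12)

  # systematic grids, k = 2..6
  for (k in 2:6) {
    for (rep_i in 1:5) {
      thetas <- seq(-1, 1, length.out = k) * rep_i / 3
      ses <- 0.05 + (seq_len(k) %% 3) * 0.07
      p <- pool_fixed(Map(log_effect, thetas, ses))
      o <- bf_fixed(thetas, ses)
      expect_equal(p$theta_hat, o$theta_hat, tolerance = 1e-10)
      expect_equal(p$Q, o$Q, tolerance = 1e-10)
      expect_equal(p$i_squared, o$i_squared, tolerance = 1e-10)
      expect_equal(p$df, k - 1)
      expect_gte(p$i_squared, 0)
      expect_lt(p$i_squared, 100)
    }
  }
})

test_that("pooling is invariant under permutation of the input order", {
  effs <- Map(log_effect, c(0.1, 0.4, -0.2, 0.8), c(0.1, 0.2, 0.15, 0.3))
  p1 <- pool_fixed(effs)
  p2 <- pool_fixed(rev(effs))
  for (f in c("theta_hat", "se_hat", "Q", "i_squared", "p_heterogeneity"))
    expect_equal(p1[[f]], p2[[f]], tolerance = 1e-14)
  r1 <- pool_random(effs)
  r2 <- pool_random(effs[c(3, 1, 4, 2)])
  expect_equal(r1$theta_hat, r2$theta_hat, tolerance = 1e-14)
  expect_equal(r1$tau_squared, r2$tau_squared, tolerance = 1e-14)
})

test_that("DerSimonian-Laird tau-squared follows its closed form and floors at zero", {
  p <- pool_random(list(log_effect(0.2, 0.1), log_effect(1.0, 0.1)))
  # (Q - df) / (sum w - sum w^2 / sum w) = (32 - 1) / (200 - 100)
  expect_equal(p$tau_squared, 0.31, tolerance = 1e-12)
  expect_equal(p$tau_squared,
               bf_dl_tau2(c(0.2, 1.0), c(0.1, 0.1)), tolerance = 1e-12)

  # homogeneous inputs: tau^2 = 0 and random equals fixed
  effs <- Map(log_effect, c(0.50, 0.52, 0.49), c(0.3, 0.3, 0.3))
  pr <- pool_random(effs)
  pf <- pool_fixed(effs)
  expect_equal(pr$tau_squared, 0)
  expect_equal(pr$theta_hat, pf$theta_hat, tolerance = 1e-14)
  expect_equal(pr$se_hat, pf$se_hat, tolerance = 1e-14)
})

test_that("pooling agrees with an independent meta-analysis implementation", {
  skip_if_not_installed("metafor")
  thetas <- c(0.12, 0.55, -0.08, 0.91, 0.30)
  ses <- c(0.11, 0.23, 0.17, 0.31, 0.09)
  effs <- Map(log_effect, thetas, ses)
  fe <- pool_fixed(effs)
  re <- pool_random(effs)
  m_fe <- metafor::rma(yi = thetas, sei = ses, method = "FE")
  m_re <- metafor::rma(yi = thetas, sei = ses, method = "DL")
  expect_equal(fe$theta_hat, as.numeric(m_fe$beta), tolerance = 1e-8)
  expect_equal(fe$Q, m_fe$QE, tolerance = 1e-8)
  expect_equal(re$theta_hat, as.numeric(m_re$beta), tolerance = 1e-8)
  expect_equal(re$tau_squared, m_re$tau2, tolerance = 1e-8)
  expect_equal(re$se_hat, m_re$se, tolerance = 1e-8)
})

test_that("pooling fewer than two effects signals that inconsistency is not assessable", {
  expect_error(pool_fixed(list(log_effect(0.5, 0.1))), "not assessable")
  expect_error(pool_random(list()), "not assessable")
})

test_that("scale equivariance: rescaling every OR shifts theta_hat and leaves heterogeneity unchanged", {
  ors <- c(1.3, 2.1, 0.8, 1.7)
  los <- ors * c(0.7, 0.8, 0.6, 0.75)
  his <- ors * c(1.5, 1.4, 1.6, 1.45)
  mk <- function(f) Map(function(o, l, h)
    to_log_effect(effect_estimate("OR", o * f, l * f, h * f)), ors, los, his)
  p1 <- pool_random(mk(1))
  p2 <- pool_random(mk(2.5))
  expect_equal(p2$theta_hat - p1$theta_hat, log(2.5), tolerance = 1e-10)
  expect_equal(p2$Q, p1$Q, tolerance = 1e-10)
  expect_equal(p2$i_squared, p1$i_squared, tolerance = 1e-10)
  expect_equal(p2$tau_squared, p1$tau_squared, tolerance = 1e-10)
})

test_that("pairwise interval overlap is measured against the shorter interval", {
  mk <- function(lo, hi) log_effect((lo + hi) / 2, (hi - lo) / (2 * qnorm(0.975)))
  # identical intervals overlap fully
  r <- ci_overlap_profile(list(mk(0, 1), mk(0, 1)))
  expect_equal(r$min_pairwise_overlap_fraction, 1.0)
  expect_false(r$any_disjoint)
  # disjoint intervals
  r <- ci_overlap_profile(list(mk(0, 1), mk(2, 3)))
  expect_equal(r$min_pairwise_overlap_fraction, 0.0)
  expect_true(r$any_disjoint)
  # intersection (1,2) against shorter length 2
  r <- ci_overlap_profile(list(mk(0, 2), mk(1, 5)))
  expect_equal(r$min_pairwise_overlap_fraction, 0.5, tolerance = 1e-12)
  expect_false(r$any_disjoint)
})

test_that("direction split classifies point estimates against the null", {
  split1 <- effect_direction_split(list(log_effect(0.6, 1), log_effect(0.2, 1)))
  expect_equal(split1$n_risk, 2)
  expect_false(split1$straddles_null)
  split2 <- effect_direction_split(list(log_effect(0.6, 1), log_effect(-0.2, 1)))
  expect_true(split2$straddles_null)
  split3 <- effect_direction_split(list(log_effect(0, 1)))
  expect_equal(split3$n_null_or_unknown, 1)
  expect_false(split3$straddles_null)
})

test_that("gradient detection requires strict monotonicity over at least three doses", {
  g <- detect_gradient(c(1, 3, 5), c(1.2, 1.7, 2.1))
  expect_true(g$gradient)
  expect_equal(g$direction, "increasing")
  # a tie breaks the gradient at the default tolerance
  expect_false(detect_gradient(c(1, 3, 5), c(1.2, 1.2, 2.1))$gradient)
  # mirrored series: decreasing gradient
  g2 <- detect_gradient(c(1, 3, 5), c(2.1, 1.7, 1.2))
  expect_true(g2$gradient)
  expect_equal(g2$direction, "decreasing")
  # fewer than three levels is not assessable
  g3 <- detect_gradient(c(1, 3), c(1.2, 1.7))
  expect_false(g3$applicable)
  expect_error(detect_gradient(c(1, 1, 2), c(1, 2, 3)), "strictly increasing")
})

test_that("2x2 odds ratios use the Woolf interval with continuity correction", {
  e <- odds_ratio_from_counts(10, 10, 10, 10)
  expect_equal(e$point, 1.0)
  e2 <- odds_ratio_from_counts(20, 10, 10, 20)
  expect_equal(e2$point, 4.0)
  se <- sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20)
  expect_equal(e2$ci_low, exp(log(4) - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(e2$ci_high, exp(log(4) + qnorm(0.975) * se), tolerance = 1e-12)
  # any zero cell adds 0.5 to every cell
  e3 <- odds_ratio_from_counts(5, 0, 10, 10)
  expect_equal(e3$point, (5.5 * 10.5) / (0.5 * 10.5), tolerance = 1e-12)
  expect_equal(e3$point, 11.0)
  # entirely empty row or column leaves the OR undefined
  expect_error(odds_ratio_from_counts(0, 0, 10, 10), "undefined")
  expect_error(odds_ratio_from_counts(5, 0, 10, 0), "undefined")
})

test_that("2x2 odds ratios agree with an independent escalc computation", {
  skip_if_not_installed("metafor")
  es <- metafor::escalc(measure = "OR", ai = 20, bi = 10, ci = 10, di = 20)
  e <- odds_ratio_from_counts(20, 10, 10, 20)
  expect_equal(log(e$point), as.numeric(es$yi), tolerance = 1e-10)
  expect_equal(to_log_effect(e)$se, sqrt(as.numeric(es$vi)), tolerance = 1e-10)
})

test_that("the heterogeneity test holds its type-I error rate under homogeneity", {
  set.seed(4242)
  k <- 10
  rejections <- 0L
  n_rep <- 500
  for (r in seq_len(n_rep)) {
    thetas <- rnorm(k, 0, 0.1)         # tau = 0: all variation is sampling error
    p <- pool_fixed(Map(log_effect, thetas, rep(0.1, k)))
    if (p$p_heterogeneity < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.08)
})
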