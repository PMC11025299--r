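test_that("latent correlation matching: closed forms and feasibility", {
  expect_identical(binary_to_normal_correlation(0.3, 0.6, 0), 0)
  # p1 = p2 = 0.5: orthant closed form P11 = 1/4 + asin(r)/(2 pi)
  expect_equal(binary_to_normal_correlation(0.5, 0.5, 0.5), sin(pi / 4),
               tolerance = 1e-6)
  expect_equal(binary_to_normal_correlation(0.5, 0.5, 1), 1)
  expect_equal(binary_to_normal_correlation(0.8, 0.8, 1), 1)
  # unequal marginals cannot reach correlation 1
  expect_error(binary_to_normal_correlation(0.3, 0.7, 0.9), "attainable")

  # round trip through the rectangle probability at mixed marginals
  r <- binary_to_normal_correlation(0.7, 0.4, 0.35)
  p11 <- copritest:::bvn_prob(qnorm(0.7), qnorm(0.4), r)
  expect_equal((p11 - 0.28) / sqrt(0.21 * 0.24), 0.35, tolerance = 1e-6)
})

test_that("LFC generator recovers means and correlations", {
  cfg <- lfc_config(m = 4, se0 = 0.8, sp0 = 0.8, n1 = 1e5, n0 = 1e5,
                    rho_se = 0.5, rho_sp = 0.5)
  sim <- generate_lfc_data(cfg, seed = 42)
  qq <- copritest:::correctness(sim$data)

  # degenerate parameters: constant columns, empirical accuracy exactly 1
  expect_true(all(qq$Q1[, cfg$b == 0] == 1))
  expect_true(all(qq$Q0[, cfg$b == 1] == 1))

  # boundary parameters: means within 3 binomial SEs of 0.8
  tol <- 3 * sqrt(0.8 * 0.2 / 1e5)
  expect_lt(max(abs(colMeans(qq$Q1[, cfg$b == 1]) - 0.8)), tol)
  expect_lt(max(abs(colMeans(qq$Q0[, cfg$b == 0]) - 0.8)), tol)

  # pairwise binary correlation of non-degenerate columns near 0.5
  c_se <- cor(qq$Q1[, cfg$b == 1])
  expect_lt(max(abs(c_se[upper.tri(c_se)] - 0.5)), 0.01)

  # every test is a true null at an LFC
  expect_true(all(sim$truth$null))

  # rho = 0: independent columns
  cfg0 <- lfc_config(m = 4, se0 = 0.8, sp0 = 0.8, n1 = 1e5, n0 = 100,
                     rho_se = 0, rho_sp = 0)
  q0 <- copritest:::correctness(generate_lfc_data(cfg0, seed = 7)$data)
  c0 <- cor(q0$Q1[, cfg0$b == 1])
  expect_lt(max(abs(c0[upper.tri(c0)])), 0.02)
})

test_that("binormal model: AUC mapping and true accuracies", {
  expect_identical(auc_to_mean(0.5), 0)
  expect_equal(auc_to_mean(0.8), 1.19023, tolerance = 1e-5)
  # inverse identity
  for (a in c(0.55, 0.7, 0.9, 0.99)) {
    expect_equal(pnorm(auc_to_mean(a) / sqrt(2)), a, tolerance = 1e-12)
  }

  cfg <- biomarker_config(l = 1, auc = 0.8,
                          cutpoints = data.frame(marker = 1, cut = 0),
                          n1 = 50, n0 = 50, se0 = 0.8, sp0 = 0.8)
  tr <- true_accuracy_biomarker(cfg)
  expect_equal(tr$se_true, 0.8830, tolerance = 1e-4)
  expect_identical(tr$sp_true, 0.5)

  # se decreasing, sp increasing in the cut point
  cuts <- seq(-2, 2, by = 0.5)
  cfg2 <- biomarker_config(l = 1, auc = 0.8,
                           cutpoints = data.frame(marker = 1, cut = cuts),
                           n1 = 10, n0 = 10, se0 = 0.8, sp0 = 0.8)
  tr2 <- true_accuracy_biomarker(cfg2)
  expect_true(all(diff(tr2$se_true) < 0))
  expect_true(all(diff(tr2$sp_true) > 0))
})

test_that("biomarker generator converges to the truth table", {
  cfg <- biomarker_config(l = 1, auc = 0.8,
                          cutpoints = data.frame(marker = 1, cut = 0),
                          n1 = 1e5, n0 = 1e5, se0 = 0.8, sp0 = 0.8)
  sim <- generate_biomarker_data(cfg, seed = 11)
  est <- estimate_accuracy(sim$data, shrinkage = 0)
  expect_equal(est$se_hat, 0.8830, tolerance = 0.01)
  expect_equal(est$sp_hat, 0.5, tolerance = 0.01)

  # two cut points on one marker: lower cut -> superset of positives
  cfg2 <- biomarker_config(l = 1, auc = 0.8,
                           cutpoints = data.frame(marker = 1, cut = c(-0.5, 0.7)),
                           n1 = 500, n0 = 500, se0 = 0.8, sp0 = 0.8)
  d2 <- generate_biomarker_data(cfg2, seed = 3)$data
  expect_true(all(d2$tests[, 1] >= d2$tests[, 2]))

  # nearby cut points correlate more strongly than distant ones
  cfg3 <- biomarker_config(l = 1, auc = 0.8,
                           cutpoints = data.frame(marker = 1,
                                                  cut = c(0, 0.1, 1.5)),
                           n1 = 2e4, n0 = 2e4, se0 = 0.8, sp0 = 0.8)
  d3 <- generate_biomarker_data(cfg3, seed = 4)$data
  cc <- cor(d3$tests)
  expect_gt(cc[1, 2], cc[1, 3])

  # independent markers give uncorrelated tests within each subgroup
  # (pooling the subgroups would induce correlation through disease status)
  cfg4 <- biomarker_config(l = 2, auc = 0.8, marker_correlation = 0,
                           cutpoints = data.frame(marker = 1:2, cut = 0),
                           n1 = 5e4, n0 = 5e4, se0 = 0.8, sp0 = 0.8)
  d4 <- generate_biomarker_data(cfg4, seed = 5)$data
  expect_lt(abs(cor(d4$tests[d4$disease == 0, ])[1, 2]), 0.02)
  expect_lt(abs(cor(d4$tests[d4$disease == 1, ])[1, 2]), 0.02)
})

test_that("pooled mixture quantiles invert the pooled CDF", {
  qs <- pooled_marker_quantiles(0.85, 0.25, c(0.3, 0.5, 0.7))
  mu <- auc_to_mean(0.85)
  cdf <- 0.25 * pnorm(qs - mu) + 0.75 * pnorm(qs)
  expect_equal(cdf, c(0.3, 0.5, 0.7), tolerance = 1e-8)
  expect_true(all(diff(qs) > 0))
})
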