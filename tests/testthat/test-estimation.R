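# effect sizes, bootstrap CIs, permutation tests, power, regression

test_that("Glass delta matches its definition and hand-computed oracle", {
  expect_equal(glass_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  ctrl <- c(0, 0, 1, 1); exp_ <- c(1, 1, 2, 2)
  expect_equal(glass_delta(exp_, ctrl), 1 / sd(c(0, 0, 1, 1)))
  # shifting by k control SDs gives exactly k
  k <- 2.5
  expect_equal(glass_delta(ctrl + k * sd(ctrl), ctrl), k)
  expect_error(glass_delta(exp_, c(1, 1, 1)), "zero control SD")
})

test_that("Cohen's d matches closed forms, unpaired and paired", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # equal variance, gap of one pooled SD -> d = 1
  a <- c(-1, 0, 1); b <- a + sd(a)
  expect_equal(cohens_d(b, a), 1)
  # paired: constant shift c over difference SD s
  before <- c(1, 3, 2, 5, 4)
  noise <- c(0.3, -0.1, 0.2, -0.4, 0)
  after <- before + 2 + noise
  expect_equal(cohens_d(after, before, paired = TRUE), mean(2 + noise) / sd(noise))
  expect_error(cohens_d(c(1, 1), c(2, 2), paired = TRUE), "zero")
})

test_that("effect sizes are invariant under common affine rescaling", {
  set.seed(4)
  a <- rnorm(20, 1); b <- rnorm(20)
  for (tf in list(function(x) 3 * x + 7, function(x) -2 * x + 1)) {
    expect_equal(abs(glass_delta(tf(a), tf(b))), abs(glass_delta(a, b)))
    expect_equal(abs(cohens_d(tf(a), tf(b))), abs(cohens_d(a, b)))
  }
})

test_that("magnitude bands follow the 0.2/0.5/0.8 cuts", {
  expect_equal(magnitude_band(c(0.1, -0.3, 0.65, 1.2, 0.2)),
               c("negligible", "small", "moderate", "large", "small"))
})

test_that("BCa interval brackets the estimate, degenerates sensibly, matches percentile for symmetric data", {
  x <- rep(3, 10)
  expect_warning(ci <- bca_ci(x, n_boot = 1000, seed = 1), "degenerate")
  expect_equal(as.numeric(ci), c(3, 3))
  set.seed(2)
  y <- rnorm(60)
  ci <- bca_ci(y, n_boot = 10000, seed = 3)
  expect_lte(ci[1], mean(y)); expect_gte(ci[2], mean(y))
  # symmetric sample: BCa close to the plain percentile interval
  pci <- with(list(), {
    set.seed(3)
    boots <- replicate(10000, mean(sample(y, replace = TRUE)))
    quantile(boots, c(0.025, 0.975), names = FALSE)
  })
  expect_lt(abs((ci[2] - ci[1]) - (pci[2] - pci[1])) / (pci[2] - pci[1]), 0.1)
  expect_error(bca_ci(1:3), "n >= 5")
})

test_that("BCa agrees with the boot package on a skewed fixture", {
  skip_if_not_installed("boot")
  set.seed(9)
  x <- rexp(40)
  ci <- bca_ci(x, n_boot = 20000, seed = 10)
  set.seed(10)
  b <- boot::boot(x, function(d, i) mean(d[i]), R = 20000)
  bci <- boot::boot.ci(b, type = "bca")$bca[4:5]
  expect_equal(as.numeric(ci), bci, tolerance = 0.03)
})

test_that("permutation p is exact on enumerable cases and includes the identity", {
  expect_equal(as.numeric(permutation_test(c(1, 2, 3), c(1, 2, 3))), 1)
  p <- permutation_test(c(1, 2), c(3, 4))
  expect_true(attr(p, "exact"))
  expect_equal(as.numeric(p), 2 / 6)
  # paired constant positive shift, n = 12: only the two all-same-sign
  # flips reach the observed |mean|
  b4 <- seq(1, 12); af <- b4 + 1
  p2 <- permutation_test(af, b4, paired = TRUE)
  expect_true(attr(p2, "exact"))
  expect_equal(as.numeric(p2), 2 / 4096)
  expect_error(permutation_test(numeric(0), 1:3), "empty")
})

test_that("sampled permutation p tracks exact enumeration on small groups", {
  set.seed(5)
  for (sizes in list(c(4, 4), c(6, 5), c(8, 8))) {
    a <- rnorm(sizes[1], 0.8); b <- rnorm(sizes[2])
    pe <- permutation_test(a, b, exact = TRUE)
    ps <- permutation_test(a, b, exact = FALSE, n_perm = 50000, seed = 6)
    expect_lt(abs(as.numeric(pe) - as.numeric(ps)), 0.01)
  }
  d <- rnorm(10, 0.5)
  pe <- permutation_test(d, rep(0, 10), paired = TRUE, exact = TRUE)
  ps <- permutation_test(d, rep(0, 10), paired = TRUE, exact = FALSE,
                         n_perm = 50000, seed = 7)
  expect_lt(abs(as.numeric(pe) - as.numeric(ps)), 0.01)
})

test_that("permutation test holds its type-I error near alpha", {
  set.seed(8)
  rej <- 0; reps <- 400
  for (i in seq_len(reps)) {
    p <- permutation_test(rnorm(12), rnorm(12), n_perm = 1000, seed = i,
                          exact = FALSE)
    rej <- rej + (p <= 0.05)
  }
  expect_gt(rej / reps, 0.02)
  expect_lt(rej / reps, 0.09)
})

test_that("analytic power matches stats::power.t.test and the null gives alpha", {
  expect_equal(power_ttest(45, 0, 0.05), 0.05)
  # power.t.test drops the far-tail rejection mass, so agreement is to ~1e-3
  for (cfg in list(c(45, 0.6), c(20, 0.5), c(100, 0.3)))
    expect_equal(power_ttest(cfg[1], cfg[2], 0.05),
                 stats::power.t.test(n = cfg[1], delta = cfg[2])$power,
                 tolerance = 1e-3)
  expect_gt(power_ttest(45, 0.6, 0.05), 0.8)
})

test_that("delta regression reproduces hand OLS and flags degenerate x", {
  x <- 1:8; y <- 2 * x + 1
  r <- delta_regression(x, y)
  expect_equal(r$slope, 2)
  expect_equal(r$r2_adj, 1.0)
  r2 <- delta_regression(c(0, 1, 2), c(0, 1, 0))
  expect_equal(r2$slope, 0)
  expect_equal(r2$r2_adj, -1)
  expect_error(delta_regression(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(delta_regression(1:2, 1:2), "at least 3")
})

test_that("slope p-values are uniform under the null", {
  set.seed(11)
  ps <- replicate(500, delta_regression(rnorm(8), rnorm(8))$p_slope)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("effect matrices key by intervention and parameter with p < 0.05 marks", {
  df <- data.frame(intervention = rep(c("A", "B", "C"), each = 4),
                   parameter = rep(c("w", "x", "y", "z"), 3),
                   d = seq(-0.6, 0.5, length.out = 12),
                   p = rep(c(0.049, 0.051, 0.2, 0.001), 3))
  em <- effect_matrix(df)
  expect_equal(dim(em$d), c(3, 4))
  expect_equal(unname(em$stars[1, ]), c(TRUE, FALSE, FALSE, TRUE))
  expect_error(effect_matrix(rbind(df, df[1, ])), "duplicate")
  single <- effect_matrix(data.frame(intervention = "A", parameter = "x",
                                     d = 0.3, p = 0.2))
  expect_equal(dim(single$d), c(1, 1))
  expect_false(any(single$stars))
})

test_that("effect_contrast bundles a coherent estimation result", {
  set.seed(12)
  ctrl <- rnorm(30); trt <- rnorm(30, 0.9)
  r <- effect_contrast(trt, ctrl, label = "trt:ratio", seed = 5)
  expect_s3_class(r, "effect_result")
  expect_lte(r$ci95[1], r$mean_difference)
  expect_gte(r$ci95[2], r$mean_difference)
  expect_true(r$p_permutation > 0 && r$p_permutation <= 1)
  expect_equal(r$magnitude_band, magnitude_band(r$cohens_d))
  # deterministic given the seed
  r2 <- effect_contrast(trt, ctrl, label = "trt:ratio", seed = 5)
  expect_identical(r$ci95, r2$ci95)
  expect_identical(r$p_permutation, r2$p_permutation)
})

test_that("tiered significance stars follow the 0.05/0.01/0.001 convention", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 0.0005)),
               c("", "*", "**", "***"))
})
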