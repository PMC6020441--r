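test_that("double-arcsine transform matches its closed form at the boundaries", {
  ft0 <- ft_transform(0, 10)
  expect_equal(ft0$y, asin(sqrt(1 / 11)))
  expect_equal(ft0$v, 1 / 10.5)
  ftn <- ft_transform(10, 10)
  expect_equal(ftn$y, asin(sqrt(10 / 11)) + pi / 2)
  # fractional weighted count, direct evaluation
  ftw <- ft_transform(5.62, 66)
  expect_equal(ftw$y, asin(sqrt(5.62 / 67)) + asin(sqrt(6.62 / 67)))
  expect_error(ft_transform(-1, 10))
  expect_error(ft_transform(11, 10))
})

test_that("transform agrees with the metafor parameterization at integer counts", {
  skip_if_not_installed("metafor")
  es <- metafor::escalc(measure = "PFT", xi = c(3, 12, 0), ni = c(40, 130, 25))
  ft <- ft_transform(c(3, 12, 0), c(40, 130, 25))
  # metafor works on the halved transform: yi = y/2, vi = v/4
  expect_equal(as.numeric(es$yi), ft$y / 2, tolerance = 1e-12)
  expect_equal(as.numeric(es$vi), ft$v / 4, tolerance = 1e-12)
})

test_that("DerSimonian-Laird pooling matches the hand-computed oracle", {
  # 3-study instance worked through the moment equations step by step:
  # w = (100, 50, 25); fixed-effect mean 65/175; Q = 8.35714...;
  # C = 175 - (100^2+50^2+25^2)/175 = 100; tau2 = (Q - 2)/100
  pooled <- pool_random_effects(c(0.2, 0.5, 0.8), c(0.01, 0.02, 0.04))
  expect_equal(pooled$Q, 8.3571428571, tolerance = 1e-9)
  expect_equal(pooled$tau2, 0.0635714286, tolerance = 1e-9)
  expect_equal(pooled$pooled_y, 0.4664581011, tolerance = 1e-9)
  expect_equal(pooled$se, 0.1685183298, tolerance = 1e-9)
})

test_that("DerSimonian-Laird pooling agrees with metafor on random instances", {
  skip_if_not_installed("metafor")
  set.seed(11)
  for (i in 1:10) {
    k <- sample(2:8, 1)
    y <- rnorm(k); v <- runif(k, 0.005, 0.05)
    ours <- pool_random_effects(y, v)
    ref <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(ours$pooled_y, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(ours$se, ref$se, tolerance = 1e-10)
    expect_equal(ours$Q, ref$QE, tolerance = 1e-10)
  }
})

test_that("single-study and homogeneous-study identities hold exactly", {
  one <- pool_random_effects(0.5, 0.01)
  expect_equal(one$pooled_y, 0.5)
  expect_equal(one$se, 0.1)
  expect_equal(one$tau2, 0)

  same <- pool_random_effects(rep(0.4, 5), rep(0.02, 5))
  expect_equal(same$pooled_y, 0.4)
  expect_equal(same$Q, 0)
  expect_equal(same$tau2, 0)

  # equal variances, tau2 = 0: pooled value is the arithmetic mean
  y <- c(0.30, 0.31, 0.32)
  eq <- pool_random_effects(y, rep(0.5, 3))  # large v => Q < df => tau2 = 0
  expect_equal(eq$tau2, 0)
  expect_equal(eq$pooled_y, mean(y))
  expect_error(pool_random_effects(numeric(0), numeric(0)), "study")
})

test_that("Miller back-transform inverts the transform on a proportion grid", {
  for (p in seq(0.05, 0.95, by = 0.05)) {
    for (n in c(50, 120, 500)) {
      ft <- ft_transform(p * n, n)
      bt <- ft_back_transform(ft$y, sqrt(ft$v), n)
      expect_equal(bt$percent / 100, p, tolerance = 1e-3)
    }
  }
  # boundary clamps
  expect_equal(ft_back_transform(0, 0.01, 100)$percent, 0)
  expect_equal(ft_back_transform(pi, 0.01, 100)$percent, 100)
  expect_error(ft_back_transform(0.5, 0.1, numeric(0)), "n_list")
})

test_that("harmonic-mean back-transform matches metafor's transf.ipft.hm", {
  skip_if_not_installed("metafor")
  ns <- c(66, 147, 61)
  for (t in c(0.3, 0.6, 1.0)) {
    ours <- ft_back_transform(t, 0.05, ns)$percent / 100
    ref <- metafor::transf.ipft.hm(t / 2, targs = list(ni = ns))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("pooling of homogeneous proportions recovers the common value", {
  studies <- data.frame(study_id = 1:4, x = c(8, 12, 4.8, 16),
                        n = c(100, 150, 60, 200))  # all x/n = 0.08
  m <- meta_proportion(studies)
  expect_equal(m$pooled_percent, 8.0, tolerance = 0.1)
  expect_lte(m$ci_low, m$pooled_percent)
  expect_gte(m$ci_high, m$pooled_percent)

  # zero-carrier studies enter without continuity corrections
  with_zero <- data.frame(study_id = 1:3, x = c(0, 5, 3), n = c(80, 100, 60))
  m0 <- meta_proportion(with_zero)
  expect_true(is.finite(m0$pooled_percent))
  expect_gte(m0$pooled_percent, 0)
})

test_that("pooled estimate is permutation-invariant and within study range when tau2=0", {
  studies <- data.frame(study_id = 1:4, x = c(3, 9, 6, 12),
                        n = c(66, 147, 61, 154))
  m1 <- meta_proportion(studies)
  m2 <- meta_proportion(studies[sample(4), ])
  expect_equal(m1$pooled_percent, m2$pooled_percent)
  expect_equal(m1$tau2, m2$tau2)
  if (m1$tau2 == 0) {
    props <- 100 * studies$x / studies$n
    expect_gte(m1$pooled_percent, min(props) - 0.5)
    expect_lte(m1$pooled_percent, max(props) + 0.5)
  }
  # I2 consistency with Q
  expect_equal(m1$I2, max(0, 100 * (m1$Q - 3) / m1$Q))
})

test_that("pooled proportion recovers the truth in simulation", {
  set.seed(99)
  x <- rbinom(20, 150, 0.10)
  m <- meta_proportion(data.frame(study_id = 1:20, x = x, n = rep(150, 20)))
  # 3 Monte-Carlo standard errors of the mean of 20 binomial proportions
  mc_se <- sqrt(0.10 * 0.90 / 150) / sqrt(20)
  expect_equal(m$pooled_percent / 100, 0.10, tolerance = 3 * mc_se / 0.10)
  expect_lt(m$p_value, 1e-6)  # clearly nonzero proportion
})

test_that("forest table carries per-study rows plus a pooled row", {
  studies <- data.frame(study_id = c("a", "b"), x = c(5.62, 11.17),
                        n = c(66, 147))
  ft <- forest_table(studies, group_name = "ALL")
  expect_equal(nrow(ft), 3L)
  expect_equal(ft$study_id, c("a", "b", "POOLED"))
  expect_equal(ft$percent[1], weighted_frequency(5.62, 66))
  expect_false(is.na(ft$tau2[3]))
})
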