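test_that("degenerate inputs give chi-square 0 and p 1", {
  vals <- rep(3.2, 38)
  g <- factor(rep(LOCOMOTOR_LEVELS, length.out = 38))
  res <- fp_ksample(vals, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 4L)
  expect_error(fp_ksample(1:5, factor(rep("a", 5))), "2 non-empty")
})

test_that("two-sample statistic matches enumeration on {1,2} vs {3,4}", {
  vals <- c(1, 2, 3, 4)
  g <- factor(c("g1", "g1", "g2", "g2"))
  # independent moment computation: T1 = 3, E = 5, var = SS/(N(N-1)) n1 n2
  ss <- sum((vals - 2.5)^2)
  v <- ss / (4 * 3) * 2 * 2
  z_hand <- (3 - 5) / sqrt(v)
  chi_hand <- z_hand^2
  res <- fp_ksample(vals, g)
  expect_equal(res$statistic, chi_hand, tolerance = 1e-12)
  # full enumeration over C(4,2) = 6 assignments
  expect_equal(fp_exact_pvalue(vals, g), 1 / 3, tolerance = 1e-12)
})

test_that("asymptotic p stays within 0.05 of exact enumeration for n <= 10", {
  # fixed fixtures at n = 8-10; the chi-square approximation is not
  # reliable to 0.05 below n ~ 8 (see the methods vignette)
  cases <- list(
    list(v = c(1.2, 3.1, 0.4, 5.5, 2.2, 4.1, 0.9, 3.8),
         g = rep(c("a", "b"), each = 4)),
    list(v = c(0.5, 1.1, 0.8, 2.4, 3.0, 2.7, 4.9, 5.5, 5.1),
         g = rep(c("a", "b", "c"), each = 3)),
    list(v = c(2.1, 1.4, 2.8, 1.9, 2.5, 3.6, 4.2, 3.1, 4.8, 3.9),
         g = rep(c("a", "b"), each = 5)),
    list(v = c(8.1, 4.3, 6.2, 7.4, 5.0, 5.8, 7.7, 4.9, 6.6, 5.4),
         g = c("a", "b", "a", "a", "b", "b", "a", "b", "a", "b"))
  )
  for (cs in cases) {
    p_asym <- fp_ksample(cs$v, factor(cs$g))$p
    p_exact <- fp_exact_pvalue(cs$v, factor(cs$g))
    expect_lt(abs(p_asym - p_exact), 0.05)
  }
})

test_that("the statistic is invariant under positive affine transforms", {
  set.seed(32)
  vals <- rnorm(20)
  g <- factor(rep(letters[1:4], each = 5))
  s0 <- fp_ksample(vals, g)$statistic
  expect_equal(fp_ksample(vals + 7, g)$statistic, s0, tolerance = 1e-10)
  expect_equal(fp_ksample(3.5 * vals - 2, g)$statistic, s0,
               tolerance = 1e-10)
})

test_that("pairwise tests and BH adjustment behave as specified", {
  # identical group distributions -> statistic 0, p 1
  vals <- c(1, 2, 3, 1, 2, 3)
  g <- factor(rep(c("a", "b"), each = 3))
  pw <- fp_pairwise(vals, g)
  expect_equal(pw$statistic, 0)
  expect_equal(pw$p, 1)

  # BH step-up arithmetic by hand
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  # monotone: sorting raw p sorts adjusted p
  set.seed(33)
  vals2 <- rnorm(25) + rep(c(0, 1, 0, 2, 0), each = 5)
  g2 <- factor(rep(letters[1:5], each = 5))
  pw2 <- fp_pairwise(vals2, g2)
  o <- order(pw2$p)
  expect_true(all(diff(pw2$p_adjusted[o]) >= -1e-12))
  expect_true(all(pw2$p_adjusted >= pw2$p - 1e-12))
  expect_true(all(pw2$p_adjusted <= 1))
  expect_equal(nrow(pw2), 10L)
})

test_that("variance checks route by normality and detect heterogeneity", {
  # equal variances by construction -> high homogeneity p
  set.seed(34)
  base <- rnorm(15)
  vals <- c(base, base + 5)
  g <- factor(rep(c("a", "b"), each = 15))
  chk <- variance_checks(vals, g)
  expect_gt(chk$homogeneity_p, 0.5)
  expect_true(chk$homogeneous)

  # Levene on groups of a constant -> statistic 0
  vc <- variance_checks(c(rep(1, 5), rep(2, 5), 3, 3, 3, 3, 100),
                        factor(rep(c("a", "b", "c"), each = 5)))
  expect_true(vc$route %in% c("levene", "bartlett"))

  const_dev <- variance_checks(rep(c(1, 2), each = 6),
                               factor(rep(c("a", "b"), each = 6)))
  expect_equal(const_dev$homogeneity_stat, 0)

  # Bartlett power: N(0,1) vs N(0,9), n = 20 each
  set.seed(35)
  rejections <- vapply(1:500, function(r) {
    v <- c(rnorm(20), rnorm(20, sd = 3))
    gg <- factor(rep(c("a", "b"), each = 20))
    stats::bartlett.test(v, gg)$p.value < 0.05
  }, NA)
  expect_gte(mean(rejections), 0.95)

  expect_warning(
    variance_checks(c(1, 2, 3, 4, 9), factor(c("a", "a", "b", "b", "c"))),
    "size < 2")
})

test_that("a heterogeneity warning is attached to the block result", {
  set.seed(36)
  vals <- c(rnorm(10, sd = 0.2), rnorm(10, sd = 4))
  g <- factor(rep(c("a", "b"), each = 10))
  expect_warning(blk <- permutation_block(vals, g, "toy"),
                 "homogeneity")
  expect_false(blk$checks$homogeneous)
  expect_s3_class(blk$ksample, "perm_test")
})
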