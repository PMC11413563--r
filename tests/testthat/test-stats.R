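test_that("Welch t test handles degenerate and published summary inputs", {
  same <- welch_t(1.2, 0.5, 10, 1.2, 0.5, 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_equal(same$effect_size, 0)
  # thought-disorder rating row: d from printed summaries
  tli <- welch_t(0.18, 0.26, 29, 1.09, 1.12, 29)
  expect_equal(tli$effect_size, 1.120, tolerance = 0.005 / 1.120)
  expect_lt(tli$p, 0.001)
  # more observations at identical summaries: stronger evidence
  p1 <- welch_t(0, 1, 20, 0.5, 1, 20)$p
  p2 <- welch_t(0, 1, 40, 0.5, 1, 40)$p
  expect_lt(p2, p1)
  zero <- welch_t(1, 0, 5, 1, 0, 5)
  expect_true(is.na(zero$effect_size))
})

test_that("Welch p from summaries equals Welch p from matching raw samples", {
  set.seed(2)
  for (rep in 1:5) {
    m1 <- rnorm(1); s1 <- runif(1, 0.5, 2); m2 <- rnorm(1); s2 <- runif(1, 0.5, 2)
    x <- as.numeric(m1 + s1 * scale(rnorm(5)))
    y <- as.numeric(m2 + s2 * scale(rnorm(4)))
    from_sum <- welch_t(m1, s1, 5, m2, s2, 4)
    from_raw <- welch_t(x = x, y = y)
    expect_equal(from_raw$p, from_sum$p, tolerance = 1e-10)
  }
})

test_that("t and chi-square match independent implementations on random inputs", {
  set.seed(3)
  for (rep in 1:100) {
    x <- rnorm(sample(4:10, 1)); y <- rnorm(sample(4:10, 1), sd = runif(1, 0.5, 2))
    ours <- welch_t(x = x, y = y)
    ref <- t.test(x, y, var.equal = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    tab <- matrix(rpois(4, 10) + 1, 2, 2)
    ours2 <- chi2_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref2 <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours2$statistic, unname(ref2$statistic), tolerance = 1e-10)
    expect_equal(ours2$p, ref2$p.value, tolerance = 1e-10)
  }
})

test_that("chi-square handles anchors, hand values and zero margins", {
  bal <- chi2_2x2(10, 10, 10, 10)
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p, 1)
  expect_equal(bal$effect_size, 0)
  expect_equal(chi2_2x2(20, 8, 15, 14)$statistic, 2.334, tolerance = 5e-4)
  expect_error(chi2_2x2(0, 0, 5, 5), "zero margin")
})

test_that("Mann-Whitney uses exact enumeration for small untied samples", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p, 0.1)  # 2 * 1/choose(6,3)
  ident <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ident$p, 1)
  shift <- mann_whitney(c(1, 2, 3) + 100, c(4, 5, 6) + 100)
  expect_equal(shift$statistic, mw$statistic)
  expect_equal(shift$p, mw$p)
})

test_that("BH correction reproduces step-up arithmetic", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(4)
  for (rep in 1:100) {
    p <- runif(sample(2:12, 1))
    q <- bh_fdr(p)
    expect_equal(q, manual_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
  }
})

test_that("partial Spearman reduces, deconfounds and respects rank invariance", {
  set.seed(5)
  x <- rnorm(30); y <- x + rnorm(30)
  plain <- partial_spearman(x, y)
  expect_equal(plain$statistic, cor(x, y, method = "spearman"),
               tolerance = 1e-10)
  # a binary covariate fully driving both variables leaves no partial signal
  g <- rep(0:1, each = 20)
  x2 <- g + rnorm(40, sd = 0.01)
  y2 <- g + rnorm(40, sd = 0.01)
  part <- partial_spearman(x2, y2, data.frame(g = g))
  expect_lt(abs(part$statistic), 0.35)
  expect_gt(part$p, 0.01)
  # strictly monotone transforms do not change rho
  tr <- partial_spearman(exp(x), y^3 + 10 * y)
  expect_equal(tr$statistic, plain$statistic, tolerance = 1e-10)
  expect_error(partial_spearman(rep(1, 10), rnorm(10)), "constant")
})
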