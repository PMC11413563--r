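test_that("binarization keeps exactly the significantly positive edges", {
  # 4-ROI toy: pairs (1,2) and (3,4) strongly positive, the rest weak
  r <- matrix(0.01, 4, 4)
  r[1, 2] <- r[2, 1] <- 0.99
  r[3, 4] <- r[4, 3] <- 0.99
  diag(r) <- 0
  z <- atanh(r)
  dimnames(z) <- list(letters[1:4], letters[1:4])
  g <- binarize_fc(z, n_timepoints = 100)
  expected <- matrix(0, 4, 4, dimnames = dimnames(z))
  expected["a", "b"] <- expected["b", "a"] <- 1
  expected["c", "d"] <- expected["d", "c"] <- 1
  expect_equal(unclass(g), expected, ignore_attr = TRUE)
  expect_equal(attr(g, "n_edges"), 2)
  # hand check of the surviving q-values: t = r sqrt((n-2)/(1-r^2))
  t_strong <- 0.99 * sqrt(98 / (1 - 0.99^2))
  p_strong <- 2 * pt(-abs(t_strong), 98)
  expect_lt(p_strong * 6 / 2, 0.001)  # worst-case BH bound still clears q
})

test_that("null and negative correlations never produce edges", {
  z0 <- matrix(0, 5, 5)
  expect_equal(attr(binarize_fc(z0, n_timepoints = 50), "n_edges"), 0)
  zneg <- matrix(0, 4, 4)
  zneg[1, 2] <- zneg[2, 1] <- atanh(-0.99)
  expect_equal(attr(binarize_fc(zneg, n_timepoints = 200), "n_edges"), 0)
})

test_that("walk counts on the path graph match hand enumeration", {
  m <- sfc_degrees(path_graph(3), "ROI001", max_steps = 3)
  expect_equal(unname(m$degrees[1, ]), c(0, 1, 0))
  expect_equal(unname(m$degrees[2, ]), c(1, 0, 1))
  expect_equal(unname(m$degrees[3, ]), c(0, 2, 0))
})

test_that("walk counts equal exhaustive enumeration on random small graphs", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(3:6, 1)
    a <- matrix(rbinom(n * n, 1, 0.5), n, n)
    a <- (a + t(a) > 0) * 1
    diag(a) <- 0
    seeds <- sample(n, sample(1:2, 1))
    m <- sfc_degrees(a, seeds, max_steps = 4)
    for (k in 1:4) {
      expect_equal(unname(m$degrees[k, ]), enumerate_walks(a, seeds, k))
    }
  }
})

test_that("walk counts are additive over seeds and zero on empty graphs", {
  a <- path_graph(4)
  m12 <- sfc_degrees(a, c("ROI001", "ROI002"), 3)
  m1 <- sfc_degrees(a, "ROI001", 3)
  m2 <- sfc_degrees(a, "ROI002", 3)
  expect_equal(m12$degrees, m1$degrees + m2$degrees)
  empty <- matrix(0, 4, 4)
  expect_true(all(sfc_degrees(empty, 1, 4)$degrees == 0))
  expect_error(sfc_degrees(a, character(0), 3), "non-empty")
})

test_that("adding an edge never decreases any walk count", {
  set.seed(9)
  for (rep in 1:20) {
    n <- 6
    a <- matrix(rbinom(n * n, 1, 0.4), n, n)
    a <- (a + t(a) > 0) * 1
    diag(a) <- 0
    off <- which(a == 0 & upper.tri(a))
    if (length(off) == 0) next
    pick <- sample(off, 1)
    b <- a
    b[pick] <- 1
    b[cbind(col(a)[pick], row(a)[pick])] <- 1
    da <- sfc_degrees(a, 1, 4)$degrees
    db <- sfc_degrees(b, 1, 4)$degrees
    expect_true(all(db >= da))
  }
})

test_that("per-step min-max normalization handles anchors and degenerate steps", {
  m <- sfc_degrees(path_graph(3), "ROI001", 2)
  m$degrees[1, ] <- c(0, 1, 0)
  m$degrees[2, ] <- c(2, 4, 6)
  nm <- normalize_sfc(m)
  expect_equal(unname(nm$degrees[1, ]), c(0, 1, 0))
  expect_equal(unname(nm$degrees[2, ]), c(0, 0.5, 1))
  m$degrees[2, ] <- c(3, 3, 3)
  expect_equal(unname(normalize_sfc(m)$degrees[2, ]), c(0, 0, 0))
})

test_that("subject and group maps combine elementwise with guardrails", {
  m <- normalize_sfc(sfc_degrees(path_graph(3), "ROI001", 2))
  ones <- m; ones$degrees[] <- 1
  expect_equal(combine_subject_group(m, ones)$degrees, m$degrees)
  g <- m
  m$degrees[1, ] <- c(0, 0.5, 1)
  g$degrees[1, ] <- c(1, 0.5, 0)
  expect_equal(unname(combine_subject_group(m, g)$degrees[1, ]), c(0, 0.25, 0))
  raw <- sfc_degrees(path_graph(3), "ROI001", 2)
  expect_error(combine_subject_group(raw, g), "normalized")
})

test_that("convergence detection finds the first stable step", {
  m <- sfc_degrees(path_graph(3), "ROI001", 3)
  m$degrees[1, ] <- c(1, 2, 3)
  m$degrees[2, ] <- c(2, 4, 6)
  m$degrees[3, ] <- c(2, 4, 6)
  expect_equal(as.integer(convergence_step(m)), 1)
  # P3 from seed 1: step1 and step2 anticorrelate, so no convergence at 1
  p3 <- sfc_degrees(path_graph(3), "ROI001", 3)
  expect_lt(cor(p3$degrees[1, ], p3$degrees[2, ]), 0)
  cs <- convergence_step(p3)
  expect_gt(as.integer(cs), 1)
  # dense random connected graph converges quickly (spectral gap)
  set.seed(3)
  a <- matrix(rbinom(900, 1, 0.5), 30); a <- (a + t(a) > 0) * 1; diag(a) <- 0
  mm <- normalize_sfc(sfc_degrees(a, 1, 8))
  cc <- convergence_step(mm)
  expect_true(attr(cc, "converged"))
  expect_lt(as.integer(cc), 8)
})
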