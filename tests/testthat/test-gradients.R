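test_that("two-block affinity yields a block-separating first gradient", {
  a <- matrix(0.1, 10, 10)
  a[1:5, 1:5] <- 1
  a[6:10, 6:10] <- 1
  diag(a) <- 1
  g <- diffusion_gradients(a, k = 3)
  g1 <- g$coords[, 1]
  expect_true(all(sign(g1[1:5]) == sign(g1[1])))
  expect_true(all(sign(g1[6:10]) == -sign(g1[1])))
  # independent check: leading non-trivial eigenvector of the Markov matrix
  d <- rowSums(a)
  w <- a / outer(sqrt(d), sqrt(d))
  p <- w / rowSums(w)
  ev <- eigen(p)
  expect_gt(abs(cor(Re(ev$vectors[, 2]), g1)), 0.999999)
})

test_that("uniform affinity gives an all-zero embedding", {
  a <- matrix(1, 8, 8)
  g <- diffusion_gradients(a, k = 3)
  expect_true(all(abs(g$coords) < 1e-10))
  expect_equal(g$variance_explained, rep(0, 3), tolerance = 1e-10)
})

test_that("variance explained is non-increasing and bounded on random affinities", {
  for (s in 1:8) {
    set.seed(s)
    x <- matrix(rnorm(12 * 30), 12, 30)
    a <- affinity_matrix(x %*% t(x) / 30 + diag(12))
    g <- diffusion_gradients(a, k = 5)
    expect_true(all(diff(g$variance_explained) <= 1e-12))
    expect_true(all(g$variance_explained >= 0))
    expect_lte(sum(g$variance_explained), 1 + 1e-12)
  }
})

test_that("disconnected affinity graphs are rejected with advice", {
  a <- matrix(0, 6, 6)
  a[1:3, 1:3] <- 1
  a[4:6, 4:6] <- 1
  expect_error(diffusion_gradients(a, k = 2), "disconnected")
})

test_that("Procrustes alignment recovers rotations, reflections and identity", {
  set.seed(7)
  tmpl <- make_gradients(matrix(rnorm(40), 10, 4))
  expect_equal(align_gradients(tmpl, tmpl)$coords, tmpl$coords,
               tolerance = 1e-10)
  flipped <- tmpl
  flipped$coords <- -tmpl$coords
  expect_equal(align_gradients(flipped, tmpl)$coords, tmpl$coords,
               tolerance = 1e-10)
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  rotated <- tmpl
  rotated$coords <- tmpl$coords %*% q
  expect_equal(align_gradients(rotated, tmpl)$coords, tmpl$coords,
               tolerance = 1e-8)
})

test_that("alignment is rigid: within-subject ROI distances are preserved", {
  set.seed(8)
  tmpl <- make_gradients(matrix(rnorm(60), 15, 4))
  subj <- make_gradients(matrix(rnorm(60), 15, 4))
  aligned <- align_gradients(subj, tmpl)
  expect_equal(as.matrix(dist(aligned$coords)), as.matrix(dist(subj$coords)),
               tolerance = 1e-8)
})

test_that("between-network dispersion follows its defining arithmetic", {
  g <- make_gradients(matrix(c(1, 3, 0), 3, 1))
  part <- setNames(c("A", "A", "B"), rownames(g$coords))
  expect_equal(dispersion_between(g, part, "A", "B", 1), 2)
  expect_equal(dispersion_between(g, part, "B", "A", 1), -2)
  expect_equal(dispersion_between(g, part, "A", "A", 1), 0)
  expect_equal(dispersion_between(g, part, "B", "A", 1, absolute = TRUE), 2)
  expect_error(dispersion_between(g, part, "A", "C", 1), "no ROIs")
})

test_that("within-network dispersion is the centroid sum of squares", {
  g <- make_gradients(matrix(c(1, 2, 3), 3, 1))
  rois <- rownames(g$coords)
  expect_equal(dispersion_within(g, rois, 1), 2)
  gc <- make_gradients(matrix(c(5, 5, 5), 3, 1))
  expect_equal(dispersion_within(gc, rois, 1), 0)
  g4 <- make_gradients(matrix(4 * c(1, 2, 3), 3, 1))
  expect_equal(dispersion_within(g4, rois, 1), 16 * 2)
  expect_error(dispersion_within(g, rois[1], 1), "at least 2")
})

test_that("the pipeline is equivariant under ROI relabeling", {
  set.seed(11)
  ts <- matrix(rnorm(60 * 24), 60, 24,
               dimnames = list(NULL, sprintf("R%02d", 1:24)))
  perm <- sample(24)
  g1 <- diffusion_gradients(affinity_matrix(sparsify_rows(compute_fc(ts), 0.3)), k = 3)
  g2 <- diffusion_gradients(affinity_matrix(sparsify_rows(compute_fc(ts[, perm]), 0.3)), k = 3)
  expect_equal(g2$coords[colnames(ts), ], g1$coords, tolerance = 1e-8)
})
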