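test_that("cohort spec validates its invariants", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(n_per_group = 1), "n_per_group")
  expect_error(cohort_spec(n_rois = 10), "3 ROIs per network")
  expect_error(cohort_spec(n_timepoints = 10), "n_timepoints")
  expect_error(cohort_spec(compression = 1.5), "compression")
  expect_error(cohort_spec(tree_params = list(p_np_embed = 2, p_vp_chain = 0,
                                              mean_len = 5)), "probabilities")
})

test_that("a non-positive-definite factor correlation is rejected diagnosably", {
  spec <- cohort_spec(c0 = 0.6, c1 = 0.999, compression = 1)
  expect_error(gen_timeseries(spec, "FEP"), "not positive definite")
})

test_that("time series generation is deterministic and group-structured", {
  spec <- cohort_spec(n_per_group = 3, n_rois = 21, n_timepoints = 30, seed = 5)
  a <- gen_timeseries(spec, "HC")
  b <- gen_timeseries(spec, "HC")
  expect_identical(a, b)
  expect_length(a, 3)
  expect_equal(dim(a[[1]]), c(30, 21))
  expect_equal(unname(table(attr(a, "networks"))), rep(3, 7), ignore_attr = TRUE)
})

test_that("no group effect at compression zero: FC templates agree", {
  spec <- cohort_spec(n_per_group = 20, compression = 0,
                      n_timepoints = 240, seed = 3)
  mean_fc <- function(ts) Reduce(`+`, lapply(ts, compute_fc)) / length(ts)
  d <- mean_fc(gen_timeseries(spec, "HC")) - mean_fc(gen_timeseries(spec, "FEP"))
  expect_lt(mean(abs(d)), 0.05)
})

test_that("the planted factor correlation is recovered from one long scan", {
  spec <- cohort_spec(n_per_group = 2, n_timepoints = 5000, compression = 1,
                      seed = 8)
  # the pinned value: c0 + compression * (c1 - c0) = 0.6
  fac <- psychspeech:::factor_correlation(spec, "FEP")
  vn <- which(spec$networks == "VN"); dmn <- which(spec$networks == "DMN")
  expect_equal(fac$cmat[vn, dmn], 0.6)
  ts <- gen_timeseries(spec, "FEP")[[1]]
  sample_r <- cor(ts)
  pop_r <- population_fc(spec, "FEP")
  nets <- attr(gen_timeseries(spec, "FEP"), "networks")
  blk <- outer(nets == "VN", nets == "DMN")
  expect_lt(abs(mean(sample_r[blk]) - mean(pop_r[blk])), 0.05)
  # and the sample FC matches the generative population values overall
  expect_lt(max(abs(sample_r - pop_r)), 0.08)
})

test_that("embedding generation is normalized, clustered and deterministic", {
  e <- gen_embeddings(10, 2, 1e-9, dim = 6, seed = 3)
  expect_equal(sqrt(rowSums(e^2)), rep(1, 10), ignore_attr = TRUE,
               tolerance = 1e-12)
  cl <- attr(e, "cluster")
  cs <- tcrossprod(e)
  same <- outer(cl, cl, "==") & upper.tri(cs)
  diff <- outer(cl, cl, "!=") & upper.tri(cs)
  expect_true(all(abs(cs[same] - 1) < 1e-9))
  expect_true(all(cs[diff] < 1 - 1e-6))
  expect_identical(gen_embeddings(8, 3, 0.4, 5, seed = 2),
                   gen_embeddings(8, 3, 0.4, 5, seed = 2))
  expect_error(gen_embeddings(3, 2, 0.1, 5, 1), "at least 4")
})

test_that("mean pairwise similarity is monotone in the spread parameter", {
  mean_sim <- function(spread) {
    mean(sapply(1:50, function(s) {
      sm <- similarity_matrix(gen_embeddings(20, 4, spread, 30, seed = s))
      mean(sm[upper.tri(sm)])
    }))
  }
  ms <- sapply(c(0.1, 0.5, 1.5), mean_sim)
  expect_true(all(diff(ms) < 0))
})

test_that("tree generation respects its grammar knobs and round-trips", {
  flat <- gen_trees(30, list(p_np_embed = 0, p_vp_chain = 0, mean_len = 5),
                    seed = 2)
  m <- syntax_metrics_many(flat)
  expect_true(all(m$np_nest == 0))
  # verb chaining raises the VP count (200 utterances per setting)
  lo <- syntax_metrics_many(gen_trees(200, list(p_np_embed = 0.1, p_vp_chain = 0.1,
                                                mean_len = 6), seed = 7))
  hi <- syntax_metrics_many(gen_trees(200, list(p_np_embed = 0.1, p_vp_chain = 0.6,
                                                mean_len = 6), seed = 7))
  expect_gt(mean(hi$vp_count), mean(lo$vp_count))
  for (tr in gen_trees(25, list(p_np_embed = 0.3, p_vp_chain = 0.4, mean_len = 7),
                       seed = 9)) {
    expect_equal(serialize_tree(parse_bracketed(tr)), tr)
  }
})

test_that("the full cohort bundles matched groups with three narratives", {
  spec <- cohort_spec(n_per_group = 3, n_rois = 21, n_timepoints = 30, seed = 4)
  co <- gen_cohort(spec)
  expect_equal(table(co$subjects$group), table(c(rep("HC", 3), rep("FEP", 3))))
  expect_true(all(lengths(co$embeddings) == 3))
  expect_true(all(lengths(co$trees) == 3))
  expect_identical(gen_cohort(spec)$subjects, co$subjects)
  expect_identical(gen_cohort(spec)$trees, co$trees)
})
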