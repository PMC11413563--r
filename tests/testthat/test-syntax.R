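test_that("bracketed parsing round-trips and reports malformed input", {
  t1 <- parse_bracketed("(S (NP (DT) (NN)) (VP (VBD)))")
  expect_equal(length(tree_leaves(t1)), 3)
  expect_equal(serialize_tree(t1), "(S (NP (DT) (NN)) (VP (VBD)))")
  t2 <- parse_bracketed("(S (VP (VB)))")
  expect_equal(tree_leaves(t2), "VB")
  expect_error(parse_bracketed("((S"), "parse error at offset")
  expect_error(parse_bracketed("   "), "empty")
  # whitespace variation does not change the parse
  expect_equal(serialize_tree(parse_bracketed("( S (NP (DT)(NN))\n (VP (VBD)) )")),
               serialize_tree(t1))
  # surface tokens inside preterminals are accepted and dropped
  expect_equal(serialize_tree(parse_bracketed("(S (NP (DT the) (NN dog)) (VP (VBD ran)))")),
               serialize_tree(t1))
})

test_that("punctuation stripping prunes leaves and collapses empty trees", {
  t1 <- parse_bracketed("(S (NP (NN)) (VP (VBD)) (.))")
  s <- strip_punctuation(t1)
  expect_equal(length(tree_leaves(s)), 2)
  t2 <- parse_bracketed("(S (NP (NN)) (VP (VBD)))")
  expect_equal(serialize_tree(strip_punctuation(t2)), serialize_tree(t2))
  expect_null(strip_punctuation(parse_bracketed("(S (. .))")))
  all_na <- syntax_metrics("(S (.) (,))")
  expect_true(all(is.na(all_na)))
})

test_that("binarization right-factors wide nodes and preserves leaves", {
  t3 <- parse_bracketed("(S (A) (B) (C))")
  b <- binarize_tree(t3)
  expect_equal(length(b$children), 2)
  expect_equal(b$children[[2]]$label, "S|<B-C>")
  expect_equal(tree_leaves(b), c("A", "B", "C"))
  binar <- parse_bracketed("(S (NP (DT) (NN)) (VP (VBD)))")
  expect_equal(serialize_tree(binarize_tree(binar)), serialize_tree(binar))
  # property: leaf sequence unchanged on generated trees
  for (tr in gen_trees(20, list(p_np_embed = 0.3, p_vp_chain = 0.3, mean_len = 7),
                       seed = 5)) {
    p <- parse_bracketed(tr)
    expect_equal(tree_leaves(binarize_tree(p)), tree_leaves(p))
  }
})

test_that("depth series counts edges from the root to each leaf", {
  expect_equal(depth_series(parse_bracketed("(S (NP (DT) (NN)) (VP (VBD)))")),
               c(2L, 2L, 2L))
  expect_equal(depth_series(parse_bracketed("(S (VP (VB)))")), 2L)
  shallow <- parse_bracketed("(S (NP (NN)) (VP (VB)))")
  deeper <- parse_bracketed("(S (NP (NN)) (VP (VP (VB))))")
  ds <- depth_series(shallow)
  dd <- depth_series(deeper)
  expect_equal(max(dd), max(ds) + 1)
  expect_equal(mean(dd), mean(ds) + 1 / 2)
})

test_that("approximate entropy matches a brute-force window-count oracle", {
  per <- rep(c(1, 2), 5)
  expect_equal(approx_entropy(per), manual_apen(per), tolerance = 1e-12)
  set.seed(13)
  for (rep in 1:5) {
    s <- sample(1:4, 12, replace = TRUE)
    if (sd(s) == 0) next
    expect_equal(approx_entropy(s), manual_apen(s), tolerance = 1e-12)
  }
  expect_equal(approx_entropy(rep(3, 10)), 0)
  expect_true(is.na(approx_entropy(c(1, 2, 3))))
  # an iid series is less predictable than a periodic one of equal length
  set.seed(4)
  iid <- sample(rep(c(1, 2), 10))
  expect_gt(approx_entropy(iid), approx_entropy(rep(c(1, 2), 10)))
})

test_that("phrase metrics follow the preterminal-leaf conventions", {
  m <- syntax_metrics("(S (NP (DT) (NN)) (VP (VBD)))")
  expect_equal(m$leaf_num, 3)
  expect_equal(m$nodes, 6)
  expect_equal(m$phrase_fraction, 1)
  expect_equal(m$np_count, 1)
  expect_equal(m$np_nest, 0)
  expect_equal(m$np_length, 2)
  expect_equal(m$vp_count, 1)
  expect_equal(m$vp_length, 1)
  nested <- phrase_metrics(parse_bracketed("(NP (NP (NN)) (PP (IN) (NP (NN))))"))
  expect_equal(nested$np_count, 3)
  expect_equal(nested$np_nest, 1 / 3)
  no_np <- phrase_metrics(parse_bracketed("(S (VP (VB)))"))
  expect_equal(no_np$np_count, 0)
  expect_true(is.na(no_np$np_nest))
  expect_true(is.na(no_np$np_length))
})

test_that("functional annotations are stripped and intermediates excluded", {
  m <- syntax_metrics("(S (NP-SBJ (DT) (NN)) (VP (VBD) (NP (NN)) (PP (IN) (NP (NN)))))")
  expect_equal(m$np_count, 3)   # NP-SBJ counts as NP; VP|<...> does not
  expect_equal(m$nodes, 12)     # binarization intermediate not counted
})

test_that("aggregation is a two-stage unweighted mean with pairwise NA removal", {
  one <- syntax_metrics("(S (NP (DT) (NN)) (VP (VBD)))")
  rep3 <- dplyr::bind_rows(one, one, one)
  rep3$narrative <- c(1, 1, 2)
  agg <- aggregate_syntax(rep3)
  expect_equal(agg$depth, one$depth)
  # narrative means 2 and 4 average to 3 regardless of utterance counts
  df <- tibble::tibble(narrative = c(1, 1, 1, 2), depth = c(2, 2, 2, 4))
  expect_equal(aggregate_syntax(df)$depth, 3)
  df_na <- tibble::tibble(narrative = c(1, 2), depth_apen = c(NA_real_, NA_real_))
  expect_true(is.na(aggregate_syntax(df_na)$depth_apen))
})

test_that("binarization never decreases leaf depth", {
  for (tr in gen_trees(15, list(p_np_embed = 0.35, p_vp_chain = 0.4, mean_len = 7),
                       seed = 11)) {
    p <- strip_punctuation(parse_bracketed(tr))
    expect_true(all(depth_series(binarize_tree(p)) >= depth_series(p)))
  }
})
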