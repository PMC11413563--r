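#' Parse a bracketed constituency tree
#'
#' Reads one Penn-style bracketed string into a rooted ordered labeled tree.
#' Leaves are part-of-speech preterminals: a bracketed node with no bracketed
#' children, e.g. `(NN)`. Bare word tokens inside a preterminal (as in
#' `(NN dog)`) are accepted and discarded, since tokens themselves are not
#' tree nodes under the leaves-are-preterminals convention.
#'
#' @param text A single bracketed string.
#' @return A `syn_tree`: nested list with elements `label` (character) and
#'   `children` (list of `syn_tree`).
#' @export
#' @examples
#' t <- parse_bracketed("(S (NP (DT) (NN)) (VP (VBD)))")
#' tree_leaves(t)
parse_bracketed <- function(text) {
  assert_that(is.character(text) && length(text) == 1, "text must be one string")
  matches <- gregexpr("\\(|\\)|[^()\\s]+", text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(matches))[[1]]
  offs <- as.integer(matches)
  if (length(toks) == 0 || all(toks == "")) {
    stop("empty tree string", call. = FALSE)
  }
  i <- 0L
  n_tok <- length(toks)
  err <- function(msg, at) {
    off <- if (at >= 1 && at <= n_tok) offs[at] else nchar(text) + 1L
    stop("parse error at offset ", off, ": ", msg, call. = FALSE)
  }
  parse_node <- function() {
    i <<- i + 1L
    if (i > n_tok || toks[i] != "(") err("expected '('", i)
    i <<- i + 1L
    if (i > n_tok || toks[i] %in% c("(", ")")) err("expected node label", i)
    label <- toks[i]
    children <- list()
    repeat {
      if (i + 1L > n_tok) err("unbalanced parentheses: unexpected end of input", i + 1L)
      nxt <- toks[i + 1L]
      if (nxt == ")") {
        i <<- i + 1L
        break
      } else if (nxt == "(") {
        children[[length(children) + 1L]] <- parse_node()
      } else {
        i <<- i + 1L  # bare token (surface word) -- dropped
      }
    }
    structure(list(label = label, children = children), class = "syn_tree")
  }
  tree <- parse_node()
  if (i < n_tok) err("trailing content after tree", i + 1L)
  tree
}

#' Serialize a tree back to canonical bracketing
#'
#' @param tree A `syn_tree`.
#' @return A single bracketed string with single-space separators, such that
#'   `serialize_tree(parse_bracketed(x))` is the canonical-whitespace form
#'   of `x`.
#' @export
serialize_tree <- function(tree) {
  if (length(tree$children) == 0) return(paste0("(", tree$label, ")"))
  paste0("(", tree$label, " ",
         paste(vapply(tree$children, serialize_tree, character(1)),
               collapse = " "), ")")
}

#' @export
print.syn_tree <- function(x, ...) {
  cat(serialize_tree(x), "\n")
  invisible(x)
}

is_leaf <- function(node) length(node$children) == 0

#' Leaf labels of a tree in surface order
#' @param tree A `syn_tree`.
#' @return Character vector of leaf (POS) labels.
#' @export
tree_leaves <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  unlist(lapply(tree$children, tree_leaves))
}

#' Default Penn Treebank punctuation tags
#' @export
ptb_punct_tags <- function() c(".", ",", ":", "``", "''", "-LRB-", "-RRB-")

#' Remove punctuation leaves from a tree
#'
#' Deletes leaves whose POS label is a punctuation tag and recursively
#' removes any internal node left childless. Punctuation is useful to the
#' parser but is not part of the syntactic structure analyzed.
#'
#' @param tree A `syn_tree`.
#' @param punct_labels Labels treated as punctuation (default
#'   [ptb_punct_tags()]).
#' @return The pruned `syn_tree`, or `NULL` when the whole tree collapses
#'   (an utterance consisting only of punctuation).
#' @export
strip_punctuation <- function(tree, punct_labels = ptb_punct_tags()) {
  prune <- function(node) {
    if (is_leaf(node)) {
      if (node$label %in% punct_labels) return(NULL)
      return(node)
    }
    kids <- Filter(Negate(is.null), lapply(node$children, prune))
    if (length(kids) == 0) return(NULL)
    node$children <- kids
    node
  }
  prune(tree)
}

#' Right-factored binarization
#'
#' Converts the tree to a Chomsky-normal-like form in which every node has
#' at most two children, introducing right-factored intermediate nodes
#' labeled `parent|<child-labels>`. The leaf sequence is unchanged.
#' Intermediate labels contain `|` and are excluded from all phrase counts.
#'
#' @param tree A `syn_tree`.
#' @return Binarized `syn_tree`.
#' @export
binarize_tree <- function(tree) {
  if (is_leaf(tree)) return(tree)
  kids <- lapply(tree$children, binarize_tree)
  while (length(kids) > 2) {
    rest <- kids[-1]
    lab <- paste0(tree$label, "|<",
                  paste(vapply(rest, function(k) k$label, character(1)),
                        collapse = "-"), ">")
    kids <- list(kids[[1]],
                 structure(list(label = lab, children = rest), class = "syn_tree"))
  }
  tree$children <- kids
  tree
}

#' Per-token syntactic depth series
#'
#' The depth of token `i` is the number of edges from the root to its POS
#' leaf, read in surface order. Computed on whatever tree is supplied; the
#' pipeline convention is the punctuation-stripped, binarized tree.
#'
#' @param tree A `syn_tree`.
#' @return Integer vector, one depth per leaf.
#' @export
depth_series <- function(tree) {
  walk <- function(node, d) {
    if (is_leaf(node)) return(d)
    unlist(lapply(node$children, walk, d = d + 1L))
  }
  walk(tree, 0L)
}

#' Approximate entropy of a series
#'
#' Pincus approximate entropy `ApEn(m, r)` with Chebyshev distance and
#' self-matches included: `ApEn = Phi_m - Phi_{m+1}` where `Phi_k` is the
#' mean over windows of the log fraction of windows within tolerance `r`.
#' The tolerance is `r_factor * sd(series)`; a constant series returns 0 by
#' convention, and a series shorter than `m + 2` returns `NA`.
#'
#' @param series Numeric vector.
#' @param m Template length (default 2).
#' @param r_factor Tolerance as a fraction of the series SD (default 0.2).
#' @return ApEn value, 0 for constant series, `NA` when too short.
#' @export
approx_entropy <- function(series, m = 2, r_factor = 0.2) {
  n <- length(series)
  if (n < m + 2) return(NA_real_)
  s <- sd(series)
  if (s == 0) return(0)
  r <- r_factor * s
  phi <- function(k) {
    n_win <- n - k + 1
    # pairwise Chebyshev distance between windows, built coordinate-wise
    d <- matrix(0, n_win, n_win)
    for (j in seq_len(k)) {
      col <- series[j:(j + n_win - 1)]
      d <- pmax(d, abs(outer(col, col, "-")))
    }
    cnt <- rowSums(d <= r)
    mean(log(cnt / n_win))
  }
  phi(m) - phi(m + 1)
}

strip_function_tag <- function(label) {
  sub("[-=].*$", "", label)
}

# internal: collect non-intermediate nodes with their dominated leaf counts
# and whether their proper subtree contains a given base label
node_table <- function(tree) {
  rows <- list()
  walk <- function(node) {
    # returns list(leaves = count, labels = base labels present in subtree)
    if (is_leaf(node)) {
      base <- strip_function_tag(node$label)
      rows[[length(rows) + 1L]] <<- list(label = node$label, base = base,
                                         leaves = 1L, internal = FALSE,
                                         sub_bases = character(0),
                                         intermediate = grepl("|", node$label, fixed = TRUE))
      return(list(leaves = 1L, bases = base))
    }
    kid_res <- lapply(node$children, walk)
    leaves <- sum(vapply(kid_res, function(x) x$leaves, integer(1)))
    sub_bases <- unlist(lapply(kid_res, function(x) x$bases))
    base <- strip_function_tag(node$label)
    interm <- grepl("|", node$label, fixed = TRUE)
    rows[[length(rows) + 1L]] <<- list(label = node$label, base = base,
                                       leaves = leaves, internal = TRUE,
                                       sub_bases = sub_bases,
                                       intermediate = interm)
    bases <- if (interm) sub_bases else c(base, sub_bases)
    list(leaves = leaves, bases = bases)
  }
  walk(tree)
  rows
}

#' Phrase, NP and VP metrics of one tree
#'
#' Counts and size measures of the phrasal structure, computed on a
#' normalized (punctuation-stripped, binarized) tree. Binarization
#' intermediates (labels containing `|`) are never counted. Labels are
#' matched after stripping functional annotations at the first hyphen or
#' equals sign (`NP-SBJ` counts as `NP`). Nesting counts proper domination
#' at any depth: an NP is nested-counting if any NP occurs strictly below
#' it.
#'
#' @param tree A normalized `syn_tree`.
#' @return Named list: `leaf_num`, `nodes`, `phrase_fraction`, `np_count`,
#'   `np_nest`, `np_length`, `vp_count`, `vp_nest`, `vp_length`. Nest and
#'   length measures are `NA` (not 0) when the corresponding count is 0.
#' @export
phrase_metrics <- function(tree) {
  rows <- node_table(tree)
  keep <- !vapply(rows, function(x) x$intermediate, logical(1))
  rows <- rows[keep]
  leaf_num <- sum(!vapply(rows, function(x) x$internal, logical(1)))
  n_nodes <- length(rows)
  phrases <- vapply(rows, function(x) x$internal, logical(1))
  cat_metrics <- function(cat) {
    sel <- rows[vapply(rows, function(x) x$internal && x$base == cat, logical(1))]
    count <- length(sel)
    if (count == 0) {
      return(list(count = 0L, nest = NA_real_, length = NA_real_))
    }
    nested <- vapply(sel, function(x) cat %in% x$sub_bases, logical(1))
    list(count = count, nest = sum(nested) / count,
         length = mean(vapply(sel, function(x) x$leaves, integer(1))))
  }
  np <- cat_metrics("NP")
  vp <- cat_metrics("VP")
  list(leaf_num = leaf_num, nodes = n_nodes,
       phrase_fraction = sum(phrases) / leaf_num,
       np_count = np$count, np_nest = np$nest, np_length = np$length,
       vp_count = vp$count, vp_nest = vp$nest, vp_length = vp$length)
}

# internal fast path: metrics for one utterance as a plain named vector
syntax_metrics_vec <- function(text, punct_labels = ptb_punct_tags(),
                               m = 2, r_factor = 0.2) {
  tree <- if (inherits(text, "syn_tree")) text else parse_bracketed(text)
  tree <- strip_punctuation(tree, punct_labels)
  nm <- c("leaf_num", "nodes", "phrase_fraction", "depth", "depth_mean",
          "depth_apen", "np_count", "np_nest", "np_length",
          "vp_count", "vp_nest", "vp_length")
  if (is.null(tree)) return(setNames(rep(NA_real_, length(nm)), nm))
  tree <- binarize_tree(tree)
  ds <- depth_series(tree)
  pm <- phrase_metrics(tree)
  setNames(c(pm$leaf_num, pm$nodes, pm$phrase_fraction, max(ds), mean(ds),
             approx_entropy(ds, m = m, r_factor = r_factor),
             pm$np_count, pm$np_nest, pm$np_length,
             pm$vp_count, pm$vp_nest, pm$vp_length), nm)
}

#' Syntax metrics for many utterances
#'
#' Vectorized convenience over [syntax_metrics()]: one row per bracketed
#' string.
#'
#' @param texts Character vector of bracketed tree strings.
#' @inheritParams syntax_metrics
#' @return Tibble with one row per utterance.
#' @export
syntax_metrics_many <- function(texts, punct_labels = ptb_punct_tags(),
                                m = 2, r_factor = 0.2) {
  nm <- c("leaf_num", "nodes", "phrase_fraction", "depth", "depth_mean",
          "depth_apen", "np_count", "np_nest", "np_length",
          "vp_count", "vp_nest", "vp_length")
  out <- t(vapply(texts, syntax_metrics_vec, setNames(numeric(12), nm),
                  punct_labels = punct_labels, m = m, r_factor = r_factor,
                  USE.NAMES = FALSE))
  colnames(out) <- nm
  as_tibble(out)
}

#' All syntax metrics for one bracketed utterance
#'
#' The full per-utterance chain: parse, strip punctuation, right-factor
#' binarize, then compute the depth series (maximum, mean, approximate
#' entropy) and the phrase/NP/VP measures. Depth is measured on the
#' binarized tree; phrase counts exclude binarization intermediates.
#'
#' @param text Bracketed tree string (or an already-parsed `syn_tree`).
#' @param punct_labels Punctuation POS tags to strip.
#' @param m,r_factor Approximate-entropy parameters (see
#'   [approx_entropy()]).
#' @return One-row tibble of the 12 syntax measures; all `NA` when the
#'   utterance collapses to punctuation only.
#' @export
syntax_metrics <- function(text, punct_labels = ptb_punct_tags(),
                           m = 2, r_factor = 0.2) {
  tree <- if (inherits(text, "syn_tree")) text else parse_bracketed(text)
  tree <- strip_punctuation(tree, punct_labels)
  empty <- tibble(leaf_num = NA_real_, nodes = NA_real_,
                  phrase_fraction = NA_real_, depth = NA_real_,
                  depth_mean = NA_real_, depth_apen = NA_real_,
                  np_count = NA_real_, np_nest = NA_real_, np_length = NA_real_,
                  vp_count = NA_real_, vp_nest = NA_real_, vp_length = NA_real_)
  if (is.null(tree)) return(empty)
  tree <- binarize_tree(tree)
  ds <- depth_series(tree)
  pm <- phrase_metrics(tree)
  tibble(leaf_num = pm$leaf_num, nodes = pm$nodes,
         phrase_fraction = pm$phrase_fraction,
         depth = max(ds), depth_mean = mean(ds),
         depth_apen = approx_entropy(ds, m = m, r_factor = r_factor),
         np_count = pm$np_count, np_nest = pm$np_nest, np_length = pm$np_length,
         vp_count = pm$vp_count, vp_nest = pm$vp_nest, vp_length = pm$vp_length)
}

#' Two-stage aggregation of utterance metrics
#'
#' Averages utterance-level syntax metrics within each narrative, then
#' averages the narrative means, giving every narrative equal weight
#' regardless of how many utterances it contains. Missing values are
#' excluded pairwise at each stage.
#'
#' @param metrics Data frame of per-utterance metrics with a `narrative`
#'   column (all other numeric columns are aggregated).
#' @return One-row tibble of per-subject metrics.
#' @export
aggregate_syntax <- function(metrics) {
  assert_that("narrative" %in% names(metrics),
              "metrics must contain a 'narrative' column")
  num_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "narrative")
  metrics |>
    dplyr::group_by(.data$narrative) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(num_cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::summarise(dplyr::across(dplyr::all_of(num_cols),
                                   ~ {
                                     v <- .x[!is.nan(.x) & !is.na(.x)]
                                     if (length(v) == 0) NA_real_ else mean(v)
                                   }))
}
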