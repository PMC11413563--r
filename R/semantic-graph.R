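#' Normalized cosine similarity between unit embeddings
#'
#' Pairwise similarity between speech units (content-word types or
#' utterances) from their embedding vectors: `s_ij = (cos(e_i, e_j) + 1)/2`,
#' mapping cosine similarity into `[0, 1]`. Downstream thresholding is
#' rank-based, so any strictly monotone rescaling of cosine gives the same
#' graphs; this normalization just keeps the stored values in a conventional
#' range.
#'
#' @param embeddings Numeric unit-by-dimension matrix; row names are unit
#'   labels.
#' @return Symmetric unit-by-unit similarity matrix with unit diagonal.
#' @export
similarity_matrix <- function(embeddings) {
  assert_that(is.matrix(embeddings) && is.numeric(embeddings),
              "embeddings must be a numeric matrix")
  assert_that(nrow(embeddings) >= 2, "need at least 2 units")
  labels <- rownames(embeddings) %||% default_labels(nrow(embeddings), "unit")
  norms <- sqrt(rowSums(embeddings^2))
  if (any(norms == 0)) {
    stop("zero-norm embedding for unit(s): ",
         paste(labels[norms == 0], collapse = ", "), call. = FALSE)
  }
  x <- embeddings / norms
  cs <- pmin(pmax(tcrossprod(x), -1), 1)
  s <- (cs + 1) / 2
  diag(s) <- 1
  dimnames(s) <- list(labels, labels)
  s
}

#' Proportional thresholding with the 2 ln N mean-degree rule
#'
#' Binarizes a similarity matrix by proportional thresholding: candidate
#' threshold `t` keeps the `round(t * N(N-1)/2)` strongest off-diagonal
#' pairs (round-half-away-from-zero; ties broken by pair index order). The
#' selected threshold is the smallest value on the grid 0.05, 0.10, ...,
#' 0.80 whose graph has mean degree `2E/N` exceeding `2 ln N`, the weakest
#' density at which small-world structure is measurable. If no grid value
#' qualifies, 0.80 is used and the graph is flagged.
#'
#' @param sim Similarity matrix from [similarity_matrix()].
#' @param grid Candidate thresholds (defaults to the 0.05-spaced grid).
#' @return A `unit_graph` list: `adjacency` (0/1 symmetric), `threshold`
#'   (grid value used), `mean_degree`, and `flagged` (`TRUE` when the
#'   fallback was taken).
#' @export
select_threshold <- function(sim, grid = seq(0.05, 0.80, by = 0.05)) {
  check_square(sim, "sim")
  n <- nrow(sim)
  assert_that(n >= 4, "at least 4 units are required to build a semantic graph")
  ut <- which(upper.tri(sim))
  # strongest first; ties resolved by earlier pair index
  ord <- ut[order(-sim[ut], ut)]
  n_pairs <- length(ut)
  target <- 2 * log(n)
  chosen <- NULL
  for (t in grid) {
    m <- round_half_away(t * n_pairs)
    if (2 * m / n > target) {
      chosen <- t
      break
    }
  }
  flagged <- is.null(chosen)
  if (flagged) chosen <- grid[length(grid)]
  m <- round_half_away(chosen * n_pairs)
  adj <- matrix(0, n, n, dimnames = dimnames(sim))
  adj[ord[seq_len(min(m, n_pairs))]] <- 1
  adj <- adj + t(adj)
  structure(list(adjacency = adj, threshold = chosen,
                 mean_degree = 2 * min(m, n_pairs) / n, flagged = flagged),
            class = "unit_graph")
}

#' @export
print.unit_graph <- function(x, ...) {
  cat("<unit_graph> ", nrow(x$adjacency), " units, threshold ", x$threshold,
      ", mean degree ", round(x$mean_degree, 2),
      if (x$flagged) " [fallback threshold]" else "", "\n", sep = "")
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Closeness, efficiency and clustering of a unit graph
#'
#' The three Table-style graph measures of a binarized semantic graph:
#' \describe{
#'   \item{cc}{Closeness centrality averaged over nodes. Per node, the
#'     reciprocal of the average shortest-path distance to its reachable
#'     nodes, scaled by the fraction of the graph that is reachable (so
#'     disconnected graphs are penalized).}
#'   \item{ge}{Global efficiency: mean over ordered node pairs of the
#'     inverse shortest-path distance, 0 for unreachable pairs.}
#'   \item{clustering}{Mean local clustering coefficient; nodes of degree
#'     below 2 contribute 0.}
#' }
#'
#' @param g A `unit_graph` (or bare 0/1 adjacency matrix).
#' @return Named list with `cc`, `ge`, `clustering`.
#' @export
graph_metrics <- function(g) {
  adj <- if (inherits(g, "unit_graph")) g$adjacency else g
  n <- nrow(adj)
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  d <- igraph::distances(ig)
  closeness_i <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    if (length(reach) == 0) return(0)
    (length(reach) / sum(reach)) * (length(reach) / (n - 1))
  }, numeric(1))
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  ge <- sum(inv) / (n * (n - 1))
  loc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  loc[is.nan(loc)] <- 0
  list(cc = mean(closeness_i), ge = ge, clustering = mean(loc))
}

#' Small-worldness coefficient sigma
#'
#' `sigma = (C / <C_rand>) / (L / <L_rand>)`, where `C` is the mean local
#' clustering coefficient, `L` the average shortest-path length on the
#' largest component, and the null ensemble consists of degree-preserving
#' Maslov-Sneppen rewirings (`10 * E` attempted edge swaps each).
#' Deterministic given `seed`.
#'
#' @param g A `unit_graph` (or adjacency matrix); must be connected with at
#'   least 4 nodes, otherwise `NA` is returned.
#' @param n_null Number of null graphs (default 20).
#' @param seed Integer seed for the rewiring stream.
#' @return `sigma` (numeric), or `NA` with attribute `reason` when
#'   undefined.
#' @export
small_worldness <- function(g, n_null = 20, seed = 1L) {
  adj <- if (inherits(g, "unit_graph")) g$adjacency else g
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  if (igraph::vcount(ig) < 4) {
    return(structure(NA_real_, reason = "fewer than 4 nodes"))
  }
  if (igraph::components(ig)$no > 1) {
    return(structure(NA_real_, reason = "graph is disconnected"))
  }
  avg_clust <- function(gg) {
    loc <- igraph::transitivity(gg, type = "local", isolates = "zero")
    loc[is.nan(loc)] <- 0
    mean(loc)
  }
  path_len <- function(gg) {
    comp <- igraph::components(gg)
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(gg, which(comp$membership == big))
    igraph::mean_distance(sub)
  }
  cc <- avg_clust(ig)
  ll <- path_len(ig)
  e <- igraph::ecount(ig)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nulls <- replicate(n_null, {
    rg <- igraph::rewire(ig, igraph::keeping_degseq(niter = 10 * e))
    c(avg_clust(rg), path_len(rg))
  })
  c_rand <- mean(nulls[1, ])
  l_rand <- mean(nulls[2, ])
  if (c_rand == 0) {
    return(structure(NA_real_, reason = "null graphs have zero clustering"))
  }
  (cc / c_rand) / (ll / l_rand)
}

#' Semantic graph metrics for a set of narratives
#'
#' Builds one semantic graph per narrative (threshold selection, graph
#' measures, small-worldness) and averages the graph measures across the
#' narratives that have at least 4 units. Narratives below 4 units cannot
#' support a graph: they still contribute to the mean unit count but are
#' excluded from the graph-metric average.
#'
#' @param narratives List of unit-by-dimension embedding matrices, one per
#'   narrative (typically 3 picture descriptions).
#' @param n_null,seed Passed to [small_worldness()].
#' @return One-row tibble: `n_narratives`, `unit_num` (mean unit count),
#'   `threshold` (mean selected threshold), `cc`, `ge`, `clustering`,
#'   `sigma`, `n_flagged`. Metrics are `NA` when no narrative has >= 4
#'   units.
#' @export
analyze_narratives <- function(narratives, n_null = 20, seed = 1L) {
  assert_that(is.list(narratives) && length(narratives) >= 1,
              "narratives must be a non-empty list of embedding matrices")
  counts <- vapply(narratives, nrow, integer(1))
  usable <- which(counts >= 4)
  if (length(usable) == 0) {
    return(tibble(
      n_narratives = length(narratives), unit_num = mean(counts),
      threshold = NA_real_, cc = NA_real_, ge = NA_real_,
      clustering = NA_real_, sigma = NA_real_, n_flagged = 0L))
  }
  rows <- lapply(seq_along(usable), function(j) {
    i <- usable[j]
    g <- select_threshold(similarity_matrix(narratives[[i]]))
    met <- graph_metrics(g)
    sig <- small_worldness(g, n_null = n_null,
                           seed = derive_seed(seed, paste0("narrative", i)))
    tibble(threshold = g$threshold, cc = met$cc, ge = met$ge,
           clustering = met$clustering, sigma = as.numeric(sig),
           flagged = g$flagged)
  })
  all_rows <- dplyr::bind_rows(rows)
  tibble(
    n_narratives = length(narratives),
    unit_num = mean(counts),
    threshold = mean(all_rows$threshold),
    cc = mean(all_rows$cc),
    ge = mean(all_rows$ge),
    clustering = mean(all_rows$clustering),
    sigma = mean(all_rows$sigma, na.rm = TRUE),
    n_flagged = sum(all_rows$flagged)
  )
}
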