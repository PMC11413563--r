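#' Significance-binarized FC graph
#'
#' Converts an FC matrix into the undirected binary graph used for stepwise
#' functional connectivity. For every off-diagonal ROI pair the correlation
#' is recovered as `tanh(z)`, a two-sided p-value is computed from
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n` the number of time points
#' actually used, p-values are Benjamini-Hochberg corrected over the unique
#' pairs, and an edge is kept only when the corrected q-value falls below
#' `q` and the correlation is positive.
#'
#' @param fc FC matrix from [compute_fc()] (Fisher z values).
#' @param n_timepoints Number of time points used for the correlations;
#'   defaults to the `n_timepoints` attribute of `fc`.
#' @param q FDR threshold for an edge (default 0.001).
#' @return An `fc_graph`: symmetric 0/1 matrix with zero diagonal and
#'   attributes `q_threshold` and `n_edges`.
#' @export
binarize_fc <- function(fc, n_timepoints = attr(fc, "n_timepoints"), q = 0.001) {
  check_square(fc, "fc")
  assert_that(!is.null(n_timepoints) && n_timepoints > 3,
              "n_timepoints must exceed 3")
  r_mat <- tanh(fc)
  n <- nrow(fc)
  ut <- upper.tri(r_mat)
  r <- r_mat[ut]
  tstat <- r * sqrt((n_timepoints - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n_timepoints - 2)
  qv <- p.adjust(p, method = "BH")
  edge <- (qv < q) & (r > 0)
  adj <- matrix(0, n, n, dimnames = dimnames(fc))
  adj[ut] <- as.numeric(edge)
  adj <- adj + t(adj)
  structure(adj, q_threshold = q, n_edges = sum(edge),
            class = c("fc_graph", "matrix", "array"))
}

#' Stepwise functional connectivity degrees
#'
#' For each step `k`, counts the walks of exact length `k` from a seed set
#' to every ROI: `degrees[k, j] = sum over seeds s of (A^k)[s, j]`, computed
#' by iterated vector-matrix multiplication (no dense matrix power is ever
#' formed). Walks may revisit nodes; this is what seed-based stepwise
#' connectivity computes (simple-path counting would be intractable).
#'
#' @param graph Binary adjacency matrix (e.g. from [binarize_fc()]).
#' @param seeds Character vector of ROI labels, or integer indices.
#' @param max_steps Number of steps to compute (default 6).
#' @return An `sfc_map` list: `seeds`, `steps`, `degrees`
#'   (steps-by-ROI matrix), `normalized = FALSE`.
#' @export
sfc_degrees <- function(graph, seeds, max_steps = 6) {
  check_square(graph, "graph")
  assert_that(length(seeds) > 0, "seed set must be non-empty")
  labels <- rownames(graph) %||% default_labels(nrow(graph))
  idx <- if (is.character(seeds)) match(seeds, labels) else as.integer(seeds)
  assert_that(!anyNA(idx), "unknown seed ROI label")
  x <- numeric(nrow(graph))
  x[idx] <- 1
  degrees <- matrix(0, max_steps, nrow(graph),
                    dimnames = list(paste0("step", seq_len(max_steps)), labels))
  for (k in seq_len(max_steps)) {
    x <- as.numeric(x %*% graph)
    degrees[k, ] <- x
  }
  structure(list(seeds = labels[idx], steps = max_steps, degrees = degrees,
                 normalized = FALSE),
            class = "sfc_map")
}

#' @export
print.sfc_map <- function(x, ...) {
  cat("<sfc_map> ", x$steps, " steps x ", ncol(x$degrees), " ROIs, seeds: ",
      paste(head(x$seeds, 4), collapse = ", "),
      if (length(x$seeds) > 4) ", ..." else "",
      if (x$normalized) " (normalized)" else "", "\n", sep = "")
  invisible(x)
}

#' Min-max normalize an SFC map per step
#'
#' Rescales each step's degree vector into `[0, 1]`. A step with zero range
#' (constant degrees) maps to all zeros.
#'
#' @param m An `sfc_map` with raw degrees.
#' @return The normalized `sfc_map`.
#' @export
normalize_sfc <- function(m) {
  assert_that(inherits(m, "sfc_map"), "m must be an sfc_map")
  deg <- m$degrees
  for (k in seq_len(nrow(deg))) {
    rng <- range(deg[k, ])
    deg[k, ] <- if (rng[2] > rng[1]) (deg[k, ] - rng[1]) / (rng[2] - rng[1]) else 0
  }
  m$degrees <- deg
  m$normalized <- TRUE
  m
}

#' Combine subject- and group-level SFC maps
#'
#' Multiplies a subject's normalized SFC map elementwise with the
#' corresponding group-level normalized map at each step, which suppresses
#' steps/regions not supported at the group level.
#'
#' @param subject,group Normalized `sfc_map` objects of identical shape.
#' @return Combined `sfc_map`.
#' @export
combine_subject_group <- function(subject, group) {
  assert_that(inherits(subject, "sfc_map") && inherits(group, "sfc_map"),
              "inputs must be sfc_map objects")
  assert_that(subject$normalized && group$normalized,
              "both maps must be normalized before combining")
  assert_that(all(dim(subject$degrees) == dim(group$degrees)),
              "subject and group maps have different shapes")
  out <- subject
  out$degrees <- subject$degrees * group$degrees
  out
}

#' Convergence step of an SFC map
#'
#' Returns the smallest step `k` at which the spatial Pearson correlation
#' between consecutive step maps exceeds `r_threshold`. If a step has zero
#' variance the comparison is skipped (correlation taken as 0) with a
#' warning. If no step converges, the last step is returned with attribute
#' `converged = FALSE`.
#'
#' @param m An `sfc_map` with at least 2 steps.
#' @param r_threshold Correlation threshold (default 0.999).
#' @return Integer step, with attribute `converged`.
#' @export
convergence_step <- function(m, r_threshold = 0.999) {
  assert_that(inherits(m, "sfc_map"), "m must be an sfc_map")
  deg <- m$degrees
  assert_that(nrow(deg) >= 2, "need at least 2 steps")
  for (k in seq_len(nrow(deg) - 1)) {
    if (sd(deg[k, ]) == 0 || sd(deg[k + 1, ]) == 0) {
      warning("zero-variance step map at step ", k, "; correlation taken as 0")
      next
    }
    if (cor(deg[k, ], deg[k + 1, ]) > r_threshold) {
      return(structure(k, converged = TRUE))
    }
  }
  structure(nrow(deg), converged = FALSE)
}
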