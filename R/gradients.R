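#' Diffusion-map embedding of an affinity matrix
#'
#' Extracts low-dimensional connectivity gradients by the diffusion-map
#' algorithm: the affinity kernel is density-normalized with exponent
#' `alpha`, row-normalized to a Markov transition matrix, and
#' eigendecomposed through its symmetric conjugate. The trivial constant
#' eigenvector is dropped and each retained eigenvector is scaled by its
#' eigenvalue (diffusion time 0 convention). Eigenvector sign is made
#' deterministic by forcing each column's largest-magnitude entry positive.
#'
#' @param aff Affinity matrix (symmetric, values in `[0, 1]`), e.g. from
#'   [affinity_matrix()].
#' @param k Number of gradients to retain (default 10).
#' @param alpha Density-normalization exponent (default 0.5, the
#'   anisotropic-diffusion convention).
#' @return A `gradient_set` list with elements `coords` (ROI-by-k matrix,
#'   columns G1...Gk), `lambdas` (the k eigenvalues), `variance_explained`
#'   (each eigenvalue over the sum of all positive non-trivial eigenvalues),
#'   and `aligned_to` (`NA` until [align_gradients()] is applied).
#' @export
diffusion_gradients <- function(aff, k = 10, alpha = 0.5) {
  check_square(aff, "aff")
  r <- nrow(aff)
  assert_that(k < r, "k must be smaller than the number of ROIs")
  g <- igraph::graph_from_adjacency_matrix(
    (aff > 0) * 1, mode = "undirected", diag = FALSE)
  if (igraph::components(g)$no > 1) {
    stop("affinity graph is disconnected; use a denser affinity ",
         "(larger keep_fraction or different kernel)", call. = FALSE)
  }
  d <- rowSums(aff)
  w <- aff / outer(d^alpha, d^alpha)
  dw <- rowSums(w)
  s <- w / outer(sqrt(dw), sqrt(dw))
  s <- (s + t(s)) / 2
  es <- eigen(s, symmetric = TRUE)
  # first eigenvector is the trivial stationary direction (eigenvalue 1)
  lam <- es$values[-1]
  phi <- es$vectors[, -1, drop = FALSE]
  psi <- phi / sqrt(dw)  # right eigenvectors of the Markov matrix
  # unit-normalize for scale stability, then fix signs
  psi <- sweep(psi, 2, sqrt(colSums(psi^2)), "/")
  lam_k <- lam[seq_len(k)]
  psi_k <- psi[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(psi_k[, j]))
    if (psi_k[top, j] < 0) psi_k[, j] <- -psi_k[, j]
  }
  coords <- sweep(psi_k, 2, lam_k, "*")
  pos_sum <- sum(lam[lam > sqrt(.Machine$double.eps)])
  ve <- if (pos_sum > 0) pmax(lam_k, 0) / pos_sum else rep(0, k)
  rownames(coords) <- rownames(aff)
  colnames(coords) <- paste0("G", seq_len(k))
  structure(
    list(coords = coords, lambdas = lam_k, variance_explained = ve,
         aligned_to = NA_character_),
    class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat("<gradient_set> ", nrow(x$coords), " ROIs x ", ncol(x$coords),
      " gradients", sep = "")
  if (!is.na(x$aligned_to)) cat(" (aligned to ", x$aligned_to, ")", sep = "")
  cat("\n  variance explained: ",
      paste(sprintf("%.3f", x$variance_explained[seq_len(min(5, length(x$variance_explained)))]),
            collapse = " "), " ...\n", sep = "")
  invisible(x)
}

#' Procrustes alignment of a gradient set to a template
#'
#' Rigidly rotates (and possibly reflects) the subject's gradient
#' coordinates to best match a template in the least-squares sense. No
#' scaling or translation is applied, so all within-subject pairwise ROI
#' distances in gradient space are preserved.
#'
#' @param subject,template `gradient_set` objects with identical dimensions.
#' @param template_id Optional label stored in `aligned_to`.
#' @return The subject `gradient_set` with rotated `coords`.
#' @export
align_gradients <- function(subject, template, template_id = "template") {
  assert_that(inherits(subject, "gradient_set") && inherits(template, "gradient_set"),
              "subject and template must be gradient_set objects")
  assert_that(all(dim(subject$coords) == dim(template$coords)),
              "subject and template gradient dimensions differ")
  m <- crossprod(subject$coords, template$coords)
  sv <- svd(m)
  rot <- sv$u %*% t(sv$v)
  out <- subject
  out$coords <- subject$coords %*% rot
  colnames(out$coords) <- colnames(template$coords)
  out$aligned_to <- template_id
  out
}

#' Between-network gradient dispersion
#'
#' Difference between the mean gradient values of two networks on one
#' gradient: `mean(G[netA]) - mean(G[netB])`. Signed by default (so the
#' measure is antisymmetric in its network arguments); `absolute = TRUE`
#' returns the magnitude, which is the quantity compared across groups when
#' template orientation is arbitrary.
#'
#' @param g A `gradient_set`.
#' @param partition Named character vector mapping ROI label to network name.
#' @param netA,netB Network names.
#' @param gradient Gradient index (1 = principal gradient).
#' @param absolute Return `abs()` of the difference?
#' @return A single numeric value.
#' @export
dispersion_between <- function(g, partition, netA, netB, gradient = 1,
                               absolute = FALSE) {
  coords <- g$coords[, gradient]
  rois <- rownames(g$coords)
  a <- rois[partition[rois] == netA]
  b <- rois[partition[rois] == netB]
  assert_that(length(a) > 0, paste("no ROIs in network", netA))
  assert_that(length(b) > 0, paste("no ROIs in network", netB))
  d <- mean(coords[a]) - mean(coords[b])
  if (absolute) abs(d) else d
}

#' Within-network gradient dispersion
#'
#' Sum of squared distances of each ROI's gradient value to the subset
#' centroid, on a single gradient. Used for the intrinsic dispersion of the
#' semantic network's principal gradient.
#'
#' @param g A `gradient_set`.
#' @param rois Character vector of ROI labels (at least 2).
#' @param gradient Gradient index.
#' @return Nonnegative numeric value.
#' @export
dispersion_within <- function(g, rois, gradient = 1) {
  assert_that(length(rois) >= 2, "need at least 2 ROIs for within-network dispersion")
  v <- g$coords[rois, gradient]
  sum((v - mean(v))^2)
}

#' Full gradient pipeline over a set of subjects
#'
#' Runs the gradient chain (FC, row sparsification, affinity, diffusion
#' embedding) on every subject and on the template built from the average FC
#' matrix, then Procrustes-aligns each subject to the template so gradient
#' orientation is comparable across subjects. The template is the grand
#' average over all supplied subjects by default, which puts both groups in
#' one common orientation; pass `template_ids` to restrict the template to a
#' subset (e.g. one group).
#'
#' @param ts_list Named list of time-by-ROI matrices (one per subject).
#' @param k Number of gradients.
#' @param keep_fraction Row sparsification fraction (see [sparsify_rows()]).
#' @param kernel Affinity kernel (see [affinity_matrix()]).
#' @param alpha Diffusion density-normalization exponent.
#' @param template_ids Subjects used for the template (default: all).
#' @return List with `template` (`gradient_set`) and `subjects` (named list
#'   of aligned `gradient_set`s).
#' @export
gradient_pipeline <- function(ts_list, k = 10, keep_fraction = 0.10,
                              kernel = "normalized_angle", alpha = 0.5,
                              template_ids = names(ts_list)) {
  assert_that(is.list(ts_list) && length(ts_list) > 0, "ts_list must be a non-empty list")
  if (is.null(names(ts_list))) names(ts_list) <- paste0("sub", seq_along(ts_list))
  fcs <- lapply(ts_list, compute_fc)
  grad_of <- function(fc) {
    diffusion_gradients(affinity_matrix(sparsify_rows(fc, keep_fraction), kernel),
                        k = k, alpha = alpha)
  }
  mean_fc <- Reduce(`+`, fcs[template_ids]) / length(template_ids)
  diag(mean_fc) <- 0
  template <- grad_of(mean_fc)
  subjects <- lapply(fcs, function(fc) {
    align_gradients(grad_of(fc), template, template_id = "group_template")
  })
  list(template = template, subjects = subjects)
}
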