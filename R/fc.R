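#' Functional connectivity from ROI time series
#'
#' Computes the region-by-region functional connectivity (FC) matrix as
#' Fisher z-transformed Pearson correlations of the columns of a time-by-ROI
#' matrix. Correlations are clipped to `|r| <= 0.999999` before the arctanh
#' transform so perfectly (anti)correlated pairs stay finite; the diagonal is
#' set to zero.
#'
#' @param ts Numeric matrix, time points in rows and ROIs in columns. Column
#'   names are used as ROI labels; unnamed columns get default labels.
#' @return An object of class `fc_matrix`: a symmetric ROI-by-ROI numeric
#'   matrix with attributes `n_timepoints` (rows of `ts`) and zero diagonal.
#' @export
#' @examples
#' ts <- matrix(rnorm(40), 10, 4)
#' fc <- compute_fc(ts)
compute_fc <- function(ts) {
  assert_that(is.matrix(ts) && is.numeric(ts), "ts must be a numeric matrix")
  assert_that(nrow(ts) >= 4, "need at least 4 time points")
  labels <- colnames(ts) %||% default_labels(ncol(ts))
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    stop("constant time series for ROI(s): ",
         paste(labels[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- cor(ts)
  r <- pmin(pmax(r, -0.999999), 0.999999)
  z <- atanh(r)
  diag(z) <- 0
  dimnames(z) <- list(labels, labels)
  structure(z, n_timepoints = nrow(ts), class = c("fc_matrix", "matrix", "array"))
}

#' Row-wise sparsification of an FC matrix
#'
#' Zeroes all negative entries per row, then keeps only the strongest
#' `ceiling(keep_fraction * (R - 1))` remaining entries of each row (ties
#' broken in favour of the lower column index). The result need not be
#' symmetric; it feeds the affinity kernel of [affinity_matrix()].
#'
#' @param fc FC matrix from [compute_fc()] (any square numeric matrix works).
#' @param keep_fraction Fraction of off-diagonal entries kept per row,
#'   in `(0, 1]`. Default 0.10, i.e. the top 10 percent.
#' @return Sparsified matrix with the same dimnames.
#' @export
sparsify_rows <- function(fc, keep_fraction = 0.10) {
  check_square(fc, "fc")
  assert_that(keep_fraction > 0 && keep_fraction <= 1,
              "keep_fraction must be in (0, 1]")
  r <- nrow(fc)
  keep <- ceiling(keep_fraction * (r - 1))
  out <- matrix(0, r, r, dimnames = dimnames(fc))
  for (i in seq_len(r)) {
    row <- fc[i, ]
    row[row < 0] <- 0
    row[i] <- 0
    pos <- which(row > 0)
    if (length(pos) == 0) next
    # order by value descending, ties by lower column index first
    ord <- pos[order(-row[pos], pos)]
    sel <- ord[seq_len(min(keep, length(ord)))]
    out[i, sel] <- row[sel]
  }
  attr(out, "n_timepoints") <- attr(fc, "n_timepoints")
  out
}

#' Normalized-angle affinity between connectivity profiles
#'
#' Builds the affinity matrix used for diffusion embedding: the cosine
#' similarity between every pair of row profiles, mapped through the
#' normalized angle `1 - acos(cos)/pi` so values lie in `[0, 1]` with 1 for
#' identical, 0.5 for orthogonal and 0 for antipodal profiles. Plain cosine
#' (rescaled from `[-1, 1]`) is available via `kernel = "cosine"`.
#'
#' @param fc_sparse Row-sparsified FC matrix (see [sparsify_rows()]).
#' @param kernel `"normalized_angle"` (default) or `"cosine"`.
#' @return Symmetric affinity matrix with unit diagonal, class
#'   `affinity_matrix`, attribute `kernel`.
#' @export
affinity_matrix <- function(fc_sparse, kernel = c("normalized_angle", "cosine")) {
  kernel <- match.arg(kernel)
  check_square(fc_sparse, "fc_sparse")
  norms <- sqrt(rowSums(fc_sparse^2))
  if (any(norms == 0)) {
    labs <- rownames(fc_sparse) %||% as.character(seq_len(nrow(fc_sparse)))
    stop("all-zero connectivity profile for ROI(s): ",
         paste(labs[norms == 0], collapse = ", "), call. = FALSE)
  }
  x <- fc_sparse / norms
  cs <- tcrossprod(x)
  cs <- pmin(pmax(cs, -1), 1)
  a <- switch(kernel,
    normalized_angle = 1 - acos(cs) / pi,
    cosine = (cs + 1) / 2
  )
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- dimnames(fc_sparse)
  structure(a, kernel = kernel, class = c("affinity_matrix", "matrix", "array"))
}
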