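# shared fixtures built in code

# a gradient_set with hand-set coordinates
make_gradients <- function(coords) {
  colnames(coords) <- paste0("G", seq_len(ncol(coords)))
  if (is.null(rownames(coords))) {
    rownames(coords) <- sprintf("ROI%03d", seq_len(nrow(coords)))
  }
  structure(list(coords = coords,
                 lambdas = rep(0.5, ncol(coords)),
                 variance_explained = rep(1 / ncol(coords), ncol(coords)),
                 aligned_to = NA_character_),
            class = "gradient_set")
}

# adjacency matrix of the path graph P_n (1-2-...-n)
path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  dimnames(a) <- list(sprintf("ROI%03d", 1:n), sprintf("ROI%03d", 1:n))
  a
}

complete_graph <- function(n) {
  a <- matrix(1, n, n) - diag(n)
  dimnames(a) <- list(sprintf("ROI%03d", 1:n), sprintf("ROI%03d", 1:n))
  a
}

# brute-force count of length-k walks from any seed in `seeds` to every node
enumerate_walks <- function(adj, seeds, k) {
  n <- nrow(adj)
  counts <- numeric(n)
  walk <- function(node, left) {
    if (left == 0) {
      counts[node] <<- counts[node] + 1
      return(invisible())
    }
    for (nb in which(adj[node, ] > 0)) walk(nb, left - 1)
  }
  for (s in seeds) walk(s, k)
  counts
}

# independent step-up BH implementation (plain arithmetic)
manual_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    val <- p[o[i]] * m / i
    prev <- min(prev, val)
    q[o[i]] <- min(prev, 1)
  }
  q
}

# independent ApEn oracle: explicit window loops, self-matches included
manual_apen <- function(series, m = 2, r_factor = 0.2) {
  n <- length(series)
  r <- r_factor * stats::sd(series)
  phi <- function(k) {
    nw <- n - k + 1
    wins <- lapply(seq_len(nw), function(i) series[i:(i + k - 1)])
    logs <- sapply(seq_len(nw), function(i) {
      cnt <- sum(sapply(wins, function(w) max(abs(w - wins[[i]])) <= r))
      log(cnt / nw)
    })
    mean(logs)
  }
  phi(m) - phi(m + 1)
}
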