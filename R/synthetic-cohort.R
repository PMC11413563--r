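#' Specification of a synthetic cohort
#'
#' Bundles every parameter of the synthetic-data generators: cohort size,
#' parcellation size and network assignment, the planted gradient
#' "compression" group effect, embedding-cluster geometry for the two
#' groups, and the probabilistic-grammar parameters that shape syntactic
#' trees per group. The defaults emulate the study conditions the pipeline
#' is designed for: 29 subjects per group, 7 canonical resting-state
#' networks over 100 parcels, 240 retained volumes, 3 one-minute picture
#' descriptions per subject.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param n_rois Number of parcels (>= 3 per network).
#' @param n_timepoints Time points per scan (> `n_rois / 5`).
#' @param networks Network names in hierarchy order; ROIs are assigned to
#'   them in contiguous, near-equal blocks.
#' @param compression Strength of the planted group effect in `[0, 1]`; 0
#'   removes it.
#' @param c0,c1 Baseline and fully-compressed visual-to-default-mode factor
#'   correlation.
#' @param semantic_spread Embedding cluster noise SD for controls.
#' @param semantic_spread_fep Embedding cluster noise SD for patients
#'   (larger noise blurs topic clusters, the patient-like condition).
#' @param n_clusters,embed_dim Embedding cluster count and dimensionality.
#' @param tree_params Probabilistic-grammar parameters for controls:
#'   `p_np_embed` (NP-in-NP embedding), `p_vp_chain` (verb chaining),
#'   `mean_len` (loose utterance-length control).
#' @param tree_params_fep Same, for patients.
#' @param n_narratives Narratives per subject (default 3).
#' @param seed Master seed.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 29,
                        n_rois = 100,
                        n_timepoints = 240,
                        networks = c("VN", "SMN", "DAN", "VAN", "LN", "FPN", "DMN"),
                        compression = 0.8,
                        c0 = 0.1, c1 = 0.6,
                        semantic_spread = 0.15,
                        semantic_spread_fep = 0.9,
                        n_clusters = 5,
                        embed_dim = 50,
                        tree_params = list(p_np_embed = 0.15, p_vp_chain = 0.05,
                                           mean_len = 6, p_sprime = 0.12,
                                           p_trans = 0.8),
                        tree_params_fep = list(p_np_embed = 0.03, p_vp_chain = 0.75,
                                               mean_len = 6, p_sprime = 0.02,
                                               p_trans = 0.3),
                        n_narratives = 3,
                        seed = 1L) {
  assert_that(n_per_group >= 2, "n_per_group must be >= 2")
  assert_that(n_rois >= 3 * length(networks),
              "need at least 3 ROIs per network")
  assert_that(n_timepoints > n_rois / 5,
              "n_timepoints must exceed n_rois / 5")
  assert_that(compression >= 0 && compression <= 1,
              "compression must lie in [0, 1]")
  for (tp in list(tree_params, tree_params_fep)) {
    assert_that(all(c("p_np_embed", "p_vp_chain", "mean_len") %in% names(tp)),
                "tree_params needs p_np_embed, p_vp_chain, mean_len")
    assert_that(tp$p_np_embed >= 0 && tp$p_np_embed <= 1 &&
                  tp$p_vp_chain >= 0 && tp$p_vp_chain <= 1,
                "tree probabilities must lie in [0, 1]")
  }
  assert_that(semantic_spread > 0 && semantic_spread_fep > 0,
              "semantic spreads must be positive")
  network_labels <- rep(networks, length.out = 0)
  sizes <- rep(n_rois %/% length(networks), length(networks))
  sizes[seq_len(n_rois %% length(networks))] <-
    sizes[seq_len(n_rois %% length(networks))] + 1
  network_labels <- rep(networks, times = sizes)
  structure(
    list(n_per_group = n_per_group, n_rois = n_rois,
         n_timepoints = n_timepoints, networks = networks,
         network_labels = network_labels, compression = compression,
         c0 = c0, c1 = c1,
         semantic_spread = semantic_spread,
         semantic_spread_fep = semantic_spread_fep,
         n_clusters = n_clusters, embed_dim = embed_dim,
         tree_params = tree_params, tree_params_fep = tree_params_fep,
         n_narratives = n_narratives, seed = as.integer(seed)),
    class = "cohort_spec")
}

# internal: network-factor correlation matrix for one group.
# Networks sit on a 1-D unimodal-to-transmodal axis; correlation decays
# with axis distance, which gives the healthy cohort a genuine principal
# gradient for the embedding stage to recover. The two clinically
# interesting pairs are pinned: visual-default at c0 (healthy) rising to
# c0 + compression*(c1 - c0) (patients), somatomotor-default at c0
# (healthy) falling by a factor 0.8*compression (patients).
factor_correlation <- function(spec, group) {
  nets <- spec$networks
  k <- length(nets)
  pos <- seq_len(k)
  cmat <- spec$c0 + 0.4 * exp(-abs(outer(pos, pos, "-")) / 1.5)
  vn <- which(nets == "VN"); smn <- which(nets == "SMN")
  dmn <- which(nets == "DMN")
  pin <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }
  if (group == "HC" || spec$compression == 0) {
    cmat <- pin(cmat, vn, dmn, spec$c0)
    cmat <- pin(cmat, smn, dmn, spec$c0)
  } else {
    cmat <- pin(cmat, vn, dmn,
                spec$c0 + spec$compression * (spec$c1 - spec$c0))
    cmat <- pin(cmat, smn, dmn, spec$c0 * (1 - 0.8 * spec$compression))
  }
  diag(cmat) <- 1
  ch <- try(chol(cmat), silent = TRUE)
  if (inherits(ch, "try-error")) {
    stop("factor correlation matrix for group ", group,
         " is not positive definite; lower compression or c1, or use ",
         "fewer/more separated networks", call. = FALSE)
  }
  list(cmat = cmat, chol = ch)
}

# internal: per-ROI loading matrix on the network factors.
# Each ROI sits at a jittered position on the 1-D unimodal-to-transmodal
# axis and loads on every network factor with weight decaying in axis
# distance (rows L2-normalized). The jitter and smooth decay give networks
# internal heterogeneity and overlapping connectivity neighborhoods --
# without them, row sparsification leaves disjoint block profiles and the
# embedding cannot see any between-network structure. The parcellation
# (positions) is drawn once per spec and shared by both groups.
roi_loadings <- function(spec, group = "HC", tau = 1.0, jitter = 0.05,
                         end_shift = 0.5) {
  k <- length(spec$networks)
  pos <- seq_len(k)
  # ROIs tile the axis evenly (network labels are contiguous blocks along
  # it), with a small jitter; even coverage keeps the connectivity chain
  # homogeneous so the principal gradient is the axis itself
  withr_seed(derive_seed(spec$seed, "parcellation"), {
    a <- seq(0.6, k + 0.4, length.out = spec$n_rois) +
      runif(spec$n_rois, -jitter, jitter)
  })
  if (group == "FEP" && spec$compression > 0) {
    # hierarchy compression: patient loadings are smoother along the axis,
    # making connectivity profiles across the hierarchy globally more
    # similar -- the "smaller range, higher peak" compression -- which
    # shrinks the functional distance between the axis endpoints
    tau <- tau * (1 + spec$compression)
  }
  w <- exp(-abs(outer(a, pos, "-")) / tau)
  w / sqrt(rowSums(w^2))
}

#' Generate ROI time series for one group
#'
#' Each network carries a latent standard-normal factor; factors are
#' correlated according to the group's factor correlation matrix (see
#' [cohort_spec()] for the planted compression effect). Every ROI sits at a
#' jittered position on the unimodal-to-transmodal network axis and its
#' signal mixes the network factors with weights that decay in axis
#' distance (dominated by its own network), plus independent Gaussian
#' noise. The smooth loading profile gives networks internal heterogeneity
#' and overlapping connectivity neighborhoods, so the planted
#' factor-correlation effects are expressed in the sparsified connectivity
#' profiles the gradient pipeline actually sees. Deterministic given the
#' spec seed and group label; the ROI positions (the "parcellation") are
#' shared between groups.
#'
#' @param spec A `cohort_spec`.
#' @param group `"HC"` or `"FEP"`.
#' @param noise_sd ROI noise standard deviation (default 0.5).
#' @return Named list of time-by-ROI matrices, one per subject; ROI columns
#'   carry labels, and the list carries attribute `networks` (the ROI to
#'   network map).
#' @export
gen_timeseries <- function(spec, group = c("HC", "FEP"), noise_sd = 0.5) {
  group <- match.arg(group)
  fac <- factor_correlation(spec, group)
  r <- spec$n_rois
  tt <- spec$n_timepoints
  k <- length(spec$networks)
  w <- roi_loadings(spec, group)
  roi_labels <- default_labels(r)
  withr_seed(derive_seed(spec$seed, paste0("timeseries_", group)), {
    subs <- lapply(seq_len(spec$n_per_group), function(s) {
      z <- matrix(rnorm(tt * k), tt, k)
      f <- z %*% fac$chol
      ts <- f %*% t(w) + matrix(rnorm(tt * r, sd = noise_sd), tt, r)
      colnames(ts) <- roi_labels
      ts
    })
    names(subs) <- sprintf("%s_%02d", group, seq_len(spec$n_per_group))
    structure(subs, networks = setNames(spec$network_labels, roi_labels))
  })
}

#' Population FC implied by the generative model
#'
#' The ROI-by-ROI Pearson correlation matrix implied by the factor
#' correlation matrix, the axis-smoothed ROI loadings and the noise
#' variance -- the ground truth against which sample FC from
#' [gen_timeseries()] can be checked, and through which planted factor
#' correlations can be recovered from data.
#'
#' @param spec A `cohort_spec`.
#' @param group `"HC"` or `"FEP"`.
#' @param noise_sd Must match the value used in [gen_timeseries()].
#' @return ROI-by-ROI correlation matrix.
#' @export
population_fc <- function(spec, group = c("HC", "FEP"), noise_sd = 0.5) {
  group <- match.arg(group)
  fac <- factor_correlation(spec, group)
  w <- roi_loadings(spec, group)
  cv <- w %*% fac$cmat %*% t(w)
  diag(cv) <- diag(cv) + noise_sd^2
  stats::cov2cor(cv)
}

# internal: evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Generate clustered unit embeddings
#'
#' Stand-in for word or utterance embeddings: `n_clusters` cluster centers
#' are drawn uniformly on the unit sphere, each unit is its (round-robin
#' assigned) center plus isotropic Gaussian noise with SD `spread`, and
#' rows are L2-normalized. Small `spread` gives sharply separated topic
#' clusters; large `spread` blurs them into an undifferentiated cloud.
#'
#' @param n_units Number of units (>= 4, the minimum for a semantic graph).
#' @param n_clusters Number of clusters (<= `n_units`).
#' @param spread Noise SD around the cluster center.
#' @param dim Embedding dimension (default 50).
#' @param seed Integer seed.
#' @return Unit-by-dim matrix with unit-norm rows and labels
#'   `unit001, ...`; attribute `cluster` holds the assignment.
#' @export
gen_embeddings <- function(n_units, n_clusters, spread, dim = 50, seed = 1L) {
  assert_that(n_units >= 4,
              "n_units must be >= 4 (semantic graphs need at least 4 nodes)")
  assert_that(n_clusters >= 1 && n_clusters <= n_units,
              "n_clusters must lie in [1, n_units]")
  assert_that(spread >= 0, "spread must be nonnegative")
  withr_seed(seed, {
    centers <- matrix(rnorm(n_clusters * dim), n_clusters, dim)
    centers <- centers / sqrt(rowSums(centers^2))
    assign_to <- rep_len(seq_len(n_clusters), n_units)
    e <- centers[assign_to, , drop = FALSE] +
      matrix(rnorm(n_units * dim, sd = spread), n_units, dim)
    e <- e / sqrt(rowSums(e^2))
    rownames(e) <- default_labels(n_units, "unit")
    structure(e, cluster = assign_to)
  })
}

# ---- probabilistic grammar -------------------------------------------------

pcfg_np <- function(p, depth, cap) {
  if (depth < cap && runif(1) < p$p_np_embed) {
    inner <- pcfg_np(p, depth + 1, cap)
    pp_np <- pcfg_np(p, depth + 1, cap)
    pp <- list(label = "PP", children = list(
      list(label = "IN", children = list()), pp_np))
    return(list(label = "NP", children = list(inner, pp)))
  }
  kids <- list()
  if (runif(1) < 0.6) kids <- c(kids, list(list(label = "DT", children = list())))
  n_jj <- rbinom(1, 2, p$p_jj)
  if (n_jj > 0) {
    kids <- c(kids, replicate(n_jj, list(label = "JJ", children = list()),
                              simplify = FALSE))
  }
  kids <- c(kids, list(list(label = "NN", children = list())))
  list(label = "NP", children = kids)
}

pcfg_vp <- function(p, depth, cap) {
  if (depth < cap && runif(1) < p$p_vp_chain) {
    return(list(label = "VP", children = list(
      list(label = "VB", children = list()),
      pcfg_vp(p, depth + 1, cap))))
  }
  u <- runif(1)
  if (depth < cap && u < p$p_sprime) {
    sbar <- list(label = "SBAR", children = list(
      list(label = "IN", children = list()),
      pcfg_s(p, depth + 1, cap)))
    list(label = "VP", children = list(
      list(label = "VB", children = list()), sbar))
  } else if (u < p$p_sprime + (1 - p$p_sprime) * p$p_trans && depth < cap) {
    list(label = "VP", children = list(
      list(label = "VB", children = list()),
      pcfg_np(p, depth + 1, cap)))
  } else {
    list(label = "VP", children = list(list(label = "VB", children = list())))
  }
}

pcfg_s <- function(p, depth, cap) {
  if (depth >= cap) {
    # depth cap reached: minimal terminal expansion
    return(list(label = "S", children = list(
      list(label = "NP", children = list(list(label = "NN", children = list()))),
      list(label = "VP", children = list(list(label = "VB", children = list()))))))
  }
  list(label = "S", children = list(
    pcfg_np(p, depth + 1, cap), pcfg_vp(p, depth + 1, cap)))
}

#' Generate bracketed constituency trees
#'
#' Expands a small probabilistic grammar `n_utts` times: `S -> NP VP`;
#' `NP -> NP PP` with probability `p_np_embed`, else a flat `(DT) JJ* NN`;
#' `VP -> VB VP` (verb chaining) with probability `p_vp_chain`, else a
#' transitive, clausal (`VB SBAR`) or bare expansion. `mean_len` loosely
#' controls utterance length through the modifier rate. A sentence-final
#' punctuation leaf is attached so punctuation stripping is exercised.
#' Recursion is capped at `depth_cap`; at the cap a minimal terminal
#' expansion is emitted. Every string parses back losslessly.
#'
#' @param n_utts Number of utterances.
#' @param params List with `p_np_embed`, `p_vp_chain`, `mean_len`, and
#'   optionally `p_sprime` (clausal-complement rate, default 0.1).
#' @param seed Integer seed.
#' @param depth_cap Maximum expansion depth (default 12).
#' @return Character vector of bracketed tree strings.
#' @export
gen_trees <- function(n_utts, params, seed = 1L, depth_cap = 12) {
  assert_that(params$p_np_embed >= 0 && params$p_np_embed <= 1 &&
                params$p_vp_chain >= 0 && params$p_vp_chain <= 1,
              "tree probabilities must lie in [0, 1]")
  p <- params
  p$p_sprime <- params$p_sprime %||% 0.1
  p$p_trans <- params$p_trans %||% 0.7
  p$p_jj <- min(0.9, max(0, (p$mean_len - 5) / 6))
  withr_seed(seed, {
    vapply(seq_len(n_utts), function(i) {
      tree <- pcfg_s(p, 0, depth_cap)
      tree$children <- c(tree$children,
                         list(list(label = ".", children = list())))
      serialize_tree(structure(tree, class = "syn_tree"))
    }, character(1))
  })
}

#' Generate a full synthetic cohort
#'
#' Bundles the three generators plus subject covariates into the complete
#' input set of the pipeline: per-subject ROI time series (with the planted
#' gradient compression), per-narrative unit embeddings (patients drawn at
#' the blurred-cluster spread), per-narrative tree lists (patients drawn at
#' the chain-heavy, embedding-poor grammar), and a matched subject table
#' with age, sex and education generated independently of group.
#'
#' @param spec A `cohort_spec`.
#' @return A `synthetic_cohort` list: `subjects` (tibble with `id`,
#'   `group`, `age`, `sex`, `education`), `timeseries` (named list of
#'   time-by-ROI matrices), `networks` (ROI to network map), `embeddings`
#'   and `trees` (named lists, one element per subject, each a list with
#'   one element per narrative), and `spec`.
#' @export
gen_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "spec must come from cohort_spec()")
  ts_hc <- gen_timeseries(spec, "HC")
  ts_fep <- gen_timeseries(spec, "FEP")
  ids <- c(names(ts_hc), names(ts_fep))
  groups <- rep(c("HC", "FEP"), each = spec$n_per_group)
  subjects <- withr_seed(derive_seed(spec$seed, "covariates"), {
    tibble(id = ids, group = groups,
           age = rnorm(length(ids), 21.5, 3),
           sex = rbinom(length(ids), 1, 0.26),
           education = rbinom(length(ids), 1, 0.6))
  })
  spreads <- c(HC = spec$semantic_spread, FEP = spec$semantic_spread_fep)
  embeddings <- withr_seed(derive_seed(spec$seed, "embedding_sizes"), {
    lapply(seq_along(ids), function(i) {
      lapply(seq_len(spec$n_narratives), function(j) {
        n_units <- max(4L, rpois(1, 25))
        gen_embeddings(n_units, spec$n_clusters, spreads[[groups[i]]],
                       dim = spec$embed_dim,
                       seed = derive_seed(spec$seed,
                                          paste0("embed_", ids[i], "_", j)))
      })
    })
  })
  names(embeddings) <- ids
  tree_par <- list(HC = spec$tree_params, FEP = spec$tree_params_fep)
  trees <- withr_seed(derive_seed(spec$seed, "tree_sizes"), {
    lapply(seq_along(ids), function(i) {
      lapply(seq_len(spec$n_narratives), function(j) {
        n_utts <- max(3L, rpois(1, 10))
        gen_trees(n_utts, tree_par[[groups[i]]],
                  seed = derive_seed(spec$seed,
                                     paste0("trees_", ids[i], "_", j)))
      })
    })
  })
  names(trees) <- ids
  structure(
    list(subjects = subjects,
         timeseries = c(ts_hc, ts_fep),
         networks = attr(ts_hc, "networks"),
         embeddings = embeddings,
         trees = trees,
         spec = spec),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$subjects), " subjects (",
      sum(x$subjects$group == "HC"), " HC / ",
      sum(x$subjects$group == "FEP"), " FEP), ",
      x$spec$n_rois, " ROIs x ", x$spec$n_timepoints, " time points, ",
      x$spec$n_narratives, " narratives each\n", sep = "")
  invisible(x)
}
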