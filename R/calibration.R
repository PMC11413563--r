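#' Gradient-compression recovery across seed replicates
#'
#' For each replicate, generates both groups of a synthetic cohort, runs
#' the per-group gradient pipeline (subjects aligned to their own group
#' template) and records whether the patient group shows the smaller
#' magnitude of mean VN-DMN dispersion on the principal gradient -- the
#' planted compression direction.
#'
#' @param n_seeds Number of replicates.
#' @param base_seed Seed offset; replicate `i` uses `base_seed + i`.
#' @param ... Arguments forwarded to [cohort_spec()] (e.g. smaller
#'   `n_per_group` for quick checks).
#' @return Tibble: `seed`, `disp_hc`, `disp_fep`, `lower_in_fep`.
#' @export
dispersion_recovery <- function(n_seeds = 100, base_seed = 0, ...) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    spec <- cohort_spec(seed = derive_seed(base_seed + i, "dispersion"), ...)
    means <- vapply(c("HC", "FEP"), function(g) {
      ts <- gen_timeseries(spec, g)
      nets <- attr(ts, "networks")
      gp <- gradient_pipeline(ts, k = 10)
      mean(vapply(gp$subjects, dispersion_between, numeric(1),
                  partition = nets, netA = "VN", netB = "DMN", gradient = 1))
    }, numeric(1))
    tibble(seed = base_seed + i, disp_hc = means["HC"], disp_fep = means["FEP"],
           lower_in_fep = abs(means["FEP"]) < abs(means["HC"]))
  })
  dplyr::bind_rows(rows)
}

#' Semantic-graph direction recovery across seed replicates
#'
#' Per replicate, draws one narrative-sized embedding set per condition
#' (control spread vs patient spread), builds the thresholded graphs and
#' records whether the patient condition shows higher closeness centrality
#' and global efficiency and lower small-worldness.
#'
#' @param n_seeds Number of replicates.
#' @param base_seed Seed offset.
#' @param n_units,n_clusters,dim Embedding geometry (defaults follow
#'   [cohort_spec()]).
#' @param spread_hc,spread_fep Condition spreads.
#' @param n_null Null graphs for sigma.
#' @return Tibble: `seed`, `cc_up`, `ge_up`, `sigma_down`.
#' @export
semantic_recovery <- function(n_seeds = 100, base_seed = 0, n_units = 25,
                              n_clusters = 5, dim = 50,
                              spread_hc = cohort_spec()$semantic_spread,
                              spread_fep = cohort_spec()$semantic_spread_fep,
                              n_null = 20) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- derive_seed(base_seed + i, "semantic")
    one <- function(spread, tag) {
      e <- gen_embeddings(n_units, n_clusters, spread, dim = dim,
                          seed = derive_seed(s, tag))
      g <- select_threshold(similarity_matrix(e))
      m <- graph_metrics(g)
      m$sigma <- as.numeric(small_worldness(g, n_null = n_null,
                                            seed = derive_seed(s, paste0(tag, "_null"))))
      m
    }
    hc <- one(spread_hc, "hc")
    fep <- one(spread_fep, "fep")
    tibble(seed = base_seed + i,
           cc_up = fep$cc > hc$cc, ge_up = fep$ge > hc$ge,
           sigma_down = !is.na(fep$sigma) && !is.na(hc$sigma) &&
             fep$sigma < hc$sigma)
  })
  dplyr::bind_rows(rows)
}

#' Syntactic-tree direction recovery across seed replicates
#'
#' Per replicate, generates `n_utts` utterances per condition under the
#' control and patient grammars and records whether the condition means
#' reproduce the expected contrasts: patients higher on nodes, maximum and
#' mean depth and VP count; lower on depth approximate entropy, NP count,
#' NP nesting, NP length and VP length.
#'
#' @param n_seeds Number of replicates.
#' @param base_seed Seed offset.
#' @param n_utts Utterances per condition per replicate.
#' @param params_hc,params_fep Grammar parameter lists (defaults follow
#'   [cohort_spec()]).
#' @return Tibble with one logical column per direction plus `all_correct`.
#' @export
syntax_recovery <- function(n_seeds = 100, base_seed = 0, n_utts = 400,
                            params_hc = cohort_spec()$tree_params,
                            params_fep = cohort_spec()$tree_params_fep) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- derive_seed(base_seed + i, "syntax")
    mm <- function(params, tag) {
      colMeans(syntax_metrics_many(
        gen_trees(n_utts, params, seed = derive_seed(s, tag))), na.rm = TRUE)
    }
    a <- mm(params_hc, "hc")
    b <- mm(params_fep, "fep")
    tibble(seed = base_seed + i,
           nodes_up = b["nodes"] > a["nodes"],
           depth_up = b["depth"] > a["depth"],
           depth_mean_up = b["depth_mean"] > a["depth_mean"],
           apen_down = b["depth_apen"] < a["depth_apen"],
           np_count_down = b["np_count"] < a["np_count"],
           np_nest_down = b["np_nest"] < a["np_nest"],
           np_length_down = b["np_length"] < a["np_length"],
           vp_count_up = b["vp_count"] > a["vp_count"],
           vp_length_down = b["vp_length"] < a["vp_length"])
  })
  out <- dplyr::bind_rows(rows)
  out$all_correct <- apply(out[, -1], 1, all)
  out
}

#' Type-I error of the mass-univariate group map under the null
#'
#' Simulates a cohort with no group effect (independent standard-normal
#' ROI values), runs [mass_univariate()] and returns the proportion of ROIs
#' with p below `alpha`.
#'
#' @param n_rois Number of null ROIs.
#' @param n_per_group Subjects per group.
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @return Proportion of uncorrected p-values below `alpha`.
#' @export
mass_univariate_type1 <- function(n_rois = 1000, n_per_group = 20,
                                  alpha = 0.05, seed = 1L) {
  withr_seed(seed, {
    n <- 2 * n_per_group
    values <- matrix(rnorm(n * n_rois), n, n_rois)
    subjects <- data.frame(group = rep(c("HC", "FEP"), each = n_per_group),
                           age = rnorm(n, 21.5, 3),
                           sex = rbinom(n, 1, 0.26),
                           education = rbinom(n, 1, 0.6))
    res <- mass_univariate(values, subjects)
    mean(res$p < alpha)
  })
}

#' Power of the mass-univariate map for planted effects
#'
#' Plants a standardized group difference `d` in `n_true` of `n_rois` ROIs
#' and reports, per replicate, whether all planted ROIs are recovered at
#' `q < 0.05`.
#'
#' @param n_seeds Replicates.
#' @param base_seed Seed offset.
#' @param n_rois,n_true,n_per_group,d Simulation design.
#' @return Tibble: `seed`, `n_recovered`, `all_recovered`.
#' @export
mass_univariate_power <- function(n_seeds = 100, base_seed = 0, n_rois = 100,
                                  n_true = 10, n_per_group = 20, d = 1.5) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    withr_seed(derive_seed(base_seed + i, "mupower"), {
      n <- 2 * n_per_group
      values <- matrix(rnorm(n * n_rois), n, n_rois)
      grp <- rep(c(0, 1), each = n_per_group)
      values[, seq_len(n_true)] <- values[, seq_len(n_true)] + d * grp
      subjects <- data.frame(group = rep(c("HC", "FEP"), each = n_per_group),
                             age = rnorm(n, 21.5, 3),
                             sex = rbinom(n, 1, 0.26),
                             education = rbinom(n, 1, 0.6))
      res <- mass_univariate(values, subjects)
      rec <- sum(res$significant[seq_len(n_true)])
      tibble(seed = base_seed + i, n_recovered = rec,
             all_recovered = rec == n_true)
    })
  })
  dplyr::bind_rows(rows)
}

#' Wald-interval coverage of the Gamma-log GLM
#'
#' Simulates Gamma-distributed responses with log-linear mean structure and
#' reports the fraction of replicates whose 95 percent Wald interval for
#' the slope covers the true value.
#'
#' @param n_reps Replicates.
#' @param n Observations per replicate.
#' @param beta True slope on the log scale.
#' @param shape Gamma shape parameter.
#' @param seed Integer seed.
#' @return Coverage proportion in `[0, 1]`.
#' @export
glm_coverage <- function(n_reps = 200, n = 500, beta = 0.5, shape = 2,
                         seed = 1L) {
  withr_seed(seed, {
    hits <- vapply(seq_len(n_reps), function(i) {
      x <- rnorm(n)
      mu <- exp(0.5 + beta * x)
      y <- rgamma(n, shape = shape, rate = shape / mu)
      fit <- fit_glm(data.frame(y = y, x = x), y ~ x, family = "gamma")
      cf <- fit$coefficients[fit$coefficients$term == "x", ]
      (cf$estimate - 1.96 * cf$std_error) <= beta &&
        beta <= (cf$estimate + 1.96 * cf$std_error)
    }, logical(1))
    mean(hits)
  })
}

#' Calibration of the deviance goodness-of-fit test
#'
#' Under a correctly specified Gamma-log model, the bootstrap
#' goodness-of-fit test should reject at close to its nominal level (the
#' plug-in chi-square version is anti-conservative for skewed responses;
#' see [fit_glm()]).
#'
#' @param n_reps Replicates.
#' @param n Observations per replicate.
#' @param shape Gamma shape.
#' @param alpha Nominal level.
#' @param gof_method,gof_reps Passed to [fit_glm()].
#' @param seed Integer seed.
#' @return Rejection proportion.
#' @export
gof_calibration <- function(n_reps = 200, n = 300, shape = 2, alpha = 0.05,
                            gof_method = "bootstrap", gof_reps = 99,
                            seed = 1L) {
  withr_seed(seed, {
    rej <- vapply(seq_len(n_reps), function(i) {
      x <- rnorm(n)
      mu <- exp(0.5 + 0.3 * x)
      y <- rgamma(n, shape = shape, rate = shape / mu)
      fit_glm(data.frame(y = y, x = x), y ~ x, family = "gamma",
              gof_method = gof_method, gof_reps = gof_reps,
              gof_seed = derive_seed(seed, paste0("gof", i)))$gof_p < alpha
    }, logical(1))
    mean(rej)
  })
}

#' Recovery of a planted brain-language association
#'
#' Plants a log-scale slope of a language measure into a Gamma-generated
#' dispersion score at the study's sample size and reports, per replicate,
#' whether the measure survives FDR at `q < 0.05` among `n_noise` null
#' measures; also reports the null-measure false-positive rate.
#'
#' @param n_seeds Replicates.
#' @param base_seed Seed offset.
#' @param n Subjects (default 58).
#' @param slope Planted log-scale slope.
#' @param n_noise Number of null language measures fitted alongside.
#' @return Tibble: `seed`, `planted_q`, `recovered`, `null_fp_rate`.
#' @export
brainlang_recovery <- function(n_seeds = 100, base_seed = 0, n = 58,
                               slope = 0.5, n_noise = 5) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    withr_seed(derive_seed(base_seed + i, "brainlang"), {
      lang <- as.data.frame(matrix(rnorm(n * (n_noise + 1)), n))
      names(lang) <- c("planted", paste0("noise", seq_len(n_noise)))
      shape <- 3
      mu <- exp(0.2 + slope * lang$planted)
      disp <- data.frame(score = rgamma(n, shape = shape, rate = shape / mu))
      covs <- data.frame(age = rnorm(n, 21.5, 3), sex = rbinom(n, 1, 0.26),
                         education = rbinom(n, 1, 0.6))
      res <- brainlang_glm(disp, lang, covs)
      tibble(seed = base_seed + i,
             planted_q = res$q[res$measure == "planted"],
             recovered = res$q[res$measure == "planted"] < 0.05,
             null_fp_rate = mean(res$q[res$measure != "planted"] < 0.05))
    })
  })
  dplyr::bind_rows(rows)
}
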