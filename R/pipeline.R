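#' Gradient dispersion scores for a cohort
#'
#' Runs the gradient chain separately per group (each group's subjects are
#' aligned to their own group template, so orientation is consistent within
#' group) and extracts the four dispersion scores analyzed downstream:
#' between-network dispersion of VN-DMN and SMN-DMN on G1 and VN-SMN on G2,
#' plus the within-network dispersion of the semantic subset's principal
#' gradient (computed by re-running the identical pipeline on the subset
#' ROIs).
#'
#' @param cohort A `synthetic_cohort` (or any list with `timeseries`,
#'   `subjects`, `networks`).
#' @param semantic_networks Networks whose ROIs form the semantic subset
#'   (default DMN and LN, the default-mode plus limbic stand-in).
#' @param k Number of gradients.
#' @return Tibble with one row per subject: `id`, `group`, `vn_dmn_g1`,
#'   `smn_dmn_g1`, `vn_smn_g2`, `semn_g1_within`.
#' @export
cohort_dispersion <- function(cohort, semantic_networks = c("DMN", "LN"),
                              k = 10) {
  nets <- cohort$networks
  sem_rois <- names(nets)[nets %in% semantic_networks]
  rows <- lapply(split(cohort$subjects$id, cohort$subjects$group), function(ids) {
    gp <- gradient_pipeline(cohort$timeseries[ids], k = k)
    sem_ts <- lapply(cohort$timeseries[ids], function(x) x[, sem_rois])
    gp_sem <- gradient_pipeline(sem_ts, k = min(k, length(sem_rois) - 1))
    dplyr::bind_rows(lapply(ids, function(id) {
      g <- gp$subjects[[id]]
      tibble(
        id = id,
        vn_dmn_g1 = dispersion_between(g, nets, "VN", "DMN", 1),
        smn_dmn_g1 = dispersion_between(g, nets, "SMN", "DMN", 1),
        vn_smn_g2 = dispersion_between(g, nets, "VN", "SMN", 2),
        semn_g1_within = dispersion_within(gp_sem$subjects[[id]], sem_rois, 1))
    }))
  })
  dplyr::bind_rows(rows) |>
    dplyr::left_join(cohort$subjects[, c("id", "group")], by = "id") |>
    dplyr::relocate("group", .after = "id")
}

#' Seed-based SFC analysis for a cohort
#'
#' Builds the group-level significance-binarized graph from each group's
#' mean FC, computes seed-based stepwise degrees, min-max normalizes them,
#' and combines each subject's normalized map with its group map. Seed sets
#' default to the first two ROIs of the visual and somatomotor blocks (the
#' primary-area stand-ins).
#'
#' @param cohort A `synthetic_cohort`.
#' @param seed_sets Named list of ROI-label vectors; `NULL` picks V1/S1
#'   stand-ins automatically.
#' @param max_steps Number of steps (default 6).
#' @param q FDR edge threshold (default 0.001).
#' @return List with `group_maps` (nested: group, seed set ->
#'   normalized `sfc_map` with attribute `convergence`), and `subject_degrees`
#'   (tibble: `id`, `group`, `seed_set`, `step`, `roi`, `degree` of the
#'   combined map).
#' @export
cohort_sfc <- function(cohort, seed_sets = NULL, max_steps = 6, q = 0.001) {
  nets <- cohort$networks
  if (is.null(seed_sets)) {
    seed_sets <- list(V1 = head(names(nets)[nets == "VN"], 2),
                      S1 = head(names(nets)[nets == "SMN"], 2))
  }
  groups <- split(cohort$subjects$id, cohort$subjects$group)
  fcs <- lapply(cohort$timeseries, compute_fc)
  n_tp <- nrow(cohort$timeseries[[1]])
  group_maps <- lapply(groups, function(ids) {
    mean_fc <- Reduce(`+`, fcs[ids]) / length(ids)
    attr(mean_fc, "n_timepoints") <- n_tp
    bg <- binarize_fc(mean_fc, q = q)
    lapply(seed_sets, function(seeds) {
      m <- normalize_sfc(sfc_degrees(bg, seeds, max_steps))
      attr(m, "convergence") <- convergence_step(m)
      m
    })
  })
  subject_rows <- lapply(names(groups), function(grp) {
    dplyr::bind_rows(lapply(groups[[grp]], function(id) {
      bg <- binarize_fc(fcs[[id]], q = q)
      dplyr::bind_rows(lapply(names(seed_sets), function(ss) {
        m <- normalize_sfc(sfc_degrees(bg, seed_sets[[ss]], max_steps))
        comb <- combine_subject_group(m, group_maps[[grp]][[ss]])
        tidy.sfc_map(comb) |>
          dplyr::mutate(id = id, group = grp, seed_set = ss, .before = 1)
      }))
    }))
  })
  list(group_maps = group_maps, subject_degrees = dplyr::bind_rows(subject_rows))
}

#' Language metrics for a cohort
#'
#' Semantic-graph metrics (per narrative, averaged) and syntactic-tree
#' metrics (utterance means averaged across narratives) for every subject.
#'
#' @param cohort A `synthetic_cohort`.
#' @param n_null Null-graph count for small-worldness.
#' @return Tibble, one row per subject, with semantic (`unit_num`, `cc`,
#'   `ge`, `clustering`, `sigma`) and syntax columns.
#' @export
cohort_language <- function(cohort, n_null = 20) {
  seed0 <- cohort$spec$seed %||% 1L
  rows <- lapply(cohort$subjects$id, function(id) {
    sem <- analyze_narratives(cohort$embeddings[[id]], n_null = n_null,
                              seed = derive_seed(seed0, paste0("sigma_", id)))
    utts <- dplyr::bind_rows(lapply(seq_along(cohort$trees[[id]]), function(j) {
      syntax_metrics_many(cohort$trees[[id]][[j]]) |>
        dplyr::mutate(narrative = j)
    }))
    syn <- aggregate_syntax(utts)
    dplyr::bind_cols(tibble(id = id), sem[, -1], syn)
  })
  dplyr::bind_rows(rows) |>
    dplyr::left_join(cohort$subjects[, c("id", "group")], by = "id") |>
    dplyr::relocate("group", .after = "id")
}

#' Group statistics for language measures
#'
#' One GLM per language measure: measure ~ group + age + sex + education,
#' with the response family chosen as in the analysis convention --
#' Tweedie-log for word counts (`leaf_num`), Gamma-log for unit counts
#' (`unit_num`), Gaussian-identity otherwise. Group-term z values are
#' BH-corrected across measures.
#'
#' @param language Tibble from [cohort_language()].
#' @param subjects Subject covariate table (`id`, `group`, `age`, `sex`,
#'   `education`).
#' @return Tibble: `measure`, `family`, `estimate`, `z`, `p`, `q`, `gof_p`.
#' @export
language_group_stats <- function(language, subjects) {
  dat <- dplyr::left_join(language,
                          subjects[, c("id", "age", "sex", "education")],
                          by = "id")
  dat$group <- factor(dat$group, levels = c("HC", "FEP"))
  measures <- setdiff(names(language),
                      c("id", "group", "n_narratives", "threshold", "n_flagged"))
  fam_of <- function(m) {
    if (m == "leaf_num") "tweedie" else if (m == "unit_num") "gamma"
    else "gaussian"
  }
  rows <- lapply(measures, function(m) {
    d <- dat[!is.na(dat[[m]]), ]
    fit <- fit_glm(d, stats::as.formula(paste(m, "~ group + age + sex + education")),
                   family = fam_of(m))
    cf <- fit$coefficients[fit$coefficients$term == "groupFEP", ]
    tibble(measure = m, family = fam_of(m), estimate = cf$estimate,
           z = cf$z, p = cf$p, gof_p = fit$gof_p)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- bh_fdr(out$p)
  out[, c("measure", "family", "estimate", "z", "p", "q", "gof_p")]
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end driver: generates (or accepts) a synthetic cohort, computes
#' the four gradient dispersion scores per subject, compares them between
#' groups with Mann-Whitney tests (BH-corrected), runs seed-based SFC,
#' computes language metrics, group GLMs for the language measures, and the
#' brain-language Tweedie GLMs. Reruns with the same spec are
#' deterministic.
#'
#' @param spec A `cohort_spec`, or an already generated `synthetic_cohort`.
#' @param out_dir Optional directory: results are written as TSV plus a
#'   JSON manifest.
#' @param n_null Null-graph count for small-worldness.
#' @return A `pipeline_result` list: `cohort`, `dispersion`,
#'   `dispersion_tests`, `sfc`, `language`, `group_stats`, `brainlang`,
#'   `manifest`.
#' @export
run_pipeline <- function(spec = cohort_spec(), out_dir = NULL, n_null = 20) {
  cohort <- if (inherits(spec, "synthetic_cohort")) spec else gen_cohort(spec)
  disp <- cohort_dispersion(cohort)
  disp_tests <- dplyr::bind_rows(lapply(
    c("vn_dmn_g1", "smn_dmn_g1", "vn_smn_g2", "semn_g1_within"),
    function(sc) {
      hc <- disp[[sc]][disp$group == "HC"]
      fep <- disp[[sc]][disp$group == "FEP"]
      # orient signed between-network scores by the HC mean so the
      # magnitude comparison is meaningful across groups
      s <- if (sc == "semn_g1_within") 1 else sign(mean(hc))
      mw <- mann_whitney(s * hc, s * fep)
      tibble(score = sc, mean_hc = mean(s * hc), mean_fep = mean(s * fep),
             u = mw$statistic, p = mw$p)
    }))
  disp_tests$q <- bh_fdr(disp_tests$p)
  sfc <- cohort_sfc(cohort)
  language <- cohort_language(cohort, n_null = n_null)
  gstats <- language_group_stats(language, cohort$subjects)
  lang_measures <- language[, setdiff(names(language),
                                      c("id", "group", "n_narratives",
                                        "threshold", "n_flagged"))]
  covs <- cohort$subjects[, c("age", "sex", "education")]
  bl <- brainlang_glm(
    disp[, c("vn_dmn_g1", "smn_dmn_g1", "vn_smn_g2", "semn_g1_within")],
    lang_measures, covariates = covs)
  manifest <- list(
    package = "psychspeech",
    version = as.character(utils::packageVersion("psychspeech")),
    config_hash = rlang::hash(cohort$spec),
    seed = cohort$spec$seed,
    n_subjects = nrow(cohort$subjects),
    n_rois = cohort$spec$n_rois,
    n_timepoints = cohort$spec$n_timepoints)
  result <- structure(
    list(cohort = cohort, dispersion = disp, dispersion_tests = disp_tests,
         sfc = sfc, language = language, group_stats = gstats,
         brainlang = bl, manifest = manifest),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> config", x$manifest$config_hash, "\n")
  cat("dispersion group tests:\n")
  print(x$dispersion_tests)
  invisible(x)
}

#' Write pipeline outputs as TSV plus a JSON manifest
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(result$dispersion, "dispersion.tsv")
  wt(result$dispersion_tests, "dispersion_tests.tsv")
  wt(result$sfc$subject_degrees, "sfc_subject_degrees.tsv")
  wt(result$language, "language_metrics.tsv")
  wt(result$group_stats, "language_group_stats.tsv")
  wt(result$brainlang, "brainlang_glm.tsv")
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
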