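#' Fit a generalized linear model from the pipeline's family set
#'
#' Fits `formula` on `data` by iteratively reweighted least squares through
#' [stats::glm()], with one of the three response families used for
#' language and dispersion measures: Gaussian with identity link, Gamma
#' with log link, or Tweedie with log link (variance power fixed at
#' `tweedie_power`, default 1.5, between the Poisson and Gamma cases).
#' Coefficients are reported with Wald z statistics and BH-corrected
#' q-values, plus a deviance goodness-of-fit test (scaled deviance against
#' chi-square on the residual degrees of freedom, with Pearson-estimated
#' dispersion).
#'
#' @param data Data frame.
#' @param formula Model formula.
#' @param family `"gaussian"`, `"gamma"` or `"tweedie"`.
#' @param tweedie_power Tweedie variance power in (1, 2).
#' @param gof_method `"pearson_chisq"` (scaled deviance against chi-square;
#'   the classical plug-in test, anti-conservative for strongly skewed
#'   responses) or `"bootstrap"` (parametric bootstrap of the scaled
#'   deviance, calibrated by construction; costs `gof_reps` refits).
#' @param gof_reps Bootstrap replicates when `gof_method = "bootstrap"`.
#' @param gof_seed Seed for the bootstrap GOF.
#' @return A `ps_glm` object: list with `fit` (the `glm` object),
#'   `coefficients` tibble (`term`, `estimate`, `std_error`, `z`, `p`, `q`),
#'   `family`, `link`, `deviance`, `gof_p`.
#' @export
fit_glm <- function(data, formula, family = c("gaussian", "gamma", "tweedie"),
                    tweedie_power = 1.5,
                    gof_method = c("pearson_chisq", "bootstrap"),
                    gof_reps = 99, gof_seed = 1L) {
  gof_method <- match.arg(gof_method)
  family <- match.arg(family)
  fam <- switch(family,
    gaussian = gaussian(),
    gamma = Gamma(link = "log"),
    tweedie = mgcv::Tweedie(p = tweedie_power, link = "log"))
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (family != "gaussian" && any(y <= 0)) {
    bad <- which(y <= 0)
    stop("log-link family requires positive response; offending rows: ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  }
  x <- stats::model.matrix(formula, data)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    aliased <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- glm(formula, data = data, family = fam)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  coefs <- tibble(term = names(est), estimate = unname(est),
                  std_error = unname(se), z = unname(z), p = unname(p),
                  q = bh_fdr(unname(p)))
  df_res <- fit$df.residual
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  dispersion <- pearson / df_res
  gof_stat <- fit$deviance / dispersion
  if (gof_method == "pearson_chisq") {
    gof_p <- pchisq(gof_stat, df = df_res, lower.tail = FALSE)
  } else {
    gof_p <- gof_bootstrap_p(fit, family, tweedie_power, dispersion,
                             gof_stat, gof_reps, gof_seed)
  }
  structure(list(fit = fit, coefficients = coefs, family = family,
                 link = fam$link, deviance = fit$deviance, gof_p = gof_p),
            class = "ps_glm")
}

# internal: parametric-bootstrap p-value for the scaled-deviance GOF
gof_bootstrap_p <- function(fit, family, tweedie_power, dispersion,
                            gof_stat, gof_reps, gof_seed) {
  mu <- stats::fitted(fit)
  n <- length(mu)
  x <- stats::model.matrix(fit)
  fam <- fit$family
  withr_seed(gof_seed, {
    stats_null <- vapply(seq_len(gof_reps), function(b) {
      yb <- switch(family,
        gaussian = rnorm(n, mu, sqrt(dispersion)),
        gamma = rgamma(n, shape = 1 / dispersion, rate = 1 / (dispersion * mu)),
        tweedie = mgcv::rTweedie(mu, p = tweedie_power, phi = dispersion))
      fb <- suppressWarnings(glm.fit(x, yb, family = fam))
      db <- sum(stats::residuals.glm(structure(fb, class = c("glm", "lm")),
                                     type = "pearson")^2) / fb$df.residual
      fb$deviance / db
    }, numeric(1))
    (1 + sum(stats_null >= gof_stat)) / (1 + gof_reps)
  })
}

#' @export
print.ps_glm <- function(x, ...) {
  cat("<ps_glm> family ", x$family, "(", x$link, "), deviance ",
      signif(x$deviance, 4), ", GOF p = ", signif(x$gof_p, 3), "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Mass-univariate group comparison across ROIs
#'
#' Fits, for every ROI, an ordinary linear model of the ROI value on group
#' plus covariates (the parcel-level stand-in for surface-based linear
#' models), extracts the group-term t statistic and p-value, and corrects
#' across ROIs with BH-FDR. All ROIs share one design matrix, so the fits
#' are computed through a single QR decomposition.
#'
#' @param values Subject-by-ROI numeric matrix.
#' @param subjects Data frame aligned with the rows of `values`, containing
#'   `group_col` and the covariate columns.
#' @param group_col Name of the group factor column (default `"group"`).
#' @param covariates Covariate column names (default age, sex, education).
#' @param q_threshold Significance threshold on q (default 0.05).
#' @return Tibble with one row per ROI: `roi`, `estimate`, `t`, `p`, `q`,
#'   `significant`.
#' @export
mass_univariate <- function(values, subjects, group_col = "group",
                            covariates = c("age", "sex", "education"),
                            q_threshold = 0.05) {
  assert_that(is.matrix(values), "values must be a subject-by-ROI matrix")
  assert_that(nrow(values) == nrow(subjects),
              "values rows and subjects rows differ")
  grp <- factor(subjects[[group_col]])
  assert_that(nlevels(grp) == 2 && all(table(grp) >= 2),
              "need two groups with >= 2 subjects each")
  covariates <- intersect(covariates, names(subjects))
  df <- data.frame(.group = grp, subjects[covariates])
  x <- stats::model.matrix(~ ., data = df)
  qx <- qr(x)
  if (qx$rank < ncol(x)) stop("collinear covariates in design", call. = FALSE)
  fit <- stats::lm.fit(x, values)
  res <- as.matrix(fit$residuals)
  df_res <- nrow(x) - ncol(x)
  sigma2 <- colSums(res^2) / df_res
  xtx_inv <- chol2inv(qr.R(qx))
  j <- which(colnames(x) == paste0(".group", levels(grp)[2]))
  beta <- as.matrix(fit$coefficients)[j, ]
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df_res)
  q <- bh_fdr(p)
  tibble(roi = colnames(values) %||% default_labels(ncol(values)),
         estimate = unname(beta), t = unname(tstat), p = unname(p),
         q = unname(q), significant = unname(q < q_threshold))
}

#' Brain-language prediction models
#'
#' Fits one GLM per (gradient-dispersion score, language measure) pair:
#' `dispersion ~ measure + covariates`, Tweedie family with log link by
#' default. Because a log link needs a positive response, signed
#' between-network dispersion scores are shifted by `|min| + eps` when
#' `shift = TRUE` (the shift is recorded in the output). Language-measure
#' z-values are BH-corrected within each dispersion score, mirroring a
#' heatmap column.
#'
#' @param dispersion Data frame of dispersion scores (one column per
#'   score), rows = subjects.
#' @param language Data frame of language measures, rows = subjects.
#' @param covariates Data frame of covariates (e.g. age, sex, education),
#'   rows = subjects; may be `NULL`.
#' @param family,tweedie_power Passed to [fit_glm()].
#' @param shift Shift nonpositive responses to positivity?
#' @param eps Shift margin (default 1e-6).
#' @return Tibble: `dispersion`, `measure`, `estimate`, `z`, `p`, `q`,
#'   `shift_applied`.
#' @export
brainlang_glm <- function(dispersion, language, covariates = NULL,
                          family = "tweedie", tweedie_power = 1.5,
                          shift = TRUE, eps = 1e-6) {
  dispersion <- as.data.frame(dispersion)
  language <- as.data.frame(language)
  assert_that(nrow(dispersion) == nrow(language),
              "dispersion and language must describe the same subjects")
  cov_df <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  out <- list()
  for (dname in names(dispersion)) {
    y <- dispersion[[dname]]
    shift_amt <- 0
    if (family != "gaussian" && any(y <= 0)) {
      if (!shift) {
        stop("nonpositive dispersion '", dname,
             "' under a log link; set shift = TRUE", call. = FALSE)
      }
      shift_amt <- abs(min(y)) + eps
      y <- y + shift_amt
    }
    rows <- lapply(names(language), function(mname) {
      dat <- data.frame(.y = y, .m = language[[mname]])
      if (!is.null(cov_df)) dat <- cbind(dat, cov_df)
      form <- stats::as.formula(paste(".y ~ .m +",
                                      paste(c("1", names(cov_df)), collapse = " + ")))
      fit <- fit_glm(dat, form, family = family, tweedie_power = tweedie_power)
      cf <- fit$coefficients[fit$coefficients$term == ".m", ]
      tibble(dispersion = dname, measure = mname, estimate = cf$estimate,
             z = cf$z, p = cf$p, shift_applied = shift_amt)
    })
    col <- dplyr::bind_rows(rows)
    col$q <- bh_fdr(col$p)
    out[[dname]] <- col
  }
  dplyr::bind_rows(out)[, c("dispersion", "measure", "estimate", "z", "p",
                            "q", "shift_applied")]
}
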