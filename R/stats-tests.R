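#' Welch's two-sample t test with Cohen's d
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom and a two-sided p-value, from either summary statistics or raw
#' samples. The effect size is Cohen's d with the equal-weight pooled SD,
#' `(mean2 - mean1) / sqrt((sd1^2 + sd2^2) / 2)`, the convention that
#' reproduces published effect sizes computed from group summaries.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries. Alternatively pass raw
#'   samples via `x` and `y`.
#' @param x,y Optional raw numeric samples; when given, summaries are
#'   computed from them.
#' @return Tibble with `statistic`, `df`, `p`, `effect_size`, `effect_name`.
#' @export
#' @examples
#' welch_t(0.18, 0.26, 29, 1.09, 1.12, 29)
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2, x = NULL, y = NULL) {
  if (!is.null(x) || !is.null(y)) {
    assert_that(!is.null(x) && !is.null(y), "supply both x and y")
    mean1 <- mean(x); sd1 <- sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- sd(y); n2 <- length(y)
  }
  assert_that(n1 >= 2 && n2 >= 2, "each group needs n >= 2")
  assert_that(sd1 >= 0 && sd2 >= 0, "standard deviations must be nonnegative")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  if (se == 0) {
    tstat <- 0
    df <- n1 + n2 - 2
    p <- 1
  } else {
    tstat <- (mean1 - mean2) / se
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    p <- 2 * pt(-abs(tstat), df)
  }
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  d <- if (pooled == 0) NA_real_ else (mean2 - mean1) / pooled
  tibble(statistic = tstat, df = df, p = p,
         effect_size = d, effect_name = "cohens_d")
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's chi-square statistic without continuity correction (df = 1),
#' with the contingency coefficient `C = sqrt(chi2 / (chi2 + n))` as effect
#' size. The uncorrected statistic is the convention that reproduces
#' published group-comparison tables computed from proportions.
#'
#' @param a,b,c,d Cell counts: rows are groups, columns the binary outcome,
#'   so the table is `rbind(c(a, b), c(c, d))`.
#' @return Tibble with `statistic`, `df`, `p`, `effect_size`, `effect_name`.
#' @export
#' @examples
#' chi2_2x2(7, 22, 8, 21)  # 7/29 vs 8/29 female
chi2_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  assert_that(all(counts >= 0), "counts must be nonnegative")
  n <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("zero margin in 2x2 table", call. = FALSE)
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  cc <- sqrt(chi2 / (chi2 + n))
  tibble(statistic = chi2, df = 1, p = p,
         effect_size = cc, effect_name = "contingency_coefficient")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test: exact enumeration when both samples have at
#' most 8 observations and no ties are present, otherwise the normal
#' approximation with tie correction (no continuity correction).
#'
#' @param x,y Numeric samples.
#' @return Tibble with `statistic` (U for the first sample), `df` (`NA`),
#'   `p`, `effect_size` (rank-biserial correlation), `effect_name`.
#' @export
mann_whitney <- function(x, y) {
  assert_that(length(x) >= 1 && length(y) >= 1, "both samples must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !has_ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE))
  u <- unname(wt$statistic)
  rb <- 2 * u / (length(x) * length(y)) - 1  # rank-biserial correlation
  tibble(statistic = u, df = NA_real_, p = min(wt$p.value, 1),
         effect_size = rb, effect_name = "rank_biserial")
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment with monotonicity enforcement; a thin, named
#' wrapper so every module corrects p-values through the same call.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `pvals`.
#' @export
bh_fdr <- function(pvals) {
  assert_that(all(pvals >= 0 & pvals <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Partial Spearman correlation
#'
#' Rank-transforms all variables, residualizes `x` and `y` on the
#' covariates by least squares, and computes the Pearson correlation of the
#' residuals with a t-based p-value on `n - 2 - k` degrees of freedom. With
#' no covariates this reduces to the plain Spearman correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame / matrix of covariates (e.g.
#'   diagnosis).
#' @return Tibble with `statistic` (rho), `df`, `p`, `effect_size`,
#'   `effect_name`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  assert_that(length(y) == n, "x and y must have equal length")
  k <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  assert_that(n > k + 2, "too few observations for the covariate count")
  if (sd(x) == 0 || sd(y) == 0) stop("constant variable", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (k > 0) {
    cv <- as.data.frame(covariates)
    cv[] <- lapply(cv, function(col) if (is.numeric(col)) rank(col) else col)
    mm <- stats::model.matrix(~ ., data = cv)
    rx <- stats::resid(stats::lm.fit(mm, rx))
    ry <- stats::resid(stats::lm.fit(mm, ry))
  }
  rho <- cor(rx, ry)
  df <- n - 2 - k
  tstat <- rho * sqrt(df / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  tibble(statistic = rho, df = df, p = p,
         effect_size = rho, effect_name = "partial_spearman_rho")
}
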