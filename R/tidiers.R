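#' Tidy a gradient set
#'
#' @param x A `gradient_set`.
#' @param ... Unused.
#' @return Tibble with columns `roi`, `gradient`, `value`.
#' @export
tidy.gradient_set <- function(x, ...) {
  as_tibble(x$coords, rownames = "roi") |>
    tidyr::pivot_longer(-"roi", names_to = "gradient", values_to = "value")
}

#' One-row summary of a gradient set
#'
#' @param x A `gradient_set`.
#' @param ... Unused.
#' @return Tibble with `n_roi`, `k`, `var_explained_g1`, `var_explained_g2`,
#'   `aligned`.
#' @export
glance.gradient_set <- function(x, ...) {
  tibble(n_roi = nrow(x$coords), k = ncol(x$coords),
         var_explained_g1 = x$variance_explained[1],
         var_explained_g2 = if (length(x$variance_explained) > 1)
           x$variance_explained[2] else NA_real_,
         aligned = !is.na(x$aligned_to))
}

#' Tidy an SFC map
#'
#' @param x An `sfc_map`.
#' @param ... Unused.
#' @return Tibble with `step`, `roi`, `degree`.
#' @export
tidy.sfc_map <- function(x, ...) {
  as_tibble(x$degrees, rownames = "step") |>
    tidyr::pivot_longer(-"step", names_to = "roi", values_to = "degree") |>
    dplyr::mutate(step = as.integer(sub("step", "", .data$step)))
}

#' Tidy a fitted pipeline GLM
#'
#' @param x A `ps_glm`.
#' @param ... Unused.
#' @return The coefficient tibble (`term`, `estimate`, `std_error`, `z`,
#'   `p`, `q`).
#' @export
tidy.ps_glm <- function(x, ...) x$coefficients

#' One-row summary of a fitted pipeline GLM
#'
#' @param x A `ps_glm`.
#' @param ... Unused.
#' @return Tibble with `family`, `link`, `deviance`, `df_residual`, `gof_p`.
#' @export
glance.ps_glm <- function(x, ...) {
  tibble(family = x$family, link = x$link, deviance = x$deviance,
         df_residual = x$fit$df.residual, gof_p = x$gof_p)
}
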