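#' Round half away from zero
#'
#' Arithmetic rounding used for proportional-threshold edge counts: 0.5 always
#' rounds up in magnitude, unlike base [round()] which rounds half to even.
#'
#' @param x Numeric vector.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -0.5))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from the master seed plus a stage name, so reruns are reproducible and
#' stages are decoupled from each other's random streams.
#'
#' @param master Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# internal: stop unless condition holds
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# internal: check a square symmetric numeric matrix
check_square <- function(x, name = "matrix") {
  assert_that(is.matrix(x) && is.numeric(x), paste(name, "must be a numeric matrix"))
  assert_that(nrow(x) == ncol(x), paste(name, "must be square"))
  invisible(x)
}

# internal: default ROI labels V1..Vn when none supplied
default_labels <- function(n, prefix = "ROI") {
  sprintf("%s%03d", prefix, seq_len(n))
}
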