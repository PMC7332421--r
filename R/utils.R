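#' @import data.table
#' @importFrom stats plogis qlogis pnorm qnorm rnorm runif rmultinom median
#'   mad sd quantile predict lowess uniroot var coef setNames as.formula
#'   weighted.mean
#' @importFrom utils head tail
NULL

utils::globalVariables(c(
  ".", "..cols", "location_id", "region_id", "super_region_id", "sex",
  "cohort", "midpoint", "asymptote", "target_mean", "p0", "p0_shift",
  "dispersion", "n_eff", "provider", "quantity", "value", "se", "age",
  "year", "age_lo", "age_hi", "pred_var", "u_provider", "u_nested",
  "region", "super_region", "value_adj", "y", "gap", "pairing_id",
  "bias", "age_mid", "source_age", "accum_years", "origin_provider",
  "prior_logit", "resid_logit", "draw", "bin", "prop", "weight",
  "mean_years", "prop_zero", "is_gold", "year_x", "year_y",
  "lv", "sexf", "yr_c", "loc_f", "prov_f", "grp", "y_corr", "v_x", "v_y",
  "age_x", "age_y", "delta", "src_age_int", "value_logit", "sigma_p2",
  "sigma2", "held_out", "predicted", "error", "period", "entity",
  "post_mean", "prior", "forecast", "metric", "lower", "upper"))

#' Clipped logit transform
#'
#' Proportions observed in survey tabulations can be exactly 0 or 1; all
#' modelling stages operate on the logit scale, so values are clipped to
#' \code{[eps, 1 - eps]} first.
#'
#' @param p numeric vector of proportions.
#' @param eps clipping bound (default \code{1e-4}).
#' @return \code{qlogis} of the clipped values.
#' @export
logit_clip <- function(p, eps = 1e-4) {
  qlogis(pmin(pmax(p, eps), 1 - eps))
}

#' Inverse logit
#' @param x numeric vector on the logit scale.
#' @return proportions in (0, 1).
#' @export
inv_logit <- function(x) plogis(x)

# Deterministic derivation of stage seeds from one master seed.
# Keeps every derived seed a valid 32-bit integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(world = 11L, survey = 23L, gpr = 37L, ensemble = 41L,
               holdout = 53L, draws = 59L, misc = 71L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else 97L
  as.integer((as.numeric(seed) * 1009 + off * 9973) %% 2147483647)
}

# number of attainment bins: 0..18 completed years, top-coded at 18
EDU_BINS <- 0:18

bin_cols <- function() paste0("p", EDU_BINS)

# mean years of schooling of a 19-bin distribution (vectorised over rows
# when given a matrix)
dist_mean <- function(p) {
  if (is.matrix(p)) as.vector(p %*% EDU_BINS) else sum(p * EDU_BINS)
}

# delta-method standard error on the logit scale for a proportion-type
# value with natural-scale SE
logit_se <- function(value, se, eps = 1e-4) {
  v <- pmin(pmax(value, eps), 1 - eps)
  se / (v * (1 - v))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

assert_distribution <- function(p, tol = 1e-8) {
  if (any(p < -tol)) stop_arg("distribution has negative bins")
  if (abs(sum(p) - 1) > tol) stop_arg("distribution does not sum to 1 (sum = %.10f)", sum(p))
  invisible(TRUE)
}
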