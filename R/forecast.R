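## Rate-of-change forecasting.
##
## Each single-year bin's proportion is projected on the logit scale using
## the average annual logit change over the last 15 observed years
## (2004-2018 differences).  Because per-bin logit projection does not
## preserve the simplex, each projected year is renormalised after the
## back-transform.  The forecast replaces cohort-informed estimates only
## where cohorts cannot inform them: from 2019 for ages 25-29, 2024 for
## 30-34, 2029 for 35-40.

#' Average annual logit rate of change per bin over 2004--2018
#'
#' \deqn{ROC_k = \sum_{i=2004}^{2018}
#'   \frac{logit(p_{k,i}) - logit(p_{k,i-1})}{15}}
#' (telescoping to \eqn{[logit(p_{k,2018}) - logit(p_{k,2003})]/15}).
#'
#' @param years integer years of the series; must cover 2003--2018.
#' @param mat years x 19 matrix of distributions.
#' @param window first/last year of the ROC window (default 2003, 2018).
#' @param eps clipping bound before logit (default \code{1e-6}).
#' @return numeric vector of 19 per-bin rates (logit units / year).
#' @export
compute_roc <- function(years, mat, window = c(2003, 2018), eps = 1e-6) {
  need <- window[1]:window[2]
  missing_years <- setdiff(need, years)
  if (length(missing_years))
    stop_arg("series is missing years: %s",
             paste(missing_years, collapse = ", "))
  idx <- match(need, years)
  lp <- qlogis(pmin(pmax(mat[idx, , drop = FALSE], eps), 1 - eps))
  n <- diff(window)
  colSums(apply(lp, 2, diff) / n)
}

#' Forecast start year for an age group
#'
#' 2019 for ages 25--29, 2024 for 30--34, 2029 for 35--40 (cohort
#' extrapolation covers older ages until then).
#' @param age age in years (25--40).
#' @return integer start year.
#' @export
forecast_start_year <- function(age) {
  if (age < 25 || age > 40) stop_arg("forecast covers ages 25-40")
  if (age <= 29) 2019L else if (age <= 34) 2024L else 2029L
}

#' Project a distribution forward with per-bin logit rates
#'
#' Applies one logit step per year (\code{logit(p) + ROC}), back-transforms
#' and renormalises after every step.  Chaining k one-year projections is
#' bit-identical to one k-year projection.
#'
#' @param dist_base 19-bin distribution at \code{base_year}.
#' @param roc per-bin rates from [compute_roc()].
#' @param base_year year of \code{dist_base} (default 2018).
#' @param horizon_year last forecast year (<= 2030).
#' @param eps clipping bound before logit.
#' @return matrix of distributions for years \code{base_year + 1} ..
#'   \code{horizon_year} (rows named by year, each summing to 1).
#' @export
project <- function(dist_base, roc, base_year = 2018, horizon_year = 2030,
                    eps = 1e-6) {
  if (horizon_year > 2030) stop_arg("horizon is capped at 2030")
  if (length(roc) != length(dist_base))
    stop_arg("roc and distribution lengths differ")
  yrs <- seq(base_year + 1, horizon_year)
  out <- matrix(0, length(yrs), length(dist_base),
                dimnames = list(yrs, names(dist_base)))
  p <- dist_base
  for (i in seq_along(yrs)) {
    lp <- qlogis(pmin(pmax(p, eps), 1 - eps)) + roc
    p <- plogis(lp)
    p <- p / sum(p)
    out[i, ] <- p
  }
  out
}

#' Mean years of schooling of a distribution
#'
#' \eqn{\sum_k k \, p_k} over bins 0--18.
#' @param dist 19-bin distribution.
#' @return mean years.
#' @export
mean_from_distribution <- function(dist) {
  sum(EDU_BINS * dist)
}
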