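#' Extract modelling summaries from observation tabulations
#'
#' Stages 1--4 of the pipeline model two scalar summaries of each survey
#' cell on the logit scale: mean years of schooling divided by 18
#' (\code{"mean18"}) and the proportion with zero years (\code{"prop_zero"}).
#' Standard errors come from the multinomial sampling model at the cell's
#' effective sample size; infinite sample sizes get a small SE floor.
#'
#' @param obs observation table (see [simulate_survey()] /
#'   [read_observations()]).
#' @param hierarchy hierarchy table; region and super-region columns are
#'   merged in.
#' @param se_floor minimum standard error (default \code{1e-4}).
#' @return long \code{data.table} of quantity points with columns
#'   \code{quantity, location_id, region_id, super_region_id, provider,
#'   year, sex, age, n_eff, value, se, pred_var}.
#' @export
points_from_observations <- function(obs, hierarchy, se_floor = 1e-4) {
  P <- as.matrix(obs[, bin_cols(), with = FALSE])
  m <- dist_mean(P)
  v <- as.vector(P %*% (EDU_BINS^2)) - m^2
  n <- obs$n_eff
  mean18 <- pmin(pmax(m / 18, 1e-4), 1 - 1e-4)
  se_mean18 <- pmax(sqrt(pmax(v, 0) / ifelse(is.finite(n), n, Inf)) / 18, se_floor)
  pz <- pmin(pmax(P[, 1], 1e-4), 1 - 1e-4)
  se_pz <- pmax(sqrt(pz * (1 - pz) / ifelse(is.finite(n), n, Inf)), se_floor)

  base <- obs[, .(location_id, provider, year, sex, age, n_eff)]
  pts <- data.table::rbindlist(list(
    cbind(base, data.table::data.table(quantity = "mean18", value = mean18,
                                       se = se_mean18)),
    cbind(base, data.table::data.table(quantity = "prop_zero", value = pz,
                                       se = se_pz))))
  pts[, pred_var := 0]
  merge(pts, hierarchy, by = "location_id")
}
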