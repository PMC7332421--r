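## Cohort extrapolation.
##
## Adult cohorts (age >= 25) are assumed educationally stable, so repeat
## observations of the same birth cohort measure survey artefacts plus any
## residual drift (differential mortality, migration).  The stage:
##   1. forms all qualifying pairs of repeat cohort observations
##      (gap <= 10 years, both after 1990, both ages >= 25);
##   2. removes a per-survey-pairing bias, estimated as the mean annualised
##      change of cohorts passing through ages 60-70 between the two waves,
##      so that the average change at 65 is zero;
##   3. fits a mixed model for the annual logit change by age (natural
##      spline with a knot at 70, location-within-super-region intercepts);
##   4. projects each observation to target ages by accumulating predicted
##      annual changes, with prediction variance growing with the span.

#' Build repeat-cohort observation pairs
#'
#' All pairs of observations of the same (quantity, location, sex, birth
#' cohort) at different survey years, subject to the two filters: years at
#' most 10 apart, both observation years strictly after 1990 (and both ages
#' at least 25).  The logit difference is annualised: later minus earlier,
#' divided by the year gap.
#'
#' @param points quantity-point table (adjusted); \code{cohort} is derived
#'   as \code{year - age}.
#' @param max_gap maximum year gap (default 10).
#' @param min_year both observation years must exceed this (default 1990).
#' @return \code{data.table} of pairs with annualised difference \code{y},
#'   midpoint age \code{age_mid}, and a \code{pairing_id} identifying the
#'   two survey waves.
#' @export
build_pairs <- function(points, max_gap = 10, min_year = 1990) {
  pts <- data.table::copy(points)
  pts[, cohort := year - age]
  pts <- pts[age >= 25]
  pairs <- merge(
    pts[, .(quantity, location_id, region_id, super_region_id, sex, cohort,
            provider_x = provider, year_x = year, age_x = age,
            v_x = value)],
    pts[, .(quantity, location_id, sex, cohort,
            provider_y = provider, year_y = year, age_y = age,
            v_y = value)],
    by = c("quantity", "location_id", "sex", "cohort"),
    allow.cartesian = TRUE)
  pairs <- pairs[year_x > year_y]          # x = later wave, y = earlier
  pairs <- pairs[year_x - year_y <= max_gap &
                 year_y > min_year & year_x > min_year]
  if (!nrow(pairs)) return(pairs)
  pairs[, gap := year_x - year_y]
  pairs[, y := (logit_clip(v_x) - logit_clip(v_y)) / gap]
  pairs[, age_mid := (age_x + age_y) / 2]
  pairs[, pairing_id := paste(quantity, location_id, sex,
                              provider_y, year_y, provider_x, year_x,
                              sep = "|")]
  pairs
}

#' Estimate and remove per-pairing survey bias
#'
#' The bias of a survey pairing is the mean annualised logit change of its
#' cohorts observed in the 60--70 age window (midpoint age), where true
#' change should be negligible.  Subtracting it centres the pairing's
#' average change at age 65 at zero.
#'
#' @param pairs output of [build_pairs()].
#' @param window age window treated as change-free (default \code{c(60, 70)}).
#' @return the pairs table with columns \code{bias} and corrected
#'   \code{y_corr = y - bias}; pairings with no window cohorts get bias 0
#'   with a warning.
#' @export
estimate_survey_bias <- function(pairs, window = c(60, 70)) {
  out <- data.table::copy(pairs)
  btab <- out[age_mid >= window[1] & age_mid <= window[2],
              .(bias = mean(y)), by = pairing_id]
  out <- merge(out, btab, by = "pairing_id", all.x = TRUE)
  n_missing <- length(unique(out$pairing_id[is.na(out$bias)]))
  if (n_missing > 0)
    warning(sprintf("%d pairing(s) have no cohorts aged %d-%d; bias set to 0",
                    n_missing, window[1], window[2]))
  out[is.na(bias), bias := 0]
  out[, y_corr := y - bias]
  out
}

#' Mean corrected change at the window centre, per pairing
#'
#' Diagnostic for the normalisation target: after bias removal, the average
#' annual change at 65 (centre of the 60--70 window) is zero for every
#' pairing that had window cohorts.
#' @param pairs bias-corrected pairs.
#' @param window age window (default \code{c(60, 70)}).
#' @return \code{data.table} of pairing-level mean corrected change.
#' @export
window_center_change <- function(pairs, window = c(60, 70)) {
  pairs[age_mid >= window[1] & age_mid <= window[2],
        .(change_at_center = mean(y_corr)), by = pairing_id]
}

#' Fit the aging model for annual logit change
#'
#' Mixed model \code{y_corr ~ ns(age, knot 70) + (1 | super_region/location)}
#' fitted by REML on the annualised, bias-corrected pair differences.
#'
#' @param pairs bias-corrected pairs (must carry \code{y_corr}).
#' @param hierarchy hierarchy table (unused beyond validation; pairs carry
#'   their own region columns).
#' @param knot spline knot age (default 70).
#' @return an \code{edu_aging_fit} with the model and a precomputed table of
#'   predicted annual change at half-ages 25.5 .. 94.5 (population level).
#' @export
fit_aging_model <- function(pairs, hierarchy = NULL, knot = 70) {
  if (nrow(pairs) < 20L)
    stop_arg("need >= 20 pairs to fit the aging model (have %d)", nrow(pairs))
  span <- range(pairs$age_mid)
  if (diff(span) < 20)
    stop_arg("insufficient age span for the aging model: %.1f-%.1f",
             span[1], span[2])
  dat <- data.table::copy(pairs)
  kn <- if (knot > span[1] && knot < span[2]) knot else numeric(0)
  bk <- c(25, 95)
  n_loc <- length(unique(dat$location_id))
  n_sr <- length(unique(dat$super_region_id))
  re_term <- if (n_sr > 1L && n_loc > n_sr)
    "(1 | super_region_id) + (1 | location_id)" else "(1 | location_id)"
  form <- as.formula(paste(
    "y_corr ~ splines::ns(age_mid, knots = kn, Boundary.knots = bk) +",
    re_term))
  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    message = function(m) invokeRestart("muffleMessage"))
  half_ages <- seq(25.5, 94.5, by = 1)
  pred <- predict(fit, newdata = data.frame(age_mid = half_ages),
                  re.form = NA)
  re <- lme4::ranef(fit)
  u_loc <- setNames(re$location_id[[1]], rownames(re$location_id))
  structure(list(model = fit, knot = kn, boundary = bk,
                 half_ages = half_ages, annual_change = as.numeric(pred),
                 u_location = u_loc,
                 sigma2_resid = stats::sigma(fit)^2),
            class = "edu_aging_fit")
}

#' @export
print.edu_aging_fit <- function(x, ...) {
  cat("<edu_aging_fit> annual logit change by age (population level)\n")
  sel <- x$half_ages %in% c(30.5, 50.5, 70.5, 90.5)
  print(round(setNames(x$annual_change[sel], x$half_ages[sel]), 5))
  invisible(x)
}

# cumulative predicted logit change from age 25 to integer age a
aging_cumulative <- function(fit, ages) {
  cum <- c(0, cumsum(fit$annual_change))   # cum[k] = change from 25 to 24+k
  idx <- ages - 25 + 1
  if (any(idx < 1 | idx > length(cum)))
    stop_arg("age out of aging-model support (25-95)")
  cum[idx]
}

#' Project observations across ages by accumulating annual changes
#'
#' Each source point (age >= 25) is carried to every target age by summing
#' the model's predicted annual logit changes between the two ages (forward
#' or backward); the calendar year moves with the cohort.  Accumulated model
#' error (residual variance per year crossed) is added to the point's
#' prediction variance.
#'
#' @param points quantity-point table (adjusted); rows with age < 25 are
#'   dropped.
#' @param fit an \code{edu_aging_fit}.
#' @param target_ages integer ages to fill (values < 25 are skipped).
#' @param year_range optional length-2 year window for the filled points.
#' @return a quantity-point table with filled values; extra columns
#'   \code{source_age}, \code{accum_years}, \code{origin_provider}; the
#'   original value is reproduced exactly at \code{target_age == source_age}.
#' @export
extrapolate_cohort <- function(points, fit, target_ages,
                               year_range = c(1970, 2018)) {
  target_ages <- sort(unique(as.integer(target_ages)))
  target_ages <- target_ages[target_ages >= 25]
  pts <- points[age >= 25]
  if (!nrow(pts) || !length(target_ages))
    return(pts[0][, `:=`(source_age = numeric(0), accum_years = numeric(0),
                         origin_provider = character(0))])
  pts <- data.table::copy(pts)
  pts[, cohort := year - age]
  pts[, src_age_int := as.integer(round(age))]

  filled <- data.table::rbindlist(lapply(target_ages, function(a) {
    dt <- data.table::copy(pts)
    dt[, delta := aging_cumulative(fit, a) - aging_cumulative(fit, src_age_int)]
    dt[, `:=`(source_age = age, origin_provider = provider,
              accum_years = abs(a - src_age_int),
              age = as.numeric(a), year = cohort + a)]
    dt[, value := plogis(logit_clip(value) + delta)]
    dt[, pred_var := pred_var + accum_years * fit$sigma2_resid]
    dt
  }))
  filled <- filled[year >= year_range[1] & year <= year_range[2]]
  filled[, c("delta", "src_age_int", "cohort") := NULL]
  filled[]
}
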