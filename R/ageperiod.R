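## Age-period prior model.
##
## Per sex, region and quantity, the cohort-filled points P'' are modelled
## on the logit scale as
##
##   logit(P'') = beta_{s,r} + delta_{s,r} * year + I_{s,r}(age) + alpha
##
## where I is a natural spline on age (knots at 45 and 65 where the data
## span them) and alpha is a random intercept.  The equation's grouping is
## country-age(-sex); since fits are per sex, the default grouping is
## country x age, with a config switch for country only.  Predictions on a
## full location-age-year grid form the GPR prior mean ("the mean
## function").

#' Fit the age-period mixed model for one sex, region and quantity
#'
#' @param points P'' quantity-point table (cohort-filled).
#' @param sex_ sex to subset to.
#' @param region region id to subset to.
#' @param quantity \code{"mean18"} or \code{"prop_zero"}.
#' @param alpha random-intercept grouping: \code{"country_age"} (default,
#'   honouring the country-age-sex subscript) or \code{"country"}.
#' @param knots age-spline knots (default 45 and 65); knots outside the
#'   observed age range are dropped.
#' @param year_center year subtracted from the year covariate for
#'   conditioning (default 1994, the midpoint of 1970--2018).
#' @return an \code{edu_ap_fit}.
#' @export
fit_age_period <- function(points, sex_, region, quantity,
                           alpha = c("country_age", "country"),
                           knots = c(45, 65), year_center = 1994) {
  alpha <- match.arg(alpha)
  sel <- points$sex == sex_ & points$region_id == region &
    points$quantity == quantity
  dat <- points[which(sel)]
  if (nrow(dat) < 30L)
    stop_arg("need >= 30 points for the age-period fit (have %d)", nrow(dat))
  if (diff(range(dat$year)) < 10)
    stop_arg("age-period fit needs >= 10 years of span")
  n_ages <- length(unique(dat$age))
  if (n_ages < 3L)
    stop_arg("age-period fit needs >= 3 distinct ages")
  dat <- data.table::copy(dat)
  dat[, lv := logit_clip(value)]
  dat[, yr_c := year - year_center]
  dat[, grp := if (alpha == "country_age")
    paste(location_id, age, sep = ":") else location_id]

  ar <- range(dat$age)
  kn <- knots[knots > ar[1] & knots < ar[2]]
  # keep the fixed-age part below the number of distinct ages
  while (length(kn) + 1L >= n_ages && length(kn) > 0L) kn <- kn[-length(kn)]
  bk <- ar
  age_term <- if (n_ages >= 2L)
    "splines::ns(age, knots = kn, Boundary.knots = bk)" else NULL
  fixed <- paste(c("yr_c", age_term), collapse = " + ")
  form <- as.formula(paste("lv ~", fixed, "+ (1 | grp)"))
  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    message = function(m) invokeRestart("muffleMessage"))
  re <- lme4::ranef(fit)$grp
  structure(list(model = fit, sex = sex_, region = region,
                 quantity = quantity, alpha = alpha, knots = kn,
                 boundary = bk, year_center = year_center,
                 alpha_effects = setNames(re[[1]], rownames(re)),
                 sigma2_resid = stats::sigma(fit)^2),
            class = "edu_ap_fit")
}

#' @export
print.edu_ap_fit <- function(x, ...) {
  fe <- lme4::fixef(x$model)
  cat(sprintf("<edu_ap_fit> sex %s, region %s, quantity %s\n",
              x$sex, x$region, x$quantity))
  cat(sprintf("  intercept %.4f, year trend %.5f / yr, %d alpha groups\n",
              fe[["(Intercept)"]],
              if ("yr_c" %in% names(fe)) fe[["yr_c"]] else NA_real_,
              length(x$alpha_effects)))
  invisible(x)
}

#' Predict the age-period prior on a grid
#'
#' @param fit an \code{edu_ap_fit}.
#' @param grid \code{data.table} with columns \code{location_id, age, year}
#'   (sex and quantity are the fit's own).
#' @return the grid with \code{prior_logit} and \code{prior} (inverse-logit)
#'   columns; random intercepts are included for in-sample groups and 0 for
#'   unseen ones.
#' @export
predict_age_period <- function(fit, grid) {
  out <- data.table::copy(data.table::as.data.table(grid))
  out[, yr_c := year - fit$year_center]
  out[, grp := if (fit$alpha == "country_age")
    paste(location_id, age, sep = ":") else location_id]
  lv <- predict(fit$model, newdata = out, re.form = NULL,
                allow.new.levels = TRUE)
  out[, prior_logit := as.numeric(lv)]
  out[, prior := plogis(prior_logit)]
  out[, c("yr_c", "grp") := NULL]
  out[]
}
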