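## Inter-provider bias adjustment.
##
## Systematic differences between data providers (census vs household
## surveys, say) are estimated with a linear mixed model per region and
## quantity on the logit scale:
##
##   logit(P) = b0 + b1*age + b2*sex + b3*location + b4*year
##              + u_provider + u_location:provider
##
## u_provider captures the region-wide average bias of each provider;
## the nested u_location:provider captures residual location-specific bias.
## Every provider is then shifted to the gold standard: the difference
## (u_gold - u_provider) is added to all of that provider's points on the
## logit scale, plus the nested difference in locations where gold-standard
## data exist.

#' Fit the provider-bias mixed model for one region and quantity
#'
#' @param points quantity-point table (see [points_from_observations()]).
#' @param region region id to subset to.
#' @param quantity \code{"mean18"} or \code{"prop_zero"}.
#' @return an object of class \code{edu_bias_fit} carrying the fitted
#'   \pkg{lme4} model, the provider random effects \code{u_provider} and the
#'   nested \code{u_nested} effects (named \code{"location:provider"}).
#' @export
fit_bias_model <- function(points, region, quantity) {
  sel <- points$region_id == region & points$quantity == quantity
  dat <- points[which(sel)]
  if (length(unique(dat$provider)) < 2L)
    stop_arg("degenerate design: region %s has a single data provider", region)
  if (nrow(dat) < 10L)
    stop_arg("need >= 10 points in region %s (have %d)", region, nrow(dat))
  dat <- data.table::copy(dat)
  dat[, lv := logit_clip(value)]
  dat[, sexf := as.numeric(sex == "female")]
  dat[, yr_c := year - mean(year)]
  dat[, loc_f := factor(location_id)]
  dat[, prov_f := factor(provider)]

  terms <- c("yr_c")
  if (length(unique(dat$age)) > 1L) terms <- c("age", terms)
  if (length(unique(dat$sexf)) > 1L) terms <- c(terms, "sexf")
  if (length(unique(dat$loc_f)) > 1L) terms <- c(terms, "loc_f")
  if (length(unique(dat$yr_c)) < 2L) terms <- setdiff(terms, "yr_c")
  fixed <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  form <- as.formula(paste("lv ~", fixed,
                           "+ (1 | prov_f) + (1 | loc_f:prov_f)"))
  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    message = function(m) invokeRestart("muffleMessage"))
  re <- lme4::ranef(fit)
  u_provider <- setNames(re$prov_f[[1]], rownames(re$prov_f))
  u_nested <- setNames(re$`loc_f:prov_f`[[1]], rownames(re$`loc_f:prov_f`))
  # The provider and nested groupings can trade variance freely when a
  # provider's bias is constant across locations (the nested BLUPs can
  # represent a pure provider shift).  Reported provider effects are
  # therefore the provider BLUP plus the location-average of its nested
  # BLUPs, and nested effects are centred within provider; the total
  # adjustment u_provider + u_nested is invariant to this re-allocation.
  nest_prov <- sub("^.*:", "", names(u_nested))
  prov_mean <- tapply(u_nested, nest_prov, mean)
  u_provider <- u_provider + ifelse(names(u_provider) %in% names(prov_mean),
                                    prov_mean[names(u_provider)], 0)
  u_nested <- u_nested - prov_mean[nest_prov]
  structure(list(model = fit, region = region, quantity = quantity,
                 u_provider = u_provider, u_nested = u_nested,
                 providers = levels(dat$prov_f)),
            class = "edu_bias_fit")
}

#' @export
print.edu_bias_fit <- function(x, ...) {
  cat(sprintf("<edu_bias_fit> region %s, quantity %s\n", x$region, x$quantity))
  cat("provider effects (u):\n")
  print(round(x$u_provider, 4))
  invisible(x)
}

#' Shift all providers to the gold standard
#'
#' Each point's logit value is shifted by \code{u_gold - u_provider}; in
#' locations that themselves have gold-standard data the nested difference
#' \code{u_location:gold - u_location:provider} is applied as well.
#' Gold-standard points are unchanged and SEs pass through untouched.
#'
#' @param points quantity-point table restricted to the fit's region and
#'   quantity (rows outside are returned unchanged).
#' @param fit an \code{edu_bias_fit}.
#' @param gold_map data.frame with columns \code{region} and
#'   \code{provider}: the gold-standard provider of each region.
#' @return the points table with adjusted \code{value}.
#' @export
apply_adjustment <- function(points, fit, gold_map) {
  gold <- gold_map$provider[match(fit$region, gold_map$region)]
  if (is.na(gold))
    stop_arg("gold_map has no provider for region %s", fit$region)
  out <- data.table::copy(points)
  sel <- out$region_id == fit$region & out$quantity == fit$quantity
  if (!any(sel)) return(out)

  u <- fit$u_provider
  if (!gold %in% names(u))
    stop_arg("gold provider %s absent from fit for region %s", gold, fit$region)
  unknown <- setdiff(unique(out$provider[sel]), names(u))
  if (length(unknown)) {
    warning(sprintf("providers not in fit passed through unadjusted: %s",
                    paste(unknown, collapse = ", ")))
  }
  shift <- rep(0, nrow(out))
  known <- sel & out$provider %in% names(u)
  shift[known] <- u[gold] - u[out$provider[known]]

  # nested effects only where the location has gold-standard data
  gold_locs <- unique(out$location_id[sel & out$provider == gold])
  nest_key <- function(loc, prov) paste(loc, prov, sep = ":")
  un <- fit$u_nested
  nested_sel <- known & out$location_id %in% gold_locs
  if (any(nested_sel) && length(un)) {
    kg <- nest_key(out$location_id[nested_sel], gold)
    kp <- nest_key(out$location_id[nested_sel], out$provider[nested_sel])
    add <- ifelse(kg %in% names(un), un[kg], 0) -
      ifelse(kp %in% names(un), un[kp], 0)
    add[is.na(add)] <- 0
    shift[nested_sel] <- shift[nested_sel] + add
  }
  idx <- which(shift != 0)
  if (length(idx)) {
    newv <- out$value
    newv[idx] <- plogis(logit_clip(newv[idx]) + shift[idx])
    out[, value := newv]
  }
  out
}

#' Adjust all regions and quantities of a point table
#'
#' Convenience wrapper: fits [fit_bias_model()] per (region, quantity) and
#' applies the adjustment.  Regions with a single provider are passed
#' through unadjusted with a warning.
#'
#' @inheritParams apply_adjustment
#' @return list with \code{points} (adjusted) and \code{fits}.
#' @export
adjust_all <- function(points, gold_map) {
  out <- data.table::copy(points)
  fits <- list()
  for (rg in unique(points$region_id)) {
    for (q in unique(points$quantity)) {
      fit <- tryCatch(fit_bias_model(points, rg, q), error = function(e) e)
      if (inherits(fit, "error")) {
        warning(sprintf("region %s / %s not adjusted: %s", rg, q,
                        conditionMessage(fit)))
        next
      }
      fits[[paste(rg, q, sep = "/")]] <- fit
      out <- apply_adjustment(out, fit, gold_map)
    }
  }
  list(points = out, fits = fits)
}
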