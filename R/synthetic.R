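## Synthetic world generator.
##
## The generator produces a known truth against which every pipeline stage
## can be tested by parameter recovery.  The stated world is:
##   * per country-sex, mean attainment of successive birth cohorts follows
##     a logistic growth curve (expansion of schooling over the 20th
##     century);
##   * the within-cohort distribution is a two-component mixture: a point
##     mass at 0 completed years plus a discretised logit-normal bulk over
##     1-18, so that (mean, proportion-zero) do not determine the full
##     shape;
##   * cohort distributions are frozen after age 25 (educational stability
##     of adult cohorts);
##   * data providers observe cohorts with additive biases on the logit
##     scale of the two modelled summaries, multinomial sampling noise, and
##     possibly 5-year age-group reporting.

#' Generate a synthetic truth world
#'
#' @param n_super,n_regions_per,n_countries_per hierarchy dimensions.
#' @param year_range length-2 integer vector of survey years the world must
#'   support, e.g. \code{c(1970, 2018)}.  Cohorts are generated for all
#'   birth years reachable from these years at ages 15--95.
#' @param seed integer seed; the world is bit-reproducible given the seed.
#' @param asymptote_range range of the logistic asymptote of cohort mean
#'   years of schooling (default 13--17 years).
#' @param midpoint_range range of the logistic midpoint birth-cohort year.
#' @param rate_range range of the logistic growth rate per cohort year.
#' @param dispersion_range range of the bulk logit-scale dispersion.
#' @param female_lag years by which the female expansion midpoint lags the
#'   male one (gender gap; default 8).
#' @param asymptote,midpoint,rate,dispersion optional scalars overriding the
#'   sampled ranges for every country (used to construct boundary worlds).
#' @return an object of class \code{edu_truth}: a list with the hierarchy,
#'   the per-country-sex generating parameters, and the per-cohort 19-bin
#'   truth distributions.
#' @export
make_world <- function(n_super = 3, n_regions_per = 2, n_countries_per = 2,
                       year_range = c(1970, 2018), seed = 1,
                       asymptote_range = c(13, 17),
                       midpoint_range = c(1950, 1985),
                       rate_range = c(0.05, 0.12),
                       dispersion_range = c(0.6, 1.1),
                       female_lag = 8,
                       asymptote = NULL, midpoint = NULL, rate = NULL,
                       dispersion = NULL) {
  if (diff(range(year_range)) + 80 < 30)
    stop_arg("year_range must cover at least 30 cohorts")
  hierarchy <- make_hierarchy(n_super, n_regions_per, n_countries_per)
  set.seed(derive_seed(seed, "world"))
  nl <- nrow(hierarchy)

  base <- data.table::data.table(
    location_id = hierarchy$location_id,
    asymptote = asymptote %||% stats::runif(nl, asymptote_range[1], asymptote_range[2]),
    midpoint = midpoint %||% stats::runif(nl, midpoint_range[1], midpoint_range[2]),
    rate = rate %||% stats::runif(nl, rate_range[1], rate_range[2]),
    dispersion = dispersion %||% stats::runif(nl, dispersion_range[1], dispersion_range[2]),
    p0_shift = stats::runif(nl, -0.3, 0.3))
  params <- data.table::rbindlist(list(
    data.table::copy(base)[, sex := "male"],
    data.table::copy(base)[, `:=`(sex = "female",
                                  midpoint = midpoint + female_lag,
                                  asymptote = asymptote * 0.97)]))

  cohorts <- (min(year_range) - 95L):(max(year_range) - 15L)
  grid <- params[, .(cohort = cohorts), by = .(location_id, sex)]
  grid <- merge(grid, params, by = c("location_id", "sex"))

  grid[, target_mean := asymptote * plogis(rate * (cohort - midpoint))]
  grid[, gen_p0 := plogis(1.2 - 0.55 * target_mean + p0_shift)]
  dist <- cbind(grid[, .(location_id, sex, cohort, gen_mean = target_mean)],
                bulk_matrix(grid$target_mean, grid$gen_p0, grid$dispersion))
  data.table::setkeyv(dist, c("location_id", "sex", "cohort"))

  structure(list(hierarchy = hierarchy, params = params, dist = dist,
                 cohort_range = range(cohorts), year_range = year_range,
                 seed = seed),
            class = "edu_truth")
}

# Discretised logit-normal bulk over bins 1..18, scaled by (1 - p0) and
# combined with the point mass at 0.  Vectorised over rows.
bulk_matrix <- function(target_mean, p0, dispersion) {
  n <- length(target_mean)
  bulk_mean <- pmin(pmax(target_mean / pmax(1 - p0, 1e-9), 1.05), 17.95)
  mu <- qlogis(bulk_mean / 18)
  edges <- qlogis((0:18) / 18)        # -Inf .. +Inf
  w <- matrix(0, n, 18L)
  for (k in 1:18) {
    w[, k] <- pnorm(edges[k + 1], mu, dispersion) - pnorm(edges[k], mu, dispersion)
  }
  w <- w / rowSums(w)
  out <- cbind(p0, w * (1 - p0))
  colnames(out) <- bin_cols()
  as.data.frame(out)
}

#' Look up the truth distribution for a location-age-sex-year cell
#'
#' Cohort stability: for ages at or above 25 the same birth cohort returns
#' an identical vector regardless of the calendar year of the query.
#'
#' @param truth an \code{edu_truth} object.
#' @param location location id.
#' @param age single age in years.
#' @param sex \code{"male"} or \code{"female"}.
#' @param year calendar year; the birth cohort is \code{year - age}.
#' @return a named numeric vector of 19 proportions summing to 1.
#' @export
truth_summary <- function(truth, location, age, sex, year) {
  cohort <- as.integer(round(year - age))
  if (cohort < truth$cohort_range[1] || cohort > truth$cohort_range[2])
    stop_arg("cohort %d outside generated range [%d, %d]",
             cohort, truth$cohort_range[1], truth$cohort_range[2])
  qdt <- data.table::data.table(location_id = location, sex = sex,
                                cohort = cohort)
  row <- truth$dist[qdt, on = c("location_id", "sex", "cohort")]
  if (nrow(row) != 1L || is.na(row$p0))
    stop_arg("no truth for (%s, %s, cohort %d)", location, sex, cohort)
  unlist(row[, bin_cols(), with = FALSE])
}

#' Specify a data provider for the survey simulator
#'
#' @param name provider name.
#' @param bias_mean additive bias on logit(mean/18).
#' @param bias_p0 additive bias on logit(proportion-zero).
#' @param gold logical; gold-standard (unbiased, trusted) provider.
#' @param years survey years covered.
#' @param age_width 1 (single ages) or 5 (5-year groups labelled by midpoint).
#' @param n_eff effective sample size per age-sex cell; \code{Inf} disables
#'   sampling noise.
#' @return a \code{provider_spec} list.
#' @export
provider_spec <- function(name, bias_mean = 0, bias_p0 = 0, gold = FALSE,
                          years, age_width = 1, n_eff = 1000) {
  if (!age_width %in% c(1, 5)) stop_arg("age_width must be 1 or 5")
  structure(list(name = name, bias_mean = bias_mean, bias_p0 = bias_p0,
                 gold = gold, years = as.integer(years),
                 age_width = age_width, n_eff = n_eff),
            class = "provider_spec")
}

# Exponential tilt of 19-bin distributions (rows of P) so that each row's
# (logit mean/18, logit p0) summaries are shifted by the provider biases.
# The point mass at zero is shifted directly; the bulk over 1..18 is
# re-weighted by exp(theta * k) with theta solved per row (vectorised
# Newton iteration; the tilted mean is strictly increasing in theta with
# derivative equal to the tilted variance).
tilt_rows <- function(P, bias_mean, bias_p0) {
  if (bias_mean == 0 && bias_p0 == 0) return(P)
  k <- 1:18
  p0 <- P[, 1]
  m <- as.vector(P %*% (0:18))
  p0_new <- plogis(logit_clip(p0) + bias_p0)
  m_new <- 18 * plogis(logit_clip(m / 18) + bias_mean)
  bulk_tot <- 1 - p0
  ok <- bulk_tot > 1e-12
  B <- P[, -1, drop = FALSE] / pmax(bulk_tot, 1e-12)
  target <- m_new / pmax(1 - p0_new, 1e-9)
  # attainable range given each row's bulk support
  lo <- apply(B, 1, function(b) min(k[b > 1e-15]))
  hi <- apply(B, 1, function(b) max(k[b > 1e-15]))
  target <- pmin(pmax(target, lo + 1e-6), hi - 1e-6)
  theta <- numeric(nrow(P))
  kc <- k - 9.5
  for (it in 1:40) {
    W <- B * exp(outer(theta, kc))
    sw <- rowSums(W)
    mu <- rowSums(W * rep(k, each = nrow(W))) / sw
    v <- rowSums(W * rep(k, each = nrow(W))^2) / sw - mu^2
    step <- (mu - target) / pmax(v, 1e-8)
    theta <- pmin(pmax(theta - step, -12), 12)
    if (max(abs(mu - target)[ok]) < 1e-12) break
  }
  W <- B * exp(outer(theta, kc))
  W <- W / rowSums(W)
  out <- cbind(p0_new, W * (1 - p0_new))
  out[!ok, ] <- P[!ok, ]             # degenerate rows: all mass at zero
  colnames(out) <- bin_cols()
  out
}

# scalar convenience wrapper used in tests and documentation examples
tilt_distribution <- function(p, bias_mean, bias_p0) {
  as.vector(tilt_rows(matrix(p, nrow = 1), bias_mean, bias_p0))
}

#' Simulate survey observations of a truth world
#'
#' Applies the provider's logit biases to each cohort's truth distribution
#' via a calibrated exponential tilt, optionally collapses single ages into
#' 5-year groups (sample-size-weighted average, labelled by midpoint), and
#' adds multinomial sampling noise at the provider's effective sample size.
#'
#' @param truth an \code{edu_truth} world.
#' @param provider a \code{provider_spec}.
#' @param seed integer seed for the sampling noise.
#' @param locations subset of location ids (default: all).
#' @param ages single ages surveyed (default 25--79).
#' @param sexes sexes surveyed.
#' @return a \code{data.table} of observations with columns
#'   \code{location_id, provider, year, sex, age_lo, age_hi, age, n_eff,
#'   p0..p18}.
#' @export
simulate_survey <- function(truth, provider, seed = 1,
                            locations = NULL, ages = 25:79,
                            sexes = c("male", "female")) {
  stopifnot(inherits(truth, "edu_truth"), inherits(provider, "provider_spec"))
  if (any(provider$years < truth$year_range[1] - 5) ||
      any(provider$years > truth$year_range[2] + 5))
    stop_arg("provider years outside truth year range")
  if (any(ages < 15)) stop_arg("ages must be >= 15")
  locations <- locations %||% truth$hierarchy$location_id
  set.seed(derive_seed(seed, "survey"))

  grid <- data.table::CJ(location_id = locations, sex = sexes,
                         year = as.integer(provider$years),
                         age = as.integer(ages), sorted = FALSE)
  grid[, cohort := year - age]
  tr <- truth$dist[grid, on = c("location_id", "sex", "cohort")]
  if (anyNA(tr$p0))
    stop_arg("survey grid reaches cohorts outside the generated range")
  P <- as.matrix(tr[, bin_cols(), with = FALSE])
  P <- tilt_rows(P, provider$bias_mean, provider$bias_p0)

  if (provider$age_width == 5) {
    grid[, age_lo := min(age) + ((age - min(age)) %/% 5L) * 5L]
    grid[, age_hi := age_lo + 4L]
    keep <- grid$age_hi <= max(ages)
    grp <- grid[keep, paste(location_id, sex, year, age_lo, sep = "|")]
    P <- rowsum(P[keep, , drop = FALSE], grp, reorder = FALSE) / 5
    out <- unique(grid[keep, .(location_id, sex, year, age_lo, age_hi)],
                  by = NULL)
    stopifnot(nrow(out) == nrow(P))
  } else {
    out <- grid[, .(location_id, sex, year, age_lo = age, age_hi = age)]
  }
  if (is.finite(provider$n_eff)) {
    n <- as.integer(provider$n_eff)
    P <- t(apply(P, 1, function(p) as.vector(rmultinom(1, n, p)) / n))
  }
  colnames(P) <- bin_cols()
  out[, `:=`(provider = provider$name, age = (age_lo + age_hi) / 2,
             n_eff = provider$n_eff)]
  res <- cbind(out[, .(location_id, provider, year, sex, age_lo, age_hi,
                       age, n_eff)],
               data.table::as.data.table(P))
  data.table::setorder(res, location_id, year, sex, age_lo)
  res
}

#' Write / read observation tables
#'
#' Plain CSV with documented headers; \code{n_eff = Inf} round-trips as the
#' string \code{"Inf"}.
#' @param obs observation \code{data.table}.
#' @param path file path.
#' @export
write_observations <- function(obs, path) {
  data.table::fwrite(obs, path)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  obs <- data.table::fread(path)
  obs[, n_eff := as.numeric(n_eff)]
  obs
}

#' Write / read a scenario configuration as plain-text key=value lines
#' @param config named list of scalar parameters.
#' @param path file path.
#' @export
write_scenario_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s=%s", k, paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(x) {
    vals <- strsplit(x[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    if (!anyNA(num)) num else vals
  })
  setNames(out, vapply(kv, `[[`, character(1), 1))
}
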