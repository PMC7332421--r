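# helper: a minimal point row for pair construction
pt_row <- function(loc, sx, cohort, year, value, provider = "s", q = "mean18") {
  data.table::data.table(
    quantity = q, location_id = loc, region_id = "R", super_region_id = "S",
    provider = provider, year = year, sex = sx, age = year - cohort,
    n_eff = Inf, value = value, se = 1e-4, pred_var = 0)
}

test_that("pair filters keep exactly the qualifying pairs of a constructed table", {
  # five candidate pairs over five cohorts: one 11 years apart, one with an
  # observation in 1989; three qualify
  mk <- function(cohort, y1, y2)
    rbind(pt_row("L", "male", cohort, y1, 0.5),
          pt_row("L", "male", cohort, y2, 0.55))
  pts <- rbind(mk(1950, 1995, 2000),   # ok
               mk(1951, 1992, 2003),   # 11 years apart -> dropped
               mk(1952, 1989, 1995),   # 1989 not after 1990 -> dropped
               mk(1953, 2001, 2009),   # ok
               mk(1954, 2010, 2018))   # ok
  pairs <- build_pairs(pts)
  expect_equal(nrow(pairs), 3L)
  expect_setequal(pairs$cohort, c(1950, 1953, 1954))
})

test_that("pair differences are annualised, later minus earlier", {
  pts <- rbind(pt_row("L", "male", 1950, 1995, plogis(0.10)),
               pt_row("L", "male", 1950, 2000, plogis(0.40)))
  pairs <- build_pairs(pts)
  expect_equal(pairs$y, 0.06, tolerance = 1e-12)   # (0.40 - 0.10) / 5
  expect_equal(pairs$age_mid, (45 + 50) / 2)

  # identical observations give y = 0 before bias subtraction
  pts0 <- rbind(pt_row("L", "male", 1950, 1995, 0.37),
                pt_row("L", "male", 1950, 2000, 0.37))
  expect_equal(build_pairs(pts0)$y, 0, tolerance = 1e-12)
})

test_that("a uniform inter-wave artifact is recovered by the 60-70 bias", {
  # two waves one year apart; every cohort's logit value rises by 0.1
  # between waves although the truth is stable
  cohorts <- 1926:1945                      # ages 55..74 at wave 1
  base <- plogis(seq(-0.5, 0.5, length.out = length(cohorts)))
  w1 <- data.table::rbindlist(lapply(seq_along(cohorts), function(i)
    pt_row("L", "male", cohorts[i], 2000, base[i], provider = "a")))
  w2 <- data.table::rbindlist(lapply(seq_along(cohorts), function(i)
    pt_row("L", "male", cohorts[i], 2001, plogis(qlogis(base[i]) + 0.1),
           provider = "b")))
  pairs <- build_pairs(rbind(w1, w2))
  corr <- estimate_survey_bias(pairs)
  expect_equal(unique(corr$bias), 0.1, tolerance = 1e-6)
  expect_true(all(abs(corr$y_corr) < 1e-9))
  # normalisation target: average change at the window centre is zero
  cc <- window_center_change(corr)
  expect_true(all(abs(cc$change_at_center) < 1e-9))
})

test_that("stable truth and unbiased waves give zero corrected changes", {
  w <- small_world()
  obs <- rbind(
    simulate_survey(w, provider_spec("g", years = 1998, n_eff = Inf),
                    seed = 1, ages = 25:79),
    simulate_survey(w, provider_spec("g", years = 2006, n_eff = Inf),
                    seed = 1, ages = 25:79))
  pts <- points_from_observations(obs, w$hierarchy)
  pairs <- estimate_survey_bias(build_pairs(pts[quantity == "mean18"]))
  expect_gt(nrow(pairs), 0)
  expect_true(all(abs(pairs$y_corr) < 1e-9))
})

test_that("pairings without 60-70 cohorts fall back to zero bias with warning", {
  pts <- rbind(pt_row("L", "male", 1960, 1995, 0.4),
               pt_row("L", "male", 1960, 2000, 0.5))   # ages 35/40
  pairs <- build_pairs(pts)
  expect_warning(corr <- estimate_survey_bias(pairs), "bias set to 0")
  expect_equal(corr$bias, 0)
})

test_that("the aging model recovers a known smooth aging function", {
  f <- function(age) -0.01 * (age - 60) / 20
  grid <- expand.grid(age_mid = seq(26, 90, by = 0.5),
                      location_id = c("A", "B", "C"),
                      stringsAsFactors = FALSE)
  pairs <- data.table::data.table(
    quantity = "mean18", location_id = grid$location_id,
    super_region_id = "S", sex = "male", age_mid = grid$age_mid,
    y_corr = f(grid$age_mid))
  fit <- fit_aging_model(pairs)
  sel <- fit$half_ages >= 30 & fit$half_ages <= 80
  expect_lt(max(abs(fit$annual_change[sel] - f(fit$half_ages[sel]))), 0.01)

  # all-zero changes produce an identically-zero spline
  pairs0 <- data.table::copy(pairs)[, y_corr := 0]
  fit0 <- fit_aging_model(pairs0)
  expect_lt(max(abs(fit0$annual_change)), 1e-6)

  # an injected location intercept is recovered (hair of noise keeps the
  # residual variance away from the degenerate zero boundary)
  set.seed(1)
  pairsu <- data.table::copy(pairs)
  pairsu[, y_corr := y_corr + rnorm(.N, 0, 1e-3)]
  pairsu[location_id == "A", y_corr := y_corr + 0.05]
  fitu <- fit_aging_model(pairsu)
  expect_equal(unname(fitu$u_location["A"] - mean(fitu$u_location[c("B", "C")])),
               0.05, tolerance = 0.02)
})

test_that("aging model preconditions are enforced", {
  pairs <- data.table::data.table(
    quantity = "mean18", location_id = "A", super_region_id = "S",
    sex = "male", age_mid = rep(c(30, 35), 15), y_corr = 0)
  expect_error(fit_aging_model(pairs), "age span")
  expect_error(fit_aging_model(pairs[1:5]), ">= 20 pairs")
})

# hand-built aging fit with a prescribed annual-change profile
manual_aging_fit <- function(annual_change, sigma2 = 0.001) {
  structure(list(half_ages = seq(25.5, 94.5, by = 1),
                 annual_change = annual_change, sigma2_resid = sigma2,
                 u_location = c()),
            class = "edu_aging_fit")
}

test_that("extrapolation accumulates annual changes exactly", {
  half <- seq(25.5, 94.5, by = 1)
  # zero change: identity at every target age
  fit0 <- manual_aging_fit(rep(0, length(half)), sigma2 = 0)
  src <- pt_row("L", "male", 1940, 2010, 0.37)     # age 70
  out0 <- extrapolate_cohort(src, fit0, c(30, 50, 70, 75),
                             year_range = c(1960, 2030))
  expect_true(all(abs(out0$value - 0.37) < 1e-12))

  # -0.01/year above age 70: logit 0 at 70 becomes -0.05 at 75
  fit1 <- manual_aging_fit(ifelse(half > 70, -0.01, 0), sigma2 = 0)
  src1 <- pt_row("L", "male", 1940, 2010, 0.5)
  out1 <- extrapolate_cohort(src1, fit1, 75, year_range = c(1960, 2030))
  expect_equal(logit_clip(out1$value), -0.05, tolerance = 1e-12)
  expect_equal(out1$year, 2015)
})

test_that("extrapolation telescopes and its error grows with the span", {
  half <- seq(25.5, 94.5, by = 1)
  fit <- manual_aging_fit(-0.002 * (half - 25), sigma2 = 0.01)
  src <- pt_row("L", "male", 1950, 1990, 0.42)     # age 40
  direct <- extrapolate_cohort(src, fit, 60, year_range = c(1900, 2100))
  step1 <- extrapolate_cohort(src, fit, 50, year_range = c(1900, 2100))
  step2 <- extrapolate_cohort(step1, fit, 60, year_range = c(1900, 2100))
  expect_equal(step2$value, direct$value, tolerance = 1e-12)

  fan <- extrapolate_cohort(src, fit, c(40, 45, 50, 60, 70),
                            year_range = c(1900, 2100))
  fan <- fan[order(abs(fan$age - 40))]
  expect_true(all(diff(fan$pred_var) >= 0))
  expect_true(all(fan$age >= 25))
})

test_that("cohort machinery recovers held-out ages on a stable world", {
  w <- small_world()
  obs <- rbind(
    simulate_survey(w, provider_spec("g", years = 1996, n_eff = Inf),
                    seed = 1, ages = 25:79),
    simulate_survey(w, provider_spec("g", years = 2004, n_eff = Inf),
                    seed = 1, ages = 25:79))
  pts <- points_from_observations(obs, w$hierarchy)[quantity == "mean18"]
  pairs <- estimate_survey_bias(build_pairs(pts))
  fit <- fit_aging_model(pairs)
  filled <- extrapolate_cohort(pts[age %in% c(30, 50, 70)], fit,
                               c(40, 60), year_range = c(1970, 2018))
  tl <- truth_logit_for_points(w, filled)
  expect_lt(mean(abs(logit_clip(filled$value) - tl)), 0.05)
})
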