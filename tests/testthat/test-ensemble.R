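# hand-built library with controllable features and covariance
manual_library <- function(n = 200, seed = 1, S = NULL) {
  set.seed(seed)
  bins <- t(replicate(n, random_dist()))
  colnames(bins) <- paste0("p", 0:18)
  feats <- cbind(rnorm(n), rnorm(n))
  colnames(feats) <- c("f_mean", "f_p0")
  hier <- make_hierarchy(2, 2, 2)
  meta <- data.table::data.table(
    location_id = sample(hier$location_id, n, replace = TRUE),
    provider = "s", year = sample(1970:2015, n, replace = TRUE),
    age = sample(25:60, n, replace = TRUE))
  meta[, cohort := year - age]
  structure(list(bins = bins, features = feats, meta = meta,
                 S = S %||% stats::cov(feats), hierarchy = hier),
            class = "edu_library")
}

test_that("library construction produces simplex bins and a PD feature covariance", {
  obs <- nonoise_obs()
  lib <- build_library(obs, small_world()$hierarchy)
  expect_equal(nrow(lib$bins), nrow(obs))
  expect_true(all(abs(rowSums(lib$bins) - 1) < 1e-8))
  expect_true(isSymmetric(lib$S))
  expect_true(all(eigen(lib$S)$values > 0))
  expect_equal(lib$meta$cohort, obs$year - obs$age)
})

test_that("Mahalanobis selection matches brute force and handles ties/identity", {
  lib <- manual_library(200)
  q <- c(0.3, -0.2)
  sel <- mahalanobis_select(q, lib, 80)
  d2 <- stats::mahalanobis(lib$features, q, lib$S)   # independent oracle
  expect_setequal(sel$index, order(d2)[1:80])
  expect_equal(sel$distance, sqrt(sort(d2)[1:80]), tolerance = 1e-10)

  # identity covariance reduces to Euclidean order
  libI <- manual_library(150, seed = 2, S = diag(2))
  qi <- c(0, 0)
  selI <- mahalanobis_select(qi, libI, 10)
  eu <- sqrt(rowSums(sweep(libI$features, 2, qi)^2))
  expect_equal(selI$index, order(eu)[1:10])

  # a query equal to an entry returns that entry at distance zero
  q0 <- lib$features[17, ]
  sel0 <- mahalanobis_select(q0, lib, 1)
  expect_equal(sel0$index, 17L)
  expect_equal(sel0$distance, 0)

  expect_error(mahalanobis_select(q, lib, 1000), "exceeds library")
})

test_that("singular feature covariance is reported as degeneracy", {
  lib <- manual_library(50)
  lib$features[, 2] <- lib$features[, 1]
  lib$S <- stats::cov(lib$features)
  expect_error(mahalanobis_select(c(0, 0), lib, 5), "degenera")
})

test_that("ensemble weights follow the printed distance formula", {
  cfg <- ensemble_config()
  hier <- make_hierarchy(2, 2, 2)
  target <- list(age = 30, cohort = 1970, location = "SR1_R1_C1")

  # symmetric candidates -> uniform 1/K
  cand <- data.table::data.table(age = rep(35, 6), cohort = rep(1960, 6),
                                 location_id = rep("SR2_R1_C1", 6))
  expect_equal(ensemble_weights(target, cand, cfg, hier), rep(1 / 6, 6))

  # same-country vs other-super-region with equal age/cohort distances:
  # hand computation from the stated constants
  cand2 <- data.table::data.table(age = c(35, 35), cohort = c(1960, 1960),
                                  location_id = c("SR1_R1_C1", "SR2_R1_C1"))
  w <- ensemble_weights(target, cand2, cfg, hier)
  dist_of <- function(dloc)
    (0.25 * 0.001)^2.5 + (0.85 * 0.001)^2.5 + (0.7 * dloc)^2.5
  expect_gt(w[1], w[2])
  expect_equal(w[1] / w[2], dist_of(1) / dist_of(0.001), tolerance = 1e-10)

  # normalisation for random candidate sets
  set.seed(4)
  for (r in 1:5) {
    cand3 <- data.table::data.table(
      age = sample(25:60, 20, TRUE), cohort = sample(1930:1990, 20, TRUE),
      location_id = sample(hier$location_id, 20, TRUE))
    expect_equal(sum(ensemble_weights(target, cand3, cfg, hier)), 1,
                 tolerance = 1e-12)
  }
})

test_that("ensemble averaging equals the loop oracle", {
  set.seed(8)
  bins <- t(replicate(12, random_dist()))
  w <- stats::rexp(12); w <- w / sum(w)
  got <- ensemble_average(bins, w)
  oracle <- numeric(19)
  for (i in 1:12) for (k in 1:19) oracle[k] <- oracle[k] + w[i] * bins[i, k]
  expect_equal(unname(got), oracle, tolerance = 1e-14)
  expect_equal(sum(got), 1, tolerance = 1e-12)

  same <- matrix(rep(random_dist(), 3), nrow = 3, byrow = TRUE)
  expect_equal(unname(ensemble_average(same, rep(1 / 3, 3))), same[1, ],
               tolerance = 1e-15)

  two <- rbind(c(rep(0, 6), 1, rep(0, 12)),   # point mass at 6
               c(rep(0, 12), 1, rep(0, 6)))   # point mass at 12
  avg <- ensemble_average(two, c(0.5, 0.5))
  expect_equal(unname(avg[c(7, 13)]), c(0.5, 0.5))
})

test_that("the time smoother preserves constants, damps spikes, renormalises", {
  years <- 1970:2018
  const <- matrix(rep(random_dist(), length(years)), nrow = length(years),
                  byrow = TRUE)
  sm <- loess_smooth_bins(years, const, 0.5)
  expect_lt(max(abs(sm - const)), 1e-9)

  spiky <- const
  spiky[25, 5] <- spiky[25, 5] + 0.3
  spiky <- spiky / rowSums(spiky)
  sms <- loess_smooth_bins(years, spiky, 0.5)
  expect_lt(sms[25, 5], spiky[25, 5])
  expect_true(all(abs(rowSums(sms) - 1) < 1e-9))

  expect_warning(short <- loess_smooth_bins(1:3, const[1:3, ], 0.5),
                 "shorter")
  expect_identical(short, const[1:3, ])
})

test_that("the batched reconstruction equals the composed exported operations", {
  lib <- manual_library(300, seed = 6)
  cfg <- ensemble_config(K = 40)
  years <- 1990:2000
  set.seed(2)
  feats <- cbind(rnorm(length(years), 0, 0.5), rnorm(length(years), 0, 0.5))
  target <- list(location = "SR1_R1_C1", age = 30)
  fast <- ensemble_reconstruct(feats, years, target, lib, cfg,
                               smooth = FALSE)
  for (i in seq_along(years)) {
    sel <- mahalanobis_select(feats[i, ], lib, cfg$K)
    w <- ensemble_weights(list(age = 30, cohort = years[i] - 30,
                               location = target$location),
                          lib$meta[sel$index], cfg, lib$hierarchy)
    slow <- ensemble_average(lib$bins[sel$index, , drop = FALSE], w)
    expect_identical(unname(fast[i, ]), unname(slow))
  }
})

test_that("a truth-family library reconstructs distributions and features", {
  w <- small_world()
  obs <- data.table::rbindlist(lapply(seq(1975, 2015, by = 5), function(y)
    simulate_survey(w, provider_spec("g", years = y, n_eff = Inf),
                    seed = 1, ages = 25:69)))
  lib <- build_library(obs, w$hierarchy)
  expect_gt(nrow(lib$bins), 1500)
  cfg <- ensemble_config()

  years <- seq(1976, 2014)
  tv <- c(); ferr <- c()
  for (sx in c("male", "female")) {
    tru <- t(vapply(years, function(y)
      truth_summary(w, "SR1_R1_C2", 30, sx, y), numeric(19)))
    feats <- cbind(logit_clip(as.vector(tru %*% (0:18)) / 18),
                   logit_clip(tru[, 1]))
    rec <- ensemble_reconstruct(feats, years,
                                list(location = "SR1_R1_C2", age = 30),
                                lib, cfg, smooth = FALSE)
    tv <- c(tv, rowSums(abs(rec - tru)) / 2)
    ferr <- c(ferr,
              abs(logit_clip(as.vector(rec %*% (0:18)) / 18) - feats[, 1]),
              abs(logit_clip(rec[, 1]) - feats[, 2]))
  }
  expect_lt(mean(tv), 0.05)     # total-variation recovery
  expect_lt(mean(ferr), 0.15)   # end-to-end feature consistency
})
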