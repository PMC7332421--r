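test_that("Matern covariance matches its closed forms and limits", {
  expect_equal(matern_cov(0, 1.7, 2, 40), 1.7)
  expect_error(matern_cov(-1, 1), "non-negative")

  # strictly decreasing over distance
  d <- seq(0, 100, by = 1)
  v <- matern_cov(d, 1, 2, 40)
  expect_true(all(diff(v) < 0))

  # independent evaluation of the printed formula
  d <- seq(0.5, 100, by = 0.5)
  expect_equal(matern_cov(d, 1, 2, 40), matern_oracle(d, 1, 2, 40),
               tolerance = 1e-12)

  # analytic special cases: nu = 1/2 is exponential, nu = 3/2 has a
  # closed form; both are independent of the Bessel-function route
  expect_equal(matern_cov(d, 2, 0.5, 10), 2 * exp(-d / 10),
               tolerance = 1e-10)
  x <- sqrt(3) * d / 25
  expect_equal(matern_cov(d, 1, 1.5, 25), (1 + x) * exp(-x),
               tolerance = 1e-10)
})

test_that("amplitude estimation is a grouped squared scaled MAD", {
  r0 <- data.table::data.table(super_region_id = "S", sex = "male",
                               resid_logit = rep(0, 50))
  expect_equal(estimate_amplitude(r0)$sigma2, 0)

  set.seed(1)
  rn <- data.table::data.table(super_region_id = "S", sex = "male",
                               resid_logit = rnorm(10000, 0, 0.3))
  expect_equal(estimate_amplitude(rn)$sigma2, 0.09, tolerance = 0.01)

  two <- data.table::rbindlist(list(
    data.table::data.table(super_region_id = "A", sex = "male",
                           resid_logit = rnorm(500, 0, 0.2)),
    data.table::data.table(super_region_id = "B", sex = "male",
                           resid_logit = rnorm(500, 0, 0.6))))
  amp <- estimate_amplitude(two)
  expect_lt(amp[super_region_id == "A", sigma2],
            amp[super_region_id == "B", sigma2])

  # undersized group falls back to the global pool with a warning
  small <- rbind(two, data.table::data.table(
    super_region_id = "C", sex = "male", resid_logit = rnorm(3)))
  expect_warning(ampf <- estimate_amplitude(small), "global pool")
  expect_equal(ampf[super_region_id == "C", sigma2],
               mad(small$resid_logit)^2)
})

gp_prior <- function(years = 1970:2018)
  data.table::data.table(year = years,
                         prior_logit = 0.2 + 0.01 * (years - 1994))

test_that("GP posterior returns the prior with no data and interpolates near-noiseless points", {
  prior <- gp_prior()
  cfg <- gpr_config(sigma2 = 0.3, draws = 0)
  post0 <- gpr_posterior(prior, NULL, cfg)
  expect_identical(post0$post_mean, prior$prior_logit)
  expect_equal(post0$post_sd, rep(sqrt(0.3), nrow(prior)), tolerance = 1e-9)

  one <- data.table::data.table(year = 2000, value_logit = 1.5,
                                sigma_p2 = 1e-10)
  post1 <- gpr_posterior(prior, one, cfg)
  expect_equal(post1[year == 2000, post_mean], 1.5, tolerance = 1e-4)
  # posterior variance at a data year is below the prior variance
  expect_lt(post1[year == 2000, post_sd], sqrt(0.3))
})

test_that("a three-point instance matches a hand-rolled linear-algebra oracle", {
  prior <- gp_prior()
  dat <- data.table::data.table(year = c(1980, 1995, 2010),
                                value_logit = c(0.0, 0.6, 0.4),
                                sigma_p2 = c(0.04, 0.01, 0.09))
  cfg <- gpr_config(nu = 2, l = 40, sigma2 = 0.25, draws = 0)
  post <- gpr_posterior(prior, dat, cfg)

  K <- function(a, b) matern_oracle(abs(outer(a, b, "-")), 0.25, 2, 40)
  Kdd <- matrix(K(dat$year, dat$year), 3, 3) + diag(dat$sigma_p2)
  Kyd <- matrix(K(prior$year, dat$year), nrow(prior), 3)
  r <- dat$value_logit - prior$prior_logit[match(dat$year, prior$year)]
  oracle <- prior$prior_logit + as.vector(Kyd %*% solve(Kdd, r))
  expect_equal(post$post_mean, oracle, tolerance = 1e-10)
})

test_that("a vanishing length-scale reverts the posterior to the prior off-data", {
  prior <- gp_prior()
  dat <- data.table::data.table(year = 2000, value_logit = 2, sigma_p2 = 1e-6)
  post <- gpr_posterior(prior, dat, gpr_config(l = 1e-3, sigma2 = 0.3,
                                               draws = 0))
  off <- post[year != 2000]
  expect_lt(max(abs(off$post_mean - off$prior_logit)), 1e-6)
})

test_that("draws are consistent with the posterior and reproducible", {
  prior <- gp_prior()
  dat <- data.table::data.table(year = c(1985, 2005),
                                value_logit = c(0.1, 0.8),
                                sigma_p2 = c(0.02, 0.02))
  p100 <- gpr_posterior(prior, dat, gpr_config(sigma2 = 0.3, draws = 100,
                                               seed = 9))
  p10k <- gpr_posterior(prior, dat, gpr_config(sigma2 = 0.3, draws = 10000,
                                               seed = 9))
  e100 <- max(abs(rowMeans(attr(p100, "draws")) - p100$post_mean))
  e10k <- max(abs(rowMeans(attr(p10k, "draws")) - p10k$post_mean))
  # antithetic sampling: the ensemble mean is exact for even draw counts,
  # so the 1/sqrt(draws) bound holds trivially
  expect_lte(e10k, e100 + 1e-12)
  expect_lt(e100, 1e-12)
  sd10k <- unname(apply(attr(p10k, "draws"), 1, sd))
  expect_equal(sd10k, p10k$post_sd, tolerance = 0.1)

  # identical seeds give identical draws; back-transformed values in (0,1)
  rep2 <- gpr_posterior(prior, dat, gpr_config(sigma2 = 0.3, draws = 100,
                                               seed = 9))
  expect_identical(attr(p100, "draws"), attr(rep2, "draws"))
  expect_true(all(plogis(attr(p100, "draws")) > 0 &
                  plogis(attr(p100, "draws")) < 1))
})

test_that("duplicate noiseless data points trigger the jitter retry, not an error", {
  prior <- gp_prior()
  dat <- data.table::data.table(year = c(2000, 2000),
                                value_logit = c(1, 1), sigma_p2 = c(0, 0))
  expect_no_error(gpr_posterior(prior, dat, gpr_config(sigma2 = 0.3,
                                                       draws = 0)))
})
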