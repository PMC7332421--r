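# Lazily-built, cached fixtures shared across test files.  Everything is
# generated in code (no stored data); the cache only avoids recomputing
# the same world twice within one test run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) assign(name, build(), envir = .fx)
  .fx[[name]]
}

# two-country single-region world, deterministic
small_world <- function() fixture("small_world", function() {
  make_world(n_super = 1, n_regions_per = 1, n_countries_per = 2,
             year_range = c(1970, 2018), seed = 42)
})

# noise-free observations of small_world by one unbiased provider
nonoise_obs <- function() fixture("nonoise_obs", function() {
  simulate_survey(small_world(),
                  provider_spec("gold", years = c(1995, 2000, 2005),
                                n_eff = Inf),
                  seed = 1, ages = 25:60)
})

# a minimal hand-built truth object with all mass at 12 years
degenerate_truth <- function() {
  dist <- data.table::data.table(location_id = "X", sex = "male",
                                 cohort = 1970L)
  probs <- as.list(c(rep(0, 12), 1, rep(0, 6)))
  names(probs) <- paste0("p", 0:18)
  dist <- cbind(dist, data.table::as.data.table(probs))
  data.table::setkeyv(dist, c("location_id", "sex", "cohort"))
  structure(list(hierarchy = make_hierarchy(1, 1, 1), dist = dist,
                 cohort_range = c(1970L, 1970L), year_range = c(1995, 2010),
                 seed = 0),
            class = "edu_truth")
}

# quantity points from a no-noise two-provider region with an injected
# logit bias on the non-gold provider; used by adjust and acceptance tests
biased_region_points <- function(bias = 0.5, n_eff = Inf,
                                 quantities = c("mean18", "prop_zero")) {
  truth <- fixture("adj_world", function() {
    make_world(n_super = 1, n_regions_per = 1, n_countries_per = 3,
               year_range = c(1970, 2018), seed = 11)
  })
  gold <- simulate_survey(truth,
                          provider_spec("gold", years = c(1995, 2000, 2005),
                                        n_eff = n_eff),
                          seed = 2, ages = 30:39)
  biased <- simulate_survey(truth,
                            provider_spec("biased", bias_mean = bias,
                                          bias_p0 = bias,
                                          years = c(1995, 2000, 2005),
                                          n_eff = n_eff),
                            seed = 3, ages = 30:39)
  pts <- points_from_observations(rbind(gold, biased), truth$hierarchy)
  list(truth = truth, points = pts[quantity %in% quantities],
       gold_map = data.table::data.table(region = unique(truth$hierarchy$region_id),
                                         provider = "gold"))
}

# truth logit values matched to a quantity-point table (for improvement
# checks against the generating world)
truth_logit_for_points <- function(truth, pts) {
  vapply(seq_len(nrow(pts)), function(i) {
    r <- pts[i]
    tru <- truth_summary(truth, r$location_id, r$age, r$sex, r$year)
    v <- if (r$quantity == "mean18") sum(0:18 * tru) / 18 else tru[1]
    logit_clip(v)
  }, numeric(1))
}

# independent Lorenz-curve (trapezoid) Gini oracle for a discrete
# distribution on 0..18; with-replacement population Gini
lorenz_gini <- function(p) {
  x <- 0:18
  mu <- sum(p * x)
  if (mu <= 0) return(0)
  Fk <- cumsum(p)
  Lk <- cumsum(p * x) / mu
  F0 <- c(0, Fk[-19])
  L0 <- c(0, Lk[-19])
  1 - sum((Fk - F0) * (Lk + L0))
}

# random 19-bin distribution
random_dist <- function() {
  p <- stats::rexp(19)
  p / sum(p)
}

# independent Matern evaluation used as an oracle (deliberately written
# from the printed formula, separate from the package implementation)
matern_oracle <- function(d, sigma2, nu, l) {
  ifelse(d == 0, sigma2, {
    x <- d * sqrt(2 * nu) / l
    sigma2 * (2^(1 - nu) / gamma(nu)) * x^nu * besselK(x, nu)
  })
}

# tiny pipeline configuration used by pipeline tests (seconds, not minutes)
tiny_config <- function(seed = 5, draws = 2) {
  run_config(seed = seed, draws = draws,
             scenario = list(n_super = 1, n_regions_per = 1,
                             n_countries_per = 2,
                             dhs_ages = seq(25, 74, by = 5)))
}
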