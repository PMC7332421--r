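## Gaussian process regression over time.
##
## Per location-age-sex and quantity, the age-period prediction is the GP
## mean function and the cohort-filled data points are noisy observations
## of the logit-scale series:
##
##   logit(y) = g(year) + eps,  eps ~ N(0, sigma_p^2)
##
## sigma_p^2 is the squared standard error of the point plus the prediction
## variance accumulated during cohort extrapolation.  The kernel is Matern
## with smoothness nu = 2 and length-scale l = 40 years; the amplitude
## sigma^2 is estimated per super-region and sex from the pooled residuals
## of the mean function (squared scaled MAD, robust to sparse countries).

#' Matern covariance function
#'
#' \deqn{M(d) = \sigma^2 \frac{2^{1-\nu}}{\Gamma(\nu)}
#'   \left(\frac{d\sqrt{2\nu}}{l}\right)^{\nu}
#'   K_\nu\!\left(\frac{d\sqrt{2\nu}}{l}\right)}
#' with \eqn{M(0) = \sigma^2} by continuity.
#'
#' @param d non-negative distance(s) in years.
#' @param sigma2 marginal variance (amplitude).
#' @param nu smoothness (default 2).
#' @param l length-scale in years (default 40).
#' @return covariance value(s), same length as \code{d}.
#' @export
matern_cov <- function(d, sigma2, nu = 2, l = 40) {
  if (any(d < 0)) stop_arg("distances must be non-negative")
  if (nu <= 0 || l <= 0) stop_arg("nu and l must be positive")
  x <- d * sqrt(2 * nu) / l
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- sigma2 * (2^(1 - nu) / gamma(nu)) * x[pos]^nu *
    besselK(x[pos], nu)
  out[!pos] <- sigma2
  out
}

#' GPR configuration
#'
#' @param nu Matern smoothness (default 2).
#' @param l Matern length-scale in years (default 40).
#' @param sigma2 kernel amplitude (marginal variance on the logit scale).
#' @param draws number of posterior draws (antithetic pairs).
#' @param seed integer seed for the draws.
#' @return a \code{gpr_config} list.
#' @export
gpr_config <- function(nu = 2, l = 40, sigma2 = 0.1, draws = 100, seed = 1) {
  if (nu <= 0 || l <= 0 || sigma2 < 0 || draws < 0)
    stop_arg("invalid GPR configuration")
  structure(list(nu = nu, l = l, sigma2 = sigma2, draws = draws, seed = seed),
            class = "gpr_config")
}

#' Estimate the kernel amplitude from mean-function residuals
#'
#' \code{sigma^2} is approximated per super-region and sex as the squared
#' scaled median absolute deviation of the logit-scale residuals of the
#' age-period prior, pooled within the group.  Groups with fewer than
#' \code{min_n} residuals fall back to the global pool with a warning.
#'
#' @param residuals \code{data.table} with columns \code{super_region_id,
#'   sex, resid_logit}.
#' @param min_n minimum residuals per group (default 10).
#' @return \code{data.table(super_region_id, sex, sigma2)}.
#' @export
estimate_amplitude <- function(residuals, min_n = 10) {
  glob <- mad(residuals$resid_logit)^2
  out <- residuals[, .(sigma2 = mad(resid_logit)^2, n = .N),
                   by = .(super_region_id, sex)]
  small <- out$n < min_n
  if (any(small)) {
    warning(sprintf("%d amplitude group(s) below %d residuals; using global pool",
                    sum(small), min_n))
    out$sigma2[small] <- glob
  }
  out[, n := NULL]
  out[]
}

#' Exact GP posterior of a logit-scale time series
#'
#' @param prior \code{data.table} with columns \code{year} and
#'   \code{prior_logit}: the mean function on the full year grid.
#' @param data \code{data.table} with columns \code{year},
#'   \code{value_logit} and \code{sigma_p2} (per-point noise variance); may
#'   be empty, in which case the posterior mean is the prior exactly.
#' @param config a [gpr_config()].
#' @return an object of class \code{edu_gp_posterior}: \code{data.table}
#'   with \code{year, prior_logit, post_mean, post_sd} plus a draws matrix
#'   (years x draws) in the \code{"draws"} attribute.
#' @export
gpr_posterior <- function(prior, data, config) {
  stopifnot(inherits(config, "gpr_config"))
  yrs <- prior$year
  g <- prior$prior_logit
  ny <- length(yrs)
  Kyy <- matern_cov(abs(outer(yrs, yrs, "-")), config$sigma2,
                    config$nu, config$l)
  dim(Kyy) <- c(ny, ny)

  if (is.null(data) || nrow(data) == 0L) {
    post_mean <- g
    post_cov <- Kyy
  } else {
    if (any(data$year < min(yrs)) || any(data$year > max(yrs)))
      stop_arg("data years outside prior grid")
    yd <- data$year
    r <- data$value_logit - g[match(yd, yrs)]
    Kdd <- matern_cov(abs(outer(yd, yd, "-")), config$sigma2,
                      config$nu, config$l)
    dim(Kdd) <- c(length(yd), length(yd))
    Kyd <- matern_cov(abs(outer(yrs, yd, "-")), config$sigma2,
                      config$nu, config$l)
    dim(Kyd) <- c(ny, length(yd))
    A <- Kdd + diag(data$sigma_p2, nrow = length(yd))
    sol <- tryCatch(solve(A, cbind(r, t(Kyd))),
                    error = function(e) {
                      solve(A + diag(1e-9, nrow(A)), cbind(r, t(Kyd)))
                    })
    post_mean <- g + as.vector(Kyd %*% sol[, 1])
    post_cov <- Kyy - Kyd %*% sol[, -1, drop = FALSE]
  }
  post_sd <- sqrt(pmax(diag(post_cov), 0))

  draws <- NULL
  if (config$draws > 0) {
    set.seed(derive_seed(config$seed, "draws"))
    L <- tryCatch(chol(post_cov + diag(1e-9, ny)),
                  error = function(e) chol(post_cov + diag(1e-6, ny)))
    half <- ceiling(config$draws / 2)
    Z <- matrix(rnorm(ny * half), ny, half)
    E <- t(L) %*% Z
    draws <- cbind(post_mean + E, post_mean - E)[, seq_len(config$draws),
                                                 drop = FALSE]
  }
  out <- data.table::data.table(year = yrs, prior_logit = g,
                                post_mean = post_mean, post_sd = post_sd)
  data.table::setattr(out, "draws", draws)
  data.table::setattr(out, "class",
                      c("edu_gp_posterior", class(out)))
  out
}
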