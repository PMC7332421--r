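## Ensemble K-nearest-neighbour distribution reconstruction.
##
## The first stage estimates only two summaries per LASY cell (mean/18 and
## proportion-zero).  The full 19-bin distribution is reconstructed by
## searching the library of observed survey distributions for the K entries
## whose (logit mean/18, logit prop-zero) feature vectors are closest in
## Mahalanobis distance, averaging them with weights that favour candidates
## close in age, birth cohort and space, and smoothing the resulting series
## over time with a local linear smoother.

#' Build the candidate library from an observation table
#'
#' @param obs observation table (see [simulate_survey()]).
#' @param hierarchy hierarchy table.
#' @return an \code{edu_library}: entries with bins, features
#'   \eqn{H^i = (logit(mean^i/18), logit(prop_0^i))}, metadata (location,
#'   age, cohort, provider) and the pooled 2x2 feature covariance S.
#' @export
build_library <- function(obs, hierarchy) {
  bins <- as.matrix(obs[, bin_cols(), with = FALSE])
  bins <- bins / rowSums(bins)
  m <- dist_mean(bins)
  feats <- cbind(logit_clip(m / 18), logit_clip(bins[, 1]))
  colnames(feats) <- c("f_mean", "f_p0")
  S <- stats::cov(feats)
  meta <- obs[, .(location_id, provider, year, sex, age)]
  meta[, cohort := year - age]
  structure(list(bins = bins, features = feats, meta = meta, S = S,
                 hierarchy = hierarchy),
            class = "edu_library")
}

#' @export
print.edu_library <- function(x, ...) {
  cat(sprintf("<edu_library> %d entries; feature covariance:\n",
              nrow(x$bins)))
  print(round(x$S, 4))
  invisible(x)
}

#' Select the K nearest library entries by Mahalanobis distance
#'
#' @param query length-2 feature vector \eqn{I = (logit(mean/18),
#'   logit(prop_0))}.
#' @param library an \code{edu_library}.
#' @param K number of candidates.
#' @return list with \code{index} (library row indices, distance order,
#'   ties broken by index) and \code{distance}.
#' @export
mahalanobis_select <- function(query, library, K) {
  n <- nrow(library$features)
  if (K > n) stop_arg("K = %d exceeds library size %d", K, n)
  Sinv <- tryCatch(solve(library$S), error = function(e)
    stop_arg(paste("feature covariance is singular; check the library for",
                   "degenerate (constant) features")))
  d1 <- library$features[, 1] - query[1]
  d2f <- library$features[, 2] - query[2]
  d2 <- Sinv[1, 1] * d1 * d1 + 2 * Sinv[1, 2] * d1 * d2f +
    Sinv[2, 2] * d2f * d2f
  # partial sort for the K-th smallest, then stable ordering of the
  # candidate set (ties broken by library index)
  thr <- sort(d2, partial = K)[K]
  cand <- which(d2 <= thr)
  cand <- cand[order(d2[cand], cand)]
  idx <- cand[seq_len(K)]
  list(index = idx, distance = sqrt(d2[idx]))
}

# min-max rescale of a raw distance vector to [0.001, 1]
rescale_unit <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] < .Machine$double.eps) return(rep(0.001, length(x)))
  0.001 + (x - rng[1]) / (rng[2] - rng[1]) * 0.999
}

#' Ensemble configuration
#'
#' Defaults are the standard hyperparameter values: K = 80, P_age = 0.25,
#' P_cohort = 0.85, P_space = 0.7, psi = 2.5, eta = 0.5.
#' @param K candidate count.
#' @param P_age,P_cohort,P_space component weights in [0, 1].
#' @param psi sharpness exponent.
#' @param eta Loess span over time.
#' @return an \code{ensemble_config} list.
#' @export
ensemble_config <- function(K = 80, P_age = 0.25, P_cohort = 0.85,
                            P_space = 0.7, psi = 2.5, eta = 0.5) {
  if (K < 1 || psi <= 0 || eta <= 0 || eta > 1)
    stop_arg("invalid ensemble configuration")
  structure(list(K = K, P_age = P_age, P_cohort = P_cohort,
                 P_space = P_space, psi = psi, eta = eta),
            class = "ensemble_config")
}

#' Distance-based weights for the selected candidates
#'
#' \deqn{Distance^i = (P_{age} D_{age}^i)^\psi + (P_{cohort} D_{cohort}^i)^\psi
#'   + (P_{space} D_{loc}^i)^\psi, \qquad Weights^i \propto 1 / Distance^i}
#' Age and cohort distances are absolute differences min-max rescaled to
#' [0.001, 1] across the candidate set; the location distance is the
#' categorical 0.001 / 0.33 / 0.66 / 1 hierarchy distance.
#'
#' @param target list with \code{age}, \code{cohort}, \code{location}.
#' @param candidates \code{data.table} with columns \code{age},
#'   \code{cohort}, \code{location_id} for the selected entries.
#' @param config an [ensemble_config()].
#' @param hierarchy hierarchy table.
#' @return normalised weights summing to 1.
#' @export
ensemble_weights <- function(target, candidates, config, hierarchy) {
  d_age <- rescale_unit(abs(candidates$age - target$age))
  d_coh <- rescale_unit(abs(candidates$cohort - target$cohort))
  d_loc <- space_distance(hierarchy, target$location, candidates$location_id)
  dist <- (config$P_age * d_age)^config$psi +
    (config$P_cohort * d_coh)^config$psi +
    (config$P_space * d_loc)^config$psi
  w <- 1 / dist
  w / sum(w)
}

#' Weighted average of candidate distributions
#'
#' @param bins K x 19 matrix of candidate distributions.
#' @param weights normalised weights.
#' @return a 19-bin distribution summing to 1.
#' @export
ensemble_average <- function(bins, weights) {
  out <- as.vector(crossprod(bins, weights))
  names(out) <- bin_cols()
  out
}

#' Smooth a year-indexed distribution series bin by bin
#'
#' Per-bin locally weighted linear regression over year (span \code{eta}),
#' followed by clipping at zero and renormalisation of each year to the
#' simplex.  Series shorter than 5 years pass through with a warning.
#'
#' @param years integer years (ascending).
#' @param mat years x 19 matrix of distributions.
#' @param eta smoother span in (0, 1].
#' @return smoothed matrix, rows summing to 1.
#' @export
loess_smooth_bins <- function(years, mat, eta = 0.5) {
  if (length(years) < 5L) {
    warning("series shorter than 5 years; smoothing skipped")
    return(mat)
  }
  sm <- apply(mat, 2, function(p) lowess(years, p, f = eta, iter = 0)$y)
  dimnames(sm) <- dimnames(mat)
  sm[sm < 0] <- 0
  sm / rowSums(sm)
}

#' Reconstruct a distribution series for one location-age-sex cell
#'
#' Maps per-year feature vectors (from the GPR posterior) through candidate
#' selection, weighting and averaging, then smooths over time.
#'
#' @param features year-indexed 2-column matrix of \code{(logit(mean/18),
#'   logit(prop0))} query vectors.
#' @param years integer years matching the feature rows.
#' @param target list with \code{location}, \code{age} (cohort is derived
#'   per year).
#' @param library an \code{edu_library}.
#' @param config an [ensemble_config()].
#' @param smooth logical; apply the time smoother (default TRUE).
#' @return years x 19 matrix of distributions.
#' @export
ensemble_reconstruct <- function(features, years, target, library, config,
                                 smooth = TRUE) {
  out <- matrix(0, length(years), 19L,
                dimnames = list(years, bin_cols()))
  # inlined equivalent of mahalanobis_select + ensemble_weights +
  # ensemble_average per year (the per-cell spatial distances and the
  # quadratic-form coefficients are hoisted out of the year loop; the
  # selection rule is identical, see the equivalence test)
  Sinv <- tryCatch(solve(library$S), error = function(e)
    stop_arg(paste("feature covariance is singular; check the library for",
                   "degenerate (constant) features")))
  f1 <- library$features[, 1]; f2 <- library$features[, 2]
  lib_age <- library$meta$age
  lib_cohort <- library$meta$cohort
  d_loc_all <- space_distance(library$hierarchy, target$location,
                              library$meta$location_id)
  K <- config$K; psi <- config$psi
  for (i in seq_along(years)) {
    u <- f1 - features[i, 1]; v <- f2 - features[i, 2]
    d2 <- Sinv[1, 1] * u * u + 2 * Sinv[1, 2] * u * v + Sinv[2, 2] * v * v
    thr <- sort(d2, partial = K)[K]
    cand <- which(d2 <= thr)
    cand <- cand[order(d2[cand], cand)][seq_len(K)]
    d_age <- rescale_unit(abs(lib_age[cand] - target$age))
    d_coh <- rescale_unit(abs(lib_cohort[cand] - (years[i] - target$age)))
    dist <- (config$P_age * d_age)^psi + (config$P_cohort * d_coh)^psi +
      (config$P_space * d_loc_all[cand])^psi
    w <- 1 / dist
    out[i, ] <- crossprod(library$bins[cand, , drop = FALSE], w / sum(w))
  }
  if (smooth) out <- loess_smooth_bins(years, out, config$eta)
  out
}
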