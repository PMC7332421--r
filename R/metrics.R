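## SDG progress and inequality metrics.
##
## From a 19-bin distribution of completed years of schooling: attainment
## proportions at the 6 / 12 / 15-year thresholds (primary, secondary,
## tertiary completion), the average interpersonal difference (AID: the
## mean absolute difference in years of schooling over all ordered pairs of
## individuals, self-pairs included) and the Gini coefficient, related by
## the exact identity AID = 2 * mean * Gini, and a male-female gap
## decomposed into primary / secondary / tertiary contributions via
## expected years within each band.

#' Proportion attaining at least a threshold of schooling
#'
#' @param dist 19-bin distribution.
#' @param threshold years of schooling (6, 12 and 15 correspond to primary,
#'   secondary and tertiary completion).
#' @return \eqn{\sum_{k \ge threshold} p_k}.
#' @export
attainment_proportion <- function(dist, threshold) {
  if (!threshold %in% EDU_BINS) stop_arg("threshold must be in 0..18")
  sum(dist[EDU_BINS >= threshold])
}

#' Average interpersonal difference (AID)
#'
#' Mean absolute difference in years of schooling between all ordered pairs
#' of individuals (self-pairs included):
#' \eqn{\sum_j \sum_k p_j p_k |j - k|}.  Equals \eqn{2 \mu G} where G is
#' the population (with-replacement) Gini.
#'
#' @param dist 19-bin distribution.
#' @return AID in years (>= 0).
#' @export
aid <- function(dist) {
  D <- abs(outer(EDU_BINS, EDU_BINS, "-"))
  as.numeric(dist %*% D %*% dist)
}

#' Gini coefficient of a schooling distribution
#'
#' Population (with-replacement) Gini: \code{aid(dist) / (2 * mean)}.  A
#' point mass (mean 0 included) has Gini 0 by convention.
#'
#' @param dist 19-bin distribution.
#' @return Gini in [0, 1].
#' @export
gini <- function(dist) {
  mu <- mean_from_distribution(dist)
  if (mu <= 0) {
    message("distribution has zero mean; Gini set to 0 by convention")
    return(0)
  }
  aid(dist) / (2 * mu)
}

# expected years completed within a band [lo, lo + width)
band_years <- function(dist, lo, width) {
  sum(dist * pmin(pmax(EDU_BINS - lo, 0), width))
}

#' Gender gap in mean schooling, decomposed by level
#'
#' Total gap is male minus female mean years (positive = favouring men).
#' Contributions use expected years completed within each band: primary
#' 0--6, secondary 6--12, tertiary 12--18; the three contributions sum to
#' the total exactly.
#'
#' @param dist_m,dist_f male and female 19-bin distributions.
#' @return named vector: \code{total, primary, secondary, tertiary}.
#' @export
gender_gap_decomposition <- function(dist_m, dist_f) {
  comp <- function(lo) band_years(dist_m, lo, 6) - band_years(dist_f, lo, 6)
  out <- c(total = mean_from_distribution(dist_m) -
             mean_from_distribution(dist_f),
           primary = comp(0), secondary = comp(6), tertiary = comp(12))
  out
}

#' Population-weighted aggregation of distributions
#'
#' Aggregation happens before metric computation, so aggregate inequality
#' includes the between-member spread.
#'
#' @param dists n x 19 matrix of member distributions.
#' @param weights non-negative population weights (not all zero); names, if
#'   present, identify members in error messages.
#' @return list with \code{dist} (the aggregate 19-bin distribution) and
#'   \code{metrics} (a [metric_set()] row).
#' @export
aggregate_distributions <- function(dists, weights) {
  if (is.null(dim(dists))) dists <- matrix(dists, nrow = 1)
  if (length(weights) != nrow(dists))
    stop_arg("need one weight per distribution")
  if (anyNA(weights)) {
    who <- names(weights)[is.na(weights)] %||% which(is.na(weights))
    stop_arg("missing population weight for: %s", paste(who, collapse = ", "))
  }
  if (any(weights < 0) || sum(weights) <= 0)
    stop_arg("weights must be non-negative and not all zero")
  w <- weights / sum(weights)
  agg <- as.vector(crossprod(dists, w))
  names(agg) <- bin_cols()
  list(dist = agg, metrics = metric_set(agg))
}

#' All scalar metrics of one distribution
#'
#' @param dist 19-bin distribution.
#' @return one-row \code{data.table}: mean years, attainment at 6/12/15,
#'   AID and Gini.
#' @export
metric_set <- function(dist) {
  data.table::data.table(
    mean_years = mean_from_distribution(dist),
    prop_zero = dist[1],
    attain6 = attainment_proportion(dist, 6),
    attain12 = attainment_proportion(dist, 12),
    attain15 = attainment_proportion(dist, 15),
    aid = aid(dist),
    gini = gini(dist))
}

#' Metrics for every row of a distribution matrix
#'
#' Vectorised equivalent of [metric_set()] applied to each row; used by the
#' pipeline to score thousands of draw series cheaply.
#'
#' @param mat n x 19 matrix of distributions.
#' @return \code{data.table} with one metrics row per input row.
#' @export
metrics_matrix <- function(mat) {
  mu <- dist_mean(mat)
  D <- abs(outer(EDU_BINS, EDU_BINS, "-"))
  aid_v <- rowSums((mat %*% D) * mat)
  data.table::data.table(
    mean_years = mu,
    prop_zero = mat[, 1],
    attain6 = rowSums(mat[, EDU_BINS >= 6, drop = FALSE]),
    attain12 = rowSums(mat[, EDU_BINS >= 12, drop = FALSE]),
    attain15 = rowSums(mat[, EDU_BINS >= 15, drop = FALSE]),
    aid = aid_v,
    gini = ifelse(mu > 0, aid_v / (2 * mu), 0))
}

#' Percentile uncertainty interval from metric draws
#'
#' @param x numeric vector of draws.
#' @param level interval mass (default 0.95).
#' @return named vector \code{mean, lower, upper} (2.5/97.5 percentiles at
#'   the default level).
#' @export
draw_interval <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  q <- quantile(x, c(a, 1 - a), names = FALSE, type = 7)
  c(mean = mean(x), lower = q[1], upper = q[2])
}
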