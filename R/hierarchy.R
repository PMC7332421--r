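#' Build a nested location hierarchy
#'
#' Countries are nested in regions, regions in super-regions.  The hierarchy
#' drives the nesting structure of the mixed models, the spatial distance
#' used by the ensemble stage, and aggregation.
#'
#' @param n_super number of super-regions.
#' @param n_regions_per regions per super-region.
#' @param n_countries_per countries per region.
#' @return a \code{data.table} with columns \code{location_id},
#'   \code{region_id}, \code{super_region_id}, one row per country.
#' @export
make_hierarchy <- function(n_super, n_regions_per, n_countries_per) {
  if (n_super < 1 || n_regions_per < 1 || n_countries_per < 1)
    stop_arg("all hierarchy counts must be >= 1")
  rows <- list()
  for (s in seq_len(n_super)) {
    sr <- sprintf("SR%d", s)
    for (r in seq_len(n_regions_per)) {
      rg <- sprintf("%s_R%d", sr, r)
      for (k in seq_len(n_countries_per)) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          location_id = sprintf("%s_C%d", rg, k),
          region_id = rg, super_region_id = sr)
      }
    }
  }
  data.table::rbindlist(rows)
}

# region / super-region lookup vectors keyed by location
hier_region <- function(hierarchy, location) {
  hierarchy$region_id[match(location, hierarchy$location_id)]
}

hier_super <- function(hierarchy, location) {
  hierarchy$super_region_id[match(location, hierarchy$location_id)]
}

#' Spatial distance between a target country and candidate countries
#'
#' The ensemble stage uses a coarse categorical distance: 0.001 for the
#' same country, 0.33 for the same region, 0.66 for the same super-region
#' and 1 otherwise.
#'
#' @param hierarchy hierarchy table from [make_hierarchy()].
#' @param target a single location id.
#' @param candidates vector of location ids.
#' @return numeric vector of distances in \{0.001, 0.33, 0.66, 1\}.
#' @export
space_distance <- function(hierarchy, target, candidates) {
  tr <- hier_region(hierarchy, target)
  ts <- hier_super(hierarchy, target)
  cr <- hier_region(hierarchy, candidates)
  cs <- hier_super(hierarchy, candidates)
  out <- rep(1, length(candidates))
  out[cs == ts] <- 0.66
  out[cr == tr] <- 0.33
  out[candidates == target] <- 0.001
  out
}
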