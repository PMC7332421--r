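## Pipeline orchestration: ingest -> adjust -> cohort -> age-period -> GPR
## -> ensemble -> forecast -> metrics, with draw propagation, plus the
## out-of-sample validation harness.  Stage functions consume and return
## plain tables so any stage can be re-run from its predecessor's CSV.

#' Pipeline run configuration
#'
#' All hyperparameters default to the standard values of the method: K = 80,
#' P_age = 0.25, P_cohort = 0.85, P_space = 0.7, psi = 2.5, eta = 0.5,
#' Matern nu = 2 and l = 40, 1000 draws (reduce for desk-scale runs).
#'
#' @param seed master seed; every stage seed is derived from it.
#' @param draws uncertainty draws propagated through GPR and the ensemble.
#' @param years estimation years (default 1970--2018).
#' @param horizon forecast horizon year (default 2030).
#' @param ages estimation ages; defaults to the 5-year group midpoints 27,
#'   32, 37 (groups 25-29, 30-34, 35-39).
#' @param alpha age-period random-intercept grouping, see
#'   [fit_age_period()].
#' @param nu,l Matern smoothness and length-scale.
#' @param K,P_age,P_cohort,P_space,psi,eta ensemble hyperparameters, see
#'   [ensemble_config()].
#' @param holdout_fraction fraction of source-location-year blocks held out
#'   by [holdout_validation()].
#' @param scenario synthetic scenario parameters (hierarchy dimensions,
#'   survey density multiplier), see [default_scenario()].
#' @return a \code{run_config} list.
#' @export
run_config <- function(seed = 1, draws = 1000, years = 1970:2018,
                       horizon = 2030, ages = c(27, 32, 37),
                       alpha = "country_age", nu = 2, l = 40, K = 80,
                       P_age = 0.25, P_cohort = 0.85, P_space = 0.7,
                       psi = 2.5, eta = 0.5, holdout_fraction = 0.2,
                       scenario = list()) {
  if (holdout_fraction < 0 || holdout_fraction > 0.5)
    stop_arg("holdout_fraction must be in [0, 0.5]")
  sc <- utils::modifyList(
    list(n_super = 3, n_regions_per = 2, n_countries_per = 2, density = 1,
         census_n = 10000, dhs_n = 3000, mics_n = 2000,
         dhs_bias_mean = -0.12, dhs_bias_p0 = 0.15,
         mics_bias_mean = 0.08, mics_bias_p0 = -0.10,
         dhs_ages = 25:74, census_ages = 25:79, mics_ages = 25:59),
    scenario)
  structure(list(seed = seed, draws = draws, years = years,
                 horizon = horizon, ages = ages, alpha = alpha,
                 nu = nu, l = l,
                 ensemble = ensemble_config(K = K, P_age = P_age,
                                            P_cohort = P_cohort,
                                            P_space = P_space, psi = psi,
                                            eta = eta),
                 holdout_fraction = holdout_fraction, scenario = sc),
            class = "run_config")
}

#' Generate the default desk-scale synthetic scenario
#'
#' Three providers observe every country: a gold-standard census (decennial,
#' 5-year age groups, large samples), a DHS-like survey (five-yearly, single
#' ages, negatively biased mean) and a MICS-like survey (decennial, 5-year
#' groups, positively biased mean).  \code{density} multiplies DHS survey
#' frequency.
#'
#' @param config a [run_config()].
#' @return list with \code{truth}, \code{hierarchy}, \code{observations},
#'   \code{gold_map}, \code{providers}.
#' @export
default_scenario <- function(config) {
  sc <- config$scenario
  truth <- make_world(sc$n_super, sc$n_regions_per, sc$n_countries_per,
                      year_range = range(config$years), seed = config$seed)
  hierarchy <- truth$hierarchy
  dhs_step <- max(1L, as.integer(round(5 / sc$density)))
  providers <- list(
    provider_spec("census", gold = TRUE, years = seq(1971, 2011, by = 10),
                  age_width = 5, n_eff = sc$census_n),
    provider_spec("dhs", bias_mean = sc$dhs_bias_mean,
                  bias_p0 = sc$dhs_bias_p0,
                  years = seq(1972, 2017, by = dhs_step),
                  age_width = 1, n_eff = sc$dhs_n),
    provider_spec("mics", bias_mean = sc$mics_bias_mean,
                  bias_p0 = sc$mics_bias_p0,
                  years = seq(1996, 2016, by = 10),
                  age_width = 5, n_eff = sc$mics_n))
  ages_for <- list(census = sc$census_ages, dhs = sc$dhs_ages,
                   mics = sc$mics_ages)
  obs <- data.table::rbindlist(lapply(providers, function(pr)
    simulate_survey(truth, pr, seed = config$seed + match(pr$name,
                                                          c("census", "dhs", "mics")),
                    ages = ages_for[[pr$name]])))
  gold_map <- data.table::data.table(
    region = unique(hierarchy$region_id), provider = "census")
  list(truth = truth, hierarchy = hierarchy, observations = obs,
       gold_map = gold_map, providers = providers)
}

# ---- stage functions -------------------------------------------------

stage_cohort <- function(points, ages, years) {
  fits <- list(); all_pairs <- list(); filled <- list()
  for (q in unique(points$quantity)) {
    pr <- build_pairs(points[quantity == q])
    if (nrow(pr)) pr <- suppressWarnings(estimate_survey_bias(pr))
    fit <- fit_aging_model(pr)
    fits[[q]] <- fit
    all_pairs[[q]] <- pr
    filled[[q]] <- extrapolate_cohort(points[quantity == q], fit, ages,
                                      range(years))
  }
  list(P2 = data.table::rbindlist(filled), fits = fits,
       pairs = data.table::rbindlist(all_pairs))
}

stage_ageperiod <- function(P2, hierarchy, ages, years, alpha) {
  fits <- list(); priors <- list()
  for (q in unique(P2$quantity)) for (sx in unique(P2$sex)) {
    for (rg in unique(P2$region_id)) {
      fit <- fit_age_period(P2, sx, rg, q, alpha = alpha)
      fits[[paste(q, sx, rg, sep = "/")]] <- fit
      grid <- data.table::CJ(
        location_id = hierarchy$location_id[hierarchy$region_id == rg],
        age = ages, year = years)
      pred <- predict_age_period(fit, grid)
      pred[, `:=`(sex = sx, quantity = q, region_id = rg)]
      priors[[paste(q, sx, rg, sep = "/")]] <- pred
    }
  }
  prior <- data.table::rbindlist(priors)
  prior <- merge(prior, unique(hierarchy[, .(region_id, super_region_id)]),
                 by = "region_id")
  list(prior = prior, fits = fits)
}

cell_key <- function(loc, age, sex, q) paste(loc, age, sex, q, sep = "|")

stage_gpr <- function(P2, prior, config, cells = NULL) {
  dat <- data.table::copy(P2)
  dat <- merge(dat,
               prior[, .(quantity, location_id, age, sex, year, prior_logit)],
               by = c("quantity", "location_id", "age", "sex", "year"))
  dat[, value_logit := logit_clip(value)]
  dat[, resid_logit := value_logit - prior_logit]
  dat[, sigma_p2 := logit_se(value, se)^2 + pred_var]

  amp <- data.table::rbindlist(lapply(unique(dat$quantity), function(q) {
    a <- suppressWarnings(
      estimate_amplitude(dat[quantity == q,
                             .(super_region_id, sex, resid_logit)]))
    a[, quantity := q]
    a
  }))
  amp[sigma2 <= 0, sigma2 := 1e-6]

  cell_tab <- unique(prior[, .(location_id, age, sex, quantity,
                               super_region_id)])
  if (!is.null(cells)) {
    cell_tab <- cell_tab[cell_key(location_id, age, sex, quantity) %in% cells]
  }
  cell_tab <- merge(cell_tab, amp, by = c("super_region_id", "sex",
                                          "quantity"))
  post_list <- vector("list", nrow(cell_tab))
  draws_store <- list()
  for (i in seq_len(nrow(cell_tab))) {
    ct <- cell_tab[i]
    pr <- prior[location_id == ct$location_id & age == ct$age &
                sex == ct$sex & quantity == ct$quantity,
                .(year, prior_logit)]
    data.table::setorder(pr, year)
    dd <- dat[location_id == ct$location_id & age == ct$age &
              sex == ct$sex & quantity == ct$quantity,
              .(year, value_logit, sigma_p2)]
    cfg <- gpr_config(nu = config$nu, l = config$l, sigma2 = ct$sigma2,
                      draws = config$draws,
                      seed = derive_seed(config$seed * 131 + i, "draws"))
    post <- gpr_posterior(pr, dd, cfg)
    key <- cell_key(ct$location_id, ct$age, ct$sex, ct$quantity)
    draws_store[[key]] <- attr(post, "draws")
    pl <- data.table::as.data.table(post)
    pl[, `:=`(location_id = ct$location_id, age = ct$age, sex = ct$sex,
              quantity = ct$quantity)]
    post_list[[i]] <- pl
  }
  list(post = data.table::rbindlist(post_list), draws = draws_store,
       amplitude = amp)
}

stage_ensemble <- function(gpr_out, obs, hierarchy, config) {
  library <- build_library(obs, hierarchy)
  post <- gpr_out$post
  years <- sort(unique(post$year))
  cells <- unique(post[, .(location_id, age, sex)])
  horizon_years <- (max(years) + 1):config$horizon
  youngest <- min(config$ages)

  est_list <- list(); draw_list <- list()
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i]
    key_m <- cell_key(cl$location_id, cl$age, cl$sex, "mean18")
    key_p <- cell_key(cl$location_id, cl$age, cl$sex, "prop_zero")
    pm <- post[location_id == cl$location_id & age == cl$age &
               sex == cl$sex & quantity == "mean18"][order(year)]
    pp <- post[location_id == cl$location_id & age == cl$age &
               sex == cl$sex & quantity == "prop_zero"][order(year)]
    target <- list(location = cl$location_id, age = cl$age)
    do_forecast <- cl$age == youngest && config$horizon > max(years) &&
      all(2003:2018 %in% years)

    run_path <- function(f_mean, f_p0) {
      mat <- ensemble_reconstruct(cbind(f_mean, f_p0), years, target,
                                  library, config$ensemble)
      if (do_forecast) {
        roc <- compute_roc(years, mat)
        proj <- project(mat[nrow(mat), ], roc, base_year = max(years),
                        horizon_year = config$horizon)
        mat <- rbind(mat, proj)
      }
      mat
    }

    mat <- run_path(pm$post_mean, pp$post_mean)
    all_years <- as.integer(rownames(mat))
    est <- data.table::data.table(
      location_id = cl$location_id, age = cl$age, sex = cl$sex,
      year = all_years, forecast = all_years > max(years))
    est <- cbind(est, metrics_matrix(mat),
                 data.table::as.data.table(mat))
    est_list[[i]] <- est

    ndr <- if (is.null(gpr_out$draws[[key_m]])) 0L
           else ncol(gpr_out$draws[[key_m]])
    if (ndr > 0) {
      dm_l <- vector("list", ndr)
      for (d in seq_len(ndr)) {
        matd <- run_path(gpr_out$draws[[key_m]][, d],
                         gpr_out$draws[[key_p]][, d])
        md <- metrics_matrix(matd)
        md[, `:=`(location_id = cl$location_id, age = cl$age, sex = cl$sex,
                  year = as.integer(rownames(matd)), draw = d)]
        dm_l[[d]] <- md
      }
      draw_list[[i]] <- data.table::rbindlist(dm_l)
    }
  }
  list(estimates = data.table::rbindlist(est_list),
       metric_draws = if (length(draw_list))
         data.table::rbindlist(draw_list) else NULL,
       library = library)
}

# ---- orchestration ---------------------------------------------------

#' Run the full estimation pipeline
#'
#' Executes simulate (or load) -> summaries -> provider-bias adjustment ->
#' cohort extrapolation -> age-period prior -> GPR -> ensemble distribution
#' reconstruction -> forecast -> metrics, propagating uncertainty draws.
#'
#' @param config a [run_config()].
#' @param scenario optional pre-built scenario (list with \code{truth} or
#'   \code{NULL}, \code{hierarchy}, \code{observations}, \code{gold_map});
#'   defaults to [default_scenario()].
#' @return an \code{edu_pipeline} result: stage outputs, estimates with
#'   19-bin distributions and metrics for 1970--2030, metric draws, gender
#'   gaps, fits and the run log.
#' @export
run_pipeline <- function(config, scenario = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- list(); t_all <- proc.time()[3]
  tick <- function(stage, rin, rout, t0) {
    line <- sprintf("stage=%s rows_in=%d rows_out=%d wall=%.2fs",
                    stage, rin, rout, proc.time()[3] - t0)
    log[[length(log) + 1L]] <<- line
  }

  t0 <- proc.time()[3]
  scen <- scenario %||% default_scenario(config)
  obs <- scen$observations
  hierarchy <- scen$hierarchy
  tick("simulate", 0L, nrow(obs), t0)

  t0 <- proc.time()[3]
  points <- points_from_observations(obs, hierarchy)
  tick("summaries", nrow(obs), nrow(points), t0)

  t0 <- proc.time()[3]
  adj <- adjust_all(points, scen$gold_map)
  tick("adjust", nrow(points), nrow(adj$points), t0)

  t0 <- proc.time()[3]
  coh <- stage_cohort(adj$points, config$ages, config$years)
  tick("cohort", nrow(adj$points), nrow(coh$P2), t0)

  t0 <- proc.time()[3]
  ap <- stage_ageperiod(coh$P2, hierarchy, config$ages, config$years,
                        config$alpha)
  tick("ageperiod", nrow(coh$P2), nrow(ap$prior), t0)

  t0 <- proc.time()[3]
  gp <- stage_gpr(coh$P2, ap$prior, config)
  tick("gpr", nrow(ap$prior), nrow(gp$post), t0)

  t0 <- proc.time()[3]
  ens <- stage_ensemble(gp, obs, hierarchy, config)
  tick("ensemble+forecast", nrow(gp$post), nrow(ens$estimates), t0)

  t0 <- proc.time()[3]
  gaps <- compute_gender_gaps(ens$estimates)
  intervals <- if (!is.null(ens$metric_draws))
    summarise_metric_draws(ens$metric_draws) else NULL
  tick("metrics", nrow(ens$estimates),
       nrow(gaps) + if (is.null(intervals)) 0L else nrow(intervals), t0)

  log[[length(log) + 1L]] <- sprintf("total wall=%.2fs seed=%d",
                                     proc.time()[3] - t_all, config$seed)
  structure(list(config = config, scenario = scen,
                 observations = obs, points = points,
                 adjusted = adj$points, bias_fits = adj$fits,
                 pairs = coh$pairs, aging_fits = coh$fits, P2 = coh$P2,
                 ap_fits = ap$fits, prior = ap$prior,
                 gpr = gp, estimates = ens$estimates,
                 metric_draws = ens$metric_draws,
                 intervals = intervals, gaps = gaps,
                 library = ens$library, log = unlist(log)),
            class = "edu_pipeline")
}

#' @export
print.edu_pipeline <- function(x, ...) {
  cat("<edu_pipeline> run with seed", x$config$seed, "\n")
  cat(sprintf("  %d observations -> %d estimate rows (%d forecast)\n",
              nrow(x$observations), nrow(x$estimates),
              sum(x$estimates$forecast)))
  cat("  log:\n")
  cat(paste0("   ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Male-female gaps with level decomposition for every cell-year
#' @param estimates pipeline estimates table (with bin columns).
#' @return \code{data.table} of gaps (male minus female) and primary /
#'   secondary / tertiary contributions.
#' @export
compute_gender_gaps <- function(estimates) {
  cols <- bin_cols()
  wide <- merge(
    estimates[sex == "male", c("location_id", "age", "year", cols),
              with = FALSE],
    estimates[sex == "female", c("location_id", "age", "year", cols),
              with = FALSE],
    by = c("location_id", "age", "year"), suffixes = c("_m", "_f"))
  if (!nrow(wide)) return(data.table::data.table())
  gm <- as.matrix(wide[, paste0(cols, "_m"), with = FALSE])
  gf <- as.matrix(wide[, paste0(cols, "_f"), with = FALSE])
  dec <- t(vapply(seq_len(nrow(wide)), function(i)
    gender_gap_decomposition(gm[i, ], gf[i, ]), numeric(4)))
  cbind(wide[, .(location_id, age, year)],
        data.table::as.data.table(dec))
}

#' Collapse metric draws into 95% uncertainty intervals
#' @param metric_draws draw-level metric table from the pipeline.
#' @return \code{data.table} with mean / lower / upper per cell-year-metric.
#' @export
summarise_metric_draws <- function(metric_draws) {
  long <- data.table::melt(
    metric_draws,
    id.vars = c("location_id", "age", "sex", "year", "draw"),
    variable.name = "metric")
  long[, .(mean = mean(value),
           lower = quantile(value, 0.025, names = FALSE),
           upper = quantile(value, 0.975, names = FALSE)),
       by = .(location_id, age, sex, year, metric)]
}

#' Population-weighted aggregate metrics by region or globally
#'
#' @param result an \code{edu_pipeline} result.
#' @param level \code{"region"}, \code{"super_region"} or \code{"global"}.
#' @param weights optional \code{data.table(location_id, weight)}; equal
#'   weights by default.
#' @param age_ age group to aggregate (default: youngest estimation age).
#' @return \code{data.table} of aggregate metrics by entity, sex and year
#'   (sex \code{"both"} rows pool the sexes).
#' @export
pipeline_aggregate <- function(result, level = c("region", "super_region",
                                                 "global"),
                               weights = NULL, age_ = NULL) {
  level <- match.arg(level)
  est <- result$estimates
  age_ <- age_ %||% min(est$age)
  est <- est[age == age_]
  hierarchy <- result$scenario$hierarchy
  est[, entity := switch(level,
                         region = hier_region(hierarchy, location_id),
                         super_region = hier_super(hierarchy, location_id),
                         global = "global")]
  if (is.null(weights))
    weights <- data.table::data.table(
      location_id = hierarchy$location_id, weight = 1)
  est <- merge(est, weights, by = "location_id")
  cols <- bin_cols()
  agg_one <- function(sub) {
    a <- aggregate_distributions(as.matrix(sub[, cols, with = FALSE]),
                                 setNames(sub$weight, sub$location_id))
    a$metrics
  }
  both <- est[, agg_one(.SD), by = .(entity, year)][, sex := "both"]
  by_sex <- est[, agg_one(.SD), by = .(entity, sex, year)]
  data.table::rbindlist(list(by_sex, both), use.names = TRUE)
}

# ---- out-of-sample validation ---------------------------------------

#' Out-of-sample validation by block holdout
#'
#' Removes whole provider-location-year blocks from the point table, re-runs
#' the summary stages (adjust, cohort, age-period, GPR posterior mean) on
#' the training data, and scores predictions of the held-out summaries at
#' the estimation ages.  Errors are reported per point and stratified by
#' region, period and provider.
#'
#' @param config a [run_config()]; \code{config$holdout_fraction} is the
#'   default fraction of blocks held out.
#' @param split_spec list with \code{fraction} overriding the config.
#' @param seed seed for block sampling.
#' @param scenario optional pre-built scenario.
#' @return an \code{edu_error_report}: per-point table plus RMSE / MAE /
#'   bias summaries overall and by stratum.
#' @export
holdout_validation <- function(config, split_spec = list(), seed = 1,
                               scenario = NULL) {
  fraction <- split_spec$fraction %||% config$holdout_fraction
  scen <- scenario %||% default_scenario(config)
  points <- points_from_observations(scen$observations, scen$hierarchy)

  blocks <- unique(points[, .(provider, location_id, year)])
  n_hold <- floor(nrow(blocks) * fraction)
  if (n_hold == 0L) {
    return(structure(list(points = points[0], summary = data.table::data.table(),
                          n_blocks = 0L),
                     class = "edu_error_report"))
  }
  set.seed(derive_seed(seed, "holdout"))
  held <- blocks[sample(nrow(blocks), n_hold)]
  held[, held_out := TRUE]
  pts <- merge(points, held, by = c("provider", "location_id", "year"),
               all.x = TRUE)
  train <- pts[is.na(held_out)][, held_out := NULL]
  test <- pts[held_out == TRUE][, held_out := NULL]
  test <- test[age %in% config$ages]

  adj <- suppressWarnings(adjust_all(train, scen$gold_map))
  # score on the gold-standard scale: held-out points are shifted with the
  # training-data bias fits (otherwise provider bias is an irreducible
  # error floor that grows with the share of biased test points)
  for (fit in adj$fits)
    test <- suppressWarnings(apply_adjustment(test, fit, scen$gold_map))
  coh <- stage_cohort(adj$points, config$ages, config$years)
  ap <- stage_ageperiod(coh$P2, scen$hierarchy, config$ages, config$years,
                        config$alpha)
  cfg_nodraw <- config; cfg_nodraw$draws <- 0L
  cells <- unique(cell_key(test$location_id, test$age, test$sex,
                           test$quantity))
  gp <- stage_gpr(coh$P2, ap$prior, cfg_nodraw, cells = cells)

  pred <- merge(test,
                gp$post[, .(location_id, age, sex, quantity, year, post_mean)],
                by = c("location_id", "age", "sex", "quantity", "year"))
  pred[, predicted := plogis(post_mean)]
  pred[, error := predicted - value]
  pred[quantity == "mean18", `:=`(predicted = predicted * 18,
                                  observed = value * 18,
                                  error = error * 18)]
  pred[quantity == "prop_zero", observed := value]
  pred[, period := cut(year, breaks = c(-Inf, 1990, 2005, Inf),
                       labels = c("pre-1990", "1990-2005", "post-2005"))]

  summarise <- function(dt, by) {
    dt[, .(rmse = sqrt(mean(error^2)), mae = mean(abs(error)),
           bias = mean(error), n = .N), by = by]
  }
  summary <- data.table::rbindlist(list(
    summarise(pred, by = "quantity")[, `:=`(stratum = "overall",
                                            level = "overall")],
    summarise(pred, by = c("quantity", "region_id"))[
      , `:=`(stratum = region_id, level = "region")][, region_id := NULL],
    summarise(pred, by = c("quantity", "period"))[
      , `:=`(stratum = as.character(period), level = "period")][
      , period := NULL],
    summarise(pred, by = c("quantity", "provider"))[
      , `:=`(stratum = provider, level = "provider")][, provider := NULL]),
    use.names = TRUE, fill = TRUE)

  structure(list(points = pred, summary = summary, n_blocks = n_hold),
            class = "edu_error_report")
}

#' @export
print.edu_error_report <- function(x, ...) {
  cat(sprintf("<edu_error_report> %d blocks held out, %d test points\n",
              x$n_blocks, nrow(x$points)))
  if (nrow(x$summary))
    print(x$summary[x$summary$level == "overall", ])
  invisible(x)
}
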