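#' Configuration for the synthetic case-crossover study generator
#'
#' Bundles every generating parameter of the synthetic study: census
#' composition, exposure processes, mortality model, and the true
#' exposure and interaction log odds against which pipeline estimates
#' are validated. The default scale (500 block groups in 120 tracts, two
#' years, roughly twenty thousand events) is large enough for stable
#' parameter recovery while keeping a full pipeline run in the order of
#' seconds.
#'
#' The racial composition is a three-part mixture chosen to mimic an
#' urbanized, majority-white study region: a point mass of block groups
#' with no black residents, a right-skewed low-percent-black bulk, and a
#' small cluster of black-majority block groups, targeting
#' decedent-weighted percent-black anchors of 0% at the 10th percentile
#' and about 16% at the 90th. PM2.5 is seasonal (summer peak) with AR(1)
#' day-to-day persistence, static per-cell heterogeneity, and a
#' cross-sectional offset proportional to neighborhood percent black so
#' that blacker block groups see systematically higher concentrations.
#' Mortality follows a log-linear daily Poisson rate with day-of-week
#' multipliers, a U-shaped lag-window temperature response, a small
#' residual winter excess, and the configured exposure and interaction
#' terms; for rare daily events this rate model is likelihood-equivalent
#' to the time-stratified conditional logistic target, so the fitted
#' exposure log odds estimate `beta_star + delta_star * m` directly.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param n_block_groups,n_tracts Census geography size.
#' @param start,end Event study period (exposure is generated with a
#'   short leading buffer so lag windows are defined from `start`).
#' @param grid_nx,grid_ny Exposure grid dimensions.
#' @param bbox Named list with `lon` and `lat` ranges (decimal degrees).
#' @param pop_meanlog,pop_sdlog Log-normal block-group population size.
#' @param p_zero_black Share of tracts with no black residents.
#' @param p_black_majority Share of tracts drawn from the high-percent-
#'   black mixture component.
#' @param black_beta,black_major_beta,other_beta Beta-distribution shape
#'   pairs for the tract-level black population share in the low and
#'   high mixture components and for the share of all other races.
#' @param kappa_within Beta concentration of block-group black shares
#'   around their tract share; larger values mean more homogeneous
#'   tracts and hence lower dissimilarity (IRD).
#' @param pm_mean,pm_amp,pm_peak_doy Annual PM2.5 cycle (ug/m3; day of
#'   year of the seasonal peak).
#' @param pm_rho,pm_ar_sd AR(1) coefficient and innovation sd of the
#'   daily PM2.5 deviation (per cell).
#' @param pm_cell_sd Static per-cell offset sd (spatial heterogeneity).
#' @param pm_black_gradient Cross-sectional PM2.5 offset per percentage
#'   point of block-group percent black (ug/m3).
#' @param pm_episode_rate,pm_episode_mean Regional pollution episodes
#'   (inversions, smoke transport): on a `pm_episode_rate` fraction of
#'   days an exponential boost with the given mean (ug/m3) is added to
#'   every cell, producing the occasional exceedance days a restriction
#'   sensitivity analysis filters out.
#' @param temp_mean,temp_amp,temp_peak_doy,temp_rho,temp_ar_sd Daily
#'   temperature process (degrees C; regional, shared across cells).
#' @param base_rate Baseline deaths per block group per day.
#' @param mort_season_amp,mort_season_peak_doy Residual (non-temperature)
#'   log-scale seasonal mortality amplitude and peak.
#' @param dow_log Named log day-of-week multipliers (Sun..Sat).
#' @param temp_lin,temp_quad Temperature response on the log rate
#'   (defaults form a U shape with minimum near 15 C).
#' @param beta_star True per-unit (ug/m3) exposure log odds.
#' @param delta_star True interaction log odds per unit of the modifier
#'   (scalar for continuous modifiers or `race`; length-4 vector G2..G5
#'   versus G1 for `rrs_category`).
#' @param modifier Which modifier the interaction acts on: `"none"`,
#'   `"pct_black"`, `"pct_white"`, `"ird"`, `"race"`, `"rrs_category"`.
#' @param lags Exposure window used by the generating rate (and, for a
#'   correctly specified analysis, by the fit), default `c(0, 1)`.
#' @param max_events Guard: error if the expected event count exceeds it.
#' @return Object of class `cc_sim_config` (a list).
#' @export
cc_sim_config <- function(seed = 1L,
                          n_block_groups = 500L,
                          n_tracts = 120L,
                          start = "2009-01-01",
                          end = "2010-12-31",
                          grid_nx = 12L,
                          grid_ny = 10L,
                          bbox = list(lon = c(-71.5, -70.9),
                                      lat = c(42.1, 42.6)),
                          pop_meanlog = log(1200),
                          pop_sdlog = 0.35,
                          p_zero_black = 0.18,
                          p_black_majority = 0.05,
                          black_beta = c(0.8, 12),
                          black_major_beta = c(1.8, 1.4),
                          other_beta = c(2, 18),
                          kappa_within = 80,
                          pm_mean = 9,
                          pm_amp = 2.5,
                          pm_peak_doy = 196,
                          pm_rho = 0.6,
                          pm_ar_sd = 4.5,
                          pm_cell_sd = 0.8,
                          pm_black_gradient = 0.08,
                          pm_episode_rate = 0.015,
                          pm_episode_mean = 8,
                          temp_mean = 10,
                          temp_amp = 12,
                          temp_peak_doy = 200,
                          temp_rho = 0.7,
                          temp_ar_sd = 2.5,
                          base_rate = 0.056,
                          mort_season_amp = 0.05,
                          mort_season_peak_doy = 15,
                          dow_log = c(Sun = 0, Mon = 0.02, Tue = 0.01,
                                      Wed = 0, Thu = 0, Fri = 0.01,
                                      Sat = -0.02),
                          temp_lin = -0.012,
                          temp_quad = 4e-4,
                          beta_star = log(1.02) / 10,
                          delta_star = 0,
                          modifier = "none",
                          lags = c(0, 1),
                          max_events = 5e5) {
  cfg <- as.list(environment())
  cfg$start <- as.Date(start)
  cfg$end <- as.Date(end)
  stopifnot(cfg$start <= cfg$end,
            pm_rho > -1, pm_rho < 1, temp_rho > -1, temp_rho < 1,
            base_rate > 0, n_block_groups >= n_tracts)
  if (modifier == "rrs_category") {
    stopifnot(length(cfg$delta_star) == 4)
  } else {
    stopifnot(length(cfg$delta_star) == 1)
  }
  structure(cfg, class = "cc_sim_config")
}

seasonal <- function(doy, amp, peak_doy) {
  amp * cos(2 * pi * (doy - peak_doy) / 365.25)
}

day_of_year <- function(dates) as.POSIXlt(dates)$yday + 1L

#' Simulate a census race-count table
#'
#' Draws block-group populations and non-Hispanic white/black counts
#' from the configured composition mixture, nested in tracts whose
#' members share a geographic neighborhood. Returns the canonical census
#' columns plus block-group coordinates (`lon`, `lat`) used for exposure
#' assignment.
#'
#' @param config A [cc_sim_config()].
#' @return Census data frame (`block_group_id`, `tract_id`, `n_white`,
#'   `n_black`, `n_total`, `lon`, `lat`).
#' @export
simulate_census <- function(config) {
  stopifnot(inherits(config, "cc_sim_config"))
  set.seed(config$seed)
  nb <- config$n_block_groups
  nt <- config$n_tracts
  tract_of <- sort(rep_len(seq_len(nt), nb))
  tlon <- stats::runif(nt, config$bbox$lon[1], config$bbox$lon[2])
  tlat <- stats::runif(nt, config$bbox$lat[1], config$bbox$lat[2])
  lon <- tlon[tract_of] + stats::rnorm(nb, 0, 0.008)
  lat <- tlat[tract_of] + stats::rnorm(nb, 0, 0.008)

  n_total <- pmax(50L, round(stats::rlnorm(nb, config$pop_meanlog,
                                           config$pop_sdlog)))
  # tract-level composition with block groups scattered around it:
  # segregation is spatially clustered, and within-tract homogeneity
  # (kappa_within) governs how much dissimilarity (IRD) tracts show.
  # Component counts are exact and the high-percent-black component is
  # spread over its distribution's quantiles, so the full RRS range
  # (all five categories) is represented at every seed.
  nt_zero <- round(config$p_zero_black * nt)
  nt_major <- round(config$p_black_majority * nt)
  nt_low <- max(0L, nt - nt_zero - nt_major)
  b_major <- if (nt_major > 0) {
    stats::qbeta((seq_len(nt_major) - 0.5) / nt_major,
                 config$black_major_beta[1], config$black_major_beta[2])
  } else numeric(0)
  b_tract <- sample(c(rep(0, nt_zero),
                      stats::rbeta(nt_low, config$black_beta[1],
                                   config$black_beta[2]),
                      b_major))
  bt <- b_tract[tract_of]
  k <- config$kappa_within
  p_black <- ifelse(bt <= 0, 0,
                    stats::rbeta(nb, k * bt, k * (1 - bt)))
  p_other <- stats::rbeta(nb, config$other_beta[1], config$other_beta[2])
  n_black <- round(p_black * n_total)
  n_other <- round(p_other * (n_total - n_black))
  n_white <- n_total - n_black - n_other

  data.frame(
    block_group_id = sprintf("bg%04d", seq_len(nb)),
    tract_id = sprintf("t%03d", tract_of),
    n_white = as.integer(n_white), n_black = as.integer(n_black),
    n_total = as.integer(n_total),
    lon = lon, lat = lat, stringsAsFactors = FALSE)
}

#' Simulate the gridded daily exposure series
#'
#' Generates daily PM2.5 and temperature for a regular lon/lat grid over
#' the study bounding box, from `start - max(lags)` (so lag windows are
#' defined on every event day) through `end`. PM2.5 per cell is a summer-
#' peaking annual cycle plus a static cell offset — the configured
#' gradient times the mean percent black of the block groups nearest the
#' cell, plus cell noise — plus an AR(1) daily deviation, truncated at
#' zero. Temperature is a shared regional annual cycle with AR(1) noise.
#'
#' @param config A [cc_sim_config()].
#' @param census Result of [simulate_census()] (provides block-group
#'   coordinates and racial composition for the spatial PM gradient).
#' @return Long exposure data frame (`cell_id`, `lon`, `lat`, `date`,
#'   `pm25`, `temperature`).
#' @export
simulate_exposure <- function(config, census) {
  stopifnot(inherits(config, "cc_sim_config"))
  set.seed(config$seed + 1L)
  gx <- seq(config$bbox$lon[1], config$bbox$lon[2],
            length.out = config$grid_nx)
  gy <- seq(config$bbox$lat[1], config$bbox$lat[2],
            length.out = config$grid_ny)
  cells <- expand.grid(lon = gx, lat = gy)
  cells$cell_id <- sprintf("c%03d", seq_len(nrow(cells)))
  nc <- nrow(cells)

  # cross-sectional gradient: offset follows percent black of the block
  # groups the cell serves (centered so the regional mean is untouched)
  pct_black <- 100 * census$n_black / pmax(1L, census$n_total)
  bg_cell <- assign_nearest_cell(census$lon, census$lat, cells)
  cell_pb <- tapply(pct_black, factor(bg_cell, levels = cells$cell_id),
                    mean)
  cell_pb[is.na(cell_pb)] <- mean(pct_black)
  offset <- config$pm_black_gradient * as.numeric(cell_pb - mean(pct_black)) +
    stats::rnorm(nc, 0, config$pm_cell_sd)

  dates <- seq(config$start - max(config$lags), config$end, by = "day")
  tt <- length(dates)
  doy <- day_of_year(dates)

  # AR(1) deviations, one series per cell, vectorized across cells
  innov <- matrix(stats::rnorm(nc * tt, 0, config$pm_ar_sd), nc, tt)
  E <- matrix(0, nc, tt)
  E[, 1] <- innov[, 1] / sqrt(1 - config$pm_rho^2)
  for (t in 2:tt) E[, t] <- config$pm_rho * E[, t - 1] + innov[, t]
  season <- seasonal(doy, config$pm_amp, config$pm_peak_doy)
  episode <- stats::rbinom(tt, 1L, config$pm_episode_rate) *
    stats::rexp(tt, 1 / config$pm_episode_mean)
  pm <- pmax(0, config$pm_mean + offset +
               matrix(season + episode, nc, tt, byrow = TRUE) + E)

  te <- stats::rnorm(tt, 0, config$temp_ar_sd)
  temp <- numeric(tt)
  temp[1] <- te[1] / sqrt(1 - config$temp_rho^2)
  for (t in 2:tt) temp[t] <- config$temp_rho * temp[t - 1] + te[t]
  temp <- temp + config$temp_mean +
    seasonal(doy, config$temp_amp, config$temp_peak_doy)

  data.frame(
    cell_id = rep(cells$cell_id, tt),
    lon = rep(cells$lon, tt), lat = rep(cells$lat, tt),
    date = rep(dates, each = nc),
    pm25 = as.vector(pm),
    temperature = rep(temp, each = nc),
    stringsAsFactors = FALSE)
}

#' Simulate event records under a known-truth mortality model
#'
#' Draws daily death counts per block group from the log-linear Poisson
#' rate described in [cc_sim_config()] and expands them into decedent
#' records (date, block group, race, descriptive covariates). For rare
#' daily events the implied time-stratified case-crossover log odds for
#' the exposure is `beta_star + delta_star * m` by construction, so
#' pipeline estimates are directly comparable to the returned ground
#' truth.
#'
#' @param config A [cc_sim_config()].
#' @param census Result of [simulate_census()].
#' @param exposure Result of [simulate_exposure()].
#' @return List: `events` (record data frame), `truth` (generating
#'   parameters echoed, with derived percent changes per 10 ug/m3).
#' @export
simulate_events <- function(config, census, exposure) {
  stopifnot(inherits(config, "cc_sim_config"))
  set.seed(config$seed + 2L)
  cells <- exposure[!duplicated(exposure$cell_id),
                    c("cell_id", "lon", "lat")]
  bg_cell <- assign_nearest_cell(census$lon, census$lat, cells)
  win <- exposure_windows(exposure, config$lags)

  dates <- seq(config$start, config$end, by = "day")
  tt <- length(dates)
  nb <- nrow(census)
  cell_ids <- sort(unique(win$cell_id))
  data.table::setkeyv(win, c("cell_id", "date"))
  sub <- win[data.table::CJ(cell_id = cell_ids, date = dates)]
  nc <- length(cell_ids)
  Wpm <- matrix(sub$pm25_window, nc, tt, byrow = TRUE)
  Wt <- matrix(sub$temp_window, nc, tt, byrow = TRUE)
  if (any(is.na(Wpm))) stop("exposure does not cover the study period")
  ci <- match(bg_cell, cell_ids)

  scores <- segregation_scores(census)
  m <- modifier_values(config$modifier, scores)

  dayterm <- seasonal(day_of_year(dates), config$mort_season_amp,
                      config$mort_season_peak_doy) +
    config$dow_log[as.character(day_of_week(dates))]
  Pg <- Wpm[ci, , drop = FALSE]
  Tg <- Wt[ci, , drop = FALSE]
  loglam <- log(config$base_rate) +
    matrix(dayterm, nb, tt, byrow = TRUE) +
    config$beta_star * Pg +
    config$temp_lin * Tg + config$temp_quad * Tg^2

  p_black2 <- ifelse(census$n_white + census$n_black > 0,
                     census$n_black / (census$n_white + census$n_black), 0)

  if (config$modifier == "race") {
    lam_w <- exp(loglam) * (1 - p_black2)
    lam_b <- exp(loglam + config$delta_star * Pg) * p_black2
    expected <- sum(lam_w) + sum(lam_b)
    if (expected > config$max_events) {
      stop("expected event count ", round(expected),
           " exceeds max_events; reduce base_rate")
    }
    cnt_w <- stats::rpois(length(lam_w), lam_w)
    cnt_b <- stats::rpois(length(lam_b), lam_b)
    ev <- rbind(expand_counts(cnt_w, census, dates, bg_cell, "white"),
                expand_counts(cnt_b, census, dates, bg_cell, "black"))
  } else {
    dl <- interaction_offset(config, m, Pg)
    lam <- exp(loglam + dl)
    expected <- sum(lam)
    if (expected > config$max_events) {
      stop("expected event count ", round(expected),
           " exceeds max_events; reduce base_rate")
    }
    cnt <- stats::rpois(length(lam), lam)
    ev <- expand_counts(cnt, census, dates, bg_cell, race = NULL)
    ev$race <- ifelse(stats::runif(nrow(ev)) <
                        p_black2[match(ev$block_group_id,
                                       census$block_group_id)],
                      "black", "white")
  }
  ev <- ev[order(ev$death_date, ev$block_group_id), , drop = FALSE]
  ev$record_id <- sprintf("r%06d", seq_len(nrow(ev)))
  n <- nrow(ev)
  ev$age <- pmin(105L, 40L + stats::rpois(n, 38))
  ev$sex <- ifelse(stats::runif(n) < 0.47, "male", "female")
  ev$education <- sample(c("lt_hs", "hs", "some_college", "college_plus"),
                         n, replace = TRUE, prob = c(.2, .35, .25, .2))
  ev$place_of_death <- sample(c("home", "hospital", "other"), n,
                              replace = TRUE, prob = c(.3, .6, .1))
  rownames(ev) <- NULL
  ev <- ev[, c("record_id", "death_date", "block_group_id", "cell_id",
               "race", "age", "sex", "education", "place_of_death")]

  truth <- list(
    beta_star = config$beta_star,
    delta_star = config$delta_star,
    modifier = config$modifier,
    pct_change_per10_at_m0 = 100 * (exp(10 * config$beta_star) - 1),
    n_events = nrow(ev),
    expected_events = expected,
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), c("bbox"))])
  list(events = ev, truth = truth)
}

modifier_values <- function(modifier, scores) {
  switch(modifier,
         none = rep(0, nrow(scores)),
         pct_black = scores$pct_black,
         pct_white = scores$pct_white,
         ird = ifelse(is.na(scores$ird), 0, scores$ird),
         rrs_category = as.integer(scores$rrs_category),
         race = rep(0, nrow(scores)),
         stop("unknown modifier: ", modifier))
}

interaction_offset <- function(config, m, Pg) {
  if (config$modifier == "none") return(0)
  if (config$modifier == "rrs_category") {
    dvec <- c(0, config$delta_star)[m]  # category index 1..5 -> delta
    return(Pg * dvec)
  }
  Pg * (config$delta_star * m)
}

expand_counts <- function(cnt, census, dates, bg_cell, race) {
  nb <- nrow(census)
  idx <- which(cnt > 0)
  if (!length(idx)) {
    out <- data.frame(death_date = as.Date(character(0)),
                      block_group_id = character(0),
                      cell_id = character(0), stringsAsFactors = FALSE)
    if (!is.null(race)) out$race <- character(0)
    return(out)
  }
  reps <- cnt[idx]
  g <- rep(((idx - 1L) %% nb) + 1L, reps)
  t <- rep(((idx - 1L) %/% nb) + 1L, reps)
  out <- data.frame(death_date = dates[t],
                    block_group_id = census$block_group_id[g],
                    cell_id = bg_cell[g], stringsAsFactors = FALSE)
  if (!is.null(race)) out$race <- race
  out
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_census()], [simulate_exposure()] and
#' [simulate_events()] and computes segregation scores, returning every
#' input the analysis pipeline needs plus the ground truth.
#'
#' @param config A [cc_sim_config()].
#' @return List: `census`, `scores`, `exposure`, `events`, `truth`,
#'   `config`.
#' @export
simulate_study <- function(config = cc_sim_config()) {
  census <- simulate_census(config)
  exposure <- simulate_exposure(config, census)
  sim <- simulate_events(config, census, exposure)
  list(census = census, scores = segregation_scores(census),
       exposure = exposure, events = sim$events, truth = sim$truth,
       config = config)
}

#' Write the synthetic study inputs to a directory
#'
#' Emits `census.csv`, `exposure.csv`, `events.csv` and `truth.json`.
#'
#' @param study Result of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$census, file.path(outdir, "census.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$exposure, file.path(outdir, "exposure.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$events, file.path(outdir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(jsonlite::toJSON(study$truth, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(outdir, "truth.json"))
  invisible(outdir)
}
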