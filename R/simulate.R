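# Stage-structured synthetic GPS cohorts with known ground truth.
#
# Movement is pieced together from two kernels: Ornstein-Uhlenbeck
# wandering around an attraction centre (nest dependence, Sahel stay,
# resident cores) and a biased correlated random walk towards a target
# (migration legs through a Gibraltar gate).  Geography is schematic --
# nest points, a gate, latitude bands -- so no basemap data is needed.
# A transmitter layer adds DOP noise, positional jitter, missed fixes,
# battery readings, post-death behaviour (stationary tag or abrupt
# silence) and optional mid-track outages, and every generative boundary
# is recorded as ground truth for recovery testing.

#' Simulation configuration
#'
#' Defaults emulate a juvenile trans-Saharan vulture cohort: 32 birds
#' from three breeding nuclei (17/10/5), balanced sexes, three
#' year-round residents (first nucleus only), a ~20-day dependence
#' period wandering ~10 km/day near the nest, pre-migration transit of
#' Iberia (~2 weeks), an ~11-day Sahara crossing, a multi-month Sahel
#' stay inside 13.3-22.5 deg N with ~10^5 km^2 ranges, a spring return
#' after ~600 days, resident seasonal cores (south September-March,
#' north April-August), per-stage daily mortality hazards concentrated
#' in migration and the Sahel, and transmitter artifacts.
#'
#' @param ... Named overrides of any default field (nested lists are
#'   replaced wholesale).
#' @return A list of class `vt_sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    nuclei = data.frame(
      nucleus = c("Arribes", "Galicia", "Segovia"),
      n = c(17L, 10L, 5L),
      nest_lon = c(-6.55, -7.30, -3.85),
      nest_lat = c(41.25, 42.10, 41.45),
      stringsAsFactors = FALSE),
    nest_jitter_deg = 0.12,
    n_non_migrants = 3L,          # first nucleus only
    tagging_year = 2020L,
    tagging_doy = c(186L, 196L),  # early-to-mid July
    obs_days = 750,
    fix_interval_min = 30,
    # dependence: tight nestling phase, then ~10 km/day wandering
    nestling_days = c(3, 8),
    nestling_sd_km = 0.05,
    nestling_reversion = 2,
    dependence_days_meanlog = log(18),
    dependence_days_sdlog = 0.45,
    dependence_sd_km = 1.0,
    dependence_reversion = 0.8,
    # pre-migration transit of Iberia
    premig_days_meanlog = log(13),
    premig_days_sdlog = 0.5,
    premig_wiggle_deg = 25,
    gate_lon = -5.65, gate_lat = 36.0, gate_jitter_deg = 0.1,
    # Sahara crossing, calibrated to ~11-day 30->22.5 deg N transits
    sahara_days_meanlog = log(10.5),
    sahara_days_sdlog = 0.35,
    sahara_wiggle_deg = 12,
    desert_north_lat = 30, sahel_north_lat = 22.5, sahel_south_lat = 13.3,
    sahel_target_lon = c(-15, -2),
    sahel_target_lat = c(14, 17.5),
    # Sahel stay
    sahel_days_mean = 600, sahel_days_sd = 40,
    sahel_sd_km = 90, sahel_reversion = 0.03,
    # return and post-return
    return_days_meanlog = log(18), return_days_sdlog = 0.3,
    return_wiggle_deg = 18,
    postreturn_lon = -6.0, postreturn_lat = 39.5,
    postreturn_sd_km = 30, postreturn_reversion = 0.2,
    # resident two-core system
    south_core_lon = -6.15, south_core_lat = 39.55,   # Caceres area
    north_core_lon = -6.00, north_core_lat = 41.00,   # Salamanca area
    south_months = c(9:12, 1:3), # September-March
    resident_sd_km = 18, resident_reversion = 0.35,
    settle_speed_kmday = 60,
    crw_attraction = 0.25,
    # per-stage daily death hazards (apparent mortality generators)
    hazards = c(dependence = 0,
                iberia_premigration = 0.006,
                sahara_crossing = 0.006,
                sahel_stay = 0.0009,
                return_migration = 0.001,
                iberia_postreturn = 0.0008,
                residency = 0.0003),
    # transmitter layer
    miss_rate = 0.05,
    jitter_m = 20,
    death_jitter_m = 5,
    dop_bad_prob = 0.05,
    battery_v = 3.95, battery_sd = 0.05,
    post_death_stationary_prob = 0.7,
    post_death_days = c(15, 30),
    outage_prob = 0.1,
    outage_days = c(10, 25),
    intermittency_age_years = 5,
    intermittent_keep_prob = 0.08
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  probs <- c(cfg$miss_rate, cfg$dop_bad_prob,
             cfg$post_death_stationary_prob, cfg$outage_prob,
             cfg$intermittent_keep_prob, unname(cfg$hazards))
  if (any(probs < 0 | probs > 1))
    stop("invalid sim_config field: probabilities must lie in [0, 1]")
  if (!(cfg$sahel_south_lat < cfg$sahel_north_lat))
    stop("invalid sim_config field: sahel latitude band must be ordered")
  if (cfg$obs_days <= 0 || cfg$fix_interval_min <= 0 ||
      cfg$sahel_sd_km <= 0 || cfg$resident_sd_km <= 0)
    stop("invalid sim_config field: scales must be positive")
  class(cfg) <- "vt_sim_config"
  cfg
}

#' One Ornstein-Uhlenbeck step
#'
#' Exact-discretisation mean-reverting Gaussian step: with reversion
#' theta and noise scale s, the stationary positional SD per axis is
#' `s / sqrt(2 theta)`.  `reversion = 0` degenerates to a pure Brownian
#' increment; `scale = 0` to deterministic decay towards the centre.
#'
#' @param current,center Numeric length-2 points (km).
#' @param reversion Mean-reversion rate (1/day).
#' @param scale Noise scale (km/sqrt(day)).
#' @param dt Time step (days).
#' @return Numeric length-2 new position.
#' @export
ou_step <- function(current, center, reversion, scale, dt) {
  if (dt <= 0) stop("dt must be positive")
  a <- exp(-reversion * dt)
  b <- if (reversion > 0) scale * sqrt((1 - a^2) / (2 * reversion))
       else scale * sqrt(dt)
  center + (current - center) * a + b * stats::rnorm(2)
}

# Vectorised OU path: n positions after `start`, one per step.
.ou_path <- function(n, start, center, reversion, scale, dt) {
  if (n <= 0L) return(matrix(numeric(), ncol = 2))
  a <- exp(-reversion * dt)
  b <- if (reversion > 0) scale * sqrt((1 - a^2) / (2 * reversion))
       else scale * sqrt(dt)
  x <- stats::filter(b * stats::rnorm(n), a, method = "recursive",
                     init = start[1] - center[1])
  y <- stats::filter(b * stats::rnorm(n), a, method = "recursive",
                     init = start[2] - center[2])
  cbind(as.numeric(x) + center[1], as.numeric(y) + center[2])
}

#' One biased correlated-random-walk step
#'
#' The new heading mixes the previous heading with the bearing to the
#' target (circular weighted mean, weight `attraction` on the target)
#' plus Gaussian angular noise; displacement is `speed * dt` along the
#' new heading.  `wiggle_sd = 0` with `attraction = 1` gives a straight
#' line to the target; `speed = 0` is stationary.
#'
#' @param current Numeric length-2 position (km).
#' @param heading Previous heading (radians).
#' @param target Numeric length-2 target (km).
#' @param speed Speed (km/day), >= 0.
#' @param attraction Weight of the bearing-to-target in `[0, 1]`.
#' @param wiggle_sd Angular noise SD (radians).
#' @param dt Time step (days).
#' @return List with `point` and `heading`.
#' @export
biased_crw_step <- function(current, heading, target, speed,
                            attraction = 0.25, wiggle_sd = 0.3, dt) {
  if (speed < 0) stop("speed must be non-negative")
  bearing <- atan2(target[2] - current[2], target[1] - current[1])
  mx <- attraction * cos(bearing) + (1 - attraction) * cos(heading)
  my <- attraction * sin(bearing) + (1 - attraction) * sin(heading)
  h <- atan2(my, mx) + stats::rnorm(1, 0, wiggle_sd)
  list(point = current + speed * dt * c(cos(h), sin(h)), heading = h)
}

# CRW path from start towards target; stops within one step of the
# target or after max_steps.  Returns a matrix of positions (possibly
# 0-row).
.crw_path <- function(start, target, speed, attraction, wiggle_sd, dt,
                      max_steps) {
  step_len <- speed * dt
  out <- matrix(NA_real_, nrow = max_steps, ncol = 2)
  pos <- start
  heading <- atan2(target[2] - start[2], target[1] - start[1])
  k <- 0L
  while (k < max_steps) {
    if (sqrt(sum((target - pos)^2)) <= step_len) break
    st <- biased_crw_step(pos, heading, target, speed, attraction,
                          wiggle_sd, dt)
    pos <- st$point; heading <- st$heading
    k <- k + 1L
    out[k, ] <- pos
  }
  out[seq_len(k), , drop = FALSE]
}

# Project lon/lat path pieces between stage frames.
.to_frame <- function(lonlat, center) {
  p <- project_laea(lonlat[, 1], lonlat[, 2], center)
  cbind(p$x, p$y)
}
.from_frame <- function(xy, center) {
  ll <- unproject_laea(xy[, 1], xy[, 2], center)
  cbind(ll$lon, ll$lat)
}

# Reflect a coordinate vector into [lo, hi].
.reflect_into <- function(v, lo, hi) {
  for (i in 1:3) {
    v <- ifelse(v > hi, 2 * hi - v, v)
    v <- ifelse(v < lo, 2 * lo - v, v)
  }
  pmin(pmax(v, lo), hi)
}

#' Plan a synthetic cohort
#'
#' Assigns nuclei, exact balanced sexes, nests, tagging dates,
#' transmitter models, migratory strategies (non-migrants drawn from the
#' first nucleus) and per-individual random-number substreams, all
#' reproducible from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return Data frame with one row per individual.
#' @export
cohort_plan <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  nuc <- config$nuclei
  n_total <- sum(nuc$n)
  nucleus <- rep(nuc$nucleus, nuc$n)
  within_i <- unlist(lapply(nuc$n, seq_len))
  id <- sprintf("%s%02d", substr(nucleus, 1, 3), within_i)
  sex <- sample(rep_len(c("M", "F"), n_total))
  nest_lon <- rep(nuc$nest_lon, nuc$n) +
    stats::runif(n_total, -config$nest_jitter_deg, config$nest_jitter_deg)
  nest_lat <- rep(nuc$nest_lat, nuc$n) +
    stats::runif(n_total, -config$nest_jitter_deg, config$nest_jitter_deg)
  doy <- sample(seq(config$tagging_doy[1], config$tagging_doy[2]),
                n_total, replace = TRUE)
  tagging_date <- as.Date(doy - 1,
                          origin = as.Date(sprintf("%d-01-01",
                                                   config$tagging_year)))
  model <- rep("solar-GSM-30g", n_total)
  if (nrow(nuc) >= 2L && sum(nucleus == nuc$nucleus[2]) > 0L) {
    k2 <- min(5L, sum(nucleus == nuc$nucleus[2]))
    model[which(nucleus == nuc$nucleus[2])[seq_len(k2)]] <-
      "archival-GPS-48g"
  }
  strategy <- rep("migrant", n_total)
  first_nuc <- which(nucleus == nuc$nucleus[1])
  k <- min(config$n_non_migrants, length(first_nuc))
  if (k > 0L) strategy[sample(first_nuc, k)] <- "non_migrant"
  sibling_group <- rep(NA_character_, n_total)
  if (sum(nucleus == nuc$nucleus[1]) >= 2L)
    sibling_group[which(nucleus == nuc$nucleus[1])[1:2]] <- "sibA"
  if (nrow(nuc) >= 3L && sum(nucleus == nuc$nucleus[3]) >= 2L)
    sibling_group[which(nucleus == nuc$nucleus[3])[1:2]] <- "sibB"
  seed_i <- (abs(seed) %% 1000000L) * 1000L + seq_len(n_total)
  data.frame(individual_id = id, nucleus = nucleus, sex = sex,
             nest_lon = nest_lon, nest_lat = nest_lat,
             tagging_date = tagging_date, transmitter_model = model,
             sibling_group = sibling_group, strategy = strategy,
             seed = seed_i, stringsAsFactors = FALSE)
}

#' Simulate one individual
#'
#' Generates the ideal (noise-free) path for one planned individual,
#' samples death from the per-stage hazards, applies the transmitter
#' layer and returns the observed track plus ground truth.
#'
#' @param plan One row of [cohort_plan()] (data frame or list).
#' @param config A [sim_config()].
#' @return List with `track` (a [vt_track] of observed fixes), `truth`
#'   (one-row data frame of generative boundaries, death and transmitter
#'   annotations) and `ideal` (the noise-free path with stage labels).
#' @export
simulate_individual <- function(plan, config = sim_config()) {
  plan <- as.list(plan)
  set.seed(plan$seed)
  dt <- config$fix_interval_min / 1440
  per_day <- 1440 / config$fix_interval_min
  n_max <- ceiling(config$obs_days * per_day)
  nest <- c(plan$nest_lon, plan$nest_lat)
  deg_wig <- function(deg) deg * pi / 180

  ll <- NULL        # lon/lat rows
  stage <- character()
  push <- function(lonlat, st) {
    ll <<- rbind(ll, lonlat)
    stage <<- c(stage, rep(st, nrow(lonlat)))
  }

  # --- dependence (nestling + wander) around the nest -------------------
  n_nestling <- round(stats::runif(1, config$nestling_days[1],
                                   config$nestling_days[2]) * per_day)
  n_dep <- round(stats::rlnorm(1, config$dependence_days_meanlog,
                               config$dependence_days_sdlog) * per_day)
  sc_nest <- config$nestling_sd_km * sqrt(2 * config$nestling_reversion)
  sc_dep <- config$dependence_sd_km * sqrt(2 * config$dependence_reversion)
  p1 <- .ou_path(n_nestling, c(0, 0), c(0, 0), config$nestling_reversion,
                 sc_nest, dt)
  p2 <- .ou_path(n_dep, if (nrow(p1)) p1[nrow(p1), ] else c(0, 0), c(0, 0),
                 config$dependence_reversion, sc_dep, dt)
  push(.from_frame(rbind(p1, p2), nest), "dependence")
  cur <- ll[nrow(ll), ]

  if (plan$strategy == "migrant") {
    # --- pre-migration: Iberia to the Gibraltar gate --------------------
    gate <- c(config$gate_lon + stats::runif(1, -1, 1) * config$gate_jitter_deg,
              config$gate_lat)
    premig_days <- stats::rlnorm(1, config$premig_days_meanlog,
                                 config$premig_days_sdlog)
    fr <- (cur + gate) / 2
    st_xy <- .to_frame(rbind(cur), fr)[1, ]
    gt_xy <- .to_frame(rbind(gate), fr)[1, ]
    dist0 <- sqrt(sum((gt_xy - st_xy)^2))
    speed <- min(300, max(30, dist0 / premig_days))
    leg <- .crw_path(st_xy, gt_xy, speed, config$crw_attraction,
                     deg_wig(config$premig_wiggle_deg), dt,
                     max_steps = round(6 * dist0 / (speed * dt)))
    push(.from_frame(leg, fr), "iberia_premigration")
    cur <- ll[nrow(ll), ]

    # --- Sahara crossing to a Sahel target ------------------------------
    target <- c(stats::runif(1, config$sahel_target_lon[1],
                             config$sahel_target_lon[2]),
                stats::runif(1, config$sahel_target_lat[1],
                             config$sahel_target_lat[2]))
    sahara_days <- stats::rlnorm(1, config$sahara_days_meanlog,
                                 config$sahara_days_sdlog)
    wig <- deg_wig(config$sahara_wiggle_deg)
    straightness <- exp(-wig^2 / 2)
    desert_km <- (config$desert_north_lat - config$sahel_north_lat) *
      pi * .EARTH_RADIUS_KM / 180
    speed <- desert_km / (sahara_days * straightness)
    fr <- (cur + target) / 2
    st_xy <- .to_frame(rbind(cur), fr)[1, ]
    tg_xy <- .to_frame(rbind(target), fr)[1, ]
    dist0 <- sqrt(sum((tg_xy - st_xy)^2))
    leg <- .crw_path(st_xy, tg_xy, speed, 2 * config$crw_attraction,
                     wig, dt, max_steps = round(4 * dist0 / (speed * dt)))
    leg_ll <- .from_frame(leg, fr)
    arr <- which(leg_ll[, 2] <= config$sahel_north_lat)[1L]
    if (is.na(arr)) arr <- nrow(leg_ll) + 1L   # never happens in practice
    if (arr > 1L) push(leg_ll[seq_len(arr - 1L), , drop = FALSE],
                       "sahara_crossing")
    if (arr <= nrow(leg_ll))
      push(leg_ll[arr:nrow(leg_ll), , drop = FALSE], "sahel_stay")
    cur <- ll[nrow(ll), ]

    # --- Sahel wandering inside the latitude band -----------------------
    sahel_days <- max(30, stats::rnorm(1, config$sahel_days_mean,
                                       config$sahel_days_sd))
    n_sahel <- min(round(sahel_days * per_day),
                   max(0L, n_max - nrow(ll)))
    if (n_sahel > 0L) {
      fr <- target
      st_xy <- .to_frame(rbind(cur), fr)[1, ]
      sc <- config$sahel_sd_km * sqrt(2 * config$sahel_reversion)
      wander <- .ou_path(n_sahel, st_xy, c(0, 0), config$sahel_reversion,
                         sc, dt)
      wl <- .from_frame(wander, fr)
      wl[, 2] <- .reflect_into(wl[, 2], config$sahel_south_lat + 0.05,
                               config$sahel_north_lat - 0.05)
      push(wl, "sahel_stay")
      cur <- ll[nrow(ll), ]
    }

    # --- return migration and post-return Iberia ------------------------
    if (nrow(ll) < n_max) {
      return_days <- stats::rlnorm(1, config$return_days_meanlog,
                                   config$return_days_sdlog)
      fr <- (cur + gate) / 2
      st_xy <- .to_frame(rbind(cur), fr)[1, ]
      gt_xy <- .to_frame(rbind(gate), fr)[1, ]
      dist0 <- sqrt(sum((gt_xy - st_xy)^2))
      speed <- min(350, max(40, dist0 / return_days))
      leg <- .crw_path(st_xy, gt_xy, speed, 2 * config$crw_attraction,
                       deg_wig(config$return_wiggle_deg), dt,
                       max_steps = round(4 * dist0 / (speed * dt)))
      push(.from_frame(leg, fr), "return_migration")
      cur <- ll[nrow(ll), ]

      post_ctr <- c(config$postreturn_lon, config$postreturn_lat)
      fr <- (cur + post_ctr) / 2
      st_xy <- .to_frame(rbind(cur), fr)[1, ]
      pc_xy <- .to_frame(rbind(post_ctr), fr)[1, ]
      dist0 <- max(1, sqrt(sum((pc_xy - st_xy)^2)))
      leg <- .crw_path(st_xy, pc_xy, 100, 2 * config$crw_attraction,
                       deg_wig(20), dt,
                       max_steps = round(4 * dist0 / (100 * dt)))
      push(.from_frame(leg, fr), "return_migration")
      cur <- ll[nrow(ll), ]

      n_rest <- n_max - nrow(ll)
      if (n_rest > 0L) {
        fr <- post_ctr
        st_xy <- .to_frame(rbind(cur), fr)[1, ]
        sc <- config$postreturn_sd_km * sqrt(2 * config$postreturn_reversion)
        wander <- .ou_path(n_rest, st_xy, c(0, 0),
                           config$postreturn_reversion, sc, dt)
        push(.from_frame(wander, fr), "iberia_postreturn")
      }
    }
  } else {
    # --- resident: settle, then seasonal two-core wandering -------------
    south <- c(config$south_core_lon, config$south_core_lat)
    north <- c(config$north_core_lon, config$north_core_lat)
    t0 <- as.POSIXct(paste(plan$tagging_date, "00:00:00"), tz = "UTC")
    month_now <- as.integer(format(t0 + nrow(ll) * dt * 86400, "%m"))
    active0 <- if (month_now %in% config$south_months) south else north
    fr <- (cur + active0) / 2
    st_xy <- .to_frame(rbind(cur), fr)[1, ]
    ac_xy <- .to_frame(rbind(active0), fr)[1, ]
    dist0 <- max(1, sqrt(sum((ac_xy - st_xy)^2)))
    leg <- .crw_path(st_xy, ac_xy, config$settle_speed_kmday,
                     2 * config$crw_attraction, deg_wig(20), dt,
                     max_steps = round(6 * dist0 /
                                         (config$settle_speed_kmday * dt)))
    push(.from_frame(leg, fr), "residency")
    cur <- ll[nrow(ll), ]

    sc <- config$resident_sd_km * sqrt(2 * config$resident_reversion)
    while (nrow(ll) < n_max) {
      t_now <- t0 + nrow(ll) * dt * 86400
      mon <- as.integer(format(t_now, "%m"))
      active <- if (mon %in% config$south_months) south else north
      # steps until the first day of the next month
      nxt <- as.POSIXct(format(
        seq(as.Date(format(t_now, "%Y-%m-01")), by = "month",
            length.out = 2)[2]), tz = "UTC")
      n_block <- min(n_max - nrow(ll),
                     max(1L, ceiling(as.numeric(difftime(nxt, t_now,
                                                         units = "days")) *
                                       per_day)))
      fr <- active
      st_xy <- .to_frame(rbind(cur), fr)[1, ]
      wander <- .ou_path(n_block, st_xy, c(0, 0),
                         config$resident_reversion, sc, dt)
      push(.from_frame(wander, fr), "residency")
      cur <- ll[nrow(ll), ]
    }
  }

  if (nrow(ll) > n_max) {
    ll <- ll[seq_len(n_max), , drop = FALSE]
    stage <- stage[seq_len(n_max)]
  }
  t0 <- as.POSIXct(paste(plan$tagging_date, "00:00:00"), tz = "UTC")
  ts <- t0 + (seq_len(nrow(ll)) - 1L) * config$fix_interval_min * 60

  # --- hazards: first per-fix Bernoulli success kills the bird ----------
  h <- unname(config$hazards[stage])
  h[is.na(h)] <- 0
  u <- stats::runif(length(h))
  die_idx <- which(u < h * dt)[1L]
  death_time <- as.POSIXct(NA)
  death_stage <- NA_character_
  post_death_mode <- NA_character_
  alive <- rep(TRUE, nrow(ll))
  if (!is.na(die_idx)) {
    death_time <- ts[die_idx]
    death_stage <- stage[die_idx]
    ll <- ll[seq_len(die_idx), , drop = FALSE]
    stage <- stage[seq_len(die_idx)]
    ts <- ts[seq_len(die_idx)]
    alive <- alive[seq_len(die_idx)]
    post_death_mode <-
      if (stats::runif(1) < config$post_death_stationary_prob)
        "stationary" else "silent"
    if (post_death_mode == "stationary") {
      n_post <- round(stats::runif(1, config$post_death_days[1],
                                   config$post_death_days[2]) * per_day)
      ll <- rbind(ll, matrix(rep(ll[nrow(ll), ], n_post), ncol = 2,
                             byrow = TRUE))
      stage <- c(stage, rep("post_death", n_post))
      ts <- c(ts, ts[length(ts)] +
                seq_len(n_post) * config$fix_interval_min * 60)
      alive <- c(alive, rep(FALSE, n_post))
    }
  }

  ideal <- data.frame(timestamp = ts, lon = ll[, 1], lat = ll[, 2],
                      stage = stage, alive = alive,
                      stringsAsFactors = FALSE)

  # --- generative truth -------------------------------------------------
  first_of <- function(st) {
    i <- which(ideal$stage == st)[1L]
    if (is.na(i)) as.POSIXct(NA) else ideal$timestamp[i]
  }
  d_nest <- haversine_km(ideal$lon, ideal$lat, nest[1], nest[2])
  i_nd <- which(d_nest >= 0.2 & ideal$alive)[1L]
  gib <- NA
  i_gib <- which(ideal$lat <= config$gate_lat &
                   ideal$stage %in% c("iberia_premigration",
                                      "sahara_crossing"))[1L]
  i_des <- {
    i_arr <- which(ideal$stage == "sahel_stay")[1L]
    if (is.na(i_arr)) NA_integer_
    else {
      cand <- which(ideal$lat >= config$desert_north_lat &
                      seq_len(nrow(ideal)) < i_arr)
      if (length(cand) == 0L) NA_integer_ else max(cand)
    }
  }
  ts_or_na <- function(i) if (is.na(i)) as.POSIXct(NA) else ideal$timestamp[i]
  i_ret <- which(ideal$stage == "return_migration")[1L]
  i_comp <- which(ideal$lat >= config$gate_lat &
                    seq_len(nrow(ideal)) > ifelse(is.na(i_ret), Inf, i_ret))[1L]

  truth <- data.frame(
    individual_id = plan$individual_id,
    strategy = plan$strategy,
    nest_departure = ts_or_na(i_nd),
    natal_departure = first_of(if (plan$strategy == "migrant")
      "iberia_premigration" else "residency"),
    gibraltar_crossing = ts_or_na(i_gib),
    desert_entry = ts_or_na(i_des),
    sahel_arrival = first_of("sahel_stay"),
    return_start = first_of("return_migration"),
    return_completion = ts_or_na(i_comp),
    death_time = death_time,
    death_stage = death_stage,
    post_death_mode = post_death_mode,
    stringsAsFactors = FALSE)

  obs <- apply_transmitter(ideal, config)
  truth$outage_start <- attr(obs, "outage_start")
  truth$outage_end <- attr(obs, "outage_end")
  truth$n_fixes <- nrow(obs)

  deployment <- data.frame(
    individual_id = plan$individual_id, sex = plan$sex,
    nucleus = plan$nucleus, nest_lon = plan$nest_lon,
    nest_lat = plan$nest_lat, tagging_date = plan$tagging_date,
    transmitter_model = plan$transmitter_model,
    sibling_group = if (is.null(plan$sibling_group)) NA_character_
      else plan$sibling_group,
    stringsAsFactors = FALSE)
  list(track = vt_track(obs, deployment), truth = truth, ideal = ideal)
}

#' Apply the transmitter observation layer to an ideal path
#'
#' Thins fixes at the missingness rate, adds positional jitter (smaller
#' after death: a motionless tag under open sky), draws HDOP/VDOP with
#' `dop_bad_prob` mass failing a DOP > 5 filter, battery voltages and an
#' activity index (near-zero after death), optionally removes a
#' mid-Sahel outage window, and thins old-tag fixes to intermittent
#' reception past the intermittency onset age.
#'
#' @param ideal Data frame with `timestamp`, `lon`, `lat`, `alive` and
#'   optionally `stage` (used for outage placement).
#' @param config A [sim_config()].
#' @return Data frame of observed fixes (`timestamp`, `lon`, `lat`,
#'   `hdop`, `vdop`, `battery_v`, `activity`) with attributes
#'   `outage_start` / `outage_end` (POSIXct or NA).
#' @export
apply_transmitter <- function(ideal, config = sim_config()) {
  n <- nrow(ideal)
  alive <- if (is.null(ideal$alive)) rep(TRUE, n) else ideal$alive
  jit_m <- ifelse(alive, config$jitter_m, config$death_jitter_m)
  lat_m_per_deg <- 111194.9
  lon <- ideal$lon + stats::rnorm(n, 0, jit_m) /
    (lat_m_per_deg * cos(ideal$lat * pi / 180))
  lat <- ideal$lat + stats::rnorm(n, 0, jit_m) / lat_m_per_deg

  bad <- stats::runif(n) < config$dop_bad_prob
  hdop <- ifelse(bad, stats::runif(n, 5.05, 15), stats::runif(n, 0.6, 4.8))
  vdop <- ifelse(bad & stats::runif(n) < 0.5,
                 stats::runif(n, 5.05, 15), stats::runif(n, 0.8, 4.8))
  battery <- pmin(4.2, pmax(3.2, stats::rnorm(n, config$battery_v,
                                              config$battery_sd)))
  activity <- ifelse(alive, stats::rlnorm(n, log(40), 0.5),
                     stats::runif(n, 0, 1))

  keep <- stats::runif(n) >= config$miss_rate

  outage_start <- as.POSIXct(NA)
  outage_end <- as.POSIXct(NA)
  sahel_idx <- if (!is.null(ideal$stage))
    which(ideal$stage == "sahel_stay" & alive) else integer()
  if (length(sahel_idx) > 48L && stats::runif(1) < config$outage_prob) {
    len_days <- stats::runif(1, config$outage_days[1], config$outage_days[2])
    i0 <- sample(sahel_idx[seq_len(max(1L, length(sahel_idx) - 48L))], 1L)
    outage_start <- ideal$timestamp[i0]
    outage_end <- outage_start + len_days * 86400
    keep <- keep & !(ideal$timestamp >= outage_start &
                       ideal$timestamp <= outage_end)
  }

  age_years <- as.numeric(difftime(ideal$timestamp, ideal$timestamp[1L],
                                   units = "days")) / 365.25
  old <- age_years > config$intermittency_age_years
  if (any(old)) {
    keep[old] <- keep[old] &
      stats::runif(sum(old)) < config$intermittent_keep_prob
  }
  keep[1L] <- TRUE   # the tagging fix is always received

  out <- data.frame(timestamp = ideal$timestamp, lon = lon, lat = lat,
                    hdop = hdop, vdop = vdop, battery_v = battery,
                    activity = activity)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "outage_start") <- outage_start
  attr(out, "outage_end") <- outage_end
  out
}

#' Simulate a full cohort
#'
#' Runs [cohort_plan()] and [simulate_individual()] for every planned
#' bird.  Fully reproducible: the same `config` and `seed` give
#' identical output, whether individuals are simulated together or one
#' at a time.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return An object of class `vt_cohort`: list with `tracks`
#'   (a `vt_tracks` list), `deployments`, `truth` (one row per bird),
#'   `plan`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  plan <- cohort_plan(config, seed)
  sims <- lapply(seq_len(nrow(plan)), function(i)
    simulate_individual(plan[i, ], config))
  tracks <- lapply(sims, function(s) s$track)
  names(tracks) <- plan$individual_id
  truth <- do.call(rbind, lapply(sims, function(s) s$truth))
  deployments <- do.call(rbind, lapply(tracks, function(t) t$deployment))
  rownames(deployments) <- NULL
  structure(list(tracks = structure(tracks, class = "vt_tracks"),
                 deployments = deployments, truth = truth,
                 plan = plan, config = config, seed = seed),
            class = "vt_cohort")
}

#' @export
print.vt_cohort <- function(x, ...) {
  cat(sprintf("<vt_cohort> %d individuals (seed %d): %s\n",
              nrow(x$plan), x$seed,
              paste(sprintf("%s n=%d", x$config$nuclei$nucleus,
                            x$config$nuclei$n), collapse = ", ")))
  cat(sprintf("  strategies: %s\n",
              paste(names(table(x$plan$strategy)), table(x$plan$strategy),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write a cohort to Movebank-dialect CSVs plus a truth table
#'
#' Emits `fixes.csv`, `deployments.csv` (both readable by
#' [read_movebank()]) and `truth.json`.
#'
#' @param cohort A `vt_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fixes_path <- file.path(dir, "fixes.csv")
  dep_path <- file.path(dir, "deployments.csv")
  truth_path <- file.path(dir, "truth.json")
  write_movebank(cohort$tracks, fixes_path, dep_path)
  tr <- cohort$truth
  for (col in names(tr)) {
    if (inherits(tr[[col]], "POSIXct"))
      tr[[col]] <- format(tr[[col]], "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = 10,
                       na = "null")
  invisible(c(fixes_path, dep_path, truth_path))
}
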