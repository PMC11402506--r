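test_that("the default cohort plan reproduces the study design", {
  plan <- cohort_plan(sim_config(), 1)
  expect_equal(nrow(plan), 32L)
  expect_equal(unname(table(plan$nucleus)[c("Arribes", "Galicia",
                                            "Segovia")]),
               c(17L, 10L, 5L), ignore_attr = TRUE)
  expect_equal(sum(plan$sex == "M"), 16L)
  expect_equal(sum(plan$strategy == "non_migrant"), 3L)
  expect_true(all(plan$nucleus[plan$strategy == "non_migrant"] == "Arribes"))
})

test_that("simulation is deterministic and independent of batching", {
  cfg <- small_sim_config(obs_days = 60)
  a <- simulate_cohort(cfg, 7)
  b <- simulate_cohort(cfg, 7)
  expect_identical(a$truth, b$truth)
  expect_identical(a$tracks[[1]]$fixes, b$tracks[[1]]$fixes)

  # simulating one individual alone reproduces its in-cohort track
  plan <- cohort_plan(cfg, 7)
  solo <- simulate_individual(plan[3, ], cfg)
  expect_identical(solo$track$fixes, a$tracks[[3]]$fixes)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(bogus_field = 1), "bogus_field")
  expect_error(sim_config(miss_rate = 1.5), "probabilities")
  expect_error(sim_config(sahel_sd_km = -5), "positive")
})

test_that("emitted files pass ingestion and truth is consistent with the fixes", {
  cfg <- small_sim_config(obs_days = 90)
  co <- simulate_cohort(cfg, 9)
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  tracks <- read_movebank(paths[1], paths[2])
  expect_equal(length(tracks), nrow(co$plan))
  expect_identical(sort(names(tracks)), sort(co$plan$individual_id))
  tj <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  expect_equal(nrow(tj), nrow(co$plan))
  # truth boundaries are ordered where defined
  for (i in seq_len(nrow(co$truth))) {
    tt <- co$truth[i, ]
    chain <- c(tt$nest_departure, tt$natal_departure,
               tt$gibraltar_crossing, tt$sahel_arrival)
    chain <- chain[!is.na(chain)]
    if (length(chain) > 1) expect_true(all(diff(as.numeric(chain)) >= 0))
  }
})

test_that("with zero hazards every migrant completes the outbound journey", {
  cfg <- small_sim_config(
    obs_days = 400,
    hazards = c(dependence = 0, iberia_premigration = 0,
                sahara_crossing = 0, sahel_stay = 0, return_migration = 0,
                iberia_postreturn = 0, residency = 0))
  co <- simulate_cohort(cfg, 13)
  mig <- co$truth[co$truth$strategy == "migrant", ]
  expect_true(all(!is.na(mig$sahel_arrival)))
  expect_true(all(is.na(co$truth$death_time)))
  # arrivals land inside the Sahel band
  for (id in mig$individual_id) {
    f <- co$tracks[[id]]$fixes
    expect_lte(min(f$lat), 22.5)
    expect_gte(min(f$lat), 13.2)
  }
})

test_that("the OU kernel has the advertised stationary spread and limits", {
  set.seed(23)
  # stationary SD = scale / sqrt(2 reversion), here 2 km
  theta <- 0.5; sc <- 2 * sqrt(2 * theta)
  x <- c(0, 0)
  keep <- matrix(NA_real_, 4000, 2)
  for (i in seq_len(6000)) {
    x <- ou_step(x, c(0, 0), theta, sc, dt = 0.25)
    if (i > 2000) keep[i - 2000, ] <- x
  }
  expect_equal(sd(keep[, 1]), 2, tolerance = 0.05 * 2)
  expect_equal(sd(keep[, 2]), 2, tolerance = 0.05 * 2)

  # zero noise: deterministic decay towards the centre
  y <- ou_step(c(10, 10), c(0, 0), 1, 0, dt = 1)
  expect_equal(y, c(10, 10) * exp(-1))

  # zero reversion: pure Brownian increment with SD scale * sqrt(dt)
  set.seed(24)
  inc <- replicate(4000, ou_step(c(0, 0), c(5, 5), 0, 3, dt = 0.5)[1])
  expect_equal(sd(inc), 3 * sqrt(0.5), tolerance = 0.05 * 3)
})

test_that("the biased CRW goes straight at full attraction and realises its speed", {
  # wiggle 0, attraction 1: straight line to the target
  st <- list(point = c(0, 0), heading = 0)
  for (i in 1:10)
    st <- biased_crw_step(st$point, st$heading, c(100, 100), speed = 24,
                          attraction = 1, wiggle_sd = 0, dt = 1 / 24)
  expect_equal(st$point[1], st$point[2], tolerance = 1e-9)
  expect_equal(sqrt(sum(st$point^2)), 10, tolerance = 1e-9)

  # zero speed: stationary
  st0 <- biased_crw_step(c(3, 4), 0, c(100, 100), 0, 1, 0.1, dt = 1)
  expect_equal(st0$point, c(3, 4))

  # at low wiggle the realised net speed is within 10% of nominal
  set.seed(25)
  pos <- c(0, 0); hd <- 0
  for (i in 1:1000) {
    st <- biased_crw_step(pos, hd, c(1e6, 0), speed = 100,
                          attraction = 0.3, wiggle_sd = 0.1, dt = 1 / 48)
    pos <- st$point; hd <- st$heading
  }
  net <- sqrt(sum(pos^2)) / (1000 / 48)
  expect_equal(net, 100, tolerance = 0.1)
})

test_that("the transmitter layer degrades fixes as configured", {
  cfg <- small_sim_config()
  n <- 10000
  ideal <- data.frame(
    timestamp = t_seq(n), lon = rep(-6.5, n), lat = rep(41.3, n),
    stage = rep("dependence", n), alive = TRUE)

  # no missingness, no jitter: observed equals ideal
  cfg0 <- small_sim_config(miss_rate = 0, jitter_m = 0, outage_prob = 0)
  set.seed(26)
  obs0 <- apply_transmitter(ideal, cfg0)
  expect_equal(nrow(obs0), n)
  expect_equal(obs0$lon, ideal$lon)
  expect_equal(obs0$lat, ideal$lat)

  # 20% DOP mass above the threshold: QC removes about 20%
  cfg2 <- small_sim_config(miss_rate = 0, jitter_m = 0, dop_bad_prob = 0.2,
                           outage_prob = 0)
  set.seed(27)
  obs2 <- apply_transmitter(ideal, cfg2)
  tr <- qc_filter(mk_track(obs2))
  removed <- 1 - nrow(tr$fixes) / nrow(obs2)
  expect_lt(abs(removed - 0.2), 0.02)

  # post-death fixes stay within the stationary radius
  cfgd <- small_sim_config(miss_rate = 0, outage_prob = 0)
  dead <- ideal
  dead$alive <- c(rep(TRUE, 5000), rep(FALSE, 5000))
  set.seed(28)
  obsd <- apply_transmitter(dead, cfgd)
  post <- obsd[obsd$timestamp >= ideal$timestamp[5001], ]
  d_m <- haversine_km(post$lon, post$lat, -6.5, 41.3) * 1000
  expect_lt(max(d_m), 50)
})

test_that("migrant Sahel ranges dwarf resident ranges as configured", {
  cfg <- small_sim_config(
    obs_days = 420,
    hazards = c(dependence = 0, iberia_premigration = 0,
                sahara_crossing = 0, sahel_stay = 0, return_migration = 0,
                iberia_postreturn = 0, residency = 0))
  co <- simulate_cohort(cfg, 29)
  pl <- run_pipeline(co)
  kt <- pl$kde_table
  mig_area <- mean(kt$area_km2[kt$stage == "sahel_stay"])
  res_area <- mean(kt$area_km2[kt$stage == "residency"])
  expect_gt(mig_area, 5 * res_area)
})
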