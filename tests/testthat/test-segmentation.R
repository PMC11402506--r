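nest <- c(-6.5, 41.3)

# fixes at given distances (km) due east of the nest
dist_track <- function(d_km, by_min = 30) {
  pts <- do.call(rbind, lapply(d_km, function(k)
    if (k == 0) data.frame(lon = nest[1], lat = nest[2])
    else offset_point(nest[1], nest[2], k, 90)))
  mk_track(mk_fixes(t_seq(length(d_km), by_min), pts$lon, pts$lat),
           mk_deployment(nest_lon = nest[1], nest_lat = nest[2]))
}

test_that("nest departure is the first fix at or beyond 200 m", {
  tr <- dist_track(c(0.05, 0.15, 0.25, 0.30))
  expect_equal(detect_nest_departure(tr), tr$fixes$timestamp[3])
  # all fixes below the threshold: no departure
  expect_true(is.na(detect_nest_departure(dist_track(c(0.05, 0.1, 0.15)))))
  # exactly 200 m counts ("200 m or more" is inclusive)
  tr2 <- dist_track(c(0.05, 0.2))
  expect_equal(detect_nest_departure(tr2), tr2$fixes$timestamp[2])
})

test_that("natal departure is the last in-territory fix before a confirmed long journey", {
  # loops to 5 km and back twice, then a fast leg to 300 km
  d <- c(0, 5, 0.5, 5, 1, seq(10, 300, by = 15))
  tr <- dist_track(d, by_min = 12 * 60)  # half-day steps
  nd <- detect_natal_departure(tr)
  expect_equal(as.numeric(nd), as.numeric(tr$fixes$timestamp[5]))
  expect_true(attr(nd, "confirmed"))

  # never exits the territory
  expect_true(is.na(detect_natal_departure(dist_track(c(0, 1, 0.5, 1.5)))))

  # exit followed by a 10-km drift only: confirmation fails
  d2 <- c(0, 1, rep(10, 48 * 8))
  expect_true(is.na(detect_natal_departure(dist_track(d2, by_min = 240))))

  # track too short to confirm: candidate flagged unconfirmed
  d3 <- c(0, 1, 10, 12)
  nd3 <- detect_natal_departure(dist_track(d3, by_min = 240))
  expect_false(is.na(nd3))
  expect_false(attr(nd3, "confirmed"))
})

test_that("Gibraltar crossings are gated by latitude, longitude window and direction", {
  dep <- mk_deployment(nest_lon = -5.6, nest_lat = 36.2)
  mk2 <- function(lats, lons) mk_track(mk_fixes(t_seq(length(lats)), lons,
                                                lats), dep)
  tr <- mk2(c(36.2, 35.8), c(-5.6, -5.5))
  expect_equal(detect_gibraltar_crossing(tr), tr$fixes$timestamp[2])
  # outside the longitude window
  expect_true(is.na(detect_gibraltar_crossing(mk2(c(36.2, 35.8),
                                                  c(-2.0, -2.0)))))
  # northbound only
  expect_true(is.na(detect_gibraltar_crossing(mk2(c(35.8, 36.2),
                                                  c(-5.5, -5.6)))))
  # interpolated crossing longitude inside the window also counts
  tr3 <- mk2(c(36.4, 35.6), c(-6.3, -5.0))
  expect_equal(detect_gibraltar_crossing(tr3), tr3$fixes$timestamp[2])
})

test_that("Sahara span runs from the last desert-entry fix to Sahel arrival", {
  dep <- mk_deployment(nest_lon = -5.6, nest_lat = 36.2)
  lat_tr <- function(lats, by_min = 12 * 60)
    mk_track(mk_fixes(t_seq(length(lats), by_min), rep(-5.6, length(lats)),
                      lats), dep)
  # monotone descent 36 -> 18 over half-day steps
  lats <- seq(36, 18, by = -0.5)
  tr <- lat_tr(lats)
  sp <- detect_sahara_span(tr)
  expect_equal(sp$start, tr$fixes$timestamp[which(lats >= 30) |> max()])
  expect_equal(sp$end, tr$fixes$timestamp[which(lats <= 22.5)[1]])
  expect_equal(sp$duration_days,
               as.numeric(difftime(sp$end, sp$start, units = "days")))

  # turns back at 25 N: no crossing
  expect_null(detect_sahara_span(lat_tr(c(seq(36, 25, -0.5),
                                          seq(25.5, 33, 0.5)))))

  # two desert attempts: the span anchors to the successful one
  lats2 <- c(seq(36, 26, -0.5), seq(26.5, 33, 0.5), seq(32.5, 18, -0.5))
  tr2 <- lat_tr(lats2)
  sp2 <- detect_sahara_span(tr2)
  arr <- which(lats2 <= 22.5)[1]
  expect_equal(sp2$end, tr2$fixes$timestamp[arr])
  expect_equal(sp2$start,
               tr2$fixes$timestamp[max(which(lats2 >= 30 &
                                               seq_along(lats2) < arr))])
})

test_that("return start requires a sustained confirmed northward run", {
  dep <- mk_deployment(nest_lon = -8, nest_lat = 16)
  lat_tr <- function(lats, by_min = 6 * 60)
    mk_track(mk_fixes(t_seq(length(lats), by_min), rep(-8, length(lats)),
                      lats), dep)
  # 0.5 deg per 6 h = 222 km/day northward: well above threshold
  ret <- c(rep(16, 200), seq(16.1, 31, by = 0.5))
  tr <- lat_tr(ret)
  rs <- detect_return_start(tr)
  expect_false(is.na(rs))
  # detected at the end of the stationary stretch, within a day of the
  # true leg start
  expect_lt(abs(as.numeric(difftime(rs, tr$fixes$timestamp[200],
                                    units = "days"))), 1)

  # an 80-km foray that returns south is not a return
  foray <- c(rep(16, 50), seq(16.1, 16.7, 0.1), seq(16.6, 16, -0.1),
             rep(16, 200))
  expect_true(is.na(detect_return_start(lat_tr(foray))))

  # aborted return: reaches the desert-entry latitude, then turns back
  # south without leaving Africa -- still a return start
  ab <- c(rep(16, 100), seq(16.1, 31, 0.5), seq(30.5, 16, -0.5),
          rep(16, 100))
  rs2 <- detect_return_start(lat_tr(ab))
  expect_false(is.na(rs2))
})

test_that("full migrant and resident cycles segment into the expected stages", {
  cfg <- small_sim_config(hazards = c(dependence = 0,
                                      iberia_premigration = 0,
                                      sahara_crossing = 0, sahel_stay = 0,
                                      return_migration = 0,
                                      iberia_postreturn = 0, residency = 0),
                          obs_days = 740, sahel_days_mean = 520)
  plan <- cohort_plan(cfg, 21)
  mig <- which(plan$strategy == "migrant")[1]
  res <- which(plan$strategy == "non_migrant")[1]

  sm <- simulate_individual(plan[mig, ], cfg)
  seg <- segment_stages(resample_track(qc_filter(sm$track)))
  expect_identical(seg$strategy, "migrant")
  expect_identical(seg$intervals$stage,
                   c("dependence", "iberia_premigration", "sahara_crossing",
                     "sahel_stay", "return_migration", "iberia_postreturn"))
  # contiguous, non-overlapping intervals covering the observed span
  iv <- seg$intervals
  expect_equal(iv$start[-1], iv$end[-nrow(iv)])
  expect_true(all(iv$duration_days >= 0))
  # boundaries close to generative truth
  tru <- sm$truth
  expect_lt(abs(as.numeric(difftime(seg$events$sahel_arrival,
                                    tru$sahel_arrival, units = "days"))), 1)
  expect_lt(abs(as.numeric(difftime(seg$events$natal_departure,
                                    tru$natal_departure, units = "days"))),
            2)

  sr <- simulate_individual(plan[res, ], cfg)
  seg2 <- segment_stages(resample_track(qc_filter(sr$track)))
  expect_identical(seg2$strategy, "non_migrant")
  expect_identical(seg2$intervals$stage, c("dependence", "residency"))

  # monotone chain of events where defined
  ev <- seg$events
  chain <- c(ev$nest_departure, ev$natal_departure, ev$gibraltar_crossing,
             ev$sahel_arrival, ev$return_start)
  expect_true(all(diff(as.numeric(chain)) >= 0))
})

test_that("segmentation ignores fixes before the tagging date and handles empty tracks", {
  cfg <- small_sim_config()
  plan <- cohort_plan(cfg, 3)
  s <- simulate_individual(plan[2, ], cfg)
  tr <- resample_track(qc_filter(s$track))
  seg0 <- segment_stages(tr)

  pre <- tr
  ghost <- tr$fixes[1:5, ]
  ghost$timestamp <- ghost$timestamp - 40 * 86400
  pre$fixes <- rbind(ghost, tr$fixes)
  seg1 <- segment_stages(pre)
  expect_equal(seg0$intervals$stage, seg1$intervals$stage)
  expect_equal(seg0$intervals$start, seg1$intervals$start)

  empty <- tr
  empty$fixes <- tr$fixes[0, ]
  seg2 <- segment_stages(empty)
  expect_identical(seg2$strategy, "undetermined")
  expect_equal(nrow(seg2$intervals), 0L)
})

test_that("stage durations are fractional days that sum to the observed span", {
  cfg <- small_sim_config()
  plan <- cohort_plan(cfg, 5)
  s <- simulate_individual(plan[1, ], cfg)
  tr <- resample_track(qc_filter(s$track))
  seg <- segment_stages(tr)
  dur <- stage_durations_days(seg)
  span <- as.numeric(difftime(max(tr$fixes$timestamp),
                              min(tr$fixes$timestamp), units = "days"))
  expect_equal(sum(dur), span, tolerance = 1e-9)

  # a 48-h interval is exactly 2 days
  iv <- seg$intervals[1, ]
  fake <- seg
  fake$intervals <- data.frame(stage = "dependence", start = iv$start,
                               end = iv$start + 48 * 3600,
                               duration_days = 2)
  expect_equal(unname(stage_durations_days(fake)), 2)
})
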