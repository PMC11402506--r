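# Gaussian point clouds with known isopleth geometry are the natural
# oracle for the kernel home-range estimator.
gauss_cloud <- function(n, sigma_km, center = c(-5, 20), offset_km = c(0, 0)) {
  xy <- cbind(rnorm(n, offset_km[1], sigma_km),
              rnorm(n, offset_km[2], sigma_km))
  unproject_laea(xy[, 1], xy[, 2], center)
}

test_that("isopleth areas are monotone in level and stable under grid refinement", {
  set.seed(11)
  pts <- gauss_cloud(2000, 80)
  k95 <- fit_kde(pts$lon, pts$lat, bandwidth = 20, cell_km = 5)
  k50 <- fit_kde(pts$lon, pts$lat, bandwidth = 20, cell_km = 5,
                 level = 0.50)
  k99 <- fit_kde(pts$lon, pts$lat, bandwidth = 20, cell_km = 5,
                 level = 0.99)
  expect_lt(k50$area_km2, k95$area_km2)
  expect_lt(k95$area_km2, k99$area_km2)

  k10 <- fit_kde(pts$lon, pts$lat, bandwidth = 20, cell_km = 10)
  expect_lt(abs(k10$area_km2 - k95$area_km2) / k95$area_km2, 0.03)
})

test_that("density integrates to one and isopleths nest cell-wise", {
  set.seed(12)
  for (sigma in c(30, 120)) {
    pts <- gauss_cloud(600, sigma)
    k <- fit_kde(pts$lon, pts$lat, cell_km = 4)
    expect_equal(sum(k$density) * k$cell_km^2, 1, tolerance = 1e-6)
    inner <- kde_mask(k, 0.5)
    expect_true(all(k$mask[inner]))
    # mass inside the isopleth is at least the level, at most one cell over
    mass_in <- sum(k$density[k$mask]) * k$cell_km^2
    expect_gte(mass_in, 0.95)
    expect_lte(mass_in, 0.95 + max(k$density) * k$cell_km^2)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_kde(runif(5), runif(5)), "10 points")
  expect_error(fit_kde(rep(-5, 20), rep(20, 20)), "degenerate")
  pts <- gauss_cloud(50, 10)
  expect_error(fit_kde(pts$lon, pts$lat, bandwidth = -1), "positive")
  expect_error(fit_kde(pts$lon, pts$lat, cell_km = 0), "positive")
})

test_that("overlap is 100 for identical ranges, 0 for distant ones, symmetric in between", {
  set.seed(13)
  pts <- gauss_cloud(800, 60)
  a <- fit_kde(pts$lon, pts$lat, bandwidth = 15, cell_km = 5)
  expect_equal(as.numeric(overlap_pct(a, a)), 100, tolerance = 1e-9)

  far <- gauss_cloud(800, 60, center = c(40, 20))
  b <- fit_kde(far$lon, far$lat, bandwidth = 15, cell_km = 5)
  expect_equal(as.numeric(overlap_pct(a, b)), 0)

  near <- gauss_cloud(800, 60, offset_km = c(60, 0))
  c2 <- fit_kde(near$lon, near$lat, bandwidth = 15, cell_km = 5)
  expect_equal(as.numeric(overlap_pct(a, c2)),
               as.numeric(overlap_pct(c2, a)), tolerance = 1e-9)
  expect_gt(as.numeric(overlap_pct(a, c2)), 0)
})

test_that("overlap matches an independent fine-grid recomputation within 2 points", {
  set.seed(14)
  # independent oracle: evaluate both smoothed densities directly on one
  # shared fine lattice, threshold each by mass, intersect
  oracle_overlap <- function(p1, p2, h, cell) {
    ctr <- c(mean(c(p1$lon, p2$lon)), mean(c(p1$lat, p2$lat)))
    q1 <- project_laea(p1$lon, p1$lat, ctr)
    q2 <- project_laea(p2$lon, p2$lat, ctr)
    gx <- seq(min(q1$x, q2$x) - 3 * h, max(q1$x, q2$x) + 3 * h, by = cell)
    gy <- seq(min(q1$y, q2$y) - 3 * h, max(q1$y, q2$y) + 3 * h, by = cell)
    dens <- function(q) {
      A <- dnorm(outer(gx, q$x, "-"), sd = h)
      B <- dnorm(outer(gy, q$y, "-"), sd = h)
      d <- A %*% t(B); d / (sum(d) * cell^2)
    }
    msk <- function(d) {
      o <- sort(as.numeric(d), decreasing = TRUE)
      thr <- o[which(cumsum(o) * cell^2 >= 0.95)[1]]
      d >= thr
    }
    m1 <- msk(dens(q1)); m2 <- msk(dens(q2))
    100 * mean(c(sum(m1 & m2) / sum(m1), sum(m1 & m2) / sum(m2)))
  }
  for (i in 1:5) {
    sig <- runif(1, 40, 90)
    off <- runif(1, 0.3, 1.2) * sig
    p1 <- gauss_cloud(700, sig)
    p2 <- gauss_cloud(700, sig, offset_km = c(off, 0))
    h <- 15
    a <- fit_kde(p1$lon, p1$lat, bandwidth = h, cell_km = 6)
    b <- fit_kde(p2$lon, p2$lat, bandwidth = h, cell_km = 6)
    got <- as.numeric(overlap_pct(a, b))
    want <- oracle_overlap(p1, p2, h, cell = 1.5)
    expect_lt(abs(got - want), 2)
  }
})

test_that("centroid distances recover construction and are symmetric", {
  set.seed(15)
  p1 <- gauss_cloud(1500, 60)
  p2 <- gauss_cloud(1500, 60, offset_km = c(400, 0))
  a <- fit_kde(p1$lon, p1$lat, bandwidth = 15, cell_km = 5)
  b <- fit_kde(p2$lon, p2$lat, bandwidth = 15, cell_km = 5)
  expect_equal(centroid_distance_km(a, b), 400, tolerance = 10 / 400)
  expect_equal(centroid_distance_km(a, b), centroid_distance_km(b, a))
  expect_equal(centroid_distance_km(a, a), 0)
})

test_that("monthly ranges skip thin months and expose the resident core calendar", {
  cfg <- small_sim_config(obs_days = 420,
                          hazards = c(dependence = 0,
                                      iberia_premigration = 0,
                                      sahara_crossing = 0, sahel_stay = 0,
                                      return_migration = 0,
                                      iberia_postreturn = 0, residency = 0))
  plan <- cohort_plan(cfg, 31)
  res <- which(plan$strategy == "non_migrant")[1]
  s <- simulate_individual(plan[res, ], cfg)
  tr <- resample_track(qc_filter(s$track))
  # restrict to residency (post natal departure)
  seg <- segment_stages(tr)
  iv <- seg$intervals[seg$intervals$stage == "residency", ]
  tr$fixes <- tr$fixes[tr$fixes$timestamp >= iv$start, ]

  sqr <- function(lon, lat, r = 0.75)
    data.frame(lon = lon + c(-r, r, r, -r, -r),
               lat = lat + c(-r, -r, r, r, -r))
  mk <- monthly_kde(tr, cores = list(
    south = sqr(cfg$south_core_lon, cfg$south_core_lat),
    north = sqr(cfg$north_core_lon, cfg$north_core_lat)))

  cs <- mk$core_share
  cs$mon <- as.integer(substr(cs$month, 6, 7))
  south_share <- with(cs[cs$core == "south" & cs$mon %in% c(10:12, 1:2), ],
                      mean(share_pct))
  north_share <- with(cs[cs$core == "north" & cs$mon %in% 5:7, ],
                      mean(share_pct))
  expect_gt(south_share, 80)
  expect_gt(north_share, 80)

  # a month with 3 fixes is skipped
  thin <- tr
  thin$fixes <- rbind(tr$fixes[1:200, ],
                      transform(tr$fixes[1:3, ],
                                timestamp = timestamp + 370 * 86400))
  mk2 <- monthly_kde(thin)
  expect_true(length(mk2$skipped) >= 1)
})

test_that("isopleth polygons export as valid GeoJSON", {
  set.seed(16)
  pts <- gauss_cloud(400, 50)
  k <- fit_kde(pts$lon, pts$lat, cell_km = 8)
  path <- tempfile(fileext = ".geojson")
  kde_geojson(list(b1 = k), path)
  gj <- jsonlite::read_json(path)
  expect_identical(gj$type, "FeatureCollection")
  expect_gt(length(gj$features), 0)
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  lons <- vapply(ring, function(p) p[[1]], 0)
  lats <- vapply(ring, function(p) p[[2]], 0)
  expect_true(all(abs(lats) <= 90) && all(abs(lons) <= 180))
})
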