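# Kernel-density utilization distributions and 95% isopleth home ranges.
#
# Points are projected onto a Lambert azimuthal equal-area plane about
# their centroid, a Gaussian product kernel is evaluated on a regular
# grid, and the isopleth is the smallest set of grid cells whose density
# mass reaches the requested level.  Areas therefore come out directly
# in km^2.

#' Fit a kernel-density utilization distribution
#'
#' Isotropic Gaussian kernel on an equal-area grid.  The reference
#' bandwidth is Silverman's rule on the projected coordinates,
#' `h = sqrt((var(x) + var(y)) / 2) * n^(-1/6)`, the common default when
#' no bandwidth is published.  The grid extends 3 bandwidths beyond the
#' data and cell densities are normalised to integrate to exactly 1.
#' The isopleth threshold is the largest density `t` such that cells
#' with density >= `t` hold at least `level` of the mass (the smallest
#' region containing >= level).
#'
#' @param lon,lat Point coordinates in decimal degrees; alternatively
#'   `lon` may be a `vt_track` or a data frame with `lon`/`lat` columns.
#' @param bandwidth Kernel standard deviation in km, or `"reference"`.
#' @param cell_km Grid cell side in km (default 5).
#' @param level Isopleth probability (default 0.95).
#' @param center Optional projection center `c(lon, lat)`.
#' @return An object of class `vt_kde` with the grid, density matrix,
#'   isopleth mask, `area_km2`, density-weighted `centroid` (lon/lat)
#'   and the bandwidth used.
#' @export
fit_kde <- function(lon, lat = NULL, bandwidth = "reference", cell_km = 5,
                    level = 0.95, center = NULL) {
  if (is.null(lat)) {
    f <- track_fixes(lon)
    lat <- f$lat; lon <- f$lon
  }
  ok <- is.finite(lon) & is.finite(lat)
  lon <- lon[ok]; lat <- lat[ok]
  n <- length(lon)
  if (n < 10L) stop("at least 10 points are required for a KDE")
  if (cell_km <= 0) stop("cell_km must be positive")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")

  pr <- project_laea(lon, lat, center)
  ctr <- attr(pr, "center")
  if (max(abs(pr$x), abs(pr$y)) < 1e-9)
    stop("all points are identical: KDE is degenerate")

  if (identical(bandwidth, "reference")) {
    h <- sqrt((stats::var(pr$x) + stats::var(pr$y)) / 2) * n^(-1 / 6)
  } else {
    h <- as.numeric(bandwidth)
    if (!is.finite(h) || h <= 0) stop("bandwidth must be positive")
  }

  pad <- 3 * h
  gx <- seq(min(pr$x) - pad, max(pr$x) + pad + cell_km, by = cell_km)
  gy <- seq(min(pr$y) - pad, max(pr$y) + pad + cell_km, by = cell_km)
  # f(gx_i, gy_j) = (1/n) sum_k phi_h(gx_i - x_k) phi_h(gy_j - y_k)
  A <- stats::dnorm(outer(gx, pr$x, "-"), sd = h)
  B <- stats::dnorm(outer(gy, pr$y, "-"), sd = h)
  dens <- (A %*% t(B)) / n
  cell_area <- cell_km^2
  dens <- dens / (sum(dens) * cell_area)   # exact unit mass on the grid

  ord <- sort(as.numeric(dens), decreasing = TRUE)
  cmass <- cumsum(ord) * cell_area
  k <- which(cmass >= level)[1L]
  threshold <- ord[k]
  mask <- dens >= threshold
  area <- sum(mask) * cell_area

  w <- dens * mask
  wsum <- sum(w)
  cx <- sum(outer(gx, rep(1, length(gy))) * w) / wsum
  cy <- sum(outer(rep(1, length(gx)), gy) * w) / wsum
  centroid <- unproject_laea(cx, cy, ctr)

  structure(list(center = ctr, gx = gx, gy = gy, cell_km = cell_km,
                 density = dens, level = level, threshold = threshold,
                 mask = mask, area_km2 = area,
                 centroid = c(lon = centroid$lon, lat = centroid$lat),
                 bandwidth_km = h, n = n),
            class = "vt_kde")
}

#' @export
print.vt_kde <- function(x, ...) {
  cat(sprintf(paste0("<vt_kde> n = %d, h = %.1f km, cell = %.1f km, ",
                     "%d%% isopleth area = %.0f km^2\n"),
              x$n, x$bandwidth_km, x$cell_km, round(100 * x$level),
              x$area_km2))
  cat(sprintf("  centroid: %.3f deg lon, %.3f deg lat\n",
              x$centroid["lon"], x$centroid["lat"]))
  invisible(x)
}

#' @export
plot.vt_kde <- function(x, ...) {
  graphics::image(x$gx, x$gy, x$density, xlab = "x (km)", ylab = "y (km)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  ...)
  graphics::contour(x$gx, x$gy, x$density, levels = x$threshold,
                    add = TRUE, drawlabels = FALSE)
  invisible(x)
}

#' Isopleth mask at an arbitrary level
#'
#' @param x A `vt_kde`.
#' @param level Probability level.
#' @return Logical matrix over the fit's grid.
#' @export
kde_mask <- function(x, level = x$level) {
  ord <- sort(as.numeric(x$density), decreasing = TRUE)
  cmass <- cumsum(ord) * x$cell_km^2
  t <- ord[which(cmass >= level)[1L]]
  x$density >= t
}

# Re-express a KDE's inside-mask as TRUE/FALSE over an arbitrary lattice
# given in lon/lat (nearest-cell lookup in the KDE's own plane).
.mask_lookup <- function(kde, lon, lat) {
  p <- project_laea(lon, lat, kde$center)
  ix <- round((p$x - kde$gx[1L]) / kde$cell_km) + 1L
  iy <- round((p$y - kde$gy[1L]) / kde$cell_km) + 1L
  ok <- ix >= 1L & ix <= length(kde$gx) & iy >= 1L & iy <= length(kde$gy)
  out <- logical(length(lon))
  out[ok] <- kde$mask[cbind(ix[ok], iy[ok])]
  out
}

#' Percentage overlap of two isopleth home ranges
#'
#' Symmetric index: the mean of area(A&B)/area(A) and area(A&B)/area(B),
#' times 100, computed on a shared equal-area lattice centred midway
#' between the two fits (the two directed percentages are returned as
#' attributes so either convention can be recovered).
#'
#' @param a,b `vt_kde` objects.
#' @return Overlap percentage in `[0, 100]`, with attributes
#'   `"pct_a_in_b"` and `"pct_b_in_a"`.
#' @export
overlap_pct <- function(a, b) {
  stopifnot(inherits(a, "vt_kde"), inherits(b, "vt_kde"))
  mid <- c(lon = mean(c(a$center["lon"], b$center["lon"])),
           lat = mean(c(a$center["lat"], b$center["lat"])))
  cell <- min(a$cell_km, b$cell_km)

  cell_lonlat <- function(k) {
    inside <- which(k$mask, arr.ind = TRUE)
    unproject_laea(k$gx[inside[, 1L]], k$gy[inside[, 2L]], k$center)
  }
  pa <- project_laea(cell_lonlat(a)$lon, cell_lonlat(a)$lat, mid)
  pb <- project_laea(cell_lonlat(b)$lon, cell_lonlat(b)$lat, mid)
  xr <- range(pa$x, pb$x); yr <- range(pa$y, pb$y)
  gx <- seq(xr[1L] - cell, xr[2L] + cell, by = cell)
  gy <- seq(yr[1L] - cell, yr[2L] + cell, by = cell)
  grid <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  ll <- unproject_laea(grid$x, grid$y, mid)
  in_a <- .mask_lookup(a, ll$lon, ll$lat)
  in_b <- .mask_lookup(b, ll$lon, ll$lat)
  na <- sum(in_a); nb <- sum(in_b); nab <- sum(in_a & in_b)
  if (na == 0L || nb == 0L) {
    out <- 0
    attr(out, "note") <- "disjoint or empty grids"
    return(out)
  }
  dir_a <- 100 * nab / na
  dir_b <- 100 * nab / nb
  out <- (dir_a + dir_b) / 2
  attr(out, "pct_a_in_b") <- dir_a
  attr(out, "pct_b_in_a") <- dir_b
  out
}

#' Distance between home-range centroids
#'
#' Great-circle distance between the density-weighted isopleth centroids
#' of two fits.
#'
#' @param a,b `vt_kde` objects.
#' @return Distance in km.
#' @export
centroid_distance_km <- function(a, b) {
  stopifnot(inherits(a, "vt_kde"), inherits(b, "vt_kde"))
  haversine_km(a$centroid["lon"], a$centroid["lat"],
               b$centroid["lon"], b$centroid["lat"])
}

#' Monthly kernel home ranges (for resident individuals)
#'
#' Fits a KDE per calendar month with at least `min_fixes` fixes (months
#' below the threshold are skipped and listed), and, if core polygons
#' are supplied, the monthly percentage of fixes inside each core.
#'
#' @param traj A `vt_track` (normally a year-round resident, restricted
#'   to its residency interval by the caller if desired).
#' @param cores Optional named list of polygons, each a data frame with
#'   `lon`/`lat` vertex columns.
#' @param min_fixes Minimum fixes for a monthly fit (default 10).
#' @param ... Passed to [fit_kde()].
#' @return List with `kde` (named list of `vt_kde` by `"YYYY-MM"`),
#'   `skipped` (months below threshold) and `core_share` (data frame
#'   `month`, `core`, `n_fixes`, `share_pct`), or `NULL` when no cores
#'   given.
#' @export
monthly_kde <- function(traj, cores = NULL, min_fixes = 10, ...) {
  f <- track_fixes(traj)
  if (nrow(f) == 0L) return(list(kde = list(), skipped = character(),
                                 core_share = NULL))
  mon <- format(f$timestamp, "%Y-%m", tz = "UTC")
  months <- sort(unique(mon))
  counts <- table(mon)[months]
  fit_ok <- counts >= min_fixes
  kdes <- lapply(months[fit_ok], function(m) {
    g <- f[mon == m, , drop = FALSE]
    fit_kde(g$lon, g$lat, ...)
  })
  names(kdes) <- months[fit_ok]

  core_share <- NULL
  if (!is.null(cores)) {
    rows <- list()
    for (m in months) {
      g <- f[mon == m, , drop = FALSE]
      for (cn in names(cores)) {
        poly <- cores[[cn]]
        inside <- mgcv::in.out(as.matrix(poly[, c("lon", "lat")]),
                               cbind(g$lon, g$lat))
        rows[[length(rows) + 1L]] <- data.frame(
          month = m, core = cn, n_fixes = nrow(g),
          share_pct = 100 * mean(inside), stringsAsFactors = FALSE)
      }
    }
    core_share <- do.call(rbind, rows)
  }
  list(kde = kdes, skipped = months[!fit_ok], core_share = core_share)
}

#' Export isopleth contours as GeoJSON
#'
#' Writes the isopleth contour polygons of one or more fits as a WGS84
#' GeoJSON FeatureCollection.
#'
#' @param kdes Named list of `vt_kde` objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
kde_geojson <- function(kdes, path) {
  features <- list()
  for (nm in names(kdes)) {
    k <- kdes[[nm]]
    cl <- grDevices::contourLines(k$gx, k$gy, k$density,
                                  levels = k$threshold)
    for (ring in cl) {
      ll <- unproject_laea(ring$x, ring$y, k$center)
      coords <- cbind(ll$lon, ll$lat)
      # close the ring
      if (any(coords[1L, ] != coords[nrow(coords), ]))
        coords <- rbind(coords, coords[1L, ])
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        properties = list(id = nm, level = k$level,
                          area_km2 = k$area_km2),
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(coords)),
                                                  function(i)
                                                    coords[i, ]))))
    }
  }
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
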