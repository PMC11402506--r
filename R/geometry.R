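# Great-circle and equal-area geometry primitives.
#
# All distances are spherical (mean Earth radius 6371.0088 km); at the
# continental scales handled here the difference from ellipsoidal
# geodesics is < 0.5% and immaterial next to GPS and resampling error.

#' Mean Earth radius (km) used throughout the package
#' @keywords internal
.EARTH_RADIUS_KM <- 6371.0088

#' Great-circle (haversine) distance in kilometres
#'
#' Vectorised haversine distance on the sphere with radius 6371.0088 km.
#' Arguments recycle as in [geosphere::distHaversine()], which does the
#' actual computation.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 1, 0)   # ~111.195 km, one degree of latitude
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = .EARTH_RADIUS_KM))
}

#' Cumulative path length of a trajectory
#'
#' Sums great-circle segment lengths between consecutive fixes, the
#' standard travelled-distance measure for resampled tracks.  The result
#' is order-dependent by design: permuting fixes changes the path.
#'
#' @param traj A `vt_track` or a data frame with `lon`/`lat` columns in
#'   time order.
#' @return Total path length in km; 0 for a single fix.
#' @export
path_length_km <- function(traj) {
  f <- track_fixes(traj)
  n <- nrow(f)
  if (n < 2L) return(0)
  sum(haversine_km(f$lon[-n], f$lat[-n], f$lon[-1L], f$lat[-1L]))
}

#' Maximum displacement from a reference point
#'
#' @param traj A `vt_track` or fix data frame.
#' @param ref_lon,ref_lat Reference point (e.g. the nest) in decimal
#'   degrees.
#' @return Maximum great-circle distance (km) from the reference over all
#'   fixes.
#' @export
max_displacement_km <- function(traj, ref_lon, ref_lat) {
  f <- track_fixes(traj)
  if (nrow(f) == 0L) return(NA_real_)
  max(haversine_km(f$lon, f$lat, ref_lon, ref_lat))
}

#' Daily travelled distance
#'
#' Path length per UTC calendar day.  A segment between consecutive fixes
#' is attributed to the day of its *start* fix, so summing over days
#' conserves the total path length.  Days observed with fewer than two
#' fixes are reported as `NA` (a single fix cannot anchor a within-day
#' distance).
#'
#' @param traj A `vt_track` or fix data frame with `timestamp`, `lon`,
#'   `lat`.
#' @return Data frame with `date`, `n_fixes`, `km`.
#' @export
daily_distance_km <- function(traj) {
  f <- track_fixes(traj)
  if (nrow(f) == 0L) {
    return(data.frame(date = as.Date(character()), n_fixes = integer(),
                      km = numeric()))
  }
  day <- as.Date(f$timestamp, tz = "UTC")
  n <- nrow(f)
  counts <- table(day)
  days <- as.Date(names(counts))
  km <- numeric(length(days))
  if (n >= 2L) {
    seg <- haversine_km(f$lon[-n], f$lat[-n], f$lon[-1L], f$lat[-1L])
    seg_day <- day[-n]  # start-fix attribution
    agg <- tapply(seg, seg_day, sum)
    km[match(names(agg), as.character(days))] <- agg
  }
  km[counts < 2L] <- NA_real_
  data.frame(date = days, n_fixes = as.integer(counts), km = km,
             row.names = NULL)
}

#' Lambert azimuthal equal-area projection (spherical)
#'
#' Projects lon/lat onto a plane tangent at `center` such that areas are
#' preserved exactly on the sphere; coordinates are in km.  Used for all
#' kernel-density work so that isopleth areas come out directly in km^2.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param center Length-2 numeric `c(lon, lat)` of the projection origin,
#'   or `NULL` to use the geographic centroid of the inputs.
#' @return Data frame with `x`, `y` (km) and attribute `"center"`.
#' @export
project_laea <- function(lon, lat, center = NULL) {
  if (length(lon) == 0L) stop("no points to project")
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  R <- .EARTH_RADIUS_KM
  lam0 <- center[1] * pi / 180
  phi0 <- center[2] * pi / 180
  lam <- lon * pi / 180
  phi <- lat * pi / 180
  dl <- lam - lam0
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl)
  # antipode of the center maps to infinity; guard (never hit at the
  # <= 3000 km working scales)
  denom[denom < 1e-12] <- 1e-12
  kp <- sqrt(2 / denom)
  out <- data.frame(
    x = R * kp * cos(phi) * sin(dl),
    y = R * kp * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl))
  )
  attr(out, "center") <- c(lon = center[1], lat = center[2])
  out
}

#' Inverse Lambert azimuthal equal-area projection
#'
#' @param x,y Plane coordinates in km.
#' @param center Length-2 numeric `c(lon, lat)` of the projection origin.
#' @return Data frame with `lon`, `lat` in decimal degrees.
#' @export
unproject_laea <- function(x, y, center) {
  R <- .EARTH_RADIUS_KM
  lam0 <- center[1] * pi / 180
  phi0 <- center[2] * pi / 180
  rho <- sqrt(x^2 + y^2)
  cc <- 2 * asin(pmin(1, rho / (2 * R)))
  sinc <- sin(cc)
  cosc <- cos(cc)
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cosc * sin(phi0) + y * sinc * cos(phi0) / rho))
  lam <- ifelse(rho < 1e-12, lam0,
                lam0 + atan2(x * sinc,
                             rho * cos(phi0) * cosc - y * sin(phi0) * sinc))
  data.frame(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

# Extract the fix data frame from a vt_track or pass a data frame through.
#' @keywords internal
track_fixes <- function(traj) {
  if (inherits(traj, "vt_track")) return(traj$fixes)
  if (is.data.frame(traj)) return(traj)
  stop("expected a vt_track or a data frame of fixes")
}
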