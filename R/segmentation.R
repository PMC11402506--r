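# Life-stage segmentation of juvenile trans-Saharan migrant tracks.
#
# Stages are delimited by displacement rules, not behavioural-state
# models: nest departure (first fix >= 200 m from the nest), natal
# departure (last nest-area fix followed by a long directed journey),
# a Gibraltar-gate crossing, Sahara transit bounded by latitude
# thresholds, multi-month Sahel residence inside a latitude band, and a
# sustained northward displacement marking the return.

#' Segmentation parameters
#'
#' Thresholds for the displacement-rule detectors.  The 200-m
#' nest-departure radius and the 22.5 deg N upper Sahel latitude come
#' from field observation of this system; the rest are operational
#' defaults exposed here because published analyses state only
#' qualitative rules ("stopped returning to the nest", "clearly directed
#' latitudinal displacements").
#'
#' @param nest_departure_m First displacement from the nest counted as
#'   leaving it (metres, inclusive threshold; default 200).
#' @param natal_radius_km Radius of the natal territory around the nest
#'   (km; default 2).
#' @param natal_confirm_days,natal_confirm_km A candidate natal departure
#'   must be followed, within this window (days), by a displacement of at
#'   least this many km (defaults 7 d / 50 km).
#' @param natal_absence_days Minimum stay away from the natal territory
#'   for a departure to count as definitive (default 60).  Year-round
#'   residents revisit their natal areas in later breeding seasons, so
#'   "stopped returning" must be read as a sustained absence, not as
#'   never returning again.
#' @param gibraltar_lat Latitude of the migration gate (deg; default 36).
#' @param gibraltar_lon_window Longitude window of the gate (deg;
#'   default c(-6.1, -5.2), covering the Strait of Gibraltar).
#' @param desert_north_lat Northern desert-entry latitude (deg; 30).
#' @param sahel_north_lat Northern edge of the Sahel band (deg; 22.5).
#' @param sahel_south_lat Southern edge of the Sahel band (deg; 13.3).
#' @param return_net_km,return_window_days Net northward displacement (km
#'   within days) that starts a candidate return (defaults 100 km / 3 d).
#' @param return_confirm_days Days a candidate return must stay out of
#'   the Sahel band unless the desert-entry latitude is reached first
#'   (default 30).
#' @param return_relapse_km Maximum southward relapse below the candidate
#'   latitude tolerated between the candidate and the band exit; ties
#'   the detected start to the final sustained northward run rather than
#'   an earlier wandering excursion (default 15).
#' @return A list of class `vt_seg_params`.
#' @export
seg_params <- function(nest_departure_m = 200,
                       natal_radius_km = 2,
                       natal_confirm_days = 7,
                       natal_confirm_km = 50,
                       natal_absence_days = 60,
                       gibraltar_lat = 36.0,
                       gibraltar_lon_window = c(-6.1, -5.2),
                       desert_north_lat = 30.0,
                       sahel_north_lat = 22.5,
                       sahel_south_lat = 13.3,
                       return_net_km = 100,
                       return_window_days = 3,
                       return_confirm_days = 30,
                       return_relapse_km = 15) {
  p <- list(nest_departure_m = nest_departure_m,
            natal_radius_km = natal_radius_km,
            natal_confirm_days = natal_confirm_days,
            natal_confirm_km = natal_confirm_km,
            natal_absence_days = natal_absence_days,
            gibraltar_lat = gibraltar_lat,
            gibraltar_lon_window = sort(gibraltar_lon_window),
            desert_north_lat = desert_north_lat,
            sahel_north_lat = sahel_north_lat,
            sahel_south_lat = sahel_south_lat,
            return_net_km = return_net_km,
            return_window_days = return_window_days,
            return_confirm_days = return_confirm_days,
            return_relapse_km = return_relapse_km)
  scalars <- p[!(names(p) == "gibraltar_lon_window")]
  if (any(!vapply(scalars, function(v) is.numeric(v) && v > 0, TRUE)))
    stop("all segmentation parameters must be positive numbers")
  if (!(p$sahel_north_lat < p$desert_north_lat &&
        p$desert_north_lat < p$gibraltar_lat))
    stop("latitude thresholds must satisfy sahel < desert < gibraltar")
  class(p) <- "vt_seg_params"
  p
}

#' Detect nest departure
#'
#' The first fix at or beyond `nest_departure_m` from the nest ("200 m or
#' more" is inclusive).
#'
#' @param traj A QC-filtered, resampled `vt_track`.
#' @param nest_lon,nest_lat Nest coordinates; default from the
#'   deployment.
#' @param params A [seg_params()] object.
#' @return Timestamp (POSIXct) of the departure fix, or `NA` if the bird
#'   never leaves.
#' @export
detect_nest_departure <- function(traj, nest_lon = NULL, nest_lat = NULL,
                                  params = seg_params()) {
  f <- track_fixes(traj)
  if (nrow(f) == 0L) {
    warning("empty trajectory: no nest departure")
    return(as.POSIXct(NA))
  }
  if (is.null(nest_lon)) nest_lon <- traj$deployment$nest_lon
  if (is.null(nest_lat)) nest_lat <- traj$deployment$nest_lat
  d_km <- haversine_km(f$lon, f$lat, nest_lon, nest_lat)
  i <- which(d_km >= params$nest_departure_m / 1000)[1L]
  if (is.na(i)) as.POSIXct(NA) else f$timestamp[i]
}

#' Detect natal departure
#'
#' The definitive departure from the natal territory: the last fix of an
#' in-territory (within `natal_radius_km` of the nest) residence run
#' that is followed by (a) an absence of at least `natal_absence_days`
#' before any re-entry -- a bird that never re-enters qualifies however
#' short its remaining track -- and (b) a displacement of at least
#' `natal_confirm_km` from that fix within `natal_confirm_days` (the
#' "long and clearly directed journey").  Residents revisiting the natal
#' area in later breeding seasons therefore still get their first-year
#' departure.  If the track ends before the confirmation window closes,
#' the candidate is returned flagged `attr(, "confirmed") = FALSE`.
#'
#' @inheritParams detect_nest_departure
#' @return Timestamp of departure (attribute `"confirmed"`), or `NA` if
#'   the bird never leaves for good.
#' @export
detect_natal_departure <- function(traj, nest_lon = NULL, nest_lat = NULL,
                                   params = seg_params()) {
  f <- track_fixes(traj)
  n <- nrow(f)
  if (n == 0L) return(as.POSIXct(NA))
  if (is.null(nest_lon)) nest_lon <- traj$deployment$nest_lon
  if (is.null(nest_lat)) nest_lat <- traj$deployment$nest_lat
  d_km <- haversine_km(f$lon, f$lat, nest_lon, nest_lat)
  inside <- d_km <= params$natal_radius_km
  if (!any(inside)) return(as.POSIXct(NA))   # never seen in the territory
  # candidate departures: last fix of each in-territory run
  run_end <- which(inside & c(!inside[-1L], TRUE))
  run_end <- run_end[run_end < n]            # track must continue outside
  t_end <- f$timestamp[n]
  for (i in run_end) {
    t0 <- f$timestamp[i]
    nxt <- which(inside & seq_len(n) > i)[1L]
    absence_ok <- is.na(nxt) ||
      as.numeric(difftime(f$timestamp[nxt], t0, units = "days")) >=
        params$natal_absence_days
    if (!absence_ok) next
    win <- which(f$timestamp > t0 &
                   f$timestamp <= t0 + params$natal_confirm_days * 86400)
    full_window <- as.numeric(difftime(t_end, t0, units = "days")) >=
      params$natal_confirm_days
    disp <- if (length(win) > 0L)
      max(haversine_km(f$lon[win], f$lat[win], f$lon[i], f$lat[i])) else 0
    if (disp >= params$natal_confirm_km) {
      out <- t0
      attr(out, "confirmed") <- TRUE
      return(out)
    }
    if (!full_window) {                      # track too short to confirm
      out <- t0
      attr(out, "confirmed") <- FALSE
      return(out)
    }
  }
  as.POSIXct(NA)
}

#' Detect a southbound Gibraltar crossing
#'
#' First consecutive fix pair whose segment crosses the gate latitude
#' southbound with both endpoints (or the interpolated crossing
#' longitude) inside the gate's longitude window.
#'
#' @param traj A `vt_track` or fix data frame.
#' @param params A [seg_params()] object.
#' @param after Optional timestamp; only crossings after it count.
#' @return Timestamp of the first fix south of the gate, or `NA`.
#' @export
detect_gibraltar_crossing <- function(traj, params = seg_params(),
                                      after = NULL) {
  f <- track_fixes(traj)
  if (!is.null(after) && !is.na(after)) f <- f[f$timestamp >= after, ,
                                               drop = FALSE]
  n <- nrow(f)
  if (n < 2L) return(as.POSIXct(NA))
  glat <- params$gibraltar_lat
  win <- params$gibraltar_lon_window
  lat1 <- f$lat[-n]; lat2 <- f$lat[-1L]
  lon1 <- f$lon[-n]; lon2 <- f$lon[-1L]
  south <- lat1 > glat & lat2 <= glat
  frac <- (glat - lat1) / (lat2 - lat1)
  lon_at <- lon1 + (lon2 - lon1) * frac
  in_win <- function(l) l >= win[1] & l <= win[2]
  hit <- south & ((in_win(lon1) & in_win(lon2)) | in_win(lon_at))
  i <- which(hit)[1L]
  if (is.na(i)) as.POSIXct(NA) else f$timestamp[i + 1L]
}

#' Classify migratory strategy
#'
#' `migrant` if a southbound Gibraltar crossing is detected after natal
#' departure; `non_migrant` if at least 365 observed days after natal
#' departure contain no crossing; `undetermined` otherwise (including
#' birds lost before a year of post-departure observation).
#'
#' @inheritParams detect_gibraltar_crossing
#' @param natal_departure Optional precomputed natal-departure time.
#' @return One of `"migrant"`, `"non_migrant"`, `"undetermined"`.
#' @export
classify_strategy <- function(traj, params = seg_params(),
                              natal_departure = NULL) {
  f <- track_fixes(traj)
  if (nrow(f) == 0L) return("undetermined")
  if (is.null(natal_departure))
    natal_departure <- detect_natal_departure(traj, params = params)
  if (is.na(natal_departure)) return("undetermined")
  crossing <- detect_gibraltar_crossing(traj, params,
                                        after = natal_departure)
  if (!is.na(crossing)) return("migrant")
  observed_days <- as.numeric(difftime(max(f$timestamp),
                                       natal_departure, units = "days"))
  if (observed_days >= 365) "non_migrant" else "undetermined"
}

#' Detect the Sahara crossing span
#'
#' Start: the last fix at or north of `desert_north_lat` before the bird
#' first drops to `sahel_north_lat` or below; end: that first fix in the
#' Sahel band (= Sahel arrival).  `NA` if the bird never reaches the
#' band (lost in the desert).
#'
#' @inheritParams detect_gibraltar_crossing
#' @param after Timestamp (normally the Gibraltar crossing); only fixes
#'   from then on are considered.
#' @return List with `start`, `end` (POSIXct) and `duration_days`, or
#'   `NULL` if no complete crossing.
#' @export
detect_sahara_span <- function(traj, params = seg_params(), after = NULL) {
  f <- track_fixes(traj)
  if (!is.null(after) && !is.na(after)) f <- f[f$timestamp >= after, ,
                                               drop = FALSE]
  if (nrow(f) == 0L) return(NULL)
  arr <- which(f$lat <= params$sahel_north_lat)[1L]
  if (is.na(arr)) return(NULL)
  north <- which(f$lat >= params$desert_north_lat & seq_len(nrow(f)) < arr)
  if (length(north) == 0L) return(NULL)
  s <- max(north)
  list(start = f$timestamp[s], end = f$timestamp[arr],
       duration_days = as.numeric(difftime(f$timestamp[arr],
                                           f$timestamp[s], units = "days")))
}

#' Detect the start of the return migration
#'
#' First instant during the Sahel stay with net northward displacement of
#' at least `return_net_km` within `return_window_days`, from which the
#' northward run is sustained -- the bird exits the Sahel band within
#' `return_confirm_days` and its latitude never draws down more than
#' `return_relapse_km` below the running maximum on the way out -- and
#' confirmed by the bird either reaching `desert_north_lat` or staying
#' out of the band for `return_confirm_days`.  An aborted return that
#' reaches the desert-entry latitude and then turns back south still
#' counts.
#'
#' @inheritParams detect_gibraltar_crossing
#' @param after Timestamp of Sahel arrival.
#' @return Timestamp of the return start, or `NA`.
#' @export
detect_return_start <- function(traj, params = seg_params(), after = NULL) {
  f <- track_fixes(traj)
  if (!is.null(after) && !is.na(after)) f <- f[f$timestamp >= after, ,
                                               drop = FALSE]
  n <- nrow(f)
  if (n < 2L) return(as.POSIXct(NA))
  tnum <- as.numeric(f$timestamp)
  wsec <- params$return_window_days * 86400
  # net northward displacement within the look-ahead window, km
  km_per_deg <- pi * .EARTH_RADIUS_KM / 180
  upper <- findInterval(tnum + wsec, tnum)
  # sliding max of latitude over (i, upper_i] via a monotonic deque
  max_lat_win <- f$lat
  lat <- f$lat
  dq <- integer(n); head <- 1L; tail <- 0L; j <- 1L
  for (i in seq_len(n)) {
    hi <- upper[i]
    while (j < hi) {
      j <- j + 1L
      while (tail >= head && lat[dq[tail]] <= lat[j]) tail <- tail - 1L
      tail <- tail + 1L
      dq[tail] <- j
    }
    while (head <= tail && dq[head] <= i) head <- head + 1L
    if (head <= tail) max_lat_win[i] <- max(lat[i], lat[dq[head]])
  }
  north_km <- (max_lat_win - f$lat) * km_per_deg
  cand <- north_km >= params$return_net_km & f$lat <= params$sahel_north_lat
  idx <- which(cand)
  if (length(idx) == 0L) return(as.POSIXct(NA))
  # next band-exit index strictly after each fix
  out_idx <- which(f$lat > params$sahel_north_lat)
  if (length(out_idx) == 0L) return(as.POSIXct(NA))
  nxt_exit <- out_idx[findInterval(seq_len(n), out_idx) + 1L]
  relapse_deg <- params$return_relapse_km / km_per_deg
  for (i in idx) {
    e <- nxt_exit[i]
    if (is.na(e)) next
    # a directed return crosses the band within the confirmation window
    if (tnum[e] - tnum[i] > params$return_confirm_days * 86400) next
    # sustained run: latitude drawdown below its running maximum stays
    # within the relapse tolerance all the way to the exit
    seg_lat <- f$lat[i:e]
    if (any(seg_lat < cummax(seg_lat) - relapse_deg)) next
    r <- which(f$lat <= params$sahel_north_lat & seq_len(n) > e)[1L]
    k <- which(f$lat >= params$desert_north_lat & seq_len(n) > e)[1L]
    ok_desert <- !is.na(k) && (is.na(r) || k < r)
    ok_sustained <- is.na(r) ||
      (tnum[r] - tnum[e]) >= params$return_confirm_days * 86400
    if (ok_desert || ok_sustained) {
      # snap to the start of the rise itself: the last fix attaining the
      # minimum latitude of the run (the lookahead window otherwise
      # biases detection early by up to return_window_days)
      j <- i + max(which(seg_lat <= min(seg_lat) + 1e-9)) - 1L
      return(f$timestamp[j])
    }
  }
  as.POSIXct(NA)
}

#' Segment a track into life stages
#'
#' Composes the displacement-rule detectors into an ordered, contiguous,
#' non-overlapping set of labelled intervals.  Migrants get
#' `dependence -> iberia_premigration -> sahara_crossing -> sahel_stay`
#' and, if the bird turns north, `-> return_migration ->
#' iberia_postreturn`; non-migrants get `dependence -> residency`.  The
#' last interval is truncated at the final fix.  Fixes before the
#' tagging date are ignored.
#'
#' @param traj A QC-filtered, resampled `vt_track` with deployment
#'   metadata.
#' @param params A [seg_params()] object.
#' @return An object of class `vt_segmentation`: list with
#'   `individual_id`, `strategy`, `intervals` (data frame `stage`,
#'   `start`, `end`, `duration_days`) and the detector `events`.
#' @export
segment_stages <- function(traj, params = seg_params()) {
  stopifnot(inherits(traj, "vt_track"))
  dep <- traj$deployment
  f <- traj$fixes
  tag0 <- as.POSIXct(paste(dep$tagging_date, "00:00:00"), tz = "UTC")
  f <- f[f$timestamp >= tag0, , drop = FALSE]
  work <- traj; work$fixes <- f
  empty <- function(strategy) {
    structure(list(individual_id = dep$individual_id, strategy = strategy,
                   intervals = data.frame(stage = character(),
                                          start = as.POSIXct(character()),
                                          end = as.POSIXct(character()),
                                          duration_days = numeric()),
                   events = list()),
              class = "vt_segmentation")
  }
  if (nrow(f) == 0L) return(empty("undetermined"))

  t_first <- f$timestamp[1L]
  t_last <- f$timestamp[nrow(f)]
  nest_dep <- suppressWarnings(detect_nest_departure(work, params = params))
  natal_dep <- detect_natal_departure(work, params = params)
  strategy <- classify_strategy(work, params, natal_departure = natal_dep)

  events <- list(nest_departure = nest_dep, natal_departure = natal_dep)
  cuts <- list()  # ordered (stage, start) boundaries
  add <- function(stage, start) cuts[[length(cuts) + 1L]] <<-
      list(stage = stage, start = start)

  add("dependence", t_first)
  if (!is.na(natal_dep)) {
    if (strategy == "non_migrant") {
      add("residency", natal_dep)
    } else {
      crossing <- detect_gibraltar_crossing(work, params, after = natal_dep)
      events$gibraltar_crossing <- crossing
      if (strategy == "migrant") {
        sahara <- detect_sahara_span(work, params, after = crossing)
        add("iberia_premigration", natal_dep)
        add("sahara_crossing", crossing)
        if (!is.null(sahara)) {
          if (sahara$end < crossing)
            stop("internal inconsistency: Sahel arrival precedes the ",
                 "Gibraltar crossing for ", dep$individual_id)
          events$desert_entry <- sahara$start
          events$sahel_arrival <- sahara$end
          events$sahara_duration_days <- sahara$duration_days
          add("sahel_stay", sahara$end)
          ret <- detect_return_start(work, params, after = sahara$end)
          if (!is.na(ret)) {
            events$return_start <- ret
            add("return_migration", ret)
            # return completion: first northbound gate crossing after the
            # return start
            g <- f[f$timestamp >= ret, , drop = FALSE]
            nn <- nrow(g)
            if (nn >= 2L) {
              northb <- which(g$lat[-nn] <= params$gibraltar_lat &
                                g$lat[-1L] > params$gibraltar_lat &
                                g$lon[-1L] >= params$gibraltar_lon_window[1] - 1 &
                                g$lon[-1L] <= params$gibraltar_lon_window[2] + 1)[1L]
              if (!is.na(northb)) {
                comp <- g$timestamp[northb + 1L]
                events$return_completion <- comp
                add("iberia_postreturn", comp)
              }
            }
          }
        }
      } else {
        # undetermined with a departure: label the rest pre-migration
        add("iberia_premigration", natal_dep)
      }
    }
  }

  stages <- vapply(cuts, function(c) c$stage, "")
  starts <- do.call(c, lapply(cuts, function(c) c$start))
  o <- order(starts)
  stages <- stages[o]; starts <- starts[o]
  ends <- c(starts[-1L], t_last)
  keep <- as.numeric(ends) >= as.numeric(starts)
  iv <- data.frame(stage = stages[keep],
                   start = starts[keep], end = ends[keep],
                   duration_days = as.numeric(difftime(ends[keep],
                                                       starts[keep],
                                                       units = "days")),
                   stringsAsFactors = FALSE)
  structure(list(individual_id = dep$individual_id, strategy = strategy,
                 intervals = iv, events = events),
            class = "vt_segmentation")
}

#' @export
print.vt_segmentation <- function(x, ...) {
  cat(sprintf("<vt_segmentation> %s (%s)\n", x$individual_id, x$strategy))
  if (nrow(x$intervals) > 0L) {
    iv <- x$intervals
    for (i in seq_len(nrow(iv))) {
      cat(sprintf("  %-19s %s -> %s (%6.1f d)\n", iv$stage[i],
                  format(iv$start[i], "%Y-%m-%d"),
                  format(iv$end[i], "%Y-%m-%d"), iv$duration_days[i]))
    }
  }
  invisible(x)
}

#' Per-stage durations in fractional days
#'
#' @param seg A `vt_segmentation`.
#' @return Named numeric vector of interval durations (days), one entry
#'   per interval in order.
#' @export
stage_durations_days <- function(seg) {
  stopifnot(inherits(seg, "vt_segmentation"))
  stats::setNames(seg$intervals$duration_days, seg$intervals$stage)
}

#' Look up the stage containing an instant
#'
#' @param seg A `vt_segmentation`.
#' @param when POSIXct instant.
#' @return Stage label, or `"unsegmented"` (with a warning) if `when`
#'   falls outside all intervals.
#' @export
stage_at <- function(seg, when) {
  iv <- seg$intervals
  if (nrow(iv) == 0L || is.na(when)) return("unsegmented")
  hit <- which(iv$start <= when & when <= iv$end)
  if (length(hit) == 0L) {
    warning("instant outside all segmented intervals")
    return("unsegmented")
  }
  iv$stage[hit[length(hit)]]  # boundaries belong to the later stage
}
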