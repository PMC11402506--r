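# Reading, writing, QC-filtering and resampling of Movebank-dialect
# GPS tracking tables.

# Movebank column names for the fixes table
.MB_REQUIRED <- c("timestamp", "location-long", "location-lat",
                  "individual-local-identifier")
.MB_OPTIONAL <- c("gps:hdop", "gps:vdop", "tag-voltage", "activity",
                  "acceleration-raw-x", "tag-local-identifier")
.DEP_REQUIRED <- c("individual-local-identifier", "sex", "nucleus",
                   "nest-long", "nest-lat", "tagging-date",
                   "transmitter-model")

#' Construct a single-individual track
#'
#' A `vt_track` couples one individual's ordered fixes with its deployment
#' metadata.  Fixes are sorted by timestamp; duplicate timestamps keep the
#' first occurrence.
#'
#' @param fixes Data frame with `timestamp` (POSIXct, UTC), `lon`, `lat`
#'   and optionally `hdop`, `vdop`, `battery_v`, `activity`.
#' @param deployment One-row data frame (or named list) with
#'   `individual_id`, `sex`, `nucleus`, `nest_lon`, `nest_lat`,
#'   `tagging_date`, `transmitter_model`, optional `sibling_group`.
#' @return An object of class `vt_track`.
#' @export
vt_track <- function(fixes, deployment) {
  deployment <- as.data.frame(deployment, stringsAsFactors = FALSE)
  stopifnot(nrow(deployment) == 1L)
  for (col in c("hdop", "vdop", "battery_v", "activity")) {
    if (is.null(fixes[[col]])) fixes[[col]] <- NA_real_
  }
  bad <- !is.finite(fixes$lon) | !is.finite(fixes$lat) |
    abs(fixes$lat) > 90 | abs(fixes$lon) > 180 | is.na(fixes$timestamp)
  fixes <- fixes[!bad, , drop = FALSE]
  o <- order(fixes$timestamp)
  fixes <- fixes[o, , drop = FALSE]
  fixes <- fixes[!duplicated(fixes$timestamp), , drop = FALSE]
  rownames(fixes) <- NULL
  structure(list(deployment = deployment, fixes = fixes,
                 n_dropped = sum(bad)),
            class = "vt_track")
}

#' @export
print.vt_track <- function(x, ...) {
  d <- x$deployment
  cat(sprintf("<vt_track> %s (%s, %s): %d fixes",
              d$individual_id, d$nucleus, d$sex, nrow(x$fixes)))
  if (nrow(x$fixes) > 0L) {
    cat(sprintf(" [%s .. %s]",
                format(min(x$fixes$timestamp), "%Y-%m-%d"),
                format(max(x$fixes$timestamp), "%Y-%m-%d")))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.vt_tracks <- function(x, ...) {
  cat(sprintf("<vt_tracks> %d individuals, %d fixes total\n",
              length(x), sum(vapply(x, function(t) nrow(t$fixes), 0L))))
  invisible(x)
}

#' Read Movebank-dialect tracking and deployment tables
#'
#' Parses a fixes CSV (columns `timestamp`, `location-long`,
#' `location-lat`, `individual-local-identifier`, optional `gps:hdop`,
#' `gps:vdop`, `tag-voltage`, `activity`/`acceleration-raw-x`) and a
#' deployment CSV, returning one [vt_track] per individual.  Rows with
#' unparseable coordinates or timestamps are dropped and counted;
#' duplicate (individual, timestamp) rows keep the first occurrence.
#'
#' @param path Path to the fixes CSV.
#' @param deployments_path Path to the deployment-metadata CSV.
#' @return A named list of `vt_track` objects (class `vt_tracks`) with
#'   attribute `"qc_log"` recording dropped-row counts.
#' @export
read_movebank <- function(path, deployments_path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(.MB_REQUIRED, names(raw))
  if (length(missing_cols) > 0L) {
    stop("fixes table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  deps <- read_deployments(deployments_path)

  ids <- as.character(raw[["individual-local-identifier"]])
  unknown <- setdiff(unique(ids), deps$individual_id)
  if (length(unknown) > 0L) {
    stop("fixes reference individual(s) absent from deployments: ",
         paste(unknown, collapse = ", "))
  }

  ts <- as.POSIXct(raw[["timestamp"]], tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  lon <- suppressWarnings(as.numeric(raw[["location-long"]]))
  lat <- suppressWarnings(as.numeric(raw[["location-lat"]]))
  num_or_na <- function(col) {
    if (is.null(raw[[col]])) rep(NA_real_, nrow(raw))
    else suppressWarnings(as.numeric(raw[[col]]))
  }
  activity <- num_or_na("activity")
  if (all(is.na(activity))) activity <- num_or_na("acceleration-raw-x")

  fixes <- data.frame(
    timestamp = ts, lon = lon, lat = lat,
    hdop = num_or_na("gps:hdop"), vdop = num_or_na("gps:vdop"),
    battery_v = num_or_na("tag-voltage"), activity = activity
  )

  tracks <- lapply(deps$individual_id, function(id) {
    vt_track(fixes[ids == id, , drop = FALSE], deps[deps$individual_id == id, ])
  })
  names(tracks) <- deps$individual_id
  tracks <- tracks[vapply(tracks, function(t) nrow(t$fixes), 0L) > 0L |
                     deps$individual_id %in% ids]
  dropped <- sum(vapply(tracks, function(t) t$n_dropped, 0L))
  structure(tracks, class = "vt_tracks",
            qc_log = list(n_rows = nrow(raw), n_dropped_invalid = dropped))
}

#' Read a deployment-metadata table
#'
#' @param path Path to the deployment CSV (Movebank-style column names).
#' @return Data frame with internal column names (`individual_id`, `sex`,
#'   `nucleus`, `nest_lon`, `nest_lat`, `tagging_date`,
#'   `transmitter_model`, `sibling_group`).
#' @export
read_deployments <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(.DEP_REQUIRED, names(raw))
  if (length(missing_cols) > 0L) {
    stop("deployment table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    individual_id = as.character(raw[["individual-local-identifier"]]),
    sex = as.character(raw[["sex"]]),
    nucleus = as.character(raw[["nucleus"]]),
    nest_lon = as.numeric(raw[["nest-long"]]),
    nest_lat = as.numeric(raw[["nest-lat"]]),
    tagging_date = as.Date(raw[["tagging-date"]]),
    transmitter_model = as.character(raw[["transmitter-model"]]),
    sibling_group = if (is.null(raw[["sibling-group"]]))
      NA_character_ else as.character(raw[["sibling-group"]]),
    stringsAsFactors = FALSE
  )
  bad_nest <- !is.finite(out$nest_lon) | !is.finite(out$nest_lat) |
    abs(out$nest_lat) > 90 | abs(out$nest_lon) > 180
  if (any(bad_nest)) {
    stop("invalid nest coordinates for: ",
         paste(out$individual_id[bad_nest], collapse = ", "))
  }
  out
}

#' Write tracks back to Movebank-dialect CSVs
#'
#' Inverse of [read_movebank()]: finite field values round-trip exactly
#' (timestamps at 1-s resolution, coordinates at full double precision).
#'
#' @param tracks A `vt_tracks` list (or list of `vt_track`).
#' @param path Output path for the fixes CSV.
#' @param deployments_path Output path for the deployments CSV.
#' @return Invisibly, the two paths.
#' @export
write_movebank <- function(tracks, path, deployments_path) {
  num17 <- function(v) ifelse(is.na(v), NA_character_,
                              sprintf("%.17g", v))
  fx <- do.call(rbind, lapply(tracks, function(t) {
    f <- t$fixes
    data.frame(
      `timestamp` = format(f$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      `location-long` = sprintf("%.17g", f$lon),
      `location-lat` = sprintf("%.17g", f$lat),
      `individual-local-identifier` = t$deployment$individual_id,
      `gps:hdop` = num17(f$hdop), `gps:vdop` = num17(f$vdop),
      `tag-voltage` = num17(f$battery_v), `activity` = num17(f$activity),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(fx, path, row.names = FALSE, na = "")
  dp <- do.call(rbind, lapply(tracks, function(t) t$deployment))
  dp_out <- data.frame(
    `individual-local-identifier` = dp$individual_id,
    `sex` = dp$sex, `nucleus` = dp$nucleus,
    `nest-long` = sprintf("%.17g", dp$nest_lon),
    `nest-lat` = sprintf("%.17g", dp$nest_lat),
    `tagging-date` = format(dp$tagging_date),
    `transmitter-model` = dp$transmitter_model,
    `sibling-group` = dp$sibling_group,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(dp_out, deployments_path, row.names = FALSE, na = "")
  invisible(c(path, deployments_path))
}

#' Dilution-of-precision quality filter
#'
#' Removes fixes whose HDOP or VDOP exceeds `max_dop` (strictly greater;
#' a fix at exactly the threshold is retained).  Fixes with missing DOP
#' are retained by default, since several transmitter models report no
#' DOP at all; set `drop_missing_dop = TRUE` for strict dropping.
#'
#' @param traj A `vt_track` (or `vt_tracks`, filtered element-wise).
#' @param max_dop DOP threshold (default 5).
#' @param drop_missing_dop Drop fixes with both DOPs missing?
#' @return Filtered object of the same class; order preserved.
#' @export
qc_filter <- function(traj, max_dop = 5, drop_missing_dop = FALSE) {
  if (inherits(traj, "vt_tracks")) {
    out <- lapply(traj, qc_filter, max_dop = max_dop,
                  drop_missing_dop = drop_missing_dop)
    return(structure(out, class = "vt_tracks", qc_log = attr(traj, "qc_log")))
  }
  f <- traj$fixes
  bad_h <- !is.na(f$hdop) & f$hdop > max_dop
  bad_v <- !is.na(f$vdop) & f$vdop > max_dop
  keep <- !(bad_h | bad_v)
  if (drop_missing_dop) keep <- keep & !(is.na(f$hdop) & is.na(f$vdop))
  traj$fixes <- f[keep, , drop = FALSE]
  rownames(traj$fixes) <- NULL
  traj
}

#' Resample a track onto a regular time grid
#'
#' Standardises the interval between fixes by snapping each fix to its
#' nearest grid slot (grid anchored at the first fix) and keeping, per
#' slot, the fix closest to the slot time (ties go to the earlier fix).
#' Slots with no fix within `tolerance_min` stay empty: positions are
#' never interpolated or fabricated, so every output timestamp is an
#' input timestamp and each original fix is used at most once.
#'
#' @param traj A `vt_track` (or `vt_tracks`, resampled element-wise).
#' @param interval_min Grid interval in minutes (default 30).
#' @param tolerance_min Maximum slot-to-fix offset in minutes (default
#'   15, i.e. half the interval).
#' @return Resampled object of the same class.
#' @export
resample_track <- function(traj, interval_min = 30, tolerance_min = 15) {
  if (interval_min <= 0) stop("interval_min must be positive")
  if (inherits(traj, "vt_tracks")) {
    out <- lapply(traj, resample_track, interval_min = interval_min,
                  tolerance_min = tolerance_min)
    return(structure(out, class = "vt_tracks", qc_log = attr(traj, "qc_log")))
  }
  f <- traj$fixes
  if (nrow(f) < 2L) return(traj)
  rel <- as.numeric(difftime(f$timestamp, f$timestamp[1L], units = "mins"))
  slot <- floor(rel / interval_min + 0.5)          # 0.5 rounds up: determinate
  offset <- abs(rel - slot * interval_min)
  cand <- offset <= tolerance_min + 1e-9
  o <- order(slot[cand], offset[cand], rel[cand])  # per slot: closest, earliest
  idx <- which(cand)[o]
  idx <- idx[!duplicated(slot[idx])]
  traj$fixes <- f[sort(idx), , drop = FALSE]
  rownames(traj$fixes) <- NULL
  traj
}
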