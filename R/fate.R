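# Transmitter-based fate classification and stage-specific apparent
# mortality.
#
# "Apparent" is deliberate: a tag that stops transmitting cannot be
# distinguished from a dead bird without recovery, so these rates
# conflate true death with unrecovered transmitter failure.

#' Fate-classification parameters
#'
#' @param stationary_radius_m Radius within which terminal fixes must sit
#'   to count as a stationary (dead-tag) run (default 50 m).
#' @param stationary_min_days Minimum length of the stationary run
#'   (default 3 days).
#' @param activity_flat_threshold Mean accelerometer-variance level at or
#'   below which the tag is considered motionless (default 2, near the
#'   noise floor of the activity index).
#' @param intermittency_age_years Tag age beyond which end-of-life
#'   intermittent reception censors the bird alive rather than killing
#'   it (default 5 years).
#' @param intermittency_gap_hours Inter-fix gap treated as irregular
#'   reception when assessing end-of-life intermittency (default 24 h).
#' @param gap_death_days Days of terminal silence, with a healthy last
#'   battery reading, presumed to be death (default 30).
#' @param battery_low_v Battery voltage below which a terminal silence is
#'   attributed to the tag, not the bird (default 3.6 V).
#' @return A list of class `vt_fate_params`.
#' @export
fate_params <- function(stationary_radius_m = 50,
                        stationary_min_days = 3,
                        activity_flat_threshold = 2,
                        intermittency_age_years = 5,
                        intermittency_gap_hours = 24,
                        gap_death_days = 30,
                        battery_low_v = 3.6) {
  p <- list(stationary_radius_m = stationary_radius_m,
            stationary_min_days = stationary_min_days,
            activity_flat_threshold = activity_flat_threshold,
            intermittency_age_years = intermittency_age_years,
            intermittency_gap_hours = intermittency_gap_hours,
            gap_death_days = gap_death_days,
            battery_low_v = battery_low_v)
  if (any(!vapply(p, function(v) is.numeric(v) && v > 0, TRUE)))
    stop("all fate parameters must be positive numbers")
  class(p) <- "vt_fate_params"
  p
}

#' Classify an individual's fate from transmitter behaviour
#'
#' Rules, in order of precedence:
#' \enumerate{
#'   \item Terminal fixes all within `stationary_radius_m` of the run's
#'     median position for at least `stationary_min_days`, with a flat
#'     activity channel, imply a dead bird under a still-transmitting
#'     tag: `presumed_dead_stationary`, dated at the start of the run.
#'     Without an activity channel the rule uses positions only and the
#'     record is flagged lower-confidence.
#'   \item Transmission that stops at least `gap_death_days` before the
#'     study end with a healthy last battery reading is assimilated to
#'     death: `presumed_dead_signal_loss`, dated at the last fix.
#'     (A mid-track outage bridged by later fixes never triggers this:
#'     only the terminal gap is examined.)
#'   \item A tag older than `intermittency_age_years` whose reception
#'     turned irregular is censored alive at the last regular fix:
#'     `censored_alive`.
#'   \item Otherwise `alive_transmitting` at the last fix.
#' }
#'
#' @param traj A QC-filtered `vt_track`.
#' @param params A [fate_params()] object.
#' @param study_end Timestamp marking the end of observation (defaults
#'   to the track's last fix, in which case rule 2 cannot fire; pass the
#'   cohort-wide last date for real use).
#' @return An object of class `vt_fate`: list with `individual_id`,
#'   `status`, `event_time`, `age_days_at_event`, `confidence`.
#' @export
infer_fate <- function(traj, params = fate_params(), study_end = NULL) {
  stopifnot(inherits(traj, "vt_track"))
  f <- traj$fixes
  dep <- traj$deployment
  if (nrow(f) == 0L) stop("cannot infer fate from an empty track")
  tag0 <- as.POSIXct(paste(dep$tagging_date, "00:00:00"), tz = "UTC")
  if (is.null(study_end)) study_end <- f$timestamp[nrow(f)]
  n <- nrow(f)
  t_last <- f$timestamp[n]

  rec <- function(status, when, confidence = "standard") {
    structure(list(individual_id = dep$individual_id, status = status,
                   event_time = when,
                   age_days_at_event = as.numeric(difftime(when, tag0,
                                                           units = "days")),
                   confidence = confidence),
              class = "vt_fate")
  }

  # rule 1: terminal stationarity
  win_start <- t_last - params$stationary_min_days * 86400
  ref_idx <- which(f$timestamp >= win_start)
  ref_lon <- stats::median(f$lon[ref_idx])
  ref_lat <- stats::median(f$lat[ref_idx])
  d_m <- haversine_km(f$lon, f$lat, ref_lon, ref_lat) * 1000
  outside <- which(d_m > params$stationary_radius_m)
  run_from <- if (length(outside) == 0L) 1L else max(outside) + 1L
  if (run_from <= n) {
    run_days <- as.numeric(difftime(t_last, f$timestamp[run_from],
                                    units = "days"))
    if (run_days >= params$stationary_min_days) {
      act <- f$activity[run_from:n]
      has_act <- any(!is.na(act))
      act_flat <- !has_act ||
        mean(act, na.rm = TRUE) <= params$activity_flat_threshold
      if (act_flat) {
        return(rec("presumed_dead_stationary", f$timestamp[run_from],
                   if (has_act) "standard" else "positions_only"))
      }
    }
  }

  # rule 2: abrupt terminal signal loss despite a healthy battery
  gap_days <- as.numeric(difftime(study_end, t_last, units = "days"))
  if (gap_days >= params$gap_death_days) {
    last_batt <- rev(f$battery_v[!is.na(f$battery_v)])[1L]
    batt_healthy <- is.na(last_batt) || length(last_batt) == 0L ||
      last_batt >= params$battery_low_v
    if (batt_healthy) {
      return(rec("presumed_dead_signal_loss", t_last))
    }
    # battery was failing: end-of-life, bird censored alive at last fix
    return(rec("censored_alive", t_last, "battery_exhausted"))
  }

  # rule 3: old tag turned intermittent
  age_years <- as.numeric(difftime(t_last, tag0, units = "days")) / 365.25
  if (age_years > params$intermittency_age_years && n >= 2L) {
    gaps_h <- diff(as.numeric(f$timestamp)) / 3600
    irregular <- gaps_h > params$intermittency_gap_hours
    if (any(irregular)) {
      # censor at the fix opening the final irregular stretch, provided
      # irregularity dominates reception from there on
      first_irr <- which(irregular)[1L]
      tail_gaps <- gaps_h[first_irr:length(gaps_h)]
      if (mean(tail_gaps > params$intermittency_gap_hours) > 0.5) {
        return(rec("censored_alive", f$timestamp[first_irr]))
      }
    }
  }

  rec("alive_transmitting", t_last)
}

#' @export
print.vt_fate <- function(x, ...) {
  cat(sprintf("<vt_fate> %s: %s at %s (age %.0f d)%s\n", x$individual_id,
              x$status, format(x$event_time, "%Y-%m-%d"),
              x$age_days_at_event,
              if (x$confidence != "standard")
                paste0(" [", x$confidence, "]") else ""))
  invisible(x)
}

# stage label -> reporting stage (Table-style roll-up)
.REPORT_STAGE <- c(dependence = "dependence",
                   iberia_premigration = "migration",
                   sahara_crossing = "migration",
                   return_migration = "migration",
                   sahel_stay = "sahel_stay",
                   iberia_postreturn = "iberia_postreturn",
                   residency = "residency")

#' Attribute a loss to a life stage
#'
#' Looks up the segmentation interval containing the fate's event time.
#' Pre-migration, Sahara-crossing and return-migration losses all roll
#' up to `"migration"` for table-style reporting.
#'
#' @param fate A `vt_fate`.
#' @param seg The individual's `vt_segmentation`.
#' @param rollup Apply the reporting roll-up? (default TRUE)
#' @return Stage label, or `"unsegmented"` with a warning if the event
#'   time falls outside all intervals.
#' @export
assign_loss_stage <- function(fate, seg, rollup = TRUE) {
  raw <- stage_at(seg, fate$event_time)
  if (!rollup || raw == "unsegmented") return(raw)
  unname(.REPORT_STAGE[raw])
}

#' Truncated mortality rate
#'
#' deaths / duration, truncated (not rounded) to two decimals, the
#' convention under which e.g. 5 deaths over a 28-day stage report as
#' 0.17 and 14 deaths over 631 days as 0.02.
#'
#' @param deaths Death count.
#' @param duration_days Stage duration in days.
#' @return Rate truncated to 2 decimals.
#' @export
mortality_rate <- function(deaths, duration_days) {
  if (any(duration_days <= 0)) stop("duration must be positive")
  floor(100 * deaths / duration_days) / 100
}

#' Format a per-nucleus loss fraction
#'
#' Renders "lost/tagged (pct)" with the percentage rounded to the
#' nearest integer, e.g. `loss_fraction(7, 17)` is `"7/17 (41%)"`.
#'
#' @param lost,tagged Counts.
#' @return Character vector.
#' @export
loss_fraction <- function(lost, tagged) {
  sprintf("%d/%d (%.0f%%)", lost, tagged, 100 * lost / tagged)
}

#' Stage-specific apparent-mortality table
#'
#' Cross-tabulates presumed deaths by reporting stage, nucleus and sex;
#' the per-stage duration is the mean observed stage duration over
#' individuals that entered the stage, and the rate is
#' deaths / duration truncated to two decimals.  Per-nucleus totals are
#' reported as "lost/tagged (pct)".
#'
#' @param fates List of `vt_fate` records.
#' @param segs List of `vt_segmentation` objects (same individuals).
#' @param deployments Deployment data frame (internal column names, as
#'   from [read_deployments()]).
#' @return An object of class `vt_mortality_table`: list with `table`
#'   (stage rows: deaths by nucleus x sex, total, duration, rate),
#'   `nucleus_totals`, and the underlying long-format `events`.
#' @export
stage_mortality_table <- function(fates, segs, deployments) {
  ids <- vapply(fates, function(x) x$individual_id, "")
  names(segs) <- vapply(segs, function(s) s$individual_id, "")
  dep <- deployments

  dead <- vapply(fates, function(x)
    x$status %in% c("presumed_dead_stationary",
                    "presumed_dead_signal_loss"), TRUE)
  stage <- character(length(fates))
  stage[dead] <- vapply(which(dead), function(i)
    assign_loss_stage(fates[[i]], segs[[ids[i]]]), "")

  events <- data.frame(
    individual_id = ids,
    nucleus = dep$nucleus[match(ids, dep$individual_id)],
    sex = dep$sex[match(ids, dep$individual_id)],
    dead = dead,
    stage = ifelse(dead, stage, NA_character_),
    stringsAsFactors = FALSE)

  # mean observed duration per reporting stage over individuals entering
  # it; an individual entering several intervals of one reporting stage
  # (e.g. pre-migration + Sahara legs under "migration") contributes
  # their sum
  dur_rows <- do.call(rbind, lapply(segs, function(s) {
    iv <- s$intervals
    if (nrow(iv) == 0L) return(NULL)
    per <- tapply(iv$duration_days, unname(.REPORT_STAGE[iv$stage]), sum)
    data.frame(stage = names(per), duration = as.numeric(per),
               stringsAsFactors = FALSE)
  }))
  all_stages <- c("dependence", "migration", "sahel_stay",
                  "iberia_postreturn", "residency")
  mean_dur <- vapply(all_stages, function(st) {
    d <- dur_rows$duration[dur_rows$stage == st]
    if (length(d) == 0L) NA_real_ else mean(d)
  }, 0)

  nuclei <- sort(unique(dep$nucleus))
  sexes <- sort(unique(dep$sex))
  rows <- list()
  for (st in all_stages) {
    if (is.na(mean_dur[[st]])) next  # stage never entered: row omitted
    r <- list(stage = st)
    for (nu in nuclei) for (sx in sexes) {
      r[[paste(nu, sx, sep = "_")]] <-
        sum(events$dead & events$stage == st & events$nucleus == nu &
              events$sex == sx, na.rm = TRUE)
    }
    r$deaths <- sum(events$dead & events$stage == st, na.rm = TRUE)
    r$duration_days <- mean_dur[[st]]
    r$mortality_rate <- mortality_rate(r$deaths, r$duration_days)
    rows[[length(rows) + 1L]] <- as.data.frame(r, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)

  nucleus_totals <- do.call(rbind, lapply(nuclei, function(nu) {
    lost <- sum(events$dead & events$nucleus == nu)
    tagged <- sum(dep$nucleus == nu)
    data.frame(nucleus = nu, lost = lost, tagged = tagged,
               lost_tagged_pct = loss_fraction(lost, tagged),
               stringsAsFactors = FALSE)
  }))

  structure(list(table = tab, nucleus_totals = nucleus_totals,
                 events = events),
            class = "vt_mortality_table")
}

#' @export
print.vt_mortality_table <- function(x, ...) {
  cat("<vt_mortality_table> apparent mortality by stage\n")
  tab <- x$table
  print(data.frame(stage = tab$stage, deaths = tab$deaths,
                   duration = round(tab$duration_days),
                   rate = sprintf("%.2f", tab$mortality_rate)))
  cat("per-nucleus losses:",
      paste(x$nucleus_totals$nucleus, x$nucleus_totals$lost_tagged_pct,
            collapse = "; "), "\n")
  invisible(x)
}
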