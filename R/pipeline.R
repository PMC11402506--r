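# End-to-end orchestration: QC -> resample -> segment -> home range ->
# fate -> survival, with table outputs mirroring a field-study report.

#' Per-group descriptive summary
#'
#' Sample mean, SD (n-1 denominator), n and range per group.  Groups
#' with no finite values are omitted (with a note attribute); a single
#' value reports `NA` SD.
#'
#' @param values Numeric vector.
#' @param groups Group labels (same length).
#' @return Data frame with `group`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
group_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  lv <- sort(unique(groups))
  out <- do.call(rbind, lapply(lv, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  empty <- setdiff(unique(as.character(groups)), lv)
  if (length(empty) > 0L) attr(out, "note") <- paste("omitted empty groups:",
                                                     paste(empty,
                                                           collapse = ", "))
  out
}

#' Run the full analysis pipeline
#'
#' Takes a cohort (either a [simulate_cohort()] object or paths to
#' Movebank-dialect fixes/deployments CSVs), applies DOP filtering and
#' 30-min resampling, infers each bird's fate, segments each track into
#' life stages (truncated at the fate event), fits Sahel-stay home
#' ranges for migrants and full-residency plus monthly ranges for
#' residents, builds the stage-mortality table, Kaplan-Meier curves and
#' log-rank comparisons, and (optionally) writes the report bundle to
#' `out_dir`: `stages.csv`, `kde.csv`, `kde.geojson`, `fates.csv`,
#' `mortality_table.csv`, `km_curves.csv`, `group_summary.csv`,
#' `run_log.txt` and `manifest.csv` (md5 checksums).
#'
#' @param cohort A `vt_cohort`, a `vt_tracks`, or a length-2 character
#'   vector `c(fixes_csv, deployments_csv)`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seg_par A [seg_params()] object.
#' @param fate_par A [fate_params()] object.
#' @param max_dop DOP threshold for QC (default 5).
#' @param interval_min,tolerance_min Resampling grid (defaults 30/15).
#' @param kde_cell_km Grid cell for home ranges (default 5 km).
#' @param min_kde_fixes Minimum stage fixes for a home-range fit
#'   (default 50).
#' @return An object of class `vt_pipeline`: list with `stages`,
#'   `fates`, `mortality`, `kde` (fits), `kde_table`, `km` (curves by
#'   grouping), `logrank`, `group_summaries`, `params`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         seg_par = seg_params(), fate_par = fate_params(),
                         max_dop = 5, interval_min = 30, tolerance_min = 15,
                         kde_cell_km = 5, min_kde_fixes = 50) {
  if (is.character(cohort)) {
    stopifnot(length(cohort) == 2L)
    tracks <- read_movebank(cohort[1], cohort[2])
  } else if (inherits(cohort, "vt_cohort")) {
    tracks <- cohort$tracks
  } else if (inherits(cohort, "vt_tracks")) {
    tracks <- cohort
  } else stop("cohort must be a vt_cohort, vt_tracks or two CSV paths")

  deployments <- do.call(rbind, lapply(tracks, function(t) t$deployment))
  rownames(deployments) <- NULL

  clean <- resample_track(qc_filter(tracks, max_dop = max_dop),
                          interval_min = interval_min,
                          tolerance_min = tolerance_min)
  nonempty <- vapply(clean, function(t) nrow(t$fixes) > 0L, TRUE)
  if (!all(nonempty))
    message("dropping ", sum(!nonempty), " empty post-QC track(s)")
  clean <- structure(clean[nonempty], class = "vt_tracks")

  study_end <- max(do.call(c, lapply(clean, function(t)
    t$fixes$timestamp[nrow(t$fixes)])))

  fates <- lapply(clean, infer_fate, params = fate_par,
                  study_end = study_end)

  # segment on the track truncated at the fate event (post-death fixes
  # from a still-transmitting tag must not stretch the final stage)
  segs <- lapply(names(clean), function(id) {
    tr <- clean[[id]]
    ev <- fates[[id]]$event_time
    tr$fixes <- tr$fixes[tr$fixes$timestamp <= ev, , drop = FALSE]
    segment_stages(tr, seg_par)
  })
  names(segs) <- names(clean)

  stages_df <- do.call(rbind, lapply(segs, function(s) {
    if (nrow(s$intervals) == 0L) return(NULL)
    data.frame(individual = s$individual_id, stage = s$intervals$stage,
               start = s$intervals$start, end = s$intervals$end,
               duration_days = s$intervals$duration_days,
               strategy = s$strategy, stringsAsFactors = FALSE)
  }))
  rownames(stages_df) <- NULL

  # --- home ranges ------------------------------------------------------
  kdes <- list()
  kde_rows <- list()
  for (id in names(clean)) {
    s <- segs[[id]]
    tr <- clean[[id]]
    stage_name <- if (s$strategy == "non_migrant") "residency"
      else "sahel_stay"
    iv <- s$intervals[s$intervals$stage == stage_name, , drop = FALSE]
    if (nrow(iv) == 0L) next
    f <- tr$fixes[tr$fixes$timestamp >= iv$start[1L] &
                    tr$fixes$timestamp <= iv$end[nrow(iv)] &
                    tr$fixes$timestamp <= fates[[id]]$event_time, ,
                  drop = FALSE]
    if (nrow(f) < min_kde_fixes) next
    k <- fit_kde(f$lon, f$lat, cell_km = kde_cell_km)
    kdes[[id]] <- k
    kde_rows[[id]] <- data.frame(
      individual = id, stage = stage_name, n_fixes = nrow(f),
      bandwidth_km = k$bandwidth_km, area_km2 = k$area_km2,
      centroid_lon = unname(k$centroid["lon"]),
      centroid_lat = unname(k$centroid["lat"]),
      stringsAsFactors = FALSE)
  }
  kde_table <- do.call(rbind, kde_rows)
  rownames(kde_table) <- NULL

  # pairwise overlap/centroid distances among migrant Sahel ranges
  overlap_rows <- list()
  mig_ids <- names(kdes)[vapply(names(kdes), function(id)
    segs[[id]]$strategy != "non_migrant", TRUE)]
  if (length(mig_ids) >= 2L) {
    prs <- utils::combn(mig_ids, 2L)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1L, j]; b <- prs[2L, j]
      ov <- overlap_pct(kdes[[a]], kdes[[b]])
      overlap_rows[[j]] <- data.frame(
        id_a = a, id_b = b, overlap_pct = as.numeric(ov),
        centroid_distance_km = centroid_distance_km(kdes[[a]], kdes[[b]]),
        same_nucleus = deployments$nucleus[match(a,
          deployments$individual_id)] ==
          deployments$nucleus[match(b, deployments$individual_id)],
        stringsAsFactors = FALSE)
    }
  }
  overlaps <- if (length(overlap_rows)) do.call(rbind, overlap_rows) else NULL

  # --- mortality and survival ------------------------------------------
  mortality <- stage_mortality_table(fates, segs, deployments)

  surv_df <- data.frame(
    individual = names(fates),
    time = vapply(fates, function(x) x$age_days_at_event, 0),
    event = vapply(fates, function(x)
      as.integer(x$status %in% c("presumed_dead_stationary",
                                 "presumed_dead_signal_loss")), 0L),
    nucleus = deployments$nucleus[match(names(fates),
                                        deployments$individual_id)],
    sex = deployments$sex[match(names(fates), deployments$individual_id)],
    strategy = vapply(names(fates), function(id) segs[[id]]$strategy, ""),
    stringsAsFactors = FALSE)
  rownames(surv_df) <- NULL

  km_all <- kaplan_meier(surv_df$time, surv_df$event)
  logrank <- list()
  for (gv in c("nucleus", "sex", "strategy")) {
    if (length(unique(surv_df[[gv]])) >= 2L)
      logrank[[gv]] <- log_rank(surv_df$time, surv_df$event, surv_df[[gv]])
  }

  # --- descriptive group summaries -------------------------------------
  metric_rows <- list()
  for (id in names(clean)) {
    s <- segs[[id]]
    dur <- stage_durations_days(s)
    dep <- deployments[match(id, deployments$individual_id), ]
    tr <- clean[[id]]
    # dependence metrics run from nest departure (not tagging) to natal
    # departure, the interval the field definitions use
    dd <- maxd <- dep_days <- NA_real_
    iv <- s$intervals[s$intervals$stage == "dependence", , drop = FALSE]
    if (nrow(iv) == 1L) {
      t_from <- s$events$nest_departure
      if (is.null(t_from) || is.na(t_from)) t_from <- iv$start
      dep_days <- as.numeric(difftime(iv$end, t_from, units = "days"))
      f <- tr$fixes[tr$fixes$timestamp >= t_from & tr$fixes$timestamp <=
                      iv$end, , drop = FALSE]
      if (nrow(f) >= 2L) {
        ddf <- daily_distance_km(f)
        dd <- mean(ddf$km, na.rm = TRUE)
        maxd <- max_displacement_km(f, dep$nest_lon, dep$nest_lat)
      }
    }
    metric_rows[[id]] <- data.frame(
      individual = id, nucleus = dep$nucleus, sex = dep$sex,
      strategy = s$strategy,
      dependence_days = dep_days,
      daily_distance_dependence_km = dd,
      max_displacement_dependence_km = maxd,
      sahara_days = if (!is.null(s$events$sahara_duration_days))
        s$events$sahara_duration_days else NA_real_,
      area_km2 = if (id %in% names(kdes)) kdes[[id]]$area_km2 else NA_real_,
      stringsAsFactors = FALSE)
  }
  metrics <- do.call(rbind, metric_rows)
  rownames(metrics) <- NULL
  gs <- list()
  for (v in c("dependence_days", "daily_distance_dependence_km",
              "max_displacement_dependence_km", "sahara_days", "area_km2")) {
    for (g in c("nucleus", "sex")) {
      tab <- group_summary(metrics[[v]], metrics[[g]])
      if (!is.null(tab) && nrow(tab) > 0L) {
        tab$metric <- v; tab$grouping <- g
        gs[[paste(v, g)]] <- tab
      }
    }
  }
  group_summaries <- do.call(rbind, gs)
  rownames(group_summaries) <- NULL

  result <- structure(list(
    stages = stages_df, fates = fates, segs = segs,
    mortality = mortality, kde = kdes, kde_table = kde_table,
    overlaps = overlaps, survival = surv_df, km = km_all,
    logrank = logrank, metrics = metrics,
    group_summaries = group_summaries,
    params = list(max_dop = max_dop, interval_min = interval_min,
                  tolerance_min = tolerance_min, seg = seg_par,
                  fate = fate_par, kde_cell_km = kde_cell_km,
                  min_kde_fixes = min_kde_fixes,
                  study_end = study_end)),
    class = "vt_pipeline")

  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

#' @export
print.vt_pipeline <- function(x, ...) {
  cat(sprintf("<vt_pipeline> %d individuals\n", length(x$segs)))
  strat <- table(vapply(x$segs, function(s) s$strategy, ""))
  cat("  strategies:", paste(names(strat), strat, sep = "=",
                             collapse = ", "), "\n")
  print(x$mortality)
  invisible(x)
}

#' Write the pipeline report bundle
#'
#' @param x A `vt_pipeline`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame (file, md5).
#' @export
write_pipeline <- function(x, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  wr(x$stages, "stages.csv")
  fates_df <- do.call(rbind, lapply(x$fates, function(f)
    data.frame(individual = f$individual_id, status = f$status,
               event_time = format(f$event_time, "%Y-%m-%d %H:%M:%S"),
               age_days_at_event = f$age_days_at_event,
               confidence = f$confidence, stringsAsFactors = FALSE)))
  wr(fates_df, "fates.csv")
  wr(x$mortality$table, "mortality_table.csv")
  if (!is.null(x$kde_table)) wr(x$kde_table, "kde.csv")
  if (!is.null(x$overlaps)) wr(x$overlaps, "overlaps.csv")
  wr(x$km$table, "km_curves.csv")
  wr(x$group_summaries, "group_summary.csv")
  if (length(x$kde) > 0L) {
    p <- file.path(out_dir, "kde.geojson")
    kde_geojson(x$kde, p)
    paths <- c(paths, p)
  }
  log_path <- file.path(out_dir, "run_log.txt")
  con <- file(log_path, "w")
  writeLines(c(
    sprintf("vultrack pipeline run %s", format(Sys.time(), "%Y-%m-%d")),
    sprintf("individuals: %d", length(x$segs)),
    sprintf("max_dop: %g", x$params$max_dop),
    sprintf("interval_min: %g  tolerance_min: %g", x$params$interval_min,
            x$params$tolerance_min),
    sprintf("kde_cell_km: %g  min_kde_fixes: %d", x$params$kde_cell_km,
            x$params$min_kde_fixes),
    sprintf("study_end: %s", format(x$params$study_end)),
    "segmentation parameters:",
    paste(sprintf("  %s: %s", names(unclass(x$params$seg)),
                  vapply(unclass(x$params$seg), function(v)
                    paste(v, collapse = ","), ""))),
    "fate parameters:",
    paste(sprintf("  %s: %s", names(unclass(x$params$fate)),
                  vapply(unclass(x$params$fate), function(v)
                    paste(v, collapse = ","), "")))
  ), con)
  close(con)
  paths <- c(paths, log_path)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
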