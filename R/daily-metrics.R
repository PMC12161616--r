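#' Classify minute intensity from MAD
#'
#' Boundary convention (see [threshold_config()]): `mad <
#' sedentary_ceiling` is sedentary, `sedentary_ceiling <= mad <
#' mvpa_floor` is light, `mad >= mvpa_floor` is MVPA. Null minutes
#' (`NA` MAD) stay `NA`.
#'
#' @param mad numeric vector of minute MAD values in g (NA for null
#'   minutes).
#' @param cfg a [threshold_config()].
#' @return character vector of labels in
#'   `c("sedentary", "light", "mvpa")`, `NA` for null minutes.
#' @export
classify_intensity <- function(mad, cfg = threshold_config()) {
  stopifnot(inherits(cfg, "wf_thresholds"))
  out <- rep(NA_character_, length(mad))
  out[!is.na(mad) & mad < cfg$sedentary_ceiling] <- "sedentary"
  out[!is.na(mad) & mad >= cfg$sedentary_ceiling & mad < cfg$mvpa_floor] <- "light"
  out[!is.na(mad) & mad >= cfg$mvpa_floor] <- "mvpa"
  out
}

#' Daily MVPA minutes
#'
#' Count of MVPA-labeled minutes over the day's 1440-minute label
#' sequence; null minutes never count.
#'
#' @param labels character vector of length 1440 from
#'   [classify_intensity()].
#' @return integer minutes.
#' @export
mvpa_minutes <- function(labels) {
  if (length(labels) != .MINUTES_PER_DAY) stop("labels must have length 1440")
  sum(labels == "mvpa", na.rm = TRUE)
}

#' Count daily sedentary breaks
#'
#' Awake time is partitioned into consecutive, non-overlapping 30-minute
#' windows anchored at waketime (a trailing partial window is ignored).
#' A window contains a break iff it holds at least 2 consecutive
#' non-sedentary minutes (`break_rule = "nonsedentary"`: light or MVPA;
#' `"mvpa_only"`: MVPA only). Null minutes count as sedentary
#' (conservative). A 16-hour awake day therefore has at most 32 breaks.
#'
#' @param labels character vector of length 1440.
#' @param waketime,bedtime awake window, minutes since midnight;
#'   `bedtime` must exceed `waketime`.
#' @param break_rule which intensities break sedentary time.
#' @return integer count of windows containing a break.
#' @export
sedentary_breaks <- function(labels, waketime, bedtime,
                             break_rule = c("nonsedentary", "mvpa_only")) {
  if (length(labels) != .MINUTES_PER_DAY) stop("labels must have length 1440")
  break_rule <- match.arg(break_rule)
  if (bedtime <= waketime) stop("bedtime must be after waketime")
  active <- break_minutes(labels, break_rule)
  n_win <- (bedtime - waketime) %/% 30L
  breaks <- 0L
  for (w in seq_len(n_win)) {
    idx <- waketime + (w - 1L) * 30L + 1:30
    if (has_run(active[idx], 2L)) breaks <- breaks + 1L
  }
  breaks
}

break_minutes <- function(labels, break_rule) {
  if (break_rule == "nonsedentary") {
    labels %in% c("light", "mvpa")
  } else {
    labels %in% "mvpa"
  }
}

#' Sedentary-behavior alert check
#'
#' Applied to the first 25 minutes of the current 30-minute window:
#' returns `TRUE` (trigger the alert) iff no run of at least 2
#' consecutive non-sedentary minutes has occurred in them.
#'
#' @param window_labels character vector of exactly 25 minute labels.
#' @param break_rule as in [sedentary_breaks()].
#' @return logical.
#' @export
alert_check <- function(window_labels,
                        break_rule = c("nonsedentary", "mvpa_only")) {
  if (length(window_labels) != 25L) stop("alert_check needs exactly 25 minute labels")
  break_rule <- match.arg(break_rule)
  !has_run(break_minutes(window_labels, break_rule), 2L)
}

#' Per-goal progress fractions
#'
#' Raw achieved/target fraction per set goal plus a display fraction
#' capped at 1 (the progress bar saturates at 100%).
#'
#' @param day a `wf_day` from [day_record()].
#' @param goals a [goal_set()].
#' @return data.frame with `goal`, `achieved`, `target`, `fraction`
#'   (raw), `display` (capped at 1).
#' @export
goal_progress <- function(day, goals) {
  stopifnot(inherits(day, "wf_day"), inherits(goals, "wf_goals"))
  achieved <- c(energy_kcal = day$energy_total,
                distance_m = day$distance_total_m,
                mvpa_min = day$mvpa_minutes,
                breaks = day$sedentary_breaks)
  target <- unlist(goals)
  keep <- !is.na(target)
  if (any(target[keep] == 0)) stop("configuration error: zero goal target")
  frac <- achieved[keep] / target[keep]
  data.frame(goal = names(target)[keep],
             achieved = unname(achieved[keep]),
             target = unname(target[keep]),
             fraction = unname(frac),
             display = pmin(unname(frac), 1),
             row.names = NULL)
}

#' Assemble the daily metrics record
#'
#' Computes the six home-screen measures for one day from the per-minute
#' feature table: total energy, total distance (meters and miles), MVPA
#' minutes, sedentary breaks, total pushes and the day's last heart
#' rate, plus coverage, sedentary-alert trigger times and goal progress.
#' Alerts are evaluated per 30-minute awake window on its first 25
#' minutes ([alert_check()]); the reported alert time is the minute the
#' 25-minute mark is reached.
#'
#' @param records a `wf_minutes` from [minute_records()].
#' @param coverage fraction from [day_coverage()].
#' @param waketime,bedtime awake window, minutes since midnight.
#' @param goals optional [goal_set()].
#' @param break_rule as in [sedentary_breaks()].
#' @return an object of class `wf_day`.
#' @export
day_record <- function(records, coverage, waketime, bedtime, goals = NULL,
                       break_rule = c("nonsedentary", "mvpa_only")) {
  stopifnot(inherits(records, "wf_minutes"))
  break_rule <- match.arg(break_rule)
  if (bedtime <= waketime) stop("bedtime must be after waketime")
  labels <- records$label
  dist_m <- sum(records$distance_m)
  n_win <- (bedtime - waketime) %/% 30L
  alerts <- integer()
  for (w in seq_len(n_win)) {
    start <- waketime + (w - 1L) * 30L
    if (alert_check(labels[start + 1:25], break_rule)) {
      alerts <- c(alerts, start + 25L)
    }
  }
  hr_obs <- records$hr_last[!is.na(records$hr_last)]
  day <- structure(
    list(day_date = attr(records, "day_date"),
         energy_total = sum(records$energy_kcal, na.rm = TRUE),
         distance_total_m = dist_m,
         distance_total_mi = dist_m / 1609.344,
         mvpa_minutes = mvpa_minutes(labels),
         sedentary_breaks = sedentary_breaks(labels, waketime, bedtime,
                                             break_rule),
         push_total = sum(records$pushes),
         hr_last = if (length(hr_obs)) tail(hr_obs, 1L) else NA_real_,
         alerts = alerts,
         coverage = coverage,
         waketime = waketime, bedtime = bedtime,
         n_nonnull = sum(!is.na(records$mad)),
         n_nonsedentary = sum(labels %in% c("light", "mvpa")),
         goal_progress = NULL),
    class = "wf_day")
  if (!is.null(goals)) day$goal_progress <- goal_progress(day, goals)
  day
}

#' Process one day of stream files end to end
#'
#' Convenience wrapper: [read_streams()] -> [bin_minutes()] ->
#' [minute_records()] -> [day_record()].
#'
#' @param dir directory with the day's `accel.csv`, `hr.csv`,
#'   `wheel.csv`.
#' @param waketime,bedtime awake window, minutes since midnight.
#' @param device,thresholds,push_cfg,demographics,model,goals,break_rule
#'   forwarded to the pipeline stages.
#' @return a `wf_day`.
#' @export
process_day <- function(dir, waketime = 420L, bedtime = 1380L,
                        device = device_profile(),
                        thresholds = threshold_config(),
                        push_cfg = push_config(),
                        demographics = NULL, model = energy_model(),
                        goals = NULL,
                        break_rule = c("nonsedentary", "mvpa_only")) {
  streams <- read_streams(dir)
  bins <- bin_minutes(streams)
  records <- minute_records(bins, device = device, thresholds = thresholds,
                            push_cfg = push_cfg, demographics = demographics,
                            model = model)
  attr(records, "day_date") <- streams$day_date
  day_record(records, day_coverage(bins), waketime, bedtime, goals = goals,
             break_rule = match.arg(break_rule))
}

#' @export
print.wf_day <- function(x, ...) {
  cat("<wf_day>", if (!is.null(x$day_date)) format(x$day_date), "\n")
  cat(sprintf("  energy        %8.1f kcal\n", x$energy_total))
  cat(sprintf("  distance      %8.1f m (%.2f mi)\n",
              x$distance_total_m, x$distance_total_mi))
  cat(sprintf("  MVPA          %8d min\n", x$mvpa_minutes))
  cat(sprintf("  sed. breaks   %8d\n", x$sedentary_breaks))
  cat(sprintf("  pushes        %8d\n", x$push_total))
  cat(sprintf("  last HR       %8s bpm\n",
              ifelse(is.na(x$hr_last), "NA", format(x$hr_last))))
  cat(sprintf("  coverage      %8.3f\n", x$coverage))
  cat(sprintf("  alerts        %8d\n", length(x$alerts)))
  invisible(x)
}
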