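#' Render a schedule into raw multi-rate sensor streams
#'
#' Produces the three streams a real recording day would yield:
#' \itemize{
#'   \item `accel`: triaxial wrist acceleration at `device$accel_rate`
#'     (30 Hz). Each awake minute is a unit-gravity baseline plus a
#'     sample-alternating square wave whose amplitude is solved (by
#'     bisection) so the minute's vector-magnitude MAD hits the target
#'     band for the scheduled intensity, plus one half-sine burst
#'     (~0.4 s, `device$push_amplitude` g) per scheduled push, plus
#'     optional white noise per axis.
#'   \item `hr`: heart rate at 1 Hz, intensity-dependent mean with AR(1)
#'     noise (plumbing only, not physiologic).
#'   \item `wheel`: rotation counts in 0.2 s windows (5 Hz), emitted only
#'     during propulsion minutes (the wheel sensor gates its gyroscope on
#'     movement); per-minute sums equal the scheduled rotation rate.
#' }
#' Watch streams (`accel`, `hr`) end at `waketime + battery_life` hours
#' (battery death, hard truncation); the wheel sensor is unaffected.
#'
#' @param schedule a `wf_schedule` from [generate_schedule()].
#' @param device a [device_profile()]. Set `noise_sd = 0` for a
#'   noise-free render whose minute labels reproduce the schedule exactly.
#' @param seed integer seed for the noise draws.
#' @param mad_targets named numeric: target minute MAD (g) rendered for
#'   each intensity. Must be consistent with the [threshold_config()]
#'   used downstream (defaults are: sedentary well under the 0.02 g
#'   ceiling, light inside [0.02, 0.08), MVPA above the 0.08 g floor).
#' @return an object of class `wf_streams`: list with `participant_id`,
#'   `day_date`, data.tables `accel` (time, ax, ay, az), `hr` (time,
#'   bpm), `wheel` (time, rotations) with `time` in seconds since local
#'   midnight, and `gaps` (data.frame start/end in minutes, maximal runs
#'   of minutes without accelerometer samples).
#' @export
render_streams <- function(schedule, device = device_profile(), seed = 1L,
                           mad_targets = c(sedentary = 0.008, light = 0.045,
                                           mvpa = 0.15)) {
  validate_schedule(schedule)
  stopifnot(inherits(device, "wf_device"))
  set.seed(seed)
  rate <- device$accel_rate
  n <- as.integer(rate * 60)
  mins <- schedule_minutes(schedule)
  death_min <- schedule$waketime + device$battery_life * 60
  watch <- mins[mins$minute < death_min, , drop = FALSE]

  accel <- vector("list", nrow(watch))
  for (i in seq_len(nrow(watch))) {
    m <- watch[i, ]
    push <- push_waveform(n, rate, m$pushes, device$push_amplitude)
    amp <- solve_square_amp(push, mad_targets[[m$intensity]], n)
    az <- 1 + rep_len(c(amp, -amp), n) + push
    if (device$noise_sd > 0) {
      ax <- rnorm(n, 0, device$noise_sd)
      ay <- rnorm(n, 0, device$noise_sd)
      az <- az + rnorm(n, 0, device$noise_sd)
    } else {
      ax <- ay <- numeric(n)
    }
    accel[[i]] <- data.table::data.table(
      time = m$minute * 60 + (seq_len(n) - 1) / rate,
      ax = ax, ay = ay, az = az)
  }
  accel <- if (length(accel)) data.table::rbindlist(accel) else
    data.table::data.table(time = numeric(), ax = numeric(),
                           ay = numeric(), az = numeric())

  hr <- render_hr(watch, device)
  wheel <- render_wheel(mins, device)

  structure(
    list(participant_id = schedule$participant_id,
         day_date = schedule$day_date,
         accel = accel, hr = hr, wheel = wheel,
         gaps = gaps_from_minutes(unique(floor(accel$time / 60)))),
    class = "wf_streams")
}

# half-sine bursts (~0.4 s each) evenly spaced over the minute
push_waveform <- function(n, rate, pushes, amplitude) {
  wave <- numeric(n)
  if (pushes <= 0) return(wave)
  width <- max(2L, as.integer(round(0.4 * rate)))
  starts <- floor((seq_len(pushes) - 1) * n / pushes) + 1L
  burst <- amplitude * sin(pi * (seq_len(width) - 0.5) / width)
  for (s in starts) {
    idx <- s:min(s + width - 1L, n)
    wave[idx] <- wave[idx] + burst[seq_along(idx)]
  }
  wave
}

# amplitude of the sample-alternating square wave so that the noise-free
# minute magnitude MAD hits `target`; 0 if the push bursts alone exceed it
solve_square_amp <- function(push, target, n) {
  mad_of <- function(a) {
    r <- 1 + rep_len(c(a, -a), n) + push
    mean(abs(r - mean(r)))
  }
  if (mad_of(0) >= target) return(0)
  lo <- 0; hi <- max(2 * target, 0.01)
  while (mad_of(hi) < target) hi <- hi * 2
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (mad_of(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

render_hr <- function(watch, device) {
  if (nrow(watch) == 0L) {
    return(data.table::data.table(time = numeric(), bpm = numeric()))
  }
  means <- c(sedentary = 72, light = 88, mvpa = 115)
  per_min <- as.integer(device$hr_rate * 60)
  mu <- rep(means[watch$intensity], each = per_min)
  ar <- as.numeric(stats::filter(rnorm(length(mu), 0, 1.5), 0.95,
                                 method = "recursive"))
  data.table::data.table(
    time = rep(watch$minute * 60, each = per_min) +
      rep((seq_len(per_min) - 1) / device$hr_rate, nrow(watch)),
    bpm = round(mu + ar))
}

render_wheel <- function(mins, device) {
  prop <- mins[mins$rotations > 0, , drop = FALSE]
  if (nrow(prop) == 0L) {
    return(data.table::data.table(time = numeric(), rotations = integer()))
  }
  ticks <- as.integer(device$gyro_rate * 60)
  out <- lapply(seq_len(nrow(prop)), function(i) {
    r <- prop$rotations[i]
    # rotation event times evenly spaced within the minute
    evt <- (seq_len(r) - 0.5) * 60 / r
    counts <- tabulate(pmin(floor(evt * device$gyro_rate) + 1L, ticks), ticks)
    data.table::data.table(
      time = prop$minute[i] * 60 + (seq_len(ticks) - 1) / device$gyro_rate,
      rotations = counts)
  })
  data.table::rbindlist(out)
}

# maximal runs of day-minutes (0..1439) absent from `present`
gaps_from_minutes <- function(present) {
  null <- setdiff(0:(.MINUTES_PER_DAY - 1L), present)
  if (length(null) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  brk <- c(0L, which(diff(null) > 1L), length(null))
  data.frame(start = null[head(brk, -1L) + 1L],
             end = null[brk[-1L]] + 1L)
}

#' Write sensor streams in the package CSV dialect
#'
#' Writes `accel.csv` (iso_timestamp, ax, ay, az), `hr.csv`
#' (iso_timestamp, bpm) and `wheel.csv` (iso_timestamp, rotations) under
#' `dir`, timestamps in ISO-8601 local time with millisecond precision.
#' This is the same dialect [read_streams()] consumes.
#'
#' @param streams a `wf_streams`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_streams <- function(streams, dir) {
  stopifnot(inherits(streams, "wf_streams"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  iso <- function(t) iso_timestamp(streams$day_date, t)
  data.table::fwrite(
    data.table::data.table(iso_timestamp = iso(streams$accel$time),
                           ax = streams$accel$ax, ay = streams$accel$ay,
                           az = streams$accel$az),
    file.path(dir, "accel.csv"))
  data.table::fwrite(
    data.table::data.table(iso_timestamp = iso(streams$hr$time),
                           bpm = streams$hr$bpm),
    file.path(dir, "hr.csv"))
  data.table::fwrite(
    data.table::data.table(iso_timestamp = iso(streams$wheel$time),
                           rotations = streams$wheel$rotations),
    file.path(dir, "wheel.csv"))
  invisible(dir)
}

iso_timestamp <- function(day_date, seconds) {
  if (length(seconds) == 0L) return(character())
  h <- floor(seconds / 3600)
  m <- floor((seconds - h * 3600) / 60)
  s <- seconds - h * 3600 - m * 60
  sprintf("%sT%02d:%02d:%06.3f", format(day_date), h, m, s)
}

#' Write a daily-log CSV for a set of schedules
#'
#' One row per day: `date`, `bedtime`, `waketime` (HH:MM clock strings)
#' and `typical_day` (TRUE/FALSE), mirroring the end-of-day log
#' participants fill in.
#'
#' @param schedules list of `wf_schedule`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_daily_log <- function(schedules, path) {
  log <- data.frame(
    date = vapply(schedules, function(s) format(s$day_date), character(1)),
    bedtime = vapply(schedules, function(s) minutes_to_clock(s$bedtime), character(1)),
    waketime = vapply(schedules, function(s) minutes_to_clock(s$waketime), character(1)),
    typical_day = vapply(schedules, function(s) s$typical_day, logical(1)))
  data.table::fwrite(log, path)
  invisible(path)
}

#' Read a daily-log CSV
#'
#' @param path CSV written by [write_daily_log()] (or hand-kept in the
#'   same format).
#' @return data.frame with `date` (Date), `bedtime`, `waketime` (minutes
#'   since midnight) and `typical_day` (logical).
#' @export
read_daily_log <- function(path) {
  log <- data.table::fread(path, colClasses = list(character = c("date", "bedtime", "waketime")))
  req <- c("date", "bedtime", "waketime", "typical_day")
  if (!all(req %in% names(log))) {
    stop("daily log must have columns: ", paste(req, collapse = ", "))
  }
  data.frame(date = as.Date(log$date),
             bedtime = clock_to_minutes(log$bedtime),
             waketime = clock_to_minutes(log$waketime),
             typical_day = as.logical(log$typical_day))
}
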