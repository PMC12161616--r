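#' Free-living activity profile for the simulator
#'
#' Parameters of the simulated day: awake window, minute-level intensity
#' mix, and propulsion behaviour per intensity. Defaults describe a
#' manual wheelchair user awake 16 hours (07:00-23:00) whose expected
#' MVPA is about 29 min/day, in line with the study cohort's baseline.
#'
#' @param proportions named numeric, expected minute fractions for
#'   `sedentary`, `light`, `mvpa`; must be non-negative and sum to 1.
#' @param waketime,bedtime awake window, minutes since midnight.
#' @param bout_minutes integer vector of candidate bout durations
#'   (sampled uniformly; shared across intensities so the minute-level
#'   intensity mix equals `proportions` in expectation).
#' @param propulsion_prob named numeric, probability that a light / mvpa
#'   bout involves wheelchair propulsion (sedentary bouts never do).
#' @param pushes_per_min,rotations_per_min named lists of integer ranges
#'   `c(lo, hi)` for per-minute push and wheel-rotation rates during
#'   propulsion bouts.
#' @param typical_day_prob probability a simulated day is flagged as
#'   routine ("typical") in the daily log.
#' @return an object of class `wf_profile`.
#' @export
activity_profile <- function(proportions = c(sedentary = 0.85, light = 0.12, mvpa = 0.03),
                             waketime = 420L, bedtime = 1380L,
                             bout_minutes = 5:15,
                             propulsion_prob = c(light = 0.3, mvpa = 0.8),
                             pushes_per_min = list(light = c(10L, 20L), mvpa = c(35L, 55L)),
                             rotations_per_min = list(light = c(5L, 15L), mvpa = c(20L, 40L)),
                             typical_day_prob = 0.9) {
  if (length(proportions) != 3L ||
      !setequal(names(proportions), c("sedentary", "light", "mvpa"))) {
    stop("proportions must be named sedentary, light, mvpa")
  }
  if (any(proportions < 0)) stop("intensity proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-8) stop("intensity proportions must sum to 1")
  if (!(0 <= waketime && waketime < bedtime && bedtime <= .MINUTES_PER_DAY)) {
    stop("need 0 <= waketime < bedtime <= 1440")
  }
  if (any(bout_minutes < 1)) stop("bout durations must be >= 1 minute")
  if (any(propulsion_prob < 0 | propulsion_prob > 1)) {
    stop("propulsion probabilities must be in [0, 1]")
  }
  structure(
    list(proportions = proportions[c("sedentary", "light", "mvpa")],
         waketime = as.integer(waketime), bedtime = as.integer(bedtime),
         bout_minutes = as.integer(bout_minutes),
         propulsion_prob = propulsion_prob,
         pushes_per_min = pushes_per_min,
         rotations_per_min = rotations_per_min,
         typical_day_prob = typical_day_prob),
    class = "wf_profile")
}

#' Generate labeled daily activity schedules
#'
#' Draws `n_days` schedules of non-overlapping activity bouts tiling the
#' awake window. Bout durations are sampled from `profile$bout_minutes`
#' (the last bout is truncated at bedtime) and bout intensities are drawn
#' independently with the profile's proportions, so the expected minute
#' intensity mix equals `proportions`. Propulsion bouts carry per-minute
#' push and wheel-rotation rates; these are the simulator's ground truth
#' for downstream recovery tests.
#'
#' @param profile a [activity_profile()].
#' @param n_days number of days to generate.
#' @param seed integer seed; the output is a deterministic function of it.
#' @param participant_id id recorded in each schedule.
#' @param start_date calendar date of day 1; subsequent days increment it.
#' @return list of `wf_schedule` objects, each with fields
#'   `participant_id`, `day_date`, `waketime`, `bedtime`, `bouts`
#'   (data.frame: start, duration, intensity, propulsion, pushes_per_min,
#'   rotations_per_min) and `typical_day`.
#' @export
generate_schedule <- function(profile = activity_profile(), n_days = 1L,
                              seed = 1L, participant_id = "P01",
                              start_date = as.Date("2021-03-01")) {
  stopifnot(inherits(profile, "wf_profile"), n_days >= 1)
  set.seed(seed)
  lapply(seq_len(n_days), function(d) {
    awake <- profile$bedtime - profile$waketime
    # oversample bout durations, then cut to tile the awake window
    durs <- sample(profile$bout_minutes,
                   ceiling(awake / min(profile$bout_minutes)) + 1L,
                   replace = TRUE)
    ends <- cumsum(durs)
    k <- which(ends >= awake)[1L]
    durs <- durs[seq_len(k)]
    durs[k] <- durs[k] - (ends[k] - awake)
    intensity <- sample(c("sedentary", "light", "mvpa"), k, replace = TRUE,
                        prob = profile$proportions)
    prop_p <- ifelse(intensity == "sedentary", 0,
                     profile$propulsion_prob[intensity])
    propulsion <- runif(k) < prop_p
    draw_rate <- function(ranges) {
      vapply(seq_len(k), function(i) {
        if (!propulsion[i]) return(0L)
        r <- ranges[[intensity[i]]]
        sample(seq(r[1], r[2]), 1L)
      }, integer(1))
    }
    bouts <- data.frame(
      start = profile$waketime + c(0L, cumsum(durs)[-k]),
      duration = durs,
      intensity = intensity,
      propulsion = propulsion,
      pushes_per_min = draw_rate(profile$pushes_per_min),
      rotations_per_min = draw_rate(profile$rotations_per_min),
      stringsAsFactors = FALSE)
    sched <- structure(
      list(participant_id = participant_id,
           day_date = start_date + (d - 1L),
           waketime = profile$waketime, bedtime = profile$bedtime,
           bouts = bouts,
           typical_day = runif(1) < profile$typical_day_prob),
      class = "wf_schedule")
    validate_schedule(sched)
    sched
  })
}

#' Validate a schedule's invariants
#'
#' Checks that bouts are non-overlapping, tile `[waketime, bedtime)`
#' exactly, have durations of at least one minute, and that push and
#' rotation rates are zero whenever the propulsion flag is off.
#'
#' @param schedule a `wf_schedule`.
#' @return the schedule, invisibly; errors on violation.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "wf_schedule"))
  b <- schedule$bouts
  if (any(b$duration < 1)) stop("bout durations must be >= 1 minute")
  if (b$start[1] != schedule$waketime) stop("bouts must start at waketime")
  ends <- b$start + b$duration
  if (nrow(b) > 1 && any(b$start[-1] != ends[-nrow(b)])) {
    stop("bouts must be contiguous and non-overlapping")
  }
  if (ends[nrow(b)] != schedule$bedtime) stop("bouts must end at bedtime")
  if (any(!b$propulsion & (b$pushes_per_min > 0 | b$rotations_per_min > 0))) {
    stop("push/rotation rates must be 0 when propulsion is FALSE")
  }
  invisible(schedule)
}

#' Ground-truth minute intensity labels of a schedule
#'
#' @param schedule a `wf_schedule`.
#' @return character vector of length 1440: bout intensity for awake
#'   minutes, `NA` outside the awake window.
#' @export
schedule_labels <- function(schedule) {
  stopifnot(inherits(schedule, "wf_schedule"))
  lab <- rep(NA_character_, .MINUTES_PER_DAY)
  b <- schedule$bouts
  for (i in seq_len(nrow(b))) {
    lab[seq(b$start[i], length.out = b$duration[i]) + 1L] <- b$intensity[i]
  }
  lab
}

# per-minute view of a schedule: minute, intensity, pushes, rotations
schedule_minutes <- function(schedule) {
  b <- schedule$bouts
  idx <- rep(seq_len(nrow(b)), b$duration)
  data.frame(minute = schedule$waketime + seq_len(sum(b$duration)) - 1L,
             intensity = b$intensity[idx],
             pushes = b$pushes_per_min[idx],
             rotations = b$rotations_per_min[idx],
             stringsAsFactors = FALSE)
}
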