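#' Minute mean absolute deviation (MAD) of acceleration magnitude
#'
#' The intensity feature: \eqn{MAD = \frac{1}{N}\sum_i |r_i - \bar r|}
#' where \eqn{r_i = \sqrt{a_x^2 + a_y^2 + a_z^2}} is the vector magnitude
#' of sample \eqn{i} within the minute and \eqn{\bar r} its minute mean.
#' Computed on the magnitude (not per axis) for orientation invariance;
#' this makes it invariant to a constant magnitude offset and linear in a
#' magnitude rescaling.
#'
#' @param mag numeric vector of per-sample vector magnitudes (g) for one
#'   minute; must be non-empty. Null minutes must be handled by the
#'   caller as `NA`, not as zero.
#' @return MAD in g.
#' @export
accel_mad <- function(mag) {
  if (length(mag) == 0L) stop("accel_mad needs at least one sample; null minutes are NA upstream")
  mean(abs(mag - mean(mag)))
}

#' Count propulsion pushes in one minute of acceleration
#'
#' Stand-in push detector (see [push_config()]): the magnitude signal is
#' detrended by a centered moving average of `smooth_s` seconds, local
#' maxima of the detrended signal at or above `prominence` g are push
#' candidates, and candidates closer than `refractory` seconds to the
#' last accepted push are merged into it. Deterministic for a fixed
#' configuration; operates on the vector magnitude, so it is invariant
#' to axis permutation.
#'
#' @param mag per-sample vector magnitudes (g) for one minute.
#' @param cfg a [push_config()].
#' @param rate sampling rate, samples/s.
#' @return integer push count.
#' @export
count_pushes <- function(mag, cfg = push_config(), rate = 30) {
  stopifnot(inherits(cfg, "wf_push_cfg"))
  n <- length(mag)
  if (n == 0L) stop("count_pushes needs a non-null minute")
  if (n < 3L) return(0L)
  det <- mag - running_mean(mag, max(3L, as.integer(round(cfg$smooth_s * rate))))
  left <- c(-Inf, det[-n])
  right <- c(det[-1L], -Inf)
  cand <- which(det >= cfg$prominence & det >= left & det >= right)
  if (length(cand) == 0L) return(0L)
  gap <- cfg$refractory * rate
  count <- 1L
  last <- cand[1L]
  for (i in cand[-1L]) {
    if (i - last >= gap) {
      count <- count + 1L
      last <- i
    }
  }
  count
}

# centered moving average with shrinking windows at the edges
running_mean <- function(x, w) {
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Convert wheel rotations to distance
#'
#' Distance is rotations times the wheel circumference
#' \eqn{\pi \cdot diameter}.
#'
#' @param rotations rotation count(s), non-negative.
#' @param wheel_diameter wheel diameter in meters; must be positive.
#' @return distance in meters (vectorized over `rotations`).
#' @export
rotations_to_distance <- function(rotations, wheel_diameter) {
  if (!is.numeric(wheel_diameter) || length(wheel_diameter) != 1L ||
      wheel_diameter <= 0) {
    stop("configuration error: wheel_diameter must be a positive number of meters")
  }
  if (any(rotations < 0)) stop("rotations must be non-negative")
  rotations * pi * wheel_diameter
}

#' Per-minute energy expenditure estimate
#'
#' Applies the pluggable linear model of [energy_model()] to a minute's
#' MAD, heart rate and the wearer's body mass. Null minutes (`mad = NA`)
#' contribute 0 kcal. This default model is a documented placeholder,
#' not a validated population-specific equation.
#'
#' @param mad minute MAD in g, or `NA` for a null minute (vectorized).
#' @param hr heart rate in bpm, or `NA` if unavailable.
#' @param demographics list with at least `mass_kg`.
#' @param model an [energy_model()].
#' @return kcal for the minute (vector).
#' @export
estimate_energy <- function(mad, hr = NA_real_, demographics,
                            model = energy_model()) {
  stopifnot(inherits(model, "wf_energy_model"))
  required <- "mass_kg"
  missing_fields <- setdiff(required, names(demographics))
  missing_fields <- union(missing_fields,
                          required[vapply(demographics[required],
                                          function(x) is.null(x) || is.na(x),
                                          logical(1), USE.NAMES = FALSE)])
  if (length(missing_fields)) {
    stop("missing demographics field(s): ", paste(missing_fields, collapse = ", "))
  }
  mass <- demographics$mass_kg
  hr <- rep_len(hr, length(mad))
  base <- mass * model$rest_kcal_per_kg_hr / 60 * (1 + model$mad_coef * mad)
  hr_term <- model$hr_coef * pmax(ifelse(is.na(hr), 0, hr - model$hr_rest), 0)
  out <- base + hr_term
  out[is.na(mad)] <- 0
  out
}

#' Compute the full per-minute feature table
#'
#' For each of the 1440 day minutes: MAD (NA for null minutes), push
#' count (the detector runs only in minutes with nonzero wheel rotations,
#' since the wheel sensor gates propulsion), rotations, distance, last
#' heart-rate sample of the minute (forward-filled across null minutes
#' for at most `hr_fill_max` minutes), energy, and the intensity label.
#'
#' @param bins a `wf_bins` from [bin_minutes()].
#' @param device a [device_profile()] (wheel diameter, accel rate).
#' @param thresholds a [threshold_config()].
#' @param push_cfg a [push_config()].
#' @param demographics list with `mass_kg`, or `NULL` to skip the energy
#'   column (all `NA`).
#' @param model an [energy_model()].
#' @param hr_fill_max forward-fill cap for `hr_last`, minutes.
#' @return data.frame of class `wf_minutes` with one row per minute:
#'   `minute` (0-1439), `n_samples`, `mad`, `label`, `pushes`,
#'   `rotations`, `distance_m`, `hr_last`, `energy_kcal`.
#' @export
minute_records <- function(bins, device = device_profile(),
                           thresholds = threshold_config(),
                           push_cfg = push_config(),
                           demographics = NULL, model = energy_model(),
                           hr_fill_max = 5L) {
  stopifnot(inherits(bins, "wf_bins"))
  minute <- mag <- bpm <- NULL # data.table NSE
  mad_v <- rep(NA_real_, .MINUTES_PER_DAY)
  if (nrow(bins$accel)) {
    bymin <- bins$accel[, list(mad = accel_mad(mag)), by = minute]
    mad_v[bymin$minute + 1L] <- bymin$mad
  }
  pushes <- rep(0L, .MINUTES_PER_DAY)
  active <- which(bins$rotations > 0L & !bins$null_minute)
  for (m in active) {
    pushes[m] <- count_pushes(bins$accel[minute == m - 1L]$mag,
                              cfg = push_cfg, rate = device$accel_rate)
  }
  hr_last <- rep(NA_real_, .MINUTES_PER_DAY)
  if (nrow(bins$hr)) {
    last <- bins$hr[, list(bpm = bpm[.N]), by = minute]
    hr_last[last$minute + 1L] <- last$bpm
    hr_last <- forward_fill(hr_last, hr_fill_max)
  }
  energy <- if (is.null(demographics)) rep(NA_real_, .MINUTES_PER_DAY) else
    estimate_energy(mad_v, hr_last, demographics, model)
  out <- data.frame(
    minute = 0:(.MINUTES_PER_DAY - 1L),
    n_samples = bins$n_accel,
    mad = mad_v,
    label = classify_intensity(mad_v, thresholds),
    pushes = pushes,
    rotations = bins$rotations,
    distance_m = rotations_to_distance(bins$rotations, device$wheel_diameter),
    hr_last = hr_last,
    energy_kcal = energy)
  class(out) <- c("wf_minutes", "data.frame")
  out
}

# forward fill NAs, carrying a value at most `cap` positions
forward_fill <- function(x, cap) {
  carry <- NA_real_
  age <- Inf
  for (i in seq_along(x)) {
    if (!is.na(x[i])) {
      carry <- x[i]
      age <- 0
    } else if (age < cap) {
      x[i] <- carry
      age <- age + 1
    }
  }
  x
}
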