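#' Device profile
#'
#' Sampling rates and physical parameters of the wearable setup: a wrist-worn
#' smartwatch sampling its accelerometer at 30 Hz and heart-rate sensor at
#' 1 Hz, and a wheel-mounted sensor registering wheel rotations at 5 Hz.
#' The smartwatch battery lasts roughly 10-11 hours of continuous streaming,
#' which truncates the watch streams mid-day; the wheel sensor battery lasts
#' weeks and is never truncated within a day.
#'
#' @param accel_rate accelerometer sampling rate, samples/s.
#' @param hr_rate heart-rate sampling rate, samples/s.
#' @param gyro_rate wheel-sensor sampling rate, samples/s.
#' @param wheel_diameter rear-wheel diameter in meters (a standard 24-inch
#'   wheelchair wheel is about 0.61 m).
#' @param battery_life smartwatch battery life in hours.
#' @param noise_sd per-axis accelerometer noise SD in g (simulation only).
#' @param push_amplitude peak acceleration of a rendered propulsion push, g
#'   (simulation only).
#' @return an object of class `wf_device`.
#' @export
device_profile <- function(accel_rate = 30, hr_rate = 1, gyro_rate = 5,
                           wheel_diameter = 0.61, battery_life = 10.5,
                           noise_sd = 0.005, push_amplitude = 0.4) {
  if (any(c(accel_rate, hr_rate, gyro_rate) <= 0)) {
    stop("sampling rates must be positive")
  }
  if (wheel_diameter <= 0) stop("wheel_diameter must be positive")
  if (battery_life <= 0) stop("battery_life must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(
    list(accel_rate = accel_rate, hr_rate = hr_rate, gyro_rate = gyro_rate,
         wheel_diameter = wheel_diameter, battery_life = battery_life,
         noise_sd = noise_sd, push_amplitude = push_amplitude),
    class = "wf_device")
}

#' Intensity classification thresholds
#'
#' MAD cut-points (in g) separating sedentary, light and
#' moderate-to-vigorous (MVPA) minutes. The deployed app used published
#' wheelchair-specific cut-points whose numeric values are not reproduced
#' here; the defaults below are documented placeholders in the plausible
#' range for wrist MAD and are fully configurable. All group-level study
#' statistics in this package are computed from daily values and are
#' independent of these defaults.
#'
#' Boundary convention: `mad < sedentary_ceiling` is sedentary;
#' `sedentary_ceiling <= mad < mvpa_floor` is light; `mad >= mvpa_floor`
#' is MVPA.
#'
#' @param sedentary_ceiling MAD below which a minute is sedentary, g.
#' @param mvpa_floor MAD at or above which a minute is MVPA, g.
#' @return an object of class `wf_thresholds`.
#' @export
threshold_config <- function(sedentary_ceiling = 0.02, mvpa_floor = 0.08) {
  if (!(0 < sedentary_ceiling && sedentary_ceiling < mvpa_floor)) {
    stop("need 0 < sedentary_ceiling < mvpa_floor")
  }
  structure(list(sedentary_ceiling = sedentary_ceiling,
                 mvpa_floor = mvpa_floor),
            class = "wf_thresholds")
}

#' Push-detector configuration
#'
#' The deployed app counted propulsion pushes with a published
#' accelerometer algorithm whose internals are not reproduced here; this
#' package ships an explicit, configurable stand-in: the acceleration
#' vector magnitude is detrended by a centered moving average, and local
#' maxima exceeding `prominence` are counted as pushes subject to a
#' refractory period.
#'
#' @param prominence minimum detrended peak height, g.
#' @param refractory minimum time between counted pushes, seconds.
#' @param smooth_s moving-average detrending window, seconds.
#' @return an object of class `wf_push_cfg`.
#' @export
push_config <- function(prominence = 0.2, refractory = 0.5, smooth_s = 1) {
  if (prominence <= 0 || refractory <= 0 || smooth_s <= 0) {
    stop("push-detector parameters must be positive")
  }
  structure(list(prominence = prominence, refractory = refractory,
                 smooth_s = smooth_s),
            class = "wf_push_cfg")
}

#' Energy-expenditure model coefficients
#'
#' Placeholder linear model for per-minute energy expenditure from minute
#' MAD, heart rate and body mass:
#' \deqn{kcal/min = mass \cdot rest/60 \cdot (1 + c_{mad} MAD) + c_{hr} \max(HR - hr_0, 0)}
#' The deployed app used a population-specific prediction model whose
#' coefficients are not published in the source study; this default is
#' NOT validated and exists so the pipeline has a complete, auditable
#' energy column. Swap coefficients via this constructor.
#'
#' @param rest_kcal_per_kg_hr resting rate, kcal per kg body mass per hour.
#' @param mad_coef multiplicative MAD slope (per g of MAD).
#' @param hr_coef kcal/min per bpm above `hr_rest` (0 by default).
#' @param hr_rest resting heart rate anchor, bpm.
#' @return an object of class `wf_energy_model`.
#' @export
energy_model <- function(rest_kcal_per_kg_hr = 1, mad_coef = 20,
                         hr_coef = 0, hr_rest = 65) {
  if (rest_kcal_per_kg_hr <= 0) stop("resting rate must be positive")
  if (mad_coef < 0 || hr_coef < 0) stop("slopes must be non-negative")
  structure(list(rest_kcal_per_kg_hr = rest_kcal_per_kg_hr,
                 mad_coef = mad_coef, hr_coef = hr_coef, hr_rest = hr_rest),
            class = "wf_energy_model")
}

#' Daily goal set
#'
#' Daily targets for the four goal-enabled measures. A target of `NA`
#' means the goal is unset; set targets must be positive.
#'
#' @param energy_kcal,distance_m,mvpa_min,breaks daily targets.
#' @return an object of class `wf_goals`.
#' @export
goal_set <- function(energy_kcal = NA, distance_m = NA, mvpa_min = NA,
                     breaks = NA) {
  g <- list(energy_kcal = energy_kcal, distance_m = distance_m,
            mvpa_min = mvpa_min, breaks = breaks)
  set <- !vapply(g, is.na, logical(1))
  if (any(unlist(g[set]) <= 0)) stop("set goal targets must be positive")
  structure(g, class = "wf_goals")
}
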