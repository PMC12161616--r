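# shared fixtures, all built in code

# hand-built schedule with explicit bouts; bouts tile [waketime, bedtime)
make_schedule <- function(bouts, waketime, bedtime,
                          day_date = as.Date("2021-03-01"),
                          typical_day = TRUE, participant_id = "T01") {
  sched <- structure(
    list(participant_id = participant_id, day_date = day_date,
         waketime = as.integer(waketime), bedtime = as.integer(bedtime),
         bouts = bouts, typical_day = typical_day),
    class = "wf_schedule")
  validate_schedule(sched)
}

bout <- function(start, duration, intensity, pushes = 0L, rotations = 0L) {
  data.frame(start = as.integer(start), duration = as.integer(duration),
             intensity = intensity,
             propulsion = pushes > 0 | rotations > 0,
             pushes_per_min = as.integer(pushes),
             rotations_per_min = as.integer(rotations),
             stringsAsFactors = FALSE)
}

# minimal wf_streams built directly (bypasses the simulator)
make_streams <- function(accel = NULL, hr = NULL, wheel = NULL,
                         day_date = as.Date("2021-03-01")) {
  empty3 <- data.table::data.table(time = numeric(), ax = numeric(),
                                   ay = numeric(), az = numeric())
  structure(
    list(participant_id = "T01", day_date = day_date,
         accel = if (is.null(accel)) empty3 else data.table::as.data.table(accel),
         hr = if (is.null(hr))
           data.table::data.table(time = numeric(), bpm = numeric())
         else data.table::as.data.table(hr),
         wheel = if (is.null(wheel))
           data.table::data.table(time = numeric(), rotations = numeric())
         else data.table::as.data.table(wheel),
         gaps = data.frame(start = integer(), end = integer())),
    class = "wf_streams")
}

# day-long label vector with selected minutes set
make_labels <- function(set = list()) {
  lab <- rep(NA_character_, 1440L)
  for (nm in names(set)) lab[set[[nm]] + 1L] <- nm
  lab
}

# minimal wf_day for valid-day checks
make_day <- function(coverage = 0.6, pushes = 0L, distance_m = 100,
                     nonsedentary = 0L, typical = TRUE) {
  structure(
    list(day_date = as.Date("2021-03-01"),
         energy_total = 0, distance_total_m = distance_m,
         distance_total_mi = distance_m / 1609.344,
         mvpa_minutes = 0L, sedentary_breaks = 0L,
         push_total = as.integer(pushes), hr_last = NA_real_,
         alerts = integer(), coverage = coverage,
         waketime = 420L, bedtime = 1380L,
         n_nonnull = 600L, n_nonsedentary = as.integer(nonsedentary),
         goal_progress = NULL),
    class = "wf_day")
}

# brute-force sedentary-break oracle: scan each 30-minute window for a
# run of >= 2 consecutive active minutes
oracle_breaks <- function(labels, waketime, bedtime, rule = "nonsedentary") {
  active <- if (rule == "nonsedentary") labels %in% c("light", "mvpa")
            else labels %in% "mvpa"
  count <- 0L
  w <- waketime
  while (w + 30L <= bedtime) {
    hit <- FALSE
    for (m in (w + 1L):(w + 29L)) {
      if (isTRUE(active[m]) && isTRUE(active[m + 1L])) hit <- TRUE
    }
    if (hit) count <- count + 1L
    w <- w + 30L
  }
  count
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns.
# Reported as the mid-p (half the point mass at the observed statistic):
# the correct discrete counterpart of an UNcorrected normal tail, which is
# what the implementation uses; the continuity-corrected approximation is
# the one that targets the conventional exact p instead.
oracle_wilcoxon_exact_p <- function(x, y) {
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  mu <- n * (n + 1) / 4
  ext_all <- abs(w_all - mu)
  ext_obs <- abs(w_obs - mu)
  mean(ext_all > ext_obs + 1e-9) + 0.5 * mean(abs(ext_all - ext_obs) <= 1e-9)
}

# random day label sequence over an awake window
random_labels <- function(waketime, bedtime, p_active = 0.3) {
  lab <- rep(NA_character_, 1440L)
  n <- bedtime - waketime
  lab[waketime + seq_len(n)] <- sample(c("sedentary", "light", "mvpa"), n,
                                       replace = TRUE,
                                       prob = c(1 - p_active, p_active / 2,
                                                p_active / 2))
  lab
}
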