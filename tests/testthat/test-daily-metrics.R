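test_that("intensity classification follows the boundary convention", {
  cfg <- threshold_config(sedentary_ceiling = 0.02, mvpa_floor = 0.08)
  expect_equal(classify_intensity(0, cfg), "sedentary")
  expect_equal(classify_intensity(0.02, cfg), "light")   # ceiling is exclusive
  expect_equal(classify_intensity(0.08, cfg), "mvpa")    # floor is inclusive
  expect_equal(classify_intensity(c(0.01, 0.05, NA, 0.2), cfg),
               c("sedentary", "light", NA, "mvpa"))
  expect_error(threshold_config(0.1, 0.05), "sedentary_ceiling < mvpa_floor")
})

test_that("mvpa_minutes counts labeled minutes with null minutes excluded", {
  expect_equal(mvpa_minutes(make_labels(list(sedentary = 0:959))), 0L)
  expect_equal(mvpa_minutes(rep("mvpa", 1440)), 1440L)
  lab <- make_labels(list(mvpa = 0:29, light = 30:59))
  expect_equal(mvpa_minutes(lab), 30L)
  expect_error(mvpa_minutes(rep("mvpa", 100)), "1440")
})

test_that("noise-free simulated day reproduces ground-truth labels and MVPA", {
  prof <- activity_profile(proportions = c(sedentary = 0.5, light = 0.3,
                                           mvpa = 0.2),
                           waketime = 480L, bedtime = 600L)
  sch <- generate_schedule(prof, n_days = 1, seed = 21)[[1]]
  st <- render_streams(sch, device_profile(noise_sd = 0), seed = 21)
  rec <- minute_records(bin_minutes(st), device_profile(noise_sd = 0))
  truth <- schedule_labels(sch)
  awake <- which(!is.na(truth))
  expect_equal(rec$label[awake], truth[awake])
  expect_equal(mvpa_minutes(rec$label), sum(truth == "mvpa", na.rm = TRUE))
  # label partition: sedentary + light + mvpa + null = 1440
  expect_equal(sum(table(rec$label, useNA = "always")), 1440L)
})

test_that("sedentary breaks: bounds and window arithmetic", {
  # all-sedentary day
  expect_equal(sedentary_breaks(make_labels(list(sedentary = 420:1379)),
                                420, 1380), 0L)
  # every window active: the 16-hour maximum of 32
  expect_equal(sedentary_breaks(make_labels(list(light = 420:1379)),
                                420, 1380), 32L)
  # trailing partial window is ignored: 16 h 15 min is still 32 windows
  expect_equal(sedentary_breaks(make_labels(list(light = 420:1394)),
                                420, 1395), 32L)
  expect_error(sedentary_breaks(rep(NA_character_, 1440), 600, 600), "after")
})

test_that("a lone active minute is not a break; two consecutive are", {
  base <- list(sedentary = 420:1379)
  one <- make_labels(base); one[431] <- "light"
  expect_equal(sedentary_breaks(one, 420, 1380), 0L)
  two <- make_labels(base); two[431:432] <- "light"
  expect_equal(sedentary_breaks(two, 420, 1380), 1L)
  # under mvpa_only, light runs do not count
  expect_equal(sedentary_breaks(two, 420, 1380, break_rule = "mvpa_only"), 0L)
  two[431:432] <- "mvpa"
  expect_equal(sedentary_breaks(two, 420, 1380, break_rule = "mvpa_only"), 1L)
})

test_that("sedentary breaks match the window-scanning oracle on random days", {
  set.seed(33)
  for (i in 1:200) {
    wake <- sample(300:480, 1)
    bed <- wake + sample(c(90, 240, 480, 960), 1)
    lab <- random_labels(wake, bed, p_active = runif(1, 0.02, 0.5))
    expect_equal(sedentary_breaks(lab, wake, bed),
                 oracle_breaks(lab, wake, bed))
  }
})

test_that("flipping a sedentary minute to active never decreases the count", {
  set.seed(34)
  for (i in 1:50) {
    lab <- random_labels(420, 900, p_active = 0.1)
    before <- sedentary_breaks(lab, 420, 900)
    sed <- which(lab == "sedentary")
    lab[sample(sed, 1)] <- "light"
    expect_gte(sedentary_breaks(lab, 420, 900), before)
  }
})

test_that("alert_check triggers iff no 2-minute active run in the first 25 minutes", {
  expect_true(alert_check(rep("sedentary", 25)))
  lab <- rep("sedentary", 25)
  lab[3:4] <- "light"
  expect_false(alert_check(lab))
  lab2 <- rep("sedentary", 25)
  lab2[c(3, 7, 12)] <- "mvpa"   # isolated minutes only
  expect_true(alert_check(lab2))
  expect_error(alert_check(rep("sedentary", 30)), "25")
  # random windows against a direct run-length oracle
  set.seed(35)
  for (i in 1:200) {
    w <- sample(c("sedentary", "light", "mvpa"), 25, replace = TRUE,
                prob = c(0.85, 0.1, 0.05))
    active <- w %in% c("light", "mvpa")
    oracle <- !any(active[-25] & active[-1])
    expect_equal(alert_check(w), oracle)
  }
})

test_that("a break starting in the first 25 minutes suppresses the alert", {
  set.seed(36)
  for (i in 1:50) {
    lab <- make_labels(list(sedentary = 420:449))
    start <- sample(421:443, 1)        # run fully inside the first 25 min
    lab[start + 0:1] <- "light"
    expect_false(alert_check(lab[421:445]))
    expect_equal(sedentary_breaks(lab, 420, 450), 1L)
  }
})

test_that("goal progress reports raw and capped fractions", {
  day <- make_day()
  day$mvpa_minutes <- 15L
  day$energy_total <- 400
  day$sedentary_breaks <- 40L
  gp <- goal_progress(day, goal_set(energy_kcal = 400, mvpa_min = 30, breaks = 32))
  expect_equal(gp$fraction[gp$goal == "energy_kcal"], 1.0)
  expect_equal(gp$fraction[gp$goal == "mvpa_min"], 0.5)
  expect_equal(gp$fraction[gp$goal == "breaks"], 1.25)   # raw retained
  expect_equal(gp$display[gp$goal == "breaks"], 1)       # display capped
  expect_error(goal_set(mvpa_min = 0), "positive")
})

test_that("day_record assembles alerts per window and respects the break bound", {
  lab_set <- list(sedentary = 420:1379)
  sch_labels <- make_labels(lab_set)
  rec <- data.frame(minute = 0:1439, n_samples = 0L,
                    mad = ifelse(is.na(sch_labels), NA_real_, 0.001),
                    label = sch_labels, pushes = 0L, rotations = 0L,
                    distance_m = 0, hr_last = NA_real_, energy_kcal = 0)
  class(rec) <- c("wf_minutes", "data.frame")
  day <- day_record(rec, coverage = 960 / 1440, waketime = 420, bedtime = 1380)
  expect_equal(day$sedentary_breaks, 0L)
  expect_equal(length(day$alerts), 32L)   # every window alerts
  expect_lte(day$sedentary_breaks, 2 * 16)
  # first alert fires at the 25-minute mark of the first window
  expect_equal(day$alerts[1], 445L)
})
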