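test_that("valid-day rule: coverage threshold, abnormal data, typical flag", {
  log <- list(typical_day = TRUE)
  expect_false(valid_day(make_day(coverage = 0.29), log))
  expect_true(valid_day(make_day(coverage = 0.30), log))
  # zero wheelchair pushing distance with nonzero pushes is abnormal
  expect_false(valid_day(make_day(coverage = 0.6, pushes = 500, distance_m = 0), log))
  # all-zero wheel stream on a day with non-sedentary wrist activity
  expect_false(valid_day(make_day(coverage = 0.6, pushes = 0, distance_m = 0,
                                  nonsedentary = 120), log))
  expect_true(valid_day(make_day(coverage = 0.6), log))
  expect_false(valid_day(make_day(coverage = 0.6), list(typical_day = FALSE)))
  expect_warning(ok <- valid_day(make_day(), NULL), "excluded")
  expect_false(ok)
})

test_that("phase means average daily variables over valid days", {
  d1 <- make_day(); d1$mvpa_minutes <- 20L; d1$sedentary_breaks <- 10L
  d2 <- make_day(); d2$mvpa_minutes <- 40L; d2$sedentary_breaks <- 14L
  one <- phase_means(list(d1), "P1", "baseline")
  expect_equal(one$exercise_min, 20)
  expect_equal(one$n_valid_days, 1L)
  two <- phase_means(list(d1, d2), "P1", "intervention")
  expect_equal(two$exercise_min, 30)
  expect_equal(two$breaks, 12)
  expect_error(phase_means(list(), "P1", "baseline"), "zero valid days")
})

test_that("phase means recover scheduled activity from the pipeline", {
  prof <- activity_profile(proportions = c(sedentary = 0.6, light = 0.25,
                                           mvpa = 0.15),
                           waketime = 480L, bedtime = 660L)
  schedules <- generate_schedule(prof, n_days = 2, seed = 51)
  days <- lapply(seq_along(schedules), function(i) {
    sch <- schedules[[i]]
    st <- render_streams(sch, device_profile(noise_sd = 0), seed = 60 + i)
    rec <- minute_records(bin_minutes(st), device_profile(noise_sd = 0))
    day_record(rec, 180 / 1440, sch$waketime, sch$bedtime)
  })
  ph <- phase_means(days, "P1", "baseline")
  truth <- mean(vapply(schedules, function(s)
    sum(schedule_labels(s) == "mvpa", na.rm = TRUE), numeric(1)))
  expect_lte(abs(ph$exercise_min - truth), 2)
})

test_that("percent change reproduces the published convention", {
  expect_equal(percent_change(26.8, 99.0), 269)
  expect_equal(percent_change(1.1, 9.9), 800)
  expect_equal(percent_change(5, 5), 0)
  expect_true(is.na(percent_change(0, 10)))
  # half-away rounding, both signs
  expect_equal(percent_change(24.0, 13.8), -43)
  expect_equal(percent_change(200, 203), 2)    # 1.5% -> 2
  # scale invariance: percent_change(b, b(1+k)) = round(100k)
  set.seed(41)
  for (i in 1:50) {
    b <- runif(1, 0.5, 100)
    k <- runif(1, -0.9, 3)
    expect_equal(percent_change(b, b * (1 + k)),
                 wheelfit:::round_half_away(round(100 * k, 9)))
  }
})

test_that("considerable-change classification uses a strict +/-10 threshold", {
  expect_equal(classify_change(16), "considerable_increase")
  expect_equal(classify_change(8), "no_considerable_change")
  expect_equal(classify_change(-64), "considerable_decrease")
  expect_equal(classify_change(c(10, -10, 11, -11)),
               c("no_considerable_change", "no_considerable_change",
                 "considerable_increase", "considerable_decrease"))
  expect_true(is.na(classify_change(NA)))
})

test_that("signed-rank mechanics: rank conservation, antisymmetry, zeros, guards", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(6:20, 1)
    x <- rnorm(n); y <- x + rnorm(n)
    res <- wilcoxon_signed_rank(x, y)
    m <- res$n
    expect_equal(res$W_plus + res$W_minus, m * (m + 1) / 2)
    flip <- wilcoxon_signed_rank(y, x)
    expect_equal(flip$Z, -res$Z, tolerance = 1e-12)
    expect_equal(flip$p_two_sided, res$p_two_sided, tolerance = 1e-12)
  }
  # zero differences are dropped
  x <- c(1, 2, 3, 4, 5, 6, 7)
  y <- c(1, 3, 5, 2, 9, 10, 4)   # first pair ties
  expect_equal(wilcoxon_signed_rank(x, y)$n, 6L)
  expect_equal(wilcoxon_signed_rank(x, y)$n_zero, 1L)
  deg <- wilcoxon_signed_rank(1:6, 1:6)
  expect_true(is.na(deg$Z))
  expect_error(wilcoxon_signed_rank(1:4, c(2, 3, 4, 5)), "at least 5")
})

test_that("normal-approximation p is close to exact enumeration for small n", {
  set.seed(43)
  for (i in 1:12) {
    n <- sample(6:10, 1)
    x <- rnorm(n)
    y <- x + rnorm(n, 0.3)
    res <- wilcoxon_signed_rank(x, y)
    expect_lte(abs(res$p_two_sided - oracle_wilcoxon_exact_p(x, y)), 0.05)
  }
})

test_that("paired t matches the closed form and guards degeneracy", {
  set.seed(44)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- x + rnorm(n, 0.5)
    res <- paired_t(x, y)
    d <- y - x
    expect_equal(res$t, mean(d) / (sd(d) / sqrt(n)), tolerance = 1e-12)
    expect_equal(res$df, n - 1L)
    expect_equal(res$d_z, mean(d) / sd(d), tolerance = 1e-12)
    expect_equal(res$p_one_sided, res$p_two_sided / 2, tolerance = 1e-12)
  }
  expect_error(paired_t(1:5, 1:5 + 2), "zero-variance")
})

test_that("power iteration: definition property, limits, Monte-Carlo oracle", {
  # output n always satisfies power(n) >= target > power(n - 1)
  for (d in c(0.3, 0.5, 0.93)) {
    n <- power_sample_size(d, 0.8, 0.05)
    expect_gte(wheelfit:::paired_t_power(n, d, 0.05, 2), 0.8)
    expect_lt(wheelfit:::paired_t_power(n - 1, d, 0.05, 2), 0.8)
  }
  # enormous effects need only the minimum df
  expect_equal(power_sample_size(50, 0.8, 0.05), 2L)
  expect_error(power_sample_size(-1), "positive")
  # Monte-Carlo oracle: smallest n whose simulated rejection rate reaches 0.8
  set.seed(45)
  mc_power <- function(n, d, reps = 3000) {
    mean(vapply(seq_len(reps), function(r) {
      diff <- rnorm(n, d, 1)
      abs(mean(diff) / (sd(diff) / sqrt(n))) > qt(0.975, n - 1)
    }, logical(1)))
  }
  n_hat <- power_sample_size(0.5, 0.8, 0.05)
  candidates <- (n_hat - 3):(n_hat + 3)
  pw <- vapply(candidates, mc_power, numeric(1), d = 0.5)
  n_mc <- candidates[which(pw >= 0.8)[1]]
  expect_lte(abs(n_mc - n_hat), 1)
})

test_that("summarize_study builds a coherent report from the fixture", {
  study <- summarize_study()
  expect_s3_class(study, "wf_study")
  expect_equal(nrow(study$table), 16L)
  # category counts partition the cohort
  expect_equal(sum(study$change_counts), 16L)
  expect_setequal(names(study$tests), c("exercise", "breaks", "distance", "eses"))
  expect_equal(study$tests$eses$method, "paired_t")
  expect_output(print(study), "Wilcoxon")
  # error paths
  expect_error(summarize_study(data.frame(participant_id = "a")), "column pairs")
  expect_error(summarize_study(table2_fixture()[1:3, ]), "at least 5")
})
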