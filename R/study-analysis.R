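#' Packaged per-participant outcome table fixture
#'
#' The 16-participant pre-post outcome table shipped with the package:
#' per-phase daily means of moderate-to-vigorous exercise time (min),
#' sedentary breaks (count) and travel distance (miles), plus the
#' exercise self-efficacy scale (ESES, 10-40) before and after the
#' intervention, and the published rounded percent-change columns for
#' cross-checking. Values are one-decimal phase means as published.
#'
#' @return data.frame with one row per participant.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_fixture.csv", package = "wheelfit",
                      mustWork = TRUE)
  utils::read.csv(path, colClasses = c(participant_id = "character"))
}

#' Valid-day check
#'
#' A day enters the analysis iff (1) accelerometer coverage is at least
#' `min_coverage` (default 30% of the 24-hour day, roughly one full
#' smartwatch battery charge), (2) no abnormal sensor data are observed
#' — nonzero pushes with zero wheel distance, or an all-zero wheel
#' stream on a day with non-sedentary minutes — and (3) the participant
#' confirmed in the daily log that the day was typical. A missing log
#' entry excludes the day with a warning.
#'
#' @param day a `wf_day`.
#' @param log_entry one row of [read_daily_log()] output (or any list
#'   with `typical_day`), or `NULL` if the log entry is missing.
#' @param min_coverage coverage threshold.
#' @return logical.
#' @export
valid_day <- function(day, log_entry, min_coverage = 0.3) {
  stopifnot(inherits(day, "wf_day"))
  if (is.null(log_entry) || nrow(as.data.frame(log_entry)) == 0L) {
    warning("no daily-log entry for ",
            if (!is.null(day$day_date)) format(day$day_date) else "day",
            "; day excluded")
    return(FALSE)
  }
  if (day$coverage < min_coverage) return(FALSE)
  if (day$push_total > 0 && day$distance_total_m == 0) return(FALSE)
  if (day$distance_total_m == 0 && day$n_nonsedentary > 0 &&
      day$push_total == 0) {
    # all-zero wheel stream while the wrist shows activity: sensor dropout
    return(FALSE)
  }
  isTRUE(log_entry$typical_day)
}

#' Aggregate valid days to a phase summary
#'
#' Arithmetic mean per daily variable over a participant's valid days in
#' one phase.
#'
#' @param days list of `wf_day` (valid days only).
#' @param participant_id,phase identifiers; `phase` is `"baseline"` or
#'   `"intervention"`.
#' @return an object of class `wf_phase`: list with per-variable daily
#'   means (`exercise_min`, `breaks`, `distance_mi`) and `n_valid_days`.
#' @export
phase_means <- function(days, participant_id = NA_character_,
                        phase = c("baseline", "intervention")) {
  phase <- match.arg(phase)
  if (length(days) == 0L) {
    stop("participant has zero valid days in the ", phase,
         " phase; exclude from group tests")
  }
  g <- function(f) mean(vapply(days, `[[`, numeric(1), f))
  structure(
    list(participant_id = participant_id, phase = phase,
         exercise_min = g("mvpa_minutes"),
         breaks = g("sedentary_breaks"),
         distance_mi = g("distance_total_mi"),
         n_valid_days = length(days)),
    class = "wf_phase")
}

#' Rounded integer percent change
#'
#' `100 * (intervention - baseline) / baseline`, rounded to the nearest
#' integer half away from zero (the convention that reproduces every
#' published table cell). Undefined (`NA`) when the baseline is zero.
#'
#' @param baseline,intervention numeric vectors.
#' @return integer percent vector, `NA` where baseline is 0.
#' @export
percent_change <- function(baseline, intervention) {
  # pre-round at 1e-9 so one-decimal inputs whose true ratio is an exact
  # half (e.g. -10.2/24.0 = -42.5%) are not pushed off the boundary by
  # binary floating point before the half-away rule applies
  out <- round_half_away(round(100 * (intervention - baseline) / baseline, 9))
  out[baseline == 0] <- NA_real_
  out
}

#' Classify percent change at the considerable-change threshold
#'
#' A rounded percent change strictly beyond +/-10% is a "considerable"
#' change; exactly +/-10 is not (the threshold must be exceeded).
#'
#' @param pct integer percent vector from [percent_change()].
#' @return character vector in `c("considerable_increase",
#'   "considerable_decrease", "no_considerable_change")`, `NA` where
#'   `pct` is `NA`.
#' @export
classify_change <- function(pct) {
  out <- rep(NA_character_, length(pct))
  out[!is.na(pct) & pct > 10] <- "considerable_increase"
  out[!is.na(pct) & pct < -10] <- "considerable_decrease"
  out[!is.na(pct) & abs(pct) <= 10] <- "no_considerable_change"
  out
}

#' Wilcoxon signed-rank test (normal approximation)
#'
#' Paired signed-rank test on `y - x`. Zero differences are dropped
#' (Wilcoxon convention); absolute differences are ranked with average
#' ranks for ties; the statistic is the positive-rank sum \eqn{W^+}.
#' The normal approximation uses the tie-corrected variance and NO
#' continuity correction:
#' \deqn{Z = \frac{W^+ - n(n+1)/4}{\sqrt{n(n+1)(2n+1)/24 - \sum_t (t^3-t)/48}}}
#' Effect size is \eqn{r = Z/\sqrt{n}} with \eqn{n} the pairs entering
#' the test (after zero-dropping). `Z` is signed: positive means `y`
#' tends to exceed `x`.
#'
#' @param x,y paired numeric vectors (x = baseline, y = intervention).
#' @return an object of class `wf_test` with fields `method`, `n`,
#'   `n_zero`, `W_plus`, `W_minus`, `Z`, `p_two_sided`, `p_one_sided`,
#'   `r`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- y - x
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(method = "wilcoxon_signed_rank", n = 0L,
                          n_zero = n_zero, W_plus = NA_real_,
                          W_minus = NA_real_, Z = NA_real_,
                          p_two_sided = NA_real_, p_one_sided = NA_real_,
                          r = NA_real_,
                          note = "all differences zero; test degenerate"),
                     class = "wf_test"))
  }
  if (n < 5L) stop("need at least 5 nonzero differences for the rank test")
  rk <- rank(abs(d))
  W_plus <- sum(rk[d > 0])
  W_minus <- sum(rk[d < 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
  Z <- (W_plus - mu) / sigma
  p2 <- 2 * pnorm(-abs(Z))
  structure(
    list(method = "wilcoxon_signed_rank", n = n, n_zero = n_zero,
         W_plus = W_plus, W_minus = W_minus, Z = Z,
         p_two_sided = min(p2, 1), p_one_sided = min(p2, 1) / 2,
         r = Z / sqrt(n)),
    class = "wf_test")
}

#' Paired t test
#'
#' \eqn{t = \bar d / (s_d/\sqrt n)} on differences `y - x`, with
#' `df = n - 1`. Both the two-sided and the one-sided (in the direction
#' of the observed effect) p-values are reported, together with the SD
#' of the paired differences `sd_diff` and Cohen's
#' \eqn{d_z = \bar d / s_d}.
#'
#' @param x,y paired numeric vectors.
#' @return an object of class `wf_test` with fields `method`, `n`, `t`,
#'   `df`, `p_two_sided`, `p_one_sided`, `mean_diff`, `sd_diff`, `d_z`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- y - x
  s <- sd(d)
  if (s == 0) stop("zero-variance differences: paired t undefined")
  t_stat <- mean(d) / (s / sqrt(n))
  p2 <- 2 * pt(-abs(t_stat), n - 1)
  structure(
    list(method = "paired_t", n = n, t = t_stat, df = n - 1L,
         p_two_sided = p2, p_one_sided = p2 / 2,
         mean_diff = mean(d), sd_diff = s, d_z = mean(d) / s),
    class = "wf_test")
}

#' @export
print.wf_test <- function(x, ...) {
  cat("<wf_test>", x$method, "\n")
  if (x$method == "wilcoxon_signed_rank") {
    cat(sprintf("  n = %d (%d zero diffs dropped), W+ = %.1f, W- = %.1f\n",
                x$n, x$n_zero, x$W_plus, x$W_minus))
    cat(sprintf("  Z = %.3f, p (two-sided) = %.4f, r = %.3f\n",
                x$Z, x$p_two_sided, x$r))
  } else {
    cat(sprintf("  t(%d) = %.3f, p two-sided = %.4f, one-sided = %.4f\n",
                x$df, x$t, x$p_two_sided, x$p_one_sided))
    cat(sprintf("  mean diff = %.3f, sd diff = %.3f, d_z = %.3f\n",
                x$mean_diff, x$sd_diff, x$d_z))
  }
  invisible(x)
}

#' Full pre-post study summary
#'
#' Builds the study report from a per-participant outcome table in the
#' shape of [table2_fixture()] (columns `<var>_base` / `<var>_int` for
#' any of `exercise`, `breaks`, `distance`, `eses`): per-participant
#' percent changes, group mean (SD) and median rows, Wilcoxon
#' signed-rank tests for the physical-activity variables, a paired t
#' test for ESES, and the considerable-change category counts for
#' exercise time.
#'
#' Percent change is computed from the table's values as given (for the
#' packaged fixture, the published one-decimal phase means, which
#' reproduce every published integer); medians are computed on the same
#' values.
#'
#' @param data per-participant table; defaults to the packaged fixture.
#' @param change_variable variable classified at the +/-10% rule.
#' @return an object of class `wf_study`: list with `table` (per
#'   participant), `group` (mean/sd/median per variable and phase),
#'   `tests` (named `wf_test` list), `change_counts` and
#'   `change_categories`.
#' @export
summarize_study <- function(data = table2_fixture(),
                            change_variable = "exercise") {
  vars <- c("exercise", "breaks", "distance", "eses")
  vars <- vars[paste0(vars, "_base") %in% names(data) &
                 paste0(vars, "_int") %in% names(data)]
  if (length(vars) == 0L) stop("no <var>_base / <var>_int column pairs found")
  if (nrow(data) < 5L) stop("need at least 5 participants")

  tab <- data.frame(participant_id = data$participant_id)
  group <- list()
  tests <- list()
  for (v in vars) {
    b <- data[[paste0(v, "_base")]]
    i <- data[[paste0(v, "_int")]]
    tab[[paste0(v, "_base")]] <- b
    tab[[paste0(v, "_int")]] <- i
    tab[[paste0(v, "_change_pct")]] <- percent_change(b, i)
    group[[v]] <- data.frame(
      phase = c("baseline", "intervention"),
      mean = c(mean(b), mean(i)), sd = c(sd(b), sd(i)),
      median = c(median(b), median(i)))
    tests[[v]] <- if (v == "eses") paired_t(b, i) else wilcoxon_signed_rank(b, i)
  }

  if (!change_variable %in% vars) {
    stop("change_variable not present in data: ", change_variable)
  }
  cats <- classify_change(tab[[paste0(change_variable, "_change_pct")]])
  counts <- c(considerable_increase = sum(cats == "considerable_increase", na.rm = TRUE),
              considerable_decrease = sum(cats == "considerable_decrease", na.rm = TRUE),
              no_considerable_change = sum(cats == "no_considerable_change", na.rm = TRUE))
  structure(
    list(table = tab, group = group, tests = tests,
         change_variable = change_variable,
         change_categories = stats::setNames(cats, data$participant_id),
         change_counts = counts),
    class = "wf_study")
}

#' @export
print.wf_study <- function(x, ...) {
  cat("<wf_study> n =", nrow(x$table), "participants\n\n")
  for (v in names(x$group)) {
    g <- x$group[[v]]
    cat(sprintf("%-9s baseline %.1f (%.1f), median %.1f | intervention %.1f (%.1f), median %.1f\n",
                v, g$mean[1], g$sd[1], g$median[1],
                g$mean[2], g$sd[2], g$median[2]))
  }
  cat("\n")
  for (v in names(x$tests)) {
    t <- x$tests[[v]]
    if (t$method == "wilcoxon_signed_rank") {
      cat(sprintf("%-9s Wilcoxon Z = %.2f, p = %.3f, r = %.2f\n",
                  v, t$Z, t$p_two_sided, t$r))
    } else {
      cat(sprintf("%-9s paired t(%d) = %.2f, p two-sided = %.3f (one-sided %.3f), sd of diffs = %.2f\n",
                  v, t$df, t$t, t$p_two_sided, t$p_one_sided, t$sd_diff))
    }
  }
  cat(sprintf("\n%s change at the +/-10%% rule: %d increase / %d decrease / %d no change\n",
              x$change_variable,
              x$change_counts[["considerable_increase"]],
              x$change_counts[["considerable_decrease"]],
              x$change_counts[["no_considerable_change"]]))
  invisible(x)
}

#' Required sample size for a paired t test
#'
#' Smallest `n` whose paired t-test power at effect size `effect_d`
#' (Cohen's d_z on the paired differences) reaches `power`, computed by
#' direct noncentral-t iteration: with critical value
#' \eqn{t_c = t_{1-\alpha/s, n-1}} and noncentrality
#' \eqn{\delta = d\sqrt n}, power(n) = P(T > t_c) (+ the opposite tail
#' for two-sided tests).
#'
#' @param effect_d Cohen's d_z, positive.
#' @param power target power in (0, 1).
#' @param alpha significance level in (0, 1).
#' @param sided 1 or 2.
#' @return smallest adequate integer n (at least 2).
#' @export
power_sample_size <- function(effect_d, power = 0.8, alpha = 0.05,
                              sided = 2) {
  if (!(effect_d > 0)) stop("effect_d must be positive")
  if (!(power > 0 && power < 1)) stop("power must be in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!sided %in% c(1, 2)) stop("sided must be 1 or 2")
  for (n in 2:100000) {
    if (paired_t_power(n, effect_d, alpha, sided) >= power) return(n)
  }
  stop("no n up to 100000 reaches the target power")
}

# exact paired-t power via the noncentral t distribution
paired_t_power <- function(n, effect_d, alpha, sided) {
  df <- n - 1
  ncp <- effect_d * sqrt(n)
  crit <- qt(1 - alpha / sided, df)
  pow <- pt(crit, df, ncp = ncp, lower.tail = FALSE)
  if (sided == 2) pow <- pow + pt(-crit, df, ncp = ncp)
  pow
}
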