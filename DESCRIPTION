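Package: wheelfit
Title: Wearable Activity Metrics and Pre-Post Analysis for Manual Wheelchair Users
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computation stack for wheelchair-adapted physical-activity monitoring
    from multi-rate wearable sensor streams (wrist accelerometer at 30 Hz, heart
    rate at 1 Hz, wheel-mounted gyroscope rotation counts at 5 Hz). Computes
    per-minute mean-absolute-deviation (MAD) features, propulsion push counts,
    wheel-rotation odometry and energy estimates; classifies minute intensity
    (sedentary / light / MVPA) by MAD cut-points; derives daily metrics including
    sedentary-break counts over 30-minute windows, inactivity alerts, coverage and
    goal progress; applies valid-day filtering and phase aggregation; and runs the
    pre-post study analysis (percent change with a +/-10 percent considerable-change
    rule, tie-corrected Wilcoxon signed-rank with normal approximation, paired t,
    noncentral-t power iteration). Includes a synthetic sensor simulator with
    ground-truth minute labels so the whole pipeline is testable at desk scale,
    and a packaged per-participant outcome table fixture.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
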