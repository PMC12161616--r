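#' Simulate a pre-post cohort of phase-mean MVPA values
#'
#' Draws per-participant baseline daily MVPA phase means from a normal
#' distribution matched to the study cohort's baseline row
#' (mean 26.4, SD 16.9 min/day), truncated at zero by resampling, and
#' sets intervention = baseline + `effect` + Normal(0, `noise_sd`).
#' Intended for type-I-error and power checks of the pre-post tests;
#' intervention values are not truncated, so the null (`effect = 0`)
#' sampling distribution of the paired difference stays symmetric.
#'
#' @param n number of participants; at least 5 (the signed-rank test is
#'   degenerate below that).
#' @param effect additive MVPA shift, minutes/day.
#' @param seed integer seed.
#' @param baseline_mean,baseline_sd baseline distribution, min/day.
#' @param noise_sd SD of the within-participant phase-to-phase change.
#' @return data.frame with `participant_id`, `baseline`, `intervention`
#'   (class `wf_cohort`).
#' @export
generate_table2_like_cohort <- function(n, effect = 0, seed = 1L,
                                        baseline_mean = 26.4,
                                        baseline_sd = 16.9,
                                        noise_sd = 15) {
  if (n < 5) stop("n must be >= 5: the signed-rank test is degenerate for fewer pairs")
  set.seed(seed)
  base <- rnorm(n, baseline_mean, baseline_sd)
  while (any(base < 0)) {
    base[base < 0] <- rnorm(sum(base < 0), baseline_mean, baseline_sd)
  }
  out <- data.frame(participant_id = sprintf("S%02d", seq_len(n)),
                    baseline = base,
                    intervention = base + effect + rnorm(n, 0, noise_sd))
  class(out) <- c("wf_cohort", "data.frame")
  out
}
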