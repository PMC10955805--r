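#' Pipeline configuration for passive sleep estimation
#'
#' Collects every tunable of the sensor-to-sleep pipeline in one
#' validated list. Defaults follow actigraphy and image-processing
#' conventions: one-minute epochs, 256-bin Otsu histograms on
#' log10-jerk, 24-hour windows anchored at local noon, and a 60%
#' coverage threshold for window inclusion.
#'
#' @param epoch_seconds Epoch length in seconds; must divide a day evenly.
#' @param bin_seconds Coverage bin length in seconds (5 s bins give
#'   17,280 bins per 24-hour window).
#' @param coverage_threshold Minimum fraction of occupied coverage bins
#'   for a window to be included.
#' @param otsu_bins Number of histogram bins for Otsu thresholding.
#' @param transform Scale on which the jerk histogram is built:
#'   `"log10"` (default, jerk is heavy-tailed) or `"linear"`.
#' @param log_epsilon Offset added before the log10 transform, in g/s.
#' @param max_gap_seconds Maximum spacing between consecutive
#'   accelerometer samples for a finite-difference jerk value; larger
#'   gaps contribute to missingness instead.
#' @param anchor_hour Local clock hour at which 24-hour windows start;
#'   noon keeps a night's sleep inside one window.
#' @param tz_offset_minutes Offset from UTC applied when anchoring
#'   windows and assigning nights; storage timestamps stay in UTC ms.
#' @param policy Sleep-duration policy per window: `"longest_bout"`
#'   (duration of the longest inactive run) or `"sum_min_bout"` (total
#'   duration of inactive runs of at least `min_bout_minutes`).
#' @param min_bout_minutes Minimum bout length for `"sum_min_bout"`.
#' @param merge_active_blips_minutes Active interruptions up to this
#'   length flanked by inactivity are relabelled inactive before bout
#'   extraction; 0 disables merging.
#' @param threshold_scope Fit the Otsu threshold once per
#'   `"participant"` (default, stable) or per `"day"` window.
#'
#' @return A list of class `"sleep_config"`.
#' @export
#' @examples
#' cfg <- sleep_config(coverage_threshold = 0.5)
#' cfg$epoch_seconds
sleep_config <- function(epoch_seconds = 60,
                         bin_seconds = 5,
                         coverage_threshold = 0.6,
                         otsu_bins = 256,
                         transform = c("log10", "linear"),
                         log_epsilon = 1e-6,
                         max_gap_seconds = 1,
                         anchor_hour = 12,
                         tz_offset_minutes = 0,
                         policy = c("longest_bout", "sum_min_bout"),
                         min_bout_minutes = 30,
                         merge_active_blips_minutes = 0,
                         threshold_scope = c("participant", "day")) {
  transform <- match.arg(transform)
  policy <- match.arg(policy)
  threshold_scope <- match.arg(threshold_scope)
  stopifnot(
    epoch_seconds > 0, 86400 %% epoch_seconds == 0,
    bin_seconds > 0, 86400 %% bin_seconds == 0,
    coverage_threshold >= 0, coverage_threshold <= 1,
    otsu_bins >= 2,
    max_gap_seconds > 0,
    anchor_hour >= 0, anchor_hour < 24,
    min_bout_minutes >= 0,
    merge_active_blips_minutes >= 0
  )
  structure(
    list(
      epoch_seconds = epoch_seconds,
      bin_seconds = bin_seconds,
      coverage_threshold = coverage_threshold,
      otsu_bins = otsu_bins,
      transform = transform,
      log_epsilon = log_epsilon,
      max_gap_seconds = max_gap_seconds,
      anchor_hour = anchor_hour,
      tz_offset_minutes = tz_offset_minutes,
      policy = policy,
      min_bout_minutes = min_bout_minutes,
      merge_active_blips_minutes = merge_active_blips_minutes,
      threshold_scope = threshold_scope
    ),
    class = "sleep_config"
  )
}
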