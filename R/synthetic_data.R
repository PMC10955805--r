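# Synthetic cohort generator. Emulates the structure the analysis
# assumes for a month-long student digital-phenotyping study: per-night
# accelerometer streams whose finite-difference jerk magnitudes follow
# distinct log-normal regimes awake vs asleep, screen events only while
# awake, segment-wise missingness targeting a Beta-distributed daily
# coverage, noisy daily self-reports, and weekly PSQI from a linear
# outcome model with participant-level random intercepts. Ground truth
# is emitted alongside the data and is never read by the pipeline.

#' Synthetic cohort configuration
#'
#' Defaults emulate a cohort of 67 participants observed for 28 days
#' with a 5 Hz accelerometer: nightly sleep around 7.5 h starting near
#' 23:30 local, jerk medians separated 50-fold between wake
#' (1 g/s) and sleep (0.02 g/s), about 4 screen-use episodes per awake
#' hour and none while asleep, daily coverage Beta(8,2) (mean 0.8),
#' 90%/95% daily/weekly survey response rates, a 0.75 h reporting noise
#' on daily sleep duration, and a PSQI outcome model whose signs mirror
#' worse sleep quality and shorter sleep raising PSQI.
#'
#' @param n_participants,n_days Cohort dimensions.
#' @param sample_rate_hz Accelerometer sampling rate.
#' @param mean_bedtime_hour,sd_bedtime_hour Local-clock bedtime model.
#' @param mean_duration_h Mean true nightly sleep duration (hours).
#' @param sd_between,sd_within Between-participant and night-to-night
#'   standard deviations of true duration (hours).
#' @param wake_jerk_log_mean,wake_jerk_log_sd,sleep_jerk_log_mean,sleep_jerk_log_sd
#'   log10-scale jerk magnitude regimes (g/s).
#' @param screen_events_per_hour_awake,screen_events_per_hour_asleep
#'   Poisson rates of screen-use episodes.
#' @param coverage_beta_shape1,coverage_beta_shape2 Beta parameters of
#'   the per-day coverage target; `c(Inf, x)` semantics are not used —
#'   set `missingness = FALSE` for complete data.
#' @param missingness Apply segment-wise deletion at all.
#' @param missing_segment_minutes Length range (min, max) of deleted
#'   segments, minutes.
#' @param daily_response_prob,weekly_response_prob Survey response
#'   probabilities.
#' @param survey_noise_sd SD of daily duration reporting noise (hours).
#' @param quality_intercept,quality_slope,quality_noise_sd Daily
#'   sleep-quality construct: trouble-sleeping score decreasing in true
#'   duration, clamped to 0-10.
#' @param psqi_intercept,psqi_random_sd,beta_quality,beta_active_dur,beta_passive_dur,psqi_residual_sd
#'   Weekly PSQI outcome model evaluated on each week's true means,
#'   rounded and clamped to 0-14.
#' @param tz_offset_minutes Timezone offset used for local anchoring.
#' @param start_date First study date (local).
#' @param seed Cohort seed; per-participant substreams are derived from
#'   it so adding a participant does not reshuffle earlier ones.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_participants = 67,
                          n_days = 28,
                          sample_rate_hz = 5,
                          mean_bedtime_hour = 23.5,
                          sd_bedtime_hour = 0.75,
                          mean_duration_h = 7.5,
                          sd_between = 0.75,
                          sd_within = 1.0,
                          wake_jerk_log_mean = 0,
                          wake_jerk_log_sd = 0.25,
                          sleep_jerk_log_mean = log10(0.02),
                          sleep_jerk_log_sd = 0.15,
                          screen_events_per_hour_awake = 4,
                          screen_events_per_hour_asleep = 0,
                          coverage_beta_shape1 = 8,
                          coverage_beta_shape2 = 2,
                          missingness = TRUE,
                          missing_segment_minutes = c(5, 25),
                          daily_response_prob = 0.9,
                          weekly_response_prob = 0.95,
                          survey_noise_sd = 0.75,
                          quality_intercept = 13,
                          quality_slope = -1.2,
                          quality_noise_sd = 1,
                          psqi_intercept = 3,
                          psqi_random_sd = 1,
                          beta_quality = 0.2,
                          beta_active_dur = 0.4,
                          beta_passive_dur = -0.3,
                          psqi_residual_sd = 0.5,
                          tz_offset_minutes = 0,
                          start_date = "2022-03-01",
                          seed = 1) {
  stopifnot(n_participants >= 1, n_days >= 1, sample_rate_hz > 0,
            sd_between >= 0, sd_within >= 0, survey_noise_sd >= 0,
            daily_response_prob >= 0, daily_response_prob <= 1,
            weekly_response_prob >= 0, weekly_response_prob <= 1,
            length(missing_segment_minutes) == 2,
            psqi_random_sd >= 0, psqi_residual_sd >= 0)
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

participant_seed <- function(seed, index) {
  (as.integer(seed) + 10007L * as.integer(index)) %% 2147483647L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# delete whole randomly placed segments from one night's streams until
# the fraction of surviving 5-second bins reaches the coverage target
apply_missingness <- function(accel_t, event_t, ws, target_coverage,
                              segment_minutes) {
  n_bins <- MS_DAY / 5000
  deleted <- rep(FALSE, n_bins)
  iter <- 0
  while (mean(deleted) < 1 - target_coverage && iter < 500) {
    len_ms <- runif(1, segment_minutes[1], segment_minutes[2]) * 60000
    start <- runif(1, ws, ws + MS_DAY - len_ms)
    b0 <- max(1, floor((start - ws) / 5000) + 1)
    b1 <- min(n_bins, floor((start + len_ms - ws) / 5000) + 1)
    deleted[b0:b1] <- TRUE
    iter <- iter + 1
  }
  in_deleted <- function(t) {
    b <- floor((t - ws) / 5000) + 1
    ok <- b >= 1 & b <= n_bins
    out <- rep(FALSE, length(t))
    out[ok] <- deleted[b[ok]]
    out
  }
  list(accel_keep = !in_deleted(accel_t),
       event_keep = if (length(event_t)) !in_deleted(event_t) else logical(0))
}

#' Generate one synthetic night of sensor data
#'
#' Simulates a noon-to-noon 24-hour window for one participant: a true
#' sleep interval from the bedtime/duration model, an accelerometer
#' stream whose finite-difference jerk magnitudes are log-normal with
#' the wake regime's parameters while awake and the sleep regime's
#' while asleep, screen-use episodes as a Poisson process with the
#' regime's rate (each episode emits an unlock event followed by an
#' off-and-locked event), and segment-wise missingness. Consumes the
#' current RNG stream; seed outside for reproducibility.
#'
#' @param config A [cohort_config()].
#' @param window_start Local-clock start of the 24-hour window (ms).
#' @param mean_duration_h This participant's mean true sleep duration.
#' @return List with `accel` (tibble `t,x,y,z`), `events` (tibble
#'   `t,state`), and `truth` (one-row tibble `sleep_start, sleep_end,
#'   true_hours, target_coverage`). Timestamps are local-clock ms.
#' @export
generate_night <- function(config, window_start,
                           mean_duration_h = config$mean_duration_h) {
  ws <- window_start
  bed <- rnorm(1, config$mean_bedtime_hour, config$sd_bedtime_hour)
  dur <- clamp(rnorm(1, mean_duration_h, config$sd_within), 3, 12)
  sleep_start <- ws + (bed - 12) * MS_HOUR
  sleep_end <- min(sleep_start + dur * MS_HOUR, ws + MS_DAY - MS_HOUR)
  true_h <- (sleep_end - sleep_start) / MS_HOUR

  dt_ms <- 1000 / config$sample_rate_hz
  t <- seq(ws, ws + MS_DAY - dt_ms, by = dt_ms)
  n <- length(t)
  mid <- t[-n] + dt_ms / 2
  asleep <- mid >= sleep_start & mid < sleep_end
  m <- 10^rnorm(n - 1,
                ifelse(asleep, config$sleep_jerk_log_mean,
                       config$wake_jerk_log_mean),
                ifelse(asleep, config$sleep_jerk_log_sd,
                       config$wake_jerk_log_sd))
  u <- matrix(rnorm(3 * (n - 1)), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  step <- u * (m * dt_ms / 1000)
  accel <- tibble::tibble(
    t = t,
    x = cumsum(c(0, step[, 1])),
    y = cumsum(c(0, step[, 2])),
    z = 1 + cumsum(c(0, step[, 3]))
  )

  wake_iv <- rbind(c(ws, sleep_start), c(sleep_end, ws + MS_DAY))
  ev_t <- numeric(0)
  for (k in 1:2) {
    hrs <- (wake_iv[k, 2] - wake_iv[k, 1]) / MS_HOUR
    if (hrs <= 0) next
    n_ev <- rpois(1, config$screen_events_per_hour_awake * hrs)
    if (n_ev > 0) ev_t <- c(ev_t, runif(n_ev, wake_iv[k, 1], wake_iv[k, 2]))
  }
  if (config$screen_events_per_hour_asleep > 0 && true_h > 0) {
    n_ev <- rpois(1, config$screen_events_per_hour_asleep * true_h)
    if (n_ev > 0) ev_t <- c(ev_t, runif(n_ev, sleep_start, sleep_end))
  }
  ev_t <- sort(ev_t)
  events <- tibble::tibble(
    t = as.numeric(rbind(ev_t, ev_t + 20000)),
    state = rep(c("on_unlocked", "off_locked"), length(ev_t))
  )

  target_cov <- 1
  if (config$missingness) {
    target_cov <- rbeta(1, config$coverage_beta_shape1,
                        config$coverage_beta_shape2)
    keep <- apply_missingness(accel$t, events$t, ws, target_cov,
                              config$missing_segment_minutes)
    accel <- accel[keep$accel_keep, ]
    events <- events[keep$event_keep, ]
  }
  accel$t <- round(accel$t)
  events$t <- round(events$t)
  list(accel = accel, events = events,
       truth = tibble::tibble(sleep_start = sleep_start,
                              sleep_end = sleep_end,
                              true_hours = true_h,
                              target_coverage = target_cov))
}

#' Generate one participant's full data
#'
#' Draws the participant's random intercept and mean sleep duration,
#' simulates every night with [generate_night()], and derives the
#' survey records: daily duration reports (true duration plus noise,
#' answered next morning with the configured response probability),
#' daily trouble-sleeping quality scores (decreasing in true duration),
#' and weekly PSQI from the linear outcome model evaluated on each
#' week's true means, rounded and clamped to 0-14.
#'
#' @param config A [cohort_config()].
#' @param index Participant index (1-based); seeds a dedicated
#'   substream so participants are independent of cohort size.
#' @return List with `participant`, `accel`, `events`, `surveys`,
#'   `truth_nights`, `random_intercept`. Timestamps are UTC ms.
#' @export
generate_participant <- function(config, index) {
  pid <- sprintf("p%03d", index)
  set.seed(participant_seed(config$seed, index))
  off_ms <- config$tz_offset_minutes * 60000
  day0 <- as.numeric(as.Date(config$start_date)) * MS_DAY
  ws0 <- day0 + 12 * MS_HOUR  # windows anchored at local noon

  u_p <- rnorm(1, 0, config$psqi_random_sd)
  mean_dur_p <- rnorm(1, config$mean_duration_h, config$sd_between)

  accel <- vector("list", config$n_days)
  events <- vector("list", config$n_days)
  truths <- vector("list", config$n_days)
  for (d in seq_len(config$n_days)) {
    ws <- ws0 + (d - 1) * MS_DAY
    night <- generate_night(config, ws, mean_dur_p)
    accel[[d]] <- night$accel
    events[[d]] <- night$events
    tr <- night$truth
    tr$night <- as.Date(config$start_date) + d
    truths[[d]] <- tr
  }
  truth <- dplyr::bind_rows(truths)
  truth <- tibble::tibble(participant = pid, truth)

  # daily surveys, answered around 09:00 the following morning
  resp <- runif(config$n_days) < config$daily_response_prob
  t_daily <- ws0 + (seq_len(config$n_days) - 1) * MS_DAY +
    21 * MS_HOUR + round(runif(config$n_days, -3600, 3600) * 1000)
  rep_dur <- clamp(truth$true_hours + rnorm(config$n_days, 0,
                                            config$survey_noise_sd), 0, 24)
  quality_true <- config$quality_intercept +
    config$quality_slope * truth$true_hours
  rep_qual <- clamp(round(quality_true +
                            rnorm(config$n_days, 0, config$quality_noise_sd)),
                    0, 10)

  surveys <- list()
  if (any(resp)) {
    surveys[[1]] <- tibble::tibble(
      participant = pid, t = t_daily[resp] - off_ms,
      instrument = "daily_duration", score = rep_dur[resp])
    surveys[[2]] <- tibble::tibble(
      participant = pid, t = t_daily[resp] - off_ms,
      instrument = "daily_quality", score = rep_qual[resp])
  }

  # weekly PSQI, evaluated on the preceding week's true means
  weeks <- if (config$n_days >= 7) seq(7, config$n_days, by = 7) else integer(0)
  psqi_rows <- list()
  for (w in seq_along(weeks)) {
    d_hi <- weeks[w]
    d_lo <- d_hi - 6
    answered <- runif(1) < config$weekly_response_prob
    wk <- d_lo:d_hi
    mu <- config$psqi_intercept + u_p +
      config$beta_quality * mean(quality_true[wk]) +
      config$beta_active_dur * mean(truth$true_hours[wk]) +
      config$beta_passive_dur * mean(truth$true_hours[wk])
    score <- clamp(round(mu + rnorm(1, 0, config$psqi_residual_sd)), 0, 14)
    if (answered) {
      t_psqi <- ws0 + (d_hi - 1) * MS_DAY + 30 * MS_HOUR  # 18:00 local day d_hi+1
      psqi_rows[[length(psqi_rows) + 1]] <- tibble::tibble(
        participant = pid, t = t_psqi - off_ms,
        instrument = "psqi", score = score)
    }
  }
  surveys <- dplyr::bind_rows(c(surveys, psqi_rows))

  accel <- dplyr::bind_rows(accel)
  events <- dplyr::bind_rows(events)
  accel$t <- accel$t - off_ms
  if (nrow(events) > 0) events$t <- events$t - off_ms
  # expose events in the reader's screen/lock schema
  parts <- strsplit(events$state, "_", fixed = TRUE)
  events <- tibble::tibble(
    participant = rep(pid, nrow(events)),
    t = events$t,
    screen = vapply(parts, `[[`, "", 1L),
    lock = vapply(parts, `[[`, "", 2L))
  list(participant = pid,
       accel = tibble::tibble(participant = pid, accel),
       events = events,
       surveys = surveys,
       truth_nights = truth,
       random_intercept = u_p)
}

#' Generate a full synthetic cohort
#'
#' Runs [generate_participant()] for every participant. With `out_dir`
#' the cohort is written as the CSV tree the readers consume
#' (`accel_<id>.csv`, `events_<id>.csv`, `surveys.csv`) plus the ground
#' truth (`truth_nights.csv`, `truth_participants.csv`) and a JSON
#' snapshot of the configuration; the truth files are never read by the
#' pipeline. Byte-identical output for identical seed and
#' configuration.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to
#'   return everything in memory.
#' @return With `out_dir`, the directory path (invisibly); otherwise a
#'   list with `participants` (list of [generate_participant()]
#'   results), `surveys`, `truth_nights`, `truth_participants`.
#' @export
generate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  surveys <- list()
  truths <- list()
  intercepts <- numeric(config$n_participants)
  parts <- if (is.null(out_dir)) vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    p <- generate_participant(config, i)
    surveys[[i]] <- p$surveys
    truths[[i]] <- p$truth_nights
    intercepts[i] <- p$random_intercept
    if (is.null(out_dir)) {
      parts[[i]] <- p
    } else {
      write_accelerometer(p$accel,
                          file.path(out_dir, paste0("accel_", p$participant, ".csv")))
      write_device_events(p$events,
                          file.path(out_dir, paste0("events_", p$participant, ".csv")))
    }
  }
  surveys <- dplyr::bind_rows(surveys)
  truth_nights <- dplyr::bind_rows(truths)
  truth_participants <- tibble::tibble(
    participant = sprintf("p%03d", seq_len(config$n_participants)),
    random_intercept = intercepts)
  if (is.null(out_dir)) {
    return(list(participants = parts, surveys = surveys,
                truth_nights = truth_nights,
                truth_participants = truth_participants))
  }
  write_surveys(surveys, file.path(out_dir, "surveys.csv"))
  readr::write_csv(truth_nights, file.path(out_dir, "truth_nights.csv"),
                   progress = FALSE)
  readr::write_csv(truth_participants,
                   file.path(out_dir, "truth_participants.csv"),
                   progress = FALSE)
  snap <- config
  class(snap) <- NULL
  jsonlite::write_json(snap, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Simulate PSQI window records directly
#'
#' Draws weekly PSQI observations straight from the random-intercept
#' outcome model — no sensor simulation — for fast parameter-recovery
#' studies of the regression layer: `n_windows` records per participant
#' with independently drawn predictor values, and
#' `psqi = intercept + u_p + beta_quality*quality +
#' beta_active*active + beta_passive*passive + e`,
#' optionally rounded and clamped to the 0-14 scale.
#'
#' @param n_participants,n_windows Design size.
#' @param intercept,random_sd,beta_quality,beta_active,beta_passive,resid_sd
#'   Outcome model parameters.
#' @param quality_mean,quality_sd,duration_mean,duration_sd,passive_sd
#'   Predictor distributions.
#' @param round_psqi Round and clamp the outcome to the integer 0-14
#'   scale.
#' @return List with `records` (tibble shaped like
#'   [build_psqi_windows()] output) and `truth` (the parameters used).
#' @export
simulate_psqi_windows <- function(n_participants = 67, n_windows = 4,
                                  intercept = 3, random_sd = 1,
                                  beta_quality = 0.2, beta_active = 0.4,
                                  beta_passive = -0.3, resid_sd = 0.5,
                                  quality_mean = 4, quality_sd = 1.5,
                                  duration_mean = 7.5, duration_sd = 1,
                                  passive_sd = 1, round_psqi = TRUE) {
  n <- n_participants * n_windows
  pid <- rep(sprintf("p%03d", seq_len(n_participants)), each = n_windows)
  u <- rep(rnorm(n_participants, 0, random_sd), each = n_windows)
  q <- rnorm(n, quality_mean, quality_sd)
  a <- rnorm(n, duration_mean, duration_sd)
  b <- rnorm(n, duration_mean, passive_sd)
  y <- intercept + u + beta_quality * q + beta_active * a +
    beta_passive * b + rnorm(n, 0, resid_sd)
  if (round_psqi) y <- clamp(round(y), 0, 14)
  records <- tibble::tibble(
    participant = pid,
    psqi_t = rep(seq_len(n_windows), n_participants) * 7 * MS_DAY,
    psqi = y,
    mean_active_quality = q,
    mean_active_duration = a,
    mean_passive_duration = b,
    complete = TRUE)
  list(records = records,
       truth = list(intercept = intercept, random_sd = random_sd,
                    beta = c(quality = beta_quality, active = beta_active,
                             passive = beta_passive),
                    resid_sd = resid_sd))
}

#' Simulate night-level duration series
#'
#' A light-weight emulator of the per-night duration streams alone:
#' true nightly sleep with between- and within-participant variation,
#' a self-reported value (truth plus reporting noise) available with
#' probability `active_prob`, and a passive estimate (truth plus
#' estimation noise) available with probability `passive_prob`.
#' Missingness is completely at random in both streams. Used to study
#' how restricting to paired nights changes the correlation between
#' participant-level mean active and mean passive durations.
#'
#' @param n_participants,n_days Design size.
#' @param mean_duration,sd_between,sd_within True-duration model
#'   (hours).
#' @param survey_noise_sd,estimate_noise_sd Noise SDs (hours).
#' @param active_prob,passive_prob Per-night availability.
#' @return Tibble `participant, night, true_hours, active_hours,
#'   passive_hours` with `NA` for unavailable nights.
#' @export
simulate_night_series <- function(n_participants = 67, n_days = 28,
                                  mean_duration = 7.5, sd_between = 0.75,
                                  sd_within = 1.0, survey_noise_sd = 0.75,
                                  estimate_noise_sd = 0.25,
                                  active_prob = 0.9, passive_prob = 0.93) {
  n <- n_participants * n_days
  pid <- rep(sprintf("p%03d", seq_len(n_participants)), each = n_days)
  mu <- rep(rnorm(n_participants, mean_duration, sd_between), each = n_days)
  true_h <- mu + rnorm(n, 0, sd_within)
  active <- true_h + rnorm(n, 0, survey_noise_sd)
  passive <- true_h + rnorm(n, 0, estimate_noise_sd)
  active[runif(n) >= active_prob] <- NA
  passive[runif(n) >= passive_prob] <- NA
  tibble::tibble(participant = pid,
                 night = rep(seq_len(n_days), n_participants),
                 true_hours = true_h,
                 active_hours = active,
                 passive_hours = passive)
}
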