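# Temporal alignment of daily surveys, passive sleep estimates and
# weekly PSQI into analysis-ready records: night keys, paired nights,
# PSQI look-back windows and participant-level means.

ms_to_local_date <- function(t, tz_offset_minutes = 0) {
  as.Date(floor((t + tz_offset_minutes * 60000) / MS_DAY),
          origin = "1970-01-01")
}

#' Assign a survey response or passive window to a night
#'
#' Daily surveys report the previous night, so a response submitted on
#' local date D describes the night ending on D. A passive 24-hour
#' window anchored at local noon of D-1 covers the same night and maps
#' to the same key.
#'
#' @param t Timestamp in ms UTC (survey submission time).
#' @param tz_offset_minutes Offset from UTC in minutes.
#' @return The night key as a `Date`.
#' @export
assign_night <- function(t, tz_offset_minutes = 0) {
  ms_to_local_date(t, tz_offset_minutes)
}

#' @rdname assign_night
#' @param window_start Local-clock anchor of a passive 24-hour window
#'   (ms), as in [estimate_participant()] output.
#' @export
night_of_window <- function(window_start) {
  as.Date(floor(window_start / MS_DAY), origin = "1970-01-01") + 1L
}

#' Night-keyed daily survey series
#'
#' Extracts one instrument from a survey table and keys it by
#' (participant, night). When a participant answered the same daily
#' survey more than once on one local date, the first response is kept
#' and the duplicates are logged.
#'
#' @param surveys Tibble from [read_surveys()].
#' @param instrument One of `"daily_duration"` or `"daily_quality"`.
#' @param tz_offset_minutes Offset from UTC in minutes.
#' @return Tibble `participant, night, score`.
#' @export
daily_nights <- function(surveys, instrument = "daily_duration",
                         tz_offset_minutes = 0) {
  d <- surveys[surveys$instrument == instrument, ]
  d <- d[order(d$participant, d$t), ]
  d$night <- assign_night(d$t, tz_offset_minutes)
  dup <- duplicated(d[, c("participant", "night")])
  if (any(dup)) {
    message(sum(dup), " duplicate ", instrument,
            " response(s) on the same date dropped (kept first)")
  }
  d <- d[!dup, ]
  tibble::tibble(participant = d$participant, night = d$night,
                 score = d$score)
}

#' Pair survey-reported and sensor-estimated nights
#'
#' Inner join on (participant, night): only nights where both an active
#' (self-reported) and a passive (sensor-estimated) sleep duration exist
#' survive, since neither stream is necessarily available every night.
#'
#' @param active Tibble `participant, night, score` (hours), e.g. from
#'   [daily_nights()].
#' @param passive Tibble `participant, night, sleep_hours`, e.g. from
#'   [passive_nights()].
#' @return Tibble `participant, night, active_hours, passive_hours`.
#' @export
pair_nights <- function(active, passive) {
  a <- tibble::tibble(participant = active$participant, night = active$night,
                      active_hours = active$score)
  p <- tibble::tibble(participant = passive$participant,
                      night = passive$night,
                      passive_hours = passive$sleep_hours)
  dplyr::inner_join(a, p, by = c("participant", "night"))
}

#' Night-keyed passive estimates
#'
#' Keeps included windows only and keys them by night.
#'
#' @param estimates Tibble from [estimate_participant()].
#' @return Tibble `participant, night, sleep_hours`.
#' @export
passive_nights <- function(estimates) {
  e <- estimates[estimates$included, ]
  tibble::tibble(participant = e$participant,
                 night = night_of_window(e$window_start),
                 sleep_hours = e$sleep_hours)
}

#' Build PSQI look-back windows
#'
#' PSQI is administered weekly while daily surveys and passive estimates
#' arrive daily, so for each PSQI response the daily predictors are
#' averaged between the timestamp of the previous PSQI and the timestamp
#' of this one — the half-open interval (prev, t], so a same-moment
#' daily response counts exactly once. The first PSQI of a participant
#' has no look-back window and is dropped; zero-length windows (PSQI
#' answered twice at one timestamp) are dropped too. Records missing any
#' predictor are flagged `complete = FALSE` and excluded from modeling
#' by default (no imputation).
#'
#' @param surveys Tibble from [read_surveys()] (daily and PSQI rows).
#' @param estimates Tibble from [estimate_participant()].
#' @param tz_offset_minutes Offset from UTC in minutes.
#' @return Tibble with one row per PSQI response after the first:
#'   `participant, psqi_t, psqi, window_start_t, initial_psqi,
#'   mean_active_quality, mean_active_duration, mean_passive_duration,
#'   n_quality, n_duration, n_passive, complete`.
#' @export
build_psqi_windows <- function(surveys, estimates,
                               tz_offset_minutes = 0) {
  empty <- tibble::tibble(
    participant = character(), psqi_t = numeric(), psqi = numeric(),
    window_start_t = numeric(), initial_psqi = numeric(),
    mean_active_quality = numeric(), mean_active_duration = numeric(),
    mean_passive_duration = numeric(), n_quality = integer(),
    n_duration = integer(), n_passive = integer(), complete = logical())

  psqi <- surveys[surveys$instrument == "psqi", ]
  psqi <- psqi[order(psqi$participant, psqi$t), ]
  qual <- surveys[surveys$instrument == "daily_quality", ]
  dur <- surveys[surveys$instrument == "daily_duration", ]
  est <- estimates[estimates$included, ]
  # a passive window is "observed at" its end instant, converted to UTC
  est_t <- est$window_start + MS_DAY - tz_offset_minutes * 60000

  rows <- list()
  for (p in unique(psqi$participant)) {
    pp <- psqi[psqi$participant == p, ]
    if (nrow(pp) < 2) {
      message("participant ", p, ": fewer than 2 PSQI responses, ",
              "no look-back windows formed")
      next
    }
    qt <- qual$t[qual$participant == p]; qs <- qual$score[qual$participant == p]
    dt <- dur$t[dur$participant == p]; ds <- dur$score[dur$participant == p]
    pe <- est$participant == p
    et <- est_t[pe]; es <- est$sleep_hours[pe]
    for (i in 2:nrow(pp)) {
      t0 <- pp$t[i - 1]; t1 <- pp$t[i]
      if (t1 <= t0) next  # zero-length window
      inq <- qt > t0 & qt <= t1
      ind <- dt > t0 & dt <= t1
      ine <- et > t0 & et <= t1
      mq <- if (any(inq)) mean(qs[inq]) else NA_real_
      md <- if (any(ind)) mean(ds[ind]) else NA_real_
      me <- if (any(ine)) mean(es[ine]) else NA_real_
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant = p, psqi_t = t1, psqi = pp$score[i],
        window_start_t = t0, initial_psqi = pp$score[1],
        mean_active_quality = mq, mean_active_duration = md,
        mean_passive_duration = me,
        n_quality = sum(inq), n_duration = sum(ind), n_passive = sum(ine),
        complete = !is.na(mq) && !is.na(md) && !is.na(me))
    }
  }
  if (length(rows) == 0) return(empty)
  dplyr::bind_rows(rows)
}

#' Per-participant metric means
#'
#' Averages each metric over the course of the study for each
#' participant, over available records only. With `paired_only = TRUE`
#' the means are restricted to nights where both the active and the
#' passive duration are present — restricting to such pairs removes the
#' night-sampling discrepancy between the two streams.
#'
#' @param nights A night-keyed tibble with column `participant` and one
#'   numeric column per metric (missing values allowed).
#' @param paired_only Restrict to rows where both `active_hours` and
#'   `passive_hours` are present (requires those columns).
#' @return One row per participant with `mean_<metric>` and
#'   `n_<metric>` columns; means are reported only when at least one
#'   value is available.
#' @export
participant_means <- function(nights, paired_only = FALSE) {
  if (paired_only) {
    stopifnot(all(c("active_hours", "passive_hours") %in% names(nights)))
    nights <- nights[!is.na(nights$active_hours) &
                       !is.na(nights$passive_hours), ]
  }
  metrics <- setdiff(names(nights)[vapply(nights, is.numeric, TRUE)],
                     "participant")
  long <- tidyr::pivot_longer(nights[, c("participant", metrics)],
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  long <- long[!is.na(long$value), ]
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$participant, .data$metric),
    mean = mean(.data$value), n = dplyr::n(), .groups = "drop")
  wide <- tidyr::pivot_wider(summ, names_from = "metric",
                             values_from = c("mean", "n"),
                             names_sep = "_")
  dplyr::arrange(wide, .data$participant)
}
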