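# Core passive sleep-estimation method: jerk -> Otsu threshold ->
# epoch classification fused with device on-events -> missingness
# bridging -> coverage-filtered per-window sleep duration.

#' Compute a jerk magnitude series from accelerometer samples
#'
#' Jerk is the first time derivative of acceleration. For each
#' consecutive pair of samples spaced at most `max_gap_seconds` apart,
#' the jerk magnitude is the Euclidean norm of the component-wise
#' acceleration difference divided by the spacing in seconds (units:
#' g/s). Pairs spaced wider emit nothing; such gaps later register as
#' missing data. Each jerk value is stamped at the midpoint of its
#' contributing pair.
#'
#' @param samples Tibble with columns `t` (ms, strictly increasing) and
#'   `x`, `y`, `z` (g), as from [read_accelerometer()].
#' @param max_gap_seconds Maximum pair spacing for a finite difference.
#' @return A tibble with columns `t` (midpoint, ms) and `j` (g/s).
#'   Fewer than two samples yield an empty result.
#' @export
compute_jerk_series <- function(samples, max_gap_seconds = 1) {
  empty <- tibble::tibble(t = numeric(), j = numeric())
  n <- nrow(samples)
  if (n < 2) return(empty)
  if (any(diff(samples$t) <= 0)) {
    stop("accelerometer timestamps must be strictly increasing", call. = FALSE)
  }
  dt <- diff(samples$t) / 1000  # seconds
  keep <- dt <= max_gap_seconds
  if (!any(keep)) return(empty)
  dx <- diff(samples$x)
  dy <- diff(samples$y)
  dz <- diff(samples$z)
  j <- sqrt(dx^2 + dy^2 + dz^2) / dt
  tm <- (samples$t[-n] + samples$t[-1]) / 2
  tibble::tibble(t = tm[keep], j = j[keep])
}

#' Otsu's threshold for a one-dimensional sample
#'
#' Builds a `bins`-bin histogram of the (optionally log10-transformed)
#' values and returns the bin boundary minimizing the weighted sum of
#' within-class variances — equivalently, maximizing between-class
#' variance. Borrowed from image binarization, applied here to separate
#' high (active) from low (at-rest) jerk magnitudes. When several
#' boundaries tie, the lowest is chosen, which favours classifying
#' borderline epochs as active. The threshold is reported back on the
#' original scale.
#'
#' @param values Numeric vector (jerk magnitudes, g/s); at least two
#'   distinct values after transformation are required.
#' @param bins Number of histogram bins (>= 2).
#' @param transform `"log10"` applies `log10(values + log_epsilon)`
#'   before binning; `"linear"` bins the raw values.
#' @param log_epsilon Offset for the log transform.
#' @return An object of class `"jerk_threshold"`: a list with `tau`
#'   (threshold on the original scale), `tau_transformed`, `bins`,
#'   `transform`, `log_epsilon` and the chosen boundary index
#'   `boundary`.
#' @export
otsu_threshold <- function(values, bins = 256,
                           transform = c("log10", "linear"),
                           log_epsilon = 1e-6) {
  transform <- match.arg(transform)
  stopifnot(bins >= 2)
  v <- values[is.finite(values)]
  if (length(v) < 2) {
    stop("need at least two finite values to threshold", call. = FALSE)
  }
  if (transform == "log10") {
    if (any(v + log_epsilon <= 0)) {
      stop("log10 transform requires values + log_epsilon > 0", call. = FALSE)
    }
    v <- log10(v + log_epsilon)
  }
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    stop("degenerate distribution: all values identical, no threshold exists",
         call. = FALSE)
  }
  breaks <- seq(lo, hi, length.out = bins + 1)
  idx <- pmin(findInterval(v, breaks), bins)
  counts <- tabulate(idx, nbins = bins)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  p <- counts / sum(counts)

  # cumulative moments; within-class variance at boundary k equals
  # total second moment minus the class-conditional first-moment terms,
  # so minimizing it maximizes c1^2/w0 + (tot1-c1)^2/w1
  w <- cumsum(p)
  c1 <- cumsum(p * mids)
  tot1 <- c1[bins]
  k <- seq_len(bins - 1)
  w0 <- w[k]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  crit <- rep(-Inf, bins - 1)
  crit[valid] <- c1[k][valid]^2 / w0[valid] +
    (tot1 - c1[k][valid])^2 / w1[valid]
  if (!any(is.finite(crit))) {
    stop("degenerate distribution: all mass in one bin", call. = FALSE)
  }
  best <- which.max(crit)  # ties resolved to the lowest boundary
  tau_t <- breaks[best + 1]
  tau <- if (transform == "log10") 10^tau_t - log_epsilon else tau_t
  structure(
    list(tau = tau, tau_transformed = tau_t, boundary = best,
         bins = bins, transform = transform, log_epsilon = log_epsilon,
         breaks = breaks),
    class = "jerk_threshold"
  )
}

#' @export
print.jerk_threshold <- function(x, ...) {
  cat("Otsu jerk threshold: tau =", signif(x$tau, 4), "g/s (",
      x$bins, "bins,", x$transform, "scale)\n")
  invisible(x)
}

tau_value <- function(tau) {
  if (inherits(tau, "jerk_threshold")) tau$tau else as.numeric(tau)
}

# identify on-events: a transition into screen=on or into lock=unlocked.
# The first event of a stream counts when it already shows the on state,
# since the state before the stream is unknown.
on_event_flags <- function(events) {
  n <- nrow(events)
  if (n == 0) return(logical(0))
  prev_screen <- c(NA, events$screen[-n])
  prev_lock <- c(NA, events$lock[-n])
  to_on <- events$screen == "on" & (is.na(prev_screen) | prev_screen == "off")
  to_unlocked <- events$lock == "unlocked" &
    (is.na(prev_lock) | prev_lock == "locked")
  to_on | to_unlocked
}

#' Classify fixed-length epochs as active, inactive or missing
#'
#' Tiles `[span_start, span_end)` with contiguous epochs of
#' `epoch_seconds`. An epoch is `ACTIVE` when any jerk sample in it
#' exceeds the threshold, or when any device on-event (a transition into
#' screen-on or into unlocked) occurs in it; `MISSING` when it contains
#' no jerk samples and no device events at all; otherwise `INACTIVE`.
#'
#' @param jerk Tibble from [compute_jerk_series()].
#' @param events Tibble from [read_device_events()] (may be empty).
#' @param tau A `"jerk_threshold"` or a plain numeric threshold in g/s.
#' @param epoch_seconds Epoch length; must divide a day evenly.
#' @param span_start,span_end Span to tile, in ms; the span length must
#'   be a multiple of the epoch length.
#' @return A tibble with `epoch_start` (ms) and `state` in
#'   \{"ACTIVE","INACTIVE","MISSING"\}.
#' @export
classify_epochs <- function(jerk, events, tau, epoch_seconds = 60,
                            span_start, span_end) {
  stopifnot(86400 %% epoch_seconds == 0)
  ep_ms <- epoch_seconds * 1000
  stopifnot(span_end > span_start, (span_end - span_start) %% ep_ms == 0)
  n_ep <- as.integer((span_end - span_start) / ep_ms)
  tau <- tau_value(tau)

  bin_of <- function(t) {
    inside <- t >= span_start & t < span_end
    as.integer(floor((t[inside] - span_start) / ep_ms)) + 1L
  }
  jerk_bins <- bin_of(jerk$t)
  jerk_present <- tabulate(jerk_bins, nbins = n_ep) > 0
  above <- jerk$j > tau
  inside_j <- jerk$t >= span_start & jerk$t < span_end
  jerk_above <- tabulate(jerk_bins[above[inside_j]], nbins = n_ep) > 0

  if (nrow(events) > 0) {
    stopifnot(all(c("t", "screen", "lock") %in% names(events)))
    ev_bins <- bin_of(events$t)
    ev_present <- tabulate(ev_bins, nbins = n_ep) > 0
    on_flags <- on_event_flags(events)
    inside_e <- events$t >= span_start & events$t < span_end
    ev_on <- tabulate(ev_bins[on_flags[inside_e]], nbins = n_ep) > 0
  } else {
    ev_present <- ev_on <- rep(FALSE, n_ep)
  }

  state <- ifelse(jerk_above | ev_on, "ACTIVE",
                  ifelse(jerk_present | ev_present, "INACTIVE", "MISSING"))
  tibble::tibble(
    epoch_start = span_start + (seq_len(n_ep) - 1) * ep_ms,
    state = state
  )
}

#' Bridge runs of missing epochs by their neighbouring states
#'
#' Each maximal run of `MISSING` epochs strictly between two observed
#' states is relabelled: when the neighbours match (asleep-missing-asleep
#' or active-missing-active) the gap takes their shared state; when they
#' mismatch, the gap becomes `INACTIVE`, because a resumption of data
#' collection is most likely caused by user activity and so marks the
#' transition out of inactivity. Leading and trailing missing runs have
#' no neighbour on one side and remain `MISSING`; they count against
#' coverage only.
#'
#' @param states Tibble from [classify_epochs()] tiling a contiguous
#'   span.
#' @return The same tibble with interior missing runs relabelled.
#' @export
bridge_missing <- function(states) {
  s <- states$state
  n <- length(s)
  if (n == 0) return(states)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (r$values[i] != "MISSING") next
    if (i == 1 || i == length(r$values)) next  # no neighbour on one side
    left <- r$values[i - 1]
    right <- r$values[i + 1]
    fill <- if (left == right) left else "INACTIVE"
    s[starts[i]:ends[i]] <- fill
  }
  states$state <- s
  states
}

#' Fraction of occupied coverage bins in a 24-hour window
#'
#' Splits the window into `bin_seconds` bins (5-second bins give 17,280
#' per 24 hours) and returns the fraction containing at least one
#' accelerometer sample. Device events do not count toward coverage.
#'
#' @param sample_t Numeric vector of accelerometer sample timestamps
#'   (ms).
#' @param window_start Window start (ms, same clock as `sample_t`).
#' @param window_hours Window length in hours.
#' @param bin_seconds Bin length in seconds.
#' @return Coverage fraction in \[0, 1\].
#' @export
compute_coverage <- function(sample_t, window_start, window_hours = 24,
                             bin_seconds = 5) {
  n_bins <- window_hours * 3600 / bin_seconds
  stopifnot(n_bins == as.integer(n_bins))
  bin_ms <- bin_seconds * 1000
  win_ms <- window_hours * MS_HOUR
  inside <- sample_t >= window_start & sample_t < window_start + win_ms
  if (!any(inside)) return(0)
  occupied <- unique(floor((sample_t[inside] - window_start) / bin_ms))
  length(occupied) / n_bins
}

# relabel ACTIVE runs of <= max_epochs flanked by INACTIVE on both sides
merge_active_blips <- function(state, max_epochs) {
  if (max_epochs <= 0) return(state)
  r <- rle(state)
  nv <- length(r$values)
  for (i in seq_len(nv)) {
    if (r$values[i] == "ACTIVE" && r$lengths[i] <= max_epochs &&
        i > 1 && i < nv &&
        r$values[i - 1] == "INACTIVE" && r$values[i + 1] == "INACTIVE") {
      r$values[i] <- "INACTIVE"
    }
  }
  inverse.rle(r)
}

#' Sleep-duration estimate for one 24-hour window
#'
#' Extracts maximal inactive runs from the bridged epoch states
#' intersected with the window and converts them to hours. Under the
#' default `longest_bout` policy the estimate is the duration of the
#' longest inactive run (the main rest period, a proxy for time in bed);
#' under `sum_min_bout` it is the total duration of inactive runs of at
#' least `min_bout_minutes`. The window is included only when its
#' coverage meets `coverage_threshold`.
#'
#' @param states Bridged epoch states ([bridge_missing()] output).
#' @param window_start Window start (ms).
#' @param coverage Coverage fraction for the window
#'   ([compute_coverage()]).
#' @param policy `"longest_bout"` or `"sum_min_bout"`.
#' @param min_bout_minutes Minimum bout length for `"sum_min_bout"`.
#' @param coverage_threshold Inclusion threshold.
#' @param epoch_seconds Epoch length used to build `states`.
#' @return One-row tibble `window_start, coverage, sleep_hours,
#'   included`.
#' @export
estimate_window_sleep <- function(states, window_start, coverage,
                                  policy = c("longest_bout", "sum_min_bout"),
                                  min_bout_minutes = 30,
                                  coverage_threshold = 0.6,
                                  epoch_seconds = 60) {
  policy <- match.arg(policy)
  ep_ms <- epoch_seconds * 1000
  win <- states$epoch_start >= window_start &
    states$epoch_start < window_start + MS_DAY
  s <- states$state[win]
  sleep_hours <- 0
  if (length(s) > 0) {
    r <- rle(s)
    inact <- r$lengths[r$values == "INACTIVE"]
    if (length(inact) > 0) {
      ep_h <- epoch_seconds / 3600
      sleep_hours <- switch(policy,
        longest_bout = max(inact) * ep_h,
        sum_min_bout = sum(inact[inact * epoch_seconds / 60 >=
                                   min_bout_minutes]) * ep_h
      )
    }
  }
  tibble::tibble(
    window_start = window_start,
    coverage = coverage,
    sleep_hours = sleep_hours,
    included = coverage >= coverage_threshold
  )
}

#' Per-participant passive sleep estimates
#'
#' Runs the full estimation chain for one participant: jerk series, an
#' Otsu threshold fitted (by default) once over all of the participant's
#' jerk values, epoch classification fused with device on-events over
#' the whole recording span, missingness bridging, and one
#' coverage-filtered sleep estimate per noon-anchored 24-hour window
#' intersecting the data span. Deterministic given inputs and
#' configuration.
#'
#' @param samples Accelerometer tibble ([read_accelerometer()]).
#' @param events Device-event tibble ([read_device_events()]); may be
#'   empty.
#' @param config A [sleep_config()].
#' @return Tibble `participant, window_start, coverage, sleep_hours,
#'   included, tau`. `window_start` is the local-clock anchor in ms
#'   (UTC ms plus the configured timezone offset). A participant with
#'   zero valid windows yields zero included rows plus a warning.
#' @export
estimate_participant <- function(samples, events = NULL,
                                 config = sleep_config()) {
  participant <- if (nrow(samples) > 0) samples$participant[1] else NA_character_
  empty <- tibble::tibble(participant = character(), window_start = numeric(),
                          coverage = numeric(), sleep_hours = numeric(),
                          included = logical(), tau = numeric())
  if (nrow(samples) < 2) {
    warning("participant ", participant,
            ": fewer than 2 accelerometer samples, no windows estimated")
    return(empty)
  }
  if (is.null(events)) {
    events <- tibble::tibble(participant = character(), t = numeric(),
                             screen = character(), lock = character())
  }
  off_ms <- config$tz_offset_minutes * 60000
  tl <- samples$t + off_ms                 # local clock ms
  ev <- events
  ev$t <- ev$t + off_ms

  jerk <- compute_jerk_series(
    tibble::tibble(t = tl, x = samples$x, y = samples$y, z = samples$z),
    max_gap_seconds = config$max_gap_seconds
  )
  anchor_ms <- config$anchor_hour * MS_HOUR
  ws0 <- floor((min(tl) - anchor_ms) / MS_DAY) * MS_DAY + anchor_ms
  n_win <- as.integer(ceiling((max(tl) - ws0) / MS_DAY))
  n_win <- max(n_win, 1L)
  window_starts <- ws0 + (seq_len(n_win) - 1) * MS_DAY

  fit_tau <- function(jvals) {
    otsu_threshold(jvals, bins = config$otsu_bins,
                   transform = config$transform,
                   log_epsilon = config$log_epsilon)
  }

  estimate_with <- function(states, tau_num) {
    states$state <- merge_active_blips(
      states$state, config$merge_active_blips_minutes * 60 / config$epoch_seconds)
    rows <- lapply(window_starts, function(ws) {
      cov <- compute_coverage(tl, ws, 24, config$bin_seconds)
      est <- estimate_window_sleep(
        states, ws, cov, policy = config$policy,
        min_bout_minutes = config$min_bout_minutes,
        coverage_threshold = config$coverage_threshold,
        epoch_seconds = config$epoch_seconds)
      est
    })
    out <- dplyr::bind_rows(rows)
    out$tau <- tau_num
    out
  }

  if (config$threshold_scope == "participant") {
    tau <- tryCatch(fit_tau(jerk$j), error = function(e) {
      warning("participant ", participant, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(tau)) return(empty)
    states <- classify_epochs(jerk, ev, tau, config$epoch_seconds,
                              ws0, ws0 + n_win * MS_DAY)
    states <- bridge_missing(states)
    out <- estimate_with(states, tau$tau)
  } else {
    # per-day threshold: fit, classify and bridge within each window
    rows <- lapply(window_starts, function(ws) {
      jw <- jerk[jerk$t >= ws & jerk$t < ws + MS_DAY, ]
      cov <- compute_coverage(tl, ws, 24, config$bin_seconds)
      tau <- tryCatch(fit_tau(jw$j), error = function(e) NULL)
      if (is.null(tau)) {
        return(tibble::tibble(window_start = ws, coverage = cov,
                              sleep_hours = 0, included = FALSE,
                              tau = NA_real_))
      }
      st <- bridge_missing(classify_epochs(jw, ev, tau, config$epoch_seconds,
                                           ws, ws + MS_DAY))
      st$state <- merge_active_blips(
        st$state, config$merge_active_blips_minutes * 60 / config$epoch_seconds)
      est <- estimate_window_sleep(
        st, ws, cov, policy = config$policy,
        min_bout_minutes = config$min_bout_minutes,
        coverage_threshold = config$coverage_threshold,
        epoch_seconds = config$epoch_seconds)
      est$tau <- tau$tau
      est
    })
    out <- dplyr::bind_rows(rows)
  }

  out <- tibble::tibble(participant = participant, out)
  if (!any(out$included)) {
    warning("participant ", participant, ": zero windows meet the coverage ",
            "threshold (", config$coverage_threshold, ")")
  }
  out
}
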