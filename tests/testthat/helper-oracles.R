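# Shared fixtures and independent oracles used across the suite.

MS_DAY <- 86400000
MS_HOUR <- 3600000

# timestamp in ms since epoch for a date string plus clock hours
ms_at <- function(date, hour = 0) {
  as.numeric(as.Date(date)) * MS_DAY + hour * MS_HOUR
}

# brute-force Otsu oracle: for every candidate boundary, compute the
# weighted sum of within-class variances of the histogram directly and
# scan for the minimum (lowest boundary on ties). Returns the boundary
# index and the implied class assignment of the input values.
oracle_otsu <- function(values, bins, transform = "linear", eps = 1e-6) {
  v <- if (transform == "log10") log10(values + eps) else values
  breaks <- seq(min(v), max(v), length.out = bins + 1)
  idx <- pmin(findInterval(v, breaks), bins)
  counts <- tabulate(idx, nbins = bins)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  p <- counts / sum(counts)
  best_k <- NA_integer_
  best <- Inf
  for (k in seq_len(bins - 1)) {
    i0 <- 1:k
    i1 <- (k + 1):bins
    w0 <- sum(p[i0])
    w1 <- sum(p[i1])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[i0] * mids[i0]) / w0
    mu1 <- sum(p[i1] * mids[i1]) / w1
    var0 <- sum(p[i0] * (mids[i0] - mu0)^2) / w0
    var1 <- sum(p[i1] * (mids[i1] - mu1)^2) / w1
    crit <- w0 * var0 + w1 * var1
    if (crit < best) {
      best <- crit
      best_k <- k
    }
  }
  list(boundary = best_k, lower_class = idx <= best_k)
}

# random positive value samples with varied shapes for threshold tests
random_jerk_sample <- function(n = 200) {
  shape <- sample(1:3, 1)
  if (shape == 1) {
    c(10^rnorm(n / 2, -1.5, 0.3), 10^rnorm(n / 2, 0, 0.3))
  } else if (shape == 2) {
    rexp(n, rate = runif(1, 0.5, 5))
  } else {
    runif(n, 0, runif(1, 1, 10))
  }
}

# epoch-state tibble from a compact string like "AIMMA"
make_states <- function(code, epoch_seconds = 60, start = 0) {
  map <- c(A = "ACTIVE", I = "INACTIVE", M = "MISSING")
  s <- map[strsplit(code, "")[[1]]]
  tibble::tibble(epoch_start = start + (seq_along(s) - 1) * epoch_seconds * 1000,
                 state = unname(s))
}

state_code <- function(states) {
  paste(c(ACTIVE = "A", INACTIVE = "I", MISSING = "M")[states$state],
        collapse = "")
}

# constant-acceleration sample stream at a given rate
flat_accel <- function(t0, n, rate_hz = 1, participant = "p1") {
  t <- t0 + (seq_len(n) - 1) * 1000 / rate_hz
  tibble::tibble(participant = participant, t = t, x = 0, y = 0, z = 1)
}

empty_events <- function() {
  tibble::tibble(participant = character(), t = numeric(),
                 screen = character(), lock = character())
}

# match included sleep estimates to generator truth by night key
recovery_errors <- function(person, config = sleep_config()) {
  est <- suppressWarnings(estimate_participant(person$accel, person$events,
                                               config))
  est <- est[est$included, ]
  if (nrow(est) == 0) return(numeric(0))
  m <- merge(
    data.frame(night = night_of_window(est$window_start),
               est_h = est$sleep_hours),
    data.frame(night = person$truth_nights$night,
               true_h = person$truth_nights$true_hours))
  abs(m$est_h - m$true_h)
}
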