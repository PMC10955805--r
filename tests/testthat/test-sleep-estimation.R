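# Jerk differencing, Otsu thresholding, epoch classification,
# missingness bridging, coverage and window estimation.

test_that("jerk of constant acceleration is zero and gaps are skipped", {
  a <- flat_accel(0, 10, rate_hz = 1)
  j <- compute_jerk_series(a)
  expect_equal(nrow(j), 9)
  expect_true(all(j$j == 0))

  # unit ramp: x = t in g with 1 s spacing gives 1 g/s at every pair
  ramp <- tibble::tibble(participant = "p", t = c(0, 1000, 2000),
                         x = c(0, 1, 2), y = 0, z = 0)
  jr <- compute_jerk_series(ramp)
  expect_equal(jr$j, c(1, 1))
  expect_equal(jr$t, c(500, 1500))

  # irregular spacing: only the pair within max_gap survives
  irr <- tibble::tibble(participant = "p", t = c(0, 200, 10000),
                        x = c(0, 0.2, 5), y = 0, z = 0)
  ji <- compute_jerk_series(irr, max_gap_seconds = 1)
  expect_equal(nrow(ji), 1)
  expect_equal(ji$j, 0.2 / 0.2)

  expect_equal(nrow(compute_jerk_series(flat_accel(0, 1))), 0)
  expect_error(compute_jerk_series(
    tibble::tibble(participant = "p", t = c(1000, 1000), x = 0, y = 0, z = 1)),
    "strictly increasing")
})

test_that("otsu threshold separates a two-point distribution", {
  tau <- otsu_threshold(c(0, 0, 0, 1, 1, 1), bins = 2, transform = "linear")
  expect_gt(tau$tau, 0)
  expect_lt(tau$tau, 1)
  expect_error(otsu_threshold(rep(3, 10), transform = "linear"),
               "degenerate")
})

test_that("otsu agrees with the exhaustive within-class-variance scan", {
  set.seed(101)
  for (i in 1:200) {
    v <- random_jerk_sample(sample(50:400, 1))
    bins <- sample(2:64, 1)
    got <- otsu_threshold(v, bins = bins, transform = "linear")
    want <- oracle_otsu(v, bins = bins, transform = "linear")
    expect_identical(v <= got$tau, want$lower_class,
                     label = paste("histogram", i, "bins", bins))
  }
})

test_that("otsu separates two well-spaced gaussian populations", {
  set.seed(102)
  lo <- rnorm(5000, 0.1, 0.01)
  hi <- rnorm(5000, 5, 0.5)
  tau <- otsu_threshold(c(lo, hi), bins = 256, transform = "linear")
  misassigned <- sum(lo > tau$tau) + sum(hi <= tau$tau)
  expect_lt(misassigned / 10000, 0.001)
})

test_that("epochs are classified by jerk, on-events and data presence", {
  hour <- 3600000
  # every epoch has jerk above threshold
  jerk <- tibble::tibble(t = seq(0, hour - 1000, by = 30000), j = 2)
  st <- classify_epochs(jerk, empty_events(), tau = 1, epoch_seconds = 60,
                        span_start = 0, span_end = hour)
  expect_equal(nrow(st), 60)
  expect_true(all(st$state == "ACTIVE"))

  # all jerk at/below threshold, one unlock at minute 30 wakes its epoch
  jerk2 <- tibble::tibble(t = seq(0, hour - 1000, by = 30000), j = 0.5)
  ev <- tibble::tibble(participant = "p", t = 30.5 * 60000,
                       screen = "on", lock = "unlocked")
  st2 <- classify_epochs(jerk2, ev, tau = 1, epoch_seconds = 60,
                         span_start = 0, span_end = hour)
  expect_equal(sum(st2$state == "ACTIVE"), 1)
  expect_equal(which(st2$state == "ACTIVE"), 31)
  expect_true(all(st2$state[-31] == "INACTIVE"))

  # no data at all: one hour of missing epochs
  st3 <- classify_epochs(tibble::tibble(t = numeric(), j = numeric()),
                         empty_events(), tau = 1, epoch_seconds = 60,
                         span_start = 0, span_end = hour)
  expect_true(all(st3$state == "MISSING"))
  expect_equal(nrow(st3), 60)
})

test_that("only transitions into screen-on or unlocked count as on-events", {
  hour <- 3600000
  jerk <- tibble::tibble(t = seq(0, hour - 1000, by = 30000), j = 0.1)
  # first event shows an on state (counts); repeat of same state does not
  ev <- tibble::tibble(participant = "p",
                       t = c(10.5, 20.5) * 60000,
                       screen = c("on", "on"), lock = c("locked", "locked"))
  st <- classify_epochs(jerk, ev, tau = 1, epoch_seconds = 60,
                        span_start = 0, span_end = hour)
  expect_equal(st$state[11], "ACTIVE")
  expect_equal(st$state[21], "INACTIVE")  # event present but no transition
  # off event after on: presence only
  ev2 <- tibble::tibble(participant = "p",
                        t = c(10.5, 20.5) * 60000,
                        screen = c("on", "off"), lock = c("unlocked", "locked"))
  st2 <- classify_epochs(jerk, ev2, tau = 1, epoch_seconds = 60,
                         span_start = 0, span_end = hour)
  expect_equal(st2$state[21], "INACTIVE")
})

test_that("bridging follows the neighbour-state rules", {
  # matching neighbours adopt the shared state; mismatches become
  # inactive (resumed data collection implies user activity)
  expect_equal(state_code(bridge_missing(make_states("IMMMI"))), "IIIII")
  expect_equal(state_code(bridge_missing(make_states("AMMMA"))), "AAAAA")
  expect_equal(state_code(bridge_missing(make_states("IMMMA"))), "IIIIA")
  expect_equal(state_code(bridge_missing(make_states("AMMMI"))), "AIIII")
  # leading/trailing gaps have one observed neighbour only and remain
  expect_equal(state_code(bridge_missing(make_states("MMIAM"))), "MMIAM")
  expect_equal(state_code(bridge_missing(make_states("MMMMM"))), "MMMMM")
})

test_that("bridging properties hold on random state sequences", {
  set.seed(103)
  for (i in 1:100) {
    code <- paste(sample(c("A", "I", "M"), 40, replace = TRUE),
                  collapse = "")
    before <- make_states(code)
    after <- bridge_missing(before)
    # observed epochs never change
    obs <- before$state != "MISSING"
    expect_identical(after$state[obs], before$state[obs])
    # bridging never reduces observed (non-missing) time
    expect_gte(sum(after$state != "MISSING"), sum(obs))
    # interior gaps are filled; only edge gaps may remain
    miss <- which(after$state == "MISSING")
    if (length(miss) > 0) {
      first_obs <- match(TRUE, obs)
      last_obs <- length(obs) + 1 - match(TRUE, rev(obs))
      expect_true(all(miss < first_obs | miss > last_obs))
    }
    # a gap with mismatched neighbours never becomes active
    r <- rle(before$state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (r$values[k] == "MISSING" && k > 1 && k < length(r$values) &&
          r$values[k - 1] != r$values[k + 1]) {
        expect_true(all(after$state[starts[k]:ends[k]] == "INACTIVE"))
      }
    }
  }
})

test_that("coverage counts occupied 5-second bins", {
  ws <- 0
  full <- ws + (0:17279) * 5000
  expect_identical(compute_coverage(full, ws), 1)
  expect_identical(compute_coverage(full[1:8640], ws), 0.5)
  expect_identical(compute_coverage(numeric(0), ws), 0)
  # sampling anywhere at 0.2 Hz or faster fills every bin
  t02 <- ws + seq(0, MS_DAY - 5000, by = 5000) + 2500
  expect_identical(compute_coverage(t02, ws), 1)
})

test_that("window inclusion flips exactly at the 60% coverage boundary", {
  ws <- 0
  states <- make_states(paste(rep("I", 1440), collapse = ""))
  just_below <- compute_coverage(ws + (0:10366) * 5000, ws)
  just_at <- compute_coverage(ws + (0:10367) * 5000, ws)
  est_below <- estimate_window_sleep(states, ws, just_below)
  est_at <- estimate_window_sleep(states, ws, just_at)
  expect_false(est_below$included)
  expect_true(est_at$included)
})

test_that("sleep policies aggregate inactive bouts as specified", {
  # a single 8 h inactive run, remainder active
  code <- paste(c(rep("A", 480), rep("I", 480), rep("A", 480)), collapse = "")
  est <- estimate_window_sleep(make_states(code), 0, coverage = 1)
  expect_equal(est$sleep_hours, 8)
  expect_true(est$included)

  # low coverage excludes regardless of the states
  est59 <- estimate_window_sleep(make_states(code), 0, coverage = 0.59)
  expect_false(est59$included)

  # 6 h and 1 h runs: longest bout takes the main rest period,
  # sum-of-bouts with a 30 min floor adds both
  code2 <- paste(c(rep("I", 360), rep("A", 600), rep("I", 60),
                   rep("A", 420)), collapse = "")
  st2 <- make_states(code2)
  expect_equal(estimate_window_sleep(st2, 0, 1,
                                     policy = "longest_bout")$sleep_hours, 6)
  expect_equal(estimate_window_sleep(st2, 0, 1, policy = "sum_min_bout",
                                     min_bout_minutes = 30)$sleep_hours, 7)
  # a 10-minute bout falls under the floor
  code3 <- paste(c(rep("I", 360), rep("A", 600), rep("I", 10),
                   rep("A", 470)), collapse = "")
  expect_equal(estimate_window_sleep(make_states(code3), 0, 1,
                                     policy = "sum_min_bout",
                                     min_bout_minutes = 30)$sleep_hours, 6)
})

test_that("raising the threshold can only extend inactivity", {
  set.seed(104)
  hour <- 3600000
  jerk <- tibble::tibble(t = sort(runif(2000, 0, 6 * hour)),
                         j = rexp(2000, 1))
  taus <- sort(runif(8, 0, 4))
  prev_states <- NULL
  prev_sleep <- -Inf
  for (tau in taus) {
    st <- classify_epochs(jerk, empty_events(), tau, 60, 0, 6 * hour)
    if (!is.null(prev_states)) {
      # ACTIVE can flip to INACTIVE with larger tau, never the reverse
      expect_false(any(prev_states == "INACTIVE" & st$state == "ACTIVE"))
    }
    sl <- estimate_window_sleep(bridge_missing(st), 0, 1)$sleep_hours
    expect_gte(sl, prev_sleep)
    prev_states <- st$state
    prev_sleep <- sl
  }
})

test_that("participant estimation recovers construction-time sleep", {
  cfg <- cohort_config(n_participants = 1, n_days = 3, sample_rate_hz = 1,
                       sd_within = 0, sd_between = 0, sd_bedtime_hour = 0,
                       mean_duration_h = 8, missingness = FALSE, seed = 21)
  p <- generate_participant(cfg, 1)
  est <- estimate_participant(p$accel, p$events, sleep_config())
  expect_equal(nrow(est), 3)
  expect_true(all(est$included))
  expect_true(all(abs(est$sleep_hours - 8) <= 2 / 60))
  # determinism: identical inputs give identical output
  est2 <- estimate_participant(p$accel, p$events, sleep_config())
  expect_identical(est, est2)
})

test_that("a participant without usable data yields no windows", {
  expect_warning(
    out <- estimate_participant(flat_accel(0, 1), empty_events()),
    "fewer than 2")
  expect_equal(nrow(out), 0)
  # constant acceleration: zero jerk everywhere is degenerate
  expect_warning(
    out2 <- estimate_participant(flat_accel(0, 5000), empty_events()),
    "degenerate|identical")
  expect_equal(nrow(out2), 0)
})
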