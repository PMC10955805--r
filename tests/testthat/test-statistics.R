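# Correlation matrix, random-intercept mixed model, LOOCV predictor.

test_that("correlation matrix matches the direct Pearson formula", {
  set.seed(501)
  n <- 65
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(n)
  cm <- correlation_matrix(tibble::tibble(x = x, y = y, neg = -x))
  # identities
  expect_equal(unname(diag(cm$r)), c(1, 1, 1))
  expect_equal(cm$r["x", "neg"], -1)
  expect_identical(cm$r, t(cm$r))
  expect_lt(abs(cm$r["x", "y"] - 0.8), 0.15)
  # textbook formula oracle
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_manual <- r_manual * sqrt((n - 2) / (1 - r_manual^2))
  p_manual <- 2 * pt(-abs(t_manual), n - 2)
  expect_equal(cm$r["x", "y"], r_manual, tolerance = 1e-12)
  expect_equal(cm$p["x", "y"], p_manual, tolerance = 1e-12)
})

test_that("constant and short series are reported as undefined", {
  d <- tibble::tibble(x = c(1, 2, 3, 4), const = 2,
                      holey = c(1, NA, NA, NA))
  cm <- correlation_matrix(d)
  expect_true(is.na(cm$r["x", "const"]))
  row <- cm$table[cm$table$var1 == "x" & cm$table$var2 == "const", ]
  expect_match(row$note, "constant")
  row2 <- cm$table[cm$table$var1 == "x" & cm$table$var2 == "holey", ]
  expect_match(row2$note, "fewer than")
})

test_that("pairwise and complete pairing differ only with missing data", {
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = c(1.1, 2, 2.9, 4.2, 5),
                      z = c(2, NA, 3, 4, 5))
  pw <- correlation_matrix(d, pairing = "pairwise")
  cp <- correlation_matrix(d, pairing = "complete")
  expect_equal(pw$n["x", "y"], 5)
  expect_equal(cp$n["x", "y"], 4)  # row with missing z dropped
  expect_equal(pw$n["x", "z"], cp$n["x", "z"])
})

test_that("mixed model recovers an exact linear outcome", {
  set.seed(502)
  s <- simulate_psqi_windows(n_participants = 20, n_windows = 4,
                             random_sd = 0, resid_sd = 0,
                             round_psqi = FALSE)
  # a zero-variance outcome trips lme4's convergence heuristics; the
  # point estimates are still exact
  m <- suppressWarnings(fit_mixed_model(s$records))
  expect_equal(m$table$estimate, c(3, 0.2, 0.4, -0.3), tolerance = 1e-6)
  expect_equal(m$n_obs, 80)
  expect_equal(m$n_groups, 20)
})

test_that("zero between-participant variance is flagged, not fatal", {
  set.seed(509)
  # every participant carries identical records, so the between-group
  # variance is exactly zero and the fit sits on the boundary
  one <- simulate_psqi_windows(n_participants = 1, n_windows = 6,
                               random_sd = 0, resid_sd = 0.5,
                               round_psqi = FALSE)$records
  rec <- dplyr::bind_rows(lapply(1:6, function(i) {
    r <- one
    r$participant <- sprintf("p%03d", i)
    r
  }))
  m <- fit_mixed_model(rec)
  expect_true(m$singular)
  expect_lt(m$ranef_var, 1e-8)
})

test_that("mixed model output is labelled like the reporting table", {
  set.seed(503)
  s <- simulate_psqi_windows(n_participants = 10, n_windows = 3)
  m <- fit_mixed_model(s$records)
  expect_equal(m$table$label,
               c("Intercept", "Active sleep quality",
                 "Active sleep duration", "Sleep duration estimate"))
  expect_true(all(m$table$se > 0))
  init <- setNames(sample(2:8, 10, replace = TRUE),
                   unique(s$records$participant))
  m2 <- fit_mixed_model(
    dplyr::mutate(s$records, initial_psqi = init[participant]),
    include_initial_psqi = TRUE)
  expect_true("Initial PSQI" %in% m2$table$label)
})

test_that("fixed effects are invariant to participant relabeling", {
  set.seed(504)
  s <- simulate_psqi_windows(n_participants = 15, n_windows = 4)
  m1 <- fit_mixed_model(s$records)
  rec2 <- s$records
  rec2$participant <- paste0("zz_", rev(rec2$participant))
  m2 <- fit_mixed_model(rec2)
  expect_equal(m1$table$estimate, m2$table$estimate, tolerance = 1e-8)
})

test_that("with no between-participant variance the fit matches pooled OLS", {
  set.seed(505)
  s <- simulate_psqi_windows(n_participants = 30, n_windows = 4,
                             random_sd = 0, round_psqi = FALSE)
  m <- fit_mixed_model(s$records)
  ols <- lm(psqi ~ mean_active_quality + mean_active_duration +
              mean_passive_duration, data = s$records)
  expect_equal(m$table$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("loocv interpolates a noise-free linear outcome", {
  set.seed(506)
  s <- simulate_psqi_windows(n_participants = 12, n_windows = 3,
                             random_sd = 0, resid_sd = 0,
                             round_psqi = FALSE)
  l <- loocv_linear_model(s$records)
  expect_lt(l$mae, 1e-8)
  expect_equal(l$n_predicted, 36)
  expect_equal(l$n_skipped, 0)
})

test_that("each held-out unit is predicted without its own data", {
  set.seed(507)
  s <- simulate_psqi_windows(n_participants = 12, n_windows = 3,
                             random_sd = 0, resid_sd = 0,
                             round_psqi = FALSE)
  rec <- s$records
  rec$psqi[1] <- rec$psqi[1] + 50  # gross outlier
  l <- loocv_linear_model(rec)
  out_err <- abs(l$predictions$error[1])
  rest <- abs(l$predictions$error[-1])
  # had the outlier been in its own training fold, OLS would fit it
  expect_gt(out_err, 40)
  expect_lt(max(rest), out_err / 4)

  # participant-level folds hold out all of a participant's records
  lp <- loocv_linear_model(rec, unit = "participant")
  errs_p1 <- abs(lp$predictions$error[lp$predictions$participant == "p001"])
  expect_gt(max(errs_p1), 40)
})

test_that("loocv error approaches the folded-normal mean", {
  set.seed(508)
  n_p <- 67
  s <- simulate_psqi_windows(n_participants = n_p, n_windows = 4,
                             random_sd = 0, resid_sd = 1.2,
                             round_psqi = FALSE)
  l <- loocv_linear_model(s$records)
  expect_equal(l$n_predicted, 268)
  expect_lt(abs(l$mae - 1.2 * sqrt(2 / pi)) / (1.2 * sqrt(2 / pi)), 0.1)
})
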