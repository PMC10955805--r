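# Statistical layer: Pearson correlation matrix over participant-level
# means, random-intercept mixed linear regression of weekly PSQI, and a
# leave-one-out cross-validated linear PSQI predictor.

#' Pearson correlation matrix with p-values
#'
#' Computes the Pearson coefficient for every pair of numeric columns
#' over jointly available observations, with a two-sided p-value from
#' the t distribution with n-2 degrees of freedom. A constant series
#' has no defined correlation; such cells are reported as `NA` with the
#' reason recorded in the tidy table.
#'
#' @param data Tibble of numeric series (one column per variable;
#'   non-numeric columns are dropped).
#' @param pairing `"pairwise"` uses, for each cell, the rows where both
#'   members of the pair are present; `"complete"` first restricts to
#'   rows complete across all variables.
#' @param min_n Minimum number of complete pairs to report a
#'   correlation.
#' @return An object of class `"sleep_cor_matrix"`: list with square
#'   matrices `r`, `p`, `n` and a tidy tibble `table`
#'   (`var1, var2, r, p, n, note`).
#' @export
correlation_matrix <- function(data, pairing = c("pairwise", "complete"),
                               min_n = 3) {
  pairing <- match.arg(pairing)
  num <- data[, vapply(data, is.numeric, TRUE), drop = FALSE]
  if (pairing == "complete") num <- num[complete.cases(num), , drop = FALSE]
  vars <- names(num)
  k <- length(vars)
  stopifnot(k >= 2)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  rows <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i > j) next
      xi <- num[[i]]; xj <- num[[j]]
      ok <- !is.na(xi) & !is.na(xj)
      nn <- sum(ok)
      n[i, j] <- n[j, i] <- nn
      note <- NA_character_
      if (i == j) {
        r[i, j] <- 1; p[i, j] <- 0
      } else if (nn < min_n) {
        note <- "fewer than min_n complete pairs"
      } else if (sd(xi[ok]) == 0 || sd(xj[ok]) == 0) {
        note <- "constant series: correlation undefined"
      } else {
        ct <- suppressWarnings(stats::cor.test(xi[ok], xj[ok]))
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
      if (i < j) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          var1 = vars[i], var2 = vars[j], r = r[i, j], p = p[i, j],
          n = nn, note = note)
      }
    }
  }
  structure(list(r = r, p = p, n = n, table = dplyr::bind_rows(rows),
                 pairing = pairing),
            class = "sleep_cor_matrix")
}

#' @export
print.sleep_cor_matrix <- function(x, ...) {
  cat("Pearson correlation matrix (", x$pairing, " pairing)\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}

# display labels for the default PSQI predictor set
term_label <- function(term) {
  labels <- c(
    "(Intercept)" = "Intercept",
    mean_active_quality = "Active sleep quality",
    mean_active_duration = "Active sleep duration",
    mean_passive_duration = "Sleep duration estimate",
    initial_psqi = "Initial PSQI"
  )
  out <- unname(labels[term])
  out[is.na(out)] <- term[is.na(out)]
  out
}

#' Random-intercept mixed linear regression of weekly PSQI
#'
#' Fits `psqi ~ fixed terms + (1 | participant)`: each participant may
#' report a different baseline PSQI, so the participant is a random
#' effect on the intercept while the relationships between each
#' predictor and PSQI are fixed effects. Estimation is REML by default;
#' p-values use Satterthwaite degrees of freedom.
#'
#' @param records PSQI window records ([build_psqi_windows()]); rows
#'   with incomplete predictors are dropped.
#' @param terms Character vector of fixed-effect column names. The
#'   default is the weekly-averaged daily sleep quality, daily sleep
#'   duration, and passive sleep-duration estimate.
#' @param response Response column name.
#' @param include_initial_psqi Add each participant's first PSQI score
#'   as an additional fixed effect.
#' @param reml Use REML (default) or ML.
#' @return Object of class `"psqi_mixed_model"`: list with `table`
#'   (tibble `term, label, estimate, se, df, statistic, p`),
#'   `ranef_var` (random-intercept variance), `resid_var`, `n_obs`,
#'   `n_groups`, `singular` flag and the underlying `model`.
#' @export
fit_mixed_model <- function(records,
                            terms = c("mean_active_quality",
                                      "mean_active_duration",
                                      "mean_passive_duration"),
                            response = "psqi",
                            include_initial_psqi = FALSE,
                            reml = TRUE) {
  if (include_initial_psqi) terms <- c(terms, "initial_psqi")
  cols <- c("participant", response, terms)
  stopifnot(all(cols %in% names(records)))
  d <- records[complete.cases(records[, cols]), cols]
  grp <- table(d$participant)
  if (length(grp) < 2 || sum(grp >= 2) < 2) {
    stop("need at least 2 participants with at least 2 records each",
         call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    response, "~", paste(terms, collapse = " + "), "+ (1 | participant)"))
  fit <- lmerTest::lmer(fml, data = d, REML = reml)
  cf <- summary(fit)$coefficients
  tab <- tibble::tibble(
    term = rownames(cf),
    label = term_label(rownames(cf)),
    estimate = unname(cf[, "Estimate"]),
    se = unname(cf[, "Std. Error"]),
    df = unname(cf[, "df"]),
    statistic = unname(cf[, "t value"]),
    p = unname(cf[, "Pr(>|t|)"])
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(table = tab,
         ranef_var = vc$vcov[vc$grp == "participant"],
         resid_var = vc$vcov[vc$grp == "Residual"],
         n_obs = nrow(d),
         n_groups = length(grp),
         singular = lme4::isSingular(fit),
         reml = reml,
         model = fit),
    class = "psqi_mixed_model"
  )
}

#' @export
print.psqi_mixed_model <- function(x, ...) {
  cat("Mixed linear regression of PSQI (random intercept per participant)\n")
  cat(x$n_obs, "observations,", x$n_groups, "participants; ",
      if (x$reml) "REML" else "ML",
      if (x$singular) "[singular fit]" else "", "\n")
  print(as.data.frame(x$table[, c("label", "estimate", "se", "p")]),
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Leave-one-out cross-validated linear PSQI predictor
#'
#' Fits an ordinary least squares model of PSQI on the chosen
#' predictors, leaving one unit out at a time: the held-out unit is a
#' single PSQI window record (default) or all records of one
#' participant. Each held-out observation is predicted by a model that
#' never saw it, and the mean absolute error over all predictions is
#' reported. Folds whose training design is rank deficient are flagged
#' and skipped.
#'
#' @inheritParams fit_mixed_model
#' @param unit `"record"` or `"participant"`.
#' @return Object of class `"psqi_loocv"`: list with `predictions`
#'   (tibble `participant, observed, predicted, error`), `mae`,
#'   `n_predicted`, `n_skipped`, `terms`.
#' @export
loocv_linear_model <- function(records,
                               terms = c("mean_active_quality",
                                         "mean_active_duration",
                                         "mean_passive_duration"),
                               response = "psqi",
                               unit = c("record", "participant")) {
  unit <- match.arg(unit)
  cols <- c("participant", response, terms)
  stopifnot(all(cols %in% names(records)))
  d <- records[complete.cases(records[, cols]), cols]
  if (nrow(d) < 3) stop("need at least 3 complete records", call. = FALSE)
  fml <- stats::as.formula(paste(response, "~",
                                 paste(terms, collapse = " + ")))
  folds <- if (unit == "record") as.list(seq_len(nrow(d))) else {
    split(seq_len(nrow(d)), d$participant)
  }
  preds <- list()
  n_skipped <- 0L
  for (f in folds) {
    train <- d[-f, , drop = FALSE]
    fit <- lm(fml, data = train)
    if (fit$rank < length(terms) + 1L) {
      n_skipped <- n_skipped + 1L
      next
    }
    ph <- predict(fit, newdata = d[f, , drop = FALSE])
    preds[[length(preds) + 1]] <- tibble::tibble(
      participant = d$participant[f],
      observed = d[[response]][f],
      predicted = unname(ph),
      error = unname(ph) - d[[response]][f])
  }
  if (length(preds) == 0) stop("all folds were rank deficient", call. = FALSE)
  pred <- dplyr::bind_rows(preds)
  structure(
    list(predictions = pred, mae = mean(abs(pred$error)),
         n_predicted = nrow(pred), n_skipped = n_skipped,
         unit = unit, terms = terms),
    class = "psqi_loocv"
  )
}

#' @export
print.psqi_loocv <- function(x, ...) {
  cat("LOOCV linear PSQI predictor (", x$unit, "-level folds)\n", sep = "")
  cat("predicted", x$n_predicted, "observations; MAE =",
      round(x$mae, 3), "\n")
  if (x$n_skipped > 0) cat(x$n_skipped, "rank-deficient fold(s) skipped\n")
  invisible(x)
}
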