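# Readers/writers for the pipeline's tabular interchange formats.
# CSV (headered, comma, "." decimal) is canonical; JSON-lines is also
# accepted since mobile-sensing exports vary. All timestamps are integer
# milliseconds since the Unix epoch, UTC.

DEVICE_STATES <- c("on_unlocked", "on_locked", "off_unlocked", "off_locked")

# default mapping from input state strings to the four-state product
default_state_map <- function() {
  setNames(DEVICE_STATES, DEVICE_STATES)
}

read_raw_table <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    return(tibble::tibble())
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^\\s*\\{", first)) {
    rows <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
    return(dplyr::bind_rows(lapply(rows, function(r) tibble::as_tibble(r))))
  }
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

# coerce a character column to numeric, reporting the first bad row
coerce_numeric <- function(df, col, path) {
  raw <- df[[col]]
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(num) & !is.na(raw) & nzchar(trimws(raw)))
  if (length(bad) > 0) {
    stop("parse error in ", path, ", column '", col, "', row ", bad[1],
         ": cannot interpret '", raw[bad[1]], "' as a number", call. = FALSE)
  }
  na <- which(is.na(num))
  if (length(na) > 0) {
    stop("parse error in ", path, ", column '", col, "', row ", na[1],
         ": empty value", call. = FALSE)
  }
  df[[col]] <- num
  df
}

#' Read an accelerometer stream
#'
#' Loads a per-participant accelerometer export with columns `t` (ms
#' since epoch, UTC) and `x`, `y`, `z` (acceleration components in g).
#' Rows are sorted by timestamp; exact duplicate rows are dropped, and
#' when duplicate timestamps carry differing values the first occurrence
#' is kept (sensor exports commonly contain duplicates).
#'
#' @param path CSV or JSON-lines file with columns `t,x,y,z`.
#' @param participant Participant identifier attached to every row.
#' @return A tibble with columns `participant, t, x, y, z`, `t` strictly
#'   increasing.
#' @export
read_accelerometer <- function(path, participant = "p1") {
  df <- read_raw_table(path)
  if (nrow(df) == 0) {
    return(tibble::tibble(participant = character(), t = numeric(),
                          x = numeric(), y = numeric(), z = numeric()))
  }
  require_columns(df, c("t", "x", "y", "z"), path)
  for (col in c("t", "x", "y", "z")) df <- coerce_numeric(df, col, path)
  if (!all(is.finite(df$t)) || !all(is.finite(c(df$x, df$y, df$z)))) {
    stop("parse error in ", path, ": non-finite sensor values", call. = FALSE)
  }
  df <- df[order(df$t), c("t", "x", "y", "z")]
  df <- df[!duplicated(df), ]          # exact duplicate rows
  df <- df[!duplicated(df$t), ]        # duplicate timestamps: keep first
  tibble::tibble(participant = participant, t = df$t,
                 x = df$x, y = df$y, z = df$z)
}

#' Read a device-state event stream
#'
#' Loads screen/lock events with columns `t` (ms, UTC) and `state`.
#' State strings are mapped onto the four-state product
#' \{on,off\} x \{locked,unlocked\} via `state_map`; unknown strings are
#' a parse error. An empty file is valid (a participant may have no
#' events) and yields an empty stream.
#'
#' @param path CSV or JSON-lines file with columns `t,state`.
#' @param participant Participant identifier.
#' @param state_map Named character vector mapping input state strings
#'   to the canonical names `on_unlocked`, `on_locked`, `off_unlocked`,
#'   `off_locked`.
#' @return A tibble with columns `participant, t, screen, lock`, sorted
#'   by `t`; `screen` in \{"on","off"\}, `lock` in
#'   \{"locked","unlocked"\}.
#' @export
read_device_events <- function(path, participant = "p1",
                               state_map = default_state_map()) {
  stopifnot(all(state_map %in% DEVICE_STATES))
  empty <- tibble::tibble(participant = character(), t = numeric(),
                          screen = character(), lock = character())
  df <- read_raw_table(path)
  if (nrow(df) == 0) return(empty)
  require_columns(df, c("t", "state"), path)
  df <- coerce_numeric(df, "t", path)
  unknown <- setdiff(unique(df$state), names(state_map))
  if (length(unknown) > 0) {
    stop("parse error in ", path, ": unknown device state(s) ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }
  canon <- unname(state_map[df$state])
  parts <- strsplit(canon, "_", fixed = TRUE)
  out <- tibble::tibble(
    participant = participant,
    t = df$t,
    screen = vapply(parts, `[[`, "", 1L),
    lock = vapply(parts, `[[`, "", 2L)
  )
  out[order(out$t), ]
}

SURVEY_INSTRUMENTS <- c("daily_duration", "daily_quality", "psqi")

#' Read survey records
#'
#' Loads active (self-reported) survey data with columns
#' `participant,t,instrument,score`. Recognized instruments:
#' `daily_duration` (hours slept the previous night, 0-24),
#' `daily_quality` (trouble sleeping, 0-10, higher is worse), and
#' `psqi` (weekly Pittsburgh Sleep Quality Index, 0-14, higher is
#' worse). Out-of-range scores are rejected.
#'
#' @param path CSV or JSON-lines file.
#' @return A tibble `participant, t, instrument, score` sorted by
#'   participant then `t`.
#' @export
read_surveys <- function(path) {
  df <- read_raw_table(path)
  if (nrow(df) == 0) {
    return(tibble::tibble(participant = character(), t = numeric(),
                          instrument = character(), score = numeric()))
  }
  require_columns(df, c("participant", "t", "instrument", "score"), path)
  df <- coerce_numeric(df, "t", path)
  df <- coerce_numeric(df, "score", path)
  bad_instr <- setdiff(unique(df$instrument), SURVEY_INSTRUMENTS)
  if (length(bad_instr) > 0) {
    stop("parse error in ", path, ": unrecognized instrument(s) ",
         paste(sQuote(bad_instr), collapse = ", "), call. = FALSE)
  }
  ranges <- list(daily_duration = c(0, 24), daily_quality = c(0, 10),
                 psqi = c(0, 14))
  for (ins in names(ranges)) {
    r <- ranges[[ins]]
    bad <- which(df$instrument == ins & (df$score < r[1] | df$score > r[2]))
    if (length(bad) > 0) {
      stop("range error in ", path, ", row ", bad[1], ": ", ins, " score ",
           df$score[bad[1]], " outside [", r[1], ", ", r[2], "]",
           call. = FALSE)
    }
  }
  out <- tibble::tibble(participant = as.character(df$participant),
                        t = df$t, instrument = df$instrument,
                        score = df$score)
  out[order(out$participant, out$t), ]
}

#' Write pipeline streams back to CSV
#'
#' Inverse of the readers: writing then reading any valid stream
#' reproduces it record for record.
#'
#' @param x Tibble as returned by the corresponding reader.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @name sensor_writers
NULL

#' @rdname sensor_writers
#' @export
write_accelerometer <- function(x, path) {
  readr::write_csv(x[, c("t", "x", "y", "z")], path, progress = FALSE)
  invisible(path)
}

#' @rdname sensor_writers
#' @export
write_device_events <- function(x, path) {
  out <- tibble::tibble(t = x$t, state = paste(x$screen, x$lock, sep = "_"))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname sensor_writers
#' @export
write_surveys <- function(x, path) {
  readr::write_csv(x[, c("participant", "t", "instrument", "score")], path,
                   progress = FALSE)
  invisible(path)
}
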