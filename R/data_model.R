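## Cohort container, delimited-text I/O, validation and row-level
## exclusion filters.
##
## A cohort is a plain list of three data frames (class "dews_cohort"):
##   observations: episode_id, timestamp (POSIXct UTC), heart_rate,
##                 resp_rate, sbp, temperature, spo2, o2_mode, o2_value,
##                 acvpu, scale2_label
##   events:       episode_id, timestamp, kind, csd_code
##   episodes:     episode_id, age, sex, chronic_resp_flag
## Observations are kept time-sorted within episode; duplicate timestamps
## keep file order (stable sort).

.obs_columns <- c("episode_id", "timestamp", "heart_rate", "resp_rate",
                  "sbp", "temperature", "spo2", "o2_mode", "o2_value",
                  "acvpu", "scale2_label")
.event_columns <- c("episode_id", "timestamp", "kind", "csd_code")
.acvpu_levels <- c("Alert", "Confused", "Voice", "Pain", "Unresponsive")
.o2_modes <- c("air", "flow", "concentration")
.event_kinds <- c("death", "icu_admission", "csd")

#' Parse ISO-8601 timestamps to absolute instants
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` with a numeric UTC offset (`+01:00`,
#' `+0100`) or `Z`. Comparisons downstream are in absolute time so the
#' 4 h / 24 h outcome horizons are unaffected by local-time conventions.
#'
#' @param x character vector of timestamps.
#' @return POSIXct vector in UTC; `NA` where unparseable.
#' @export
parse_timestamp <- function(x) {
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  # bare timestamps (no offset) are taken as UTC
  bare <- grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}:[0-9]{2}$", x)
  x[bare] <- paste0(x[bare], "+0000")
  as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S%z", tz = "UTC"))
}

#' Format absolute instants as ISO-8601 UTC
#' @param t POSIXct vector.
#' @return character vector `YYYY-MM-DDTHH:MM:SS+00:00`.
#' @export
format_timestamp <- function(t) {
  if (length(t) == 0L) return(character(0))
  paste0(format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), "+00:00")
}

.num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read a cohort from delimited text files
#'
#' Assembles admission episodes from an observations file and an events
#' file (comma-separated, header row, UTF-8). Observations are sorted by
#' timestamp within episode (stable for ties), and the episode-level
#' chronic-respiratory flag is derived: an episode is flagged iff any of
#' its observation sets carries `scale2_label = TRUE` ("O2 sats scale 2").
#'
#' Malformed rows (unparseable timestamp or numeric, unknown enumeration
#' level, oxygen value missing for flow/concentration mode) are collected
#' with their line numbers and dropped; if more than `max_bad_frac` of
#' rows fail the read aborts. A missing required column is always fatal.
#'
#' @param obs_path path to the observations file.
#' @param events_path path to the events file (may contain zero rows).
#' @param episodes_path optional episode metadata file
#'   (`episode_id, age, sex`).
#' @param max_bad_frac maximum tolerated fraction of malformed rows
#'   (default 0.1).
#' @return a `dews_cohort`: list of data frames `observations`, `events`,
#'   `episodes`, with attribute `row_errors` (data.frame of file, line,
#'   message).
#' @export
read_cohort <- function(obs_path, events_path, episodes_path = NULL,
                        max_bad_frac = 0.1) {
  obs_raw <- read.csv(obs_path, colClasses = "character",
                      na.strings = c("", "NA"), fileEncoding = "UTF-8")
  missing_cols <- setdiff(.obs_columns, names(obs_raw))
  if (length(missing_cols) > 0L) {
    stop("observations file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  errors <- list()
  note <- function(file, line, msg) {
    errors[[length(errors) + 1L]] <<- data.frame(
      file = file, line = line, message = msg, stringsAsFactors = FALSE)
  }

  n <- nrow(obs_raw)
  ts <- parse_timestamp(obs_raw$timestamp)
  bad <- logical(n)
  for (i in which(is.na(ts) & !is.na(obs_raw$timestamp))) {
    note(obs_path, i + 1L, "unparseable timestamp"); bad[i] <- TRUE
  }
  bad[is.na(obs_raw$timestamp)] <- TRUE
  num_fields <- c("heart_rate", "resp_rate", "sbp", "temperature", "spo2",
                  "o2_value")
  parsed <- list()
  for (f in num_fields) {
    v <- .num_or_na(obs_raw[[f]])
    mangled <- which(is.na(v) & !is.na(obs_raw[[f]]))
    for (i in mangled) {
      note(obs_path, i + 1L, paste0("non-numeric ", f)); bad[i] <- TRUE
    }
    parsed[[f]] <- v
  }
  bad_mode <- !is.na(obs_raw$o2_mode) & !(obs_raw$o2_mode %in% .o2_modes)
  for (i in which(bad_mode)) {
    note(obs_path, i + 1L, "unknown o2_mode"); bad[i] <- TRUE
  }
  bad_acvpu <- !is.na(obs_raw$acvpu) & !(obs_raw$acvpu %in% .acvpu_levels)
  for (i in which(bad_acvpu)) {
    note(obs_path, i + 1L, "unknown acvpu level"); bad[i] <- TRUE
  }
  o2_incons <- !is.na(obs_raw$o2_mode) & obs_raw$o2_mode != "air" &
    is.na(parsed$o2_value) & !bad
  for (i in which(o2_incons)) {
    note(obs_path, i + 1L, "o2_value absent for oxygen mode"); bad[i] <- TRUE
  }
  spo2_bad <- !is.na(parsed$spo2) & (parsed$spo2 < 0 | parsed$spo2 > 100)
  for (i in which(spo2_bad)) {
    note(obs_path, i + 1L, "spo2 outside [0,100]"); bad[i] <- TRUE
  }

  if (n > 0 && sum(bad) / n > max_bad_frac) {
    stop(sprintf("%d of %d observation rows malformed (> %.0f%%); aborting",
                 sum(bad), n, 100 * max_bad_frac), call. = FALSE)
  }

  keep <- !bad
  obs <- data.frame(
    episode_id   = obs_raw$episode_id[keep],
    timestamp    = ts[keep],
    heart_rate   = parsed$heart_rate[keep],
    resp_rate    = parsed$resp_rate[keep],
    sbp          = parsed$sbp[keep],
    temperature  = parsed$temperature[keep],
    spo2         = parsed$spo2[keep],
    o2_mode      = obs_raw$o2_mode[keep],
    o2_value     = parsed$o2_value[keep],
    acvpu        = obs_raw$acvpu[keep],
    scale2_label = tolower(obs_raw$scale2_label[keep]) %in%
      c("true", "t", "1", "yes"),
    stringsAsFactors = FALSE)
  # stable sort: episode, then timestamp; ties keep file order
  obs <- obs[order(obs$episode_id, obs$timestamp, method = "radix"), ,
             drop = FALSE]
  rownames(obs) <- NULL

  ev_raw <- read.csv(events_path, colClasses = "character",
                     na.strings = c("", "NA"), fileEncoding = "UTF-8")
  missing_ev <- setdiff(.event_columns, names(ev_raw))
  if (length(missing_ev) > 0L) {
    stop("events file is missing required column(s): ",
         paste(missing_ev, collapse = ", "), call. = FALSE)
  }
  ev_ts <- parse_timestamp(ev_raw$timestamp)
  ev_bad <- is.na(ev_ts) & nrow(ev_raw) > 0
  for (i in which(ev_bad)) note(events_path, i + 1L, "unparseable timestamp")
  kind_bad <- !is.na(ev_raw$kind) & !(ev_raw$kind %in% .event_kinds)
  for (i in which(kind_bad)) note(events_path, i + 1L, "unknown event kind")
  ev_keep <- !ev_bad & !kind_bad
  events <- data.frame(
    episode_id = ev_raw$episode_id[ev_keep],
    timestamp  = ev_ts[ev_keep],
    kind       = ev_raw$kind[ev_keep],
    csd_code   = ev_raw$csd_code[ev_keep],
    stringsAsFactors = FALSE)
  events <- events[order(events$episode_id, events$timestamp,
                         method = "radix"), , drop = FALSE]
  rownames(events) <- NULL

  ids <- unique(obs$episode_id)
  flag <- vapply(split(obs$scale2_label, obs$episode_id)[ids],
                 any, logical(1))
  episodes <- data.frame(episode_id = ids,
                         age = NA_real_, sex = NA_character_,
                         chronic_resp_flag = unname(flag),
                         stringsAsFactors = FALSE)
  if (!is.null(episodes_path)) {
    meta <- read.csv(episodes_path, colClasses = "character",
                     na.strings = c("", "NA"), fileEncoding = "UTF-8")
    m <- match(episodes$episode_id, meta$episode_id)
    if ("age" %in% names(meta)) episodes$age <- .num_or_na(meta$age)[m]
    if ("sex" %in% names(meta)) episodes$sex <- meta$sex[m]
  }

  err_df <- if (length(errors)) do.call(rbind, errors) else
    data.frame(file = character(), line = integer(), message = character(),
               stringsAsFactors = FALSE)
  structure(list(observations = obs, events = events, episodes = episodes),
            class = "dews_cohort", row_errors = err_df)
}

#' Write a cohort to delimited text files
#'
#' Inverse of [read_cohort()]: timestamps are written as ISO-8601 with an
#' explicit UTC offset, numerics with full precision, so that a
#' write-then-read round trip reproduces every field exactly.
#'
#' @param cohort a `dews_cohort`.
#' @param obs_path,events_path,episodes_path output paths;
#'   `episodes_path` may be `NULL` to skip metadata.
#' @return invisibly, the cohort.
#' @export
write_cohort <- function(cohort, obs_path, events_path,
                         episodes_path = NULL) {
  stopifnot(inherits(cohort, "dews_cohort"))
  obs <- cohort$observations
  out <- data.frame(
    episode_id = obs$episode_id,
    timestamp = format_timestamp(obs$timestamp),
    heart_rate = as.character(obs$heart_rate),
    resp_rate = as.character(obs$resp_rate),
    sbp = as.character(obs$sbp),
    temperature = as.character(obs$temperature),
    spo2 = as.character(obs$spo2),
    o2_mode = obs$o2_mode,
    o2_value = as.character(obs$o2_value),
    acvpu = obs$acvpu,
    scale2_label = ifelse(obs$scale2_label, "true", "false"),
    stringsAsFactors = FALSE)
  write.csv(out, obs_path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  ev <- cohort$events
  ev_out <- data.frame(episode_id = ev$episode_id,
                       timestamp = format_timestamp(ev$timestamp),
                       kind = ev$kind, csd_code = ev$csd_code,
                       stringsAsFactors = FALSE)
  write.csv(ev_out, events_path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  if (!is.null(episodes_path)) {
    ep <- cohort$episodes
    write.csv(data.frame(episode_id = ep$episode_id,
                         age = as.character(ep$age), sex = ep$sex,
                         stringsAsFactors = FALSE),
              episodes_path, row.names = FALSE, na = "", quote = FALSE,
              fileEncoding = "UTF-8")
  }
  invisible(cohort)
}

#' @export
print.dews_cohort <- function(x, ...) {
  cat(sprintf(
    "<dews_cohort> %d episodes, %d observation sets, %d events\n",
    nrow(x$episodes), nrow(x$observations), nrow(x$events)))
  n_err <- nrow(attr(x, "row_errors") %||% data.frame())
  if (n_err > 0) cat(sprintf("  %d malformed rows dropped on read\n", n_err))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Complete-case filter for observation sets
#'
#' Keeps observation sets with all seven clinical fields present: heart
#' rate, respiratory rate, systolic blood pressure, temperature, SpO2,
#' inspired oxygen (mode, plus a value when the mode is flow or
#' concentration — breathing air is a valid value, not missingness), and
#' consciousness level. The analysis downstream is complete-case only; no
#' imputation is performed. Order is preserved.
#'
#' @param obs observations data frame (as in a `dews_cohort`).
#' @return the subset of complete rows.
#' @export
filter_complete <- function(obs) {
  obs[is_complete_obs(obs), , drop = FALSE]
}

#' @rdname filter_complete
#' @return for `is_complete_obs`, a logical vector.
#' @export
is_complete_obs <- function(obs) {
  !is.na(obs$heart_rate) & !is.na(obs$resp_rate) & !is.na(obs$sbp) &
    !is.na(obs$temperature) & !is.na(obs$spo2) &
    !is.na(obs$o2_mode) & (obs$o2_mode == "air" | !is.na(obs$o2_value)) &
    !is.na(obs$acvpu)
}

#' Drop the first k observation sets of an episode
#'
#' Scoring targets de-novo deterioration during the stay, not illness
#' severity at admission, and several time-series features need at least
#' three prior observation sets; the first `k` (default two) complete
#' observation sets of each episode are therefore not scored. They remain
#' available as history for rolling-window features of retained rows.
#'
#' @param obs time-sorted complete observations of one episode.
#' @param k number of initial rows to drop (default 2).
#' @return the retained rows (possibly zero rows).
#' @export
exclude_initial <- function(obs, k = 2L) {
  stopifnot(k >= 0)
  n <- nrow(obs)
  if (n <= k) return(obs[0L, , drop = FALSE])
  obs[(k + 1L):n, , drop = FALSE]
}

#' Validate a cohort and summarise row errors
#'
#' @param cohort a `dews_cohort` from [read_cohort()].
#' @param quiet suppress printed report.
#' @return invisibly, a list with counts (`n_episodes`, `n_obs`,
#'   `n_complete`, `n_events`, `n_row_errors`) and the row-error table.
#' @export
validate_cohort <- function(cohort, quiet = FALSE) {
  errs <- attr(cohort, "row_errors") %||%
    data.frame(file = character(), line = integer(), message = character())
  res <- list(n_episodes = nrow(cohort$episodes),
              n_obs = nrow(cohort$observations),
              n_complete = sum(is_complete_obs(cohort$observations)),
              n_events = nrow(cohort$events),
              n_row_errors = nrow(errs),
              row_errors = errs)
  if (!quiet) {
    cat(sprintf("episodes: %d\nobservation sets: %d (%d complete)\n",
                res$n_episodes, res$n_obs, res$n_complete))
    cat(sprintf("events: %d\nrow errors: %d\n", res$n_events,
                res$n_row_errors))
    if (nrow(errs) > 0) {
      for (i in seq_len(min(nrow(errs), 50L))) {
        cat(sprintf("  %s line %d: %s\n", errs$file[i], errs$line[i],
                    errs$message[i]))
      }
    }
  }
  invisible(res)
}

#' Split a cohort's observations by episode
#'
#' @param cohort a `dews_cohort`.
#' @return named list of per-episode observation data frames, time-sorted.
#' @keywords internal
episode_observations <- function(cohort) {
  split(cohort$observations, cohort$observations$episode_id)
}
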