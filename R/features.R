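## 38-feature engineering for scoring-eligible observation sets.
##
## Channels: heart rate (hr), respiratory rate (rr), systolic pressure
## (sbp), temperature (temp), oxygen saturation (spo2), inspired-oxygen
## ordinal (fio2), consciousness ordinal (acvpu).
##
## Manifest (38 = 11 static + 21 dynamic + 6 slope categories):
##   static : hinge high/low for hr, rr, sbp, temp (U-shaped risk);
##            spo2_low hinge (no high hinge: supranormal saturation is
##            not a risk signal); fio2_ordinal; acvpu_ordinal
##   dynamic: difference from previous observation, rolling mean and
##            rolling (sample) SD of the last 5 (minimum 3) observations,
##            for all 7 channels
##   slope  : trajectory category 0-4 for hr, rr, sbp, temp, spo2, fio2

.feature_channels <- c("hr", "rr", "sbp", "temp", "spo2", "fio2", "acvpu")
.slope_channels <- c("hr", "rr", "sbp", "temp", "spo2", "fio2")

#' The 38-feature manifest
#'
#' @return character vector of the 38 feature names, in canonical order,
#'   with a `version` attribute.
#' @export
feature_manifest <- function() {
  static <- c("hr_high", "hr_low", "rr_high", "rr_low", "sbp_high",
              "sbp_low", "temp_high", "temp_low", "spo2_low",
              "fio2_ordinal", "acvpu_ordinal")
  dynamic <- as.vector(t(outer(.feature_channels,
                               c("_delta", "_rollmean", "_rollsd"),
                               paste0)))
  slope <- paste0(.slope_channels, "_slopecat")
  structure(c(static, dynamic, slope), version = "1.0")
}

#' Normal (zero-score) bands per channel
#'
#' The "normal range" used by the hinge splits and the trajectory
#' categories is the NEWS-2 zero-score band of each parameter; for the
#' inspired-oxygen ordinal, breathing air (level 0) is normal.
#'
#' @param scale2 use the Scale 2 SpO2 band (88–92) instead of Scale 1
#'   (96–100)?
#' @return named list of `c(lower, upper)` for hr, rr, sbp, temp, spo2,
#'   fio2.
#' @export
normal_bands <- function(scale2 = FALSE) {
  list(hr = c(51, 90), rr = c(12, 20), sbp = c(111, 219),
       temp = c(36.1, 38.0),
       spo2 = if (scale2) c(88, 92) else c(96, 100),
       fio2 = c(-0.5, 0.5))
}

#' Inspired-oxygen mapping table
#' @param path optional CSV override (columns mode, upper, level, label).
#' @return the mapping data frame.
#' @export
fio2_mapping <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.dews_cache$fio2_mapping)) return(.dews_cache$fio2_mapping)
    path <- system.file("extdata", "fio2_mapping.csv", package = "dews",
                        mustWork = TRUE)
    tab <- read.csv(path, stringsAsFactors = FALSE)
    tab$upper <- as.numeric(tab$upper)
    .dews_cache$fio2_mapping <- tab
    return(tab)
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$upper <- as.numeric(tab$upper)
  tab
}

#' Encode inspired oxygen as an ordinal 0–5
#'
#' Oxygen therapy has mixed units (flow in L/min, concentration in %);
#' both are mapped to a single ordinal: None = 0, Low = 1, Low-moderate =
#' 2, Moderate = 3, High = 4, Very high = 5. The default banding (1–2
#' L/min or 24–28% = Low, 3–5 or 29–40% = Low-moderate, 6–9 or 41–60% =
#' Moderate, 10–15 or 61–80% = High, above = Very high) ships as an
#' editable resource file.
#'
#' @param o2_mode character vector in \{air, flow, concentration\}.
#' @param o2_value numeric vector (L/min or %); ignored for air.
#' @param mapping mapping table from [fio2_mapping()].
#' @return integer vector 0–5.
#' @export
encode_fio2 <- function(o2_mode, o2_value, mapping = fio2_mapping()) {
  n <- length(o2_mode)
  o2_value <- rep_len(o2_value, n)
  if (any(o2_mode != "air" & is.na(o2_value))) {
    stop("o2_value required when o2_mode is flow or concentration",
         call. = FALSE)
  }
  out <- integer(n)
  for (md in c("flow", "concentration")) {
    rows <- mapping[mapping$mode == md, , drop = FALSE]
    rows <- rows[order(rows$upper), , drop = FALSE]
    idx <- which(o2_mode == md)
    if (length(idx)) {
      lev <- rows$level[findInterval(o2_value[idx], rows$upper,
                                     left.open = TRUE) + 1L]
      out[idx] <- lev
    }
  }
  out
}

#' Hinge split of a U-shaped vital
#'
#' Splits a value against its normal band into non-negative excursions:
#' `low = max(0, lower - value)`, `high = max(0, value - upper)`. At most
#' one of the two is nonzero.
#'
#' @param value numeric vector.
#' @param band `c(lower, upper)`.
#' @return list with components `low` and `high`.
#' @export
hinge_split <- function(value, band) {
  list(low = pmax(0, band[1] - value), high = pmax(0, value - band[2]))
}

#' Difference from the previous observation
#'
#' @param x time-ordered values of one channel within one episode.
#' @return `x[i] - x[i-1]`, with 0 for the first observation (no
#'   previous).
#' @export
delta_feature <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  c(0, diff(x))
}

#' Rolling mean and SD of the most recent observations
#'
#' At each position the window is the up-to-`window` most recent values
#' including the current one; with fewer than `min_n` values available
#' the statistics are undefined (`NA`). SD is the sample (n-1) standard
#' deviation.
#'
#' @param x time-ordered values of one channel within one episode.
#' @param window window length (default 5).
#' @param min_n minimum observations required (default 3).
#' @return list of vectors `mean`, `sd`, `n` (window sizes).
#' @export
rolling_stats <- function(x, window = 5L, min_n = 3L) {
  n <- length(x)
  m <- rep(NA_real_, n); s <- rep(NA_real_, n); cnt <- integer(n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - window + 1L):i]
    cnt[i] <- length(w)
    if (length(w) >= min_n) {
      m[i] <- mean(w)
      s[i] <- sd(w)
    }
  }
  list(mean = m, sd = s, n = cnt)
}

# least-squares slope of v against t (hours); NA if var(t) == 0
.ls_slope <- function(t_hours, v) {
  vt <- var(t_hours)
  if (!is.finite(vt) || vt == 0) return(NA_real_)
  cov(t_hours, v) / vt
}

#' Trajectory category of a channel
#'
#' Categorises the recent trajectory of a vital sign into: 0 normal and
#' stable, 1 normal and unstable, 2 outside normal range and improving,
#' 3 outside normal range and stable, 4 outside normal range and
#' worsening. "Normal" means the current value lies inside `band`;
#' stability inside the band is judged by the window SD against
#' `sd_tol`, and direction outside the band by the least-squares slope
#' (units/hour) against `slope_tol`: a slope pointing back toward the
#' band is improving, away from it worsening. Windows with fewer than 3
#' values take category 0 by convention.
#'
#' @param times POSIXct (or numeric hours) of the episode's observations.
#' @param values channel values, same length.
#' @param band `c(lower, upper)` normal range.
#' @param slope_tol slope tolerance in units/hour (default band
#'   width / 24).
#' @param sd_tol SD tolerance in units (default band width / 8).
#' @param window,min_n window definition as in [rolling_stats()].
#' @return integer vector of categories 0–4, one per observation.
#' @export
slope_category <- function(times, values, band,
                           slope_tol = (band[2] - band[1]) / 24,
                           sd_tol = (band[2] - band[1]) / 8,
                           window = 5L, min_n = 3L) {
  n <- length(values)
  stopifnot(length(times) == n)
  t_hours <- as.numeric(times) / 3600
  out <- integer(n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - window + 1L):i
    if (length(idx) < min_n) { out[i] <- 0L; next }
    v <- values[i]
    w <- values[idx]
    s <- .ls_slope(t_hours[idx], w)
    if (is.na(s)) s <- 0
    inside <- v >= band[1] & v <= band[2]
    if (inside) {
      out[i] <- if (sd(w) <= sd_tol) 0L else 1L
    } else if (abs(s) <= slope_tol) {
      out[i] <- 3L
    } else {
      improving <- (v > band[2] && s < -slope_tol) ||
        (v < band[1] && s > slope_tol)
      out[i] <- if (improving) 2L else 4L
    }
  }
  out
}

# per-episode feature block; obs must be the episode's complete,
# time-sorted observations. Returns matrix n x 38 for ALL rows (caller
# applies the first-k exclusion).
.episode_feature_matrix <- function(obs, chronic_resp,
                                    mapping = fio2_mapping(),
                                    window = 5L, min_n = 3L) {
  bands <- normal_bands(scale2 = chronic_resp)
  ch <- list(
    hr = obs$heart_rate, rr = obs$resp_rate, sbp = obs$sbp,
    temp = obs$temperature, spo2 = obs$spo2,
    fio2 = as.numeric(encode_fio2(obs$o2_mode, obs$o2_value, mapping)),
    acvpu = as.numeric(acvpu_ordinal(obs$acvpu)))
  n <- nrow(obs)
  manifest <- feature_manifest()
  X <- matrix(0, nrow = n, ncol = length(manifest),
              dimnames = list(NULL, manifest))
  for (p in c("hr", "rr", "sbp", "temp")) {
    h <- hinge_split(ch[[p]], bands[[p]])
    X[, paste0(p, "_high")] <- h$high
    X[, paste0(p, "_low")] <- h$low
  }
  X[, "spo2_low"] <- hinge_split(ch$spo2, bands$spo2)$low
  X[, "fio2_ordinal"] <- ch$fio2
  X[, "acvpu_ordinal"] <- ch$acvpu
  for (p in .feature_channels) {
    X[, paste0(p, "_delta")] <- delta_feature(ch[[p]])
    rs <- rolling_stats(ch[[p]], window, min_n)
    # undefined rolling statistics (n < 3) encode as 0 on the raw scale
    X[, paste0(p, "_rollmean")] <- ifelse(is.na(rs$mean), 0, rs$mean)
    X[, paste0(p, "_rollsd")] <- ifelse(is.na(rs$sd), 0, rs$sd)
  }
  for (p in .slope_channels) {
    X[, paste0(p, "_slopecat")] <-
      slope_category(obs$timestamp, ch[[p]], bands[[p]],
                     window = window, min_n = min_n)
  }
  X
}

#' Build the 38-feature matrix for a cohort
#'
#' For every scoring-eligible observation set (complete, and not among
#' the first `k_exclude` complete sets of its episode) assembles the
#' full 38-feature vector. Excluded initial rows still contribute
#' history to the rolling windows of retained rows, so the third
#' observation of an episode already has defined rolling statistics
#' (window of 3). Features are a pure function of the episode's
#' observations up to and including the scored row — no future values
#' leak in.
#'
#' @param cohort a `dews_cohort`.
#' @param k_exclude initial complete observation sets to exclude per
#'   episode (default 2).
#' @param mapping inspired-oxygen mapping table.
#' @return data frame: `episode_id`, `timestamp`, then the 38 feature
#'   columns in manifest order.
#' @export
build_features <- function(cohort, k_exclude = 2L,
                           mapping = fio2_mapping()) {
  obs_all <- filter_complete(cohort$observations)
  flag <- setNames(cohort$episodes$chronic_resp_flag,
                   cohort$episodes$episode_id)
  pieces <- lapply(split(obs_all, obs_all$episode_id), function(eo) {
    n <- nrow(eo)
    if (n <= k_exclude) return(NULL)
    X <- .episode_feature_matrix(eo, isTRUE(flag[[eo$episode_id[1]]]),
                                 mapping)
    keep <- (k_exclude + 1L):n
    cbind(data.frame(episode_id = eo$episode_id[keep],
                     timestamp = eo$timestamp[keep],
                     stringsAsFactors = FALSE),
          as.data.frame(X[keep, , drop = FALSE]))
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) {
    out <- cbind(data.frame(episode_id = character(),
                            timestamp = as.POSIXct(character(), tz = "UTC")),
                 as.data.frame(matrix(numeric(0), 0,
                                      length(feature_manifest()),
                                      dimnames = list(NULL,
                                                      feature_manifest()))))
    return(out)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Build the feature vector for a single observation set
#'
#' @param episode_obs complete, time-sorted observations of one episode.
#' @param at index of the scored observation within `episode_obs`; must
#'   be past the excluded initial rows.
#' @param chronic_resp episode-level Scale 2 flag.
#' @param k_exclude excluded initial rows (default 2).
#' @param mapping inspired-oxygen mapping table.
#' @return named numeric vector of 38 features.
#' @export
build_features_at <- function(episode_obs, at, chronic_resp = FALSE,
                              k_exclude = 2L, mapping = fio2_mapping()) {
  if (at <= k_exclude || at > nrow(episode_obs)) {
    stop("index 'at' is not scoring-eligible", call. = FALSE)
  }
  X <- .episode_feature_matrix(episode_obs[seq_len(at), , drop = FALSE],
                               chronic_resp, mapping)
  X[at, ]
}

#' Fit / apply a zero-mean unit-variance normalizer
#'
#' Normalisation constants are estimated on training data only;
#' validation data are transformed with the stored constants. A feature
#' that is constant in training gets SD 1 (its normalised values are all
#' zero) and is recorded in the `constant` field.
#'
#' @param x numeric matrix or feature data frame (non-feature columns
#'   are ignored for data frames built by [build_features()]).
#' @return an object of class `dews_normalizer` with fields `mean`,
#'   `sd`, `constant`, `features`.
#' @export
fit_normalizer <- function(x) {
  X <- feature_matrix(x)
  if (nrow(X) < 2L) stop("need at least 2 rows to fit a normalizer",
                         call. = FALSE)
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  const <- !is.finite(sdev) | sdev == 0
  if (any(const)) {
    warning("constant feature(s): ",
            paste(colnames(X)[const], collapse = ", "),
            "; SD set to 1", call. = FALSE)
    sdev[const] <- 1
  }
  structure(list(mean = mu, sd = sdev, constant = colnames(X)[const],
                 features = colnames(X)),
            class = "dews_normalizer")
}

#' @rdname fit_normalizer
#' @param normalizer a fitted `dews_normalizer`.
#' @return for `apply_normalizer`, the normalised numeric matrix.
#' @export
apply_normalizer <- function(normalizer, x) {
  X <- feature_matrix(x)
  if (!identical(colnames(X), normalizer$features)) {
    X <- X[, normalizer$features, drop = FALSE]
  }
  sweep(sweep(X, 2, normalizer$mean, "-"), 2, normalizer$sd, "/")
}

#' Extract the numeric feature matrix from a feature data frame
#' @param x matrix or data frame containing the manifest columns.
#' @return numeric matrix with manifest columns.
#' @export
feature_matrix <- function(x) {
  manifest <- feature_manifest()
  if (is.matrix(x)) {
    if (!is.null(colnames(x)) && all(manifest %in% colnames(x))) {
      return(x[, manifest, drop = FALSE])
    }
    return(x)
  }
  if (all(manifest %in% names(x))) {
    return(as.matrix(x[, manifest, drop = FALSE]))
  }
  as.matrix(x[, vapply(x, is.numeric, logical(1)), drop = FALSE])
}
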