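## NEWS-2 aggregate score.
##
## The scorer is entirely table-driven: the published band chart ships as
## a machine-readable resource (inst/extdata/news2_bands.csv, columns
## parameter, scale, on_oxygen, lower, upper, points) and the scorer only
## performs lookups against it. Values are snapped to the chart's
## granularity first (integer for rates and pressure, one decimal for
## temperature) so the integer band edges are well-defined.

#' NEWS-2 band table
#'
#' @param path path to a band-table CSV; defaults to the packaged chart.
#' @return data frame with columns parameter, scale, on_oxygen, lower,
#'   upper, points.
#' @export
news2_bands <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.dews_cache$news2_bands)) return(.dews_cache$news2_bands)
    path <- system.file("extdata", "news2_bands.csv", package = "dews",
                        mustWork = TRUE)
    tab <- read.csv(path, stringsAsFactors = FALSE)
    tab$lower <- as.numeric(tab$lower)
    tab$upper <- as.numeric(tab$upper)
    .dews_cache$news2_bands <- tab
    return(tab)
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$lower <- as.numeric(tab$lower)
  tab$upper <- as.numeric(tab$upper)
  tab
}

#' ACVPU level to ordinal (Alert = 0 ... Unresponsive = 4)
#' @param acvpu character vector of ACVPU levels.
#' @return integer vector 0-4.
#' @export
acvpu_ordinal <- function(acvpu) {
  match(acvpu, .acvpu_levels) - 1L
}

# points for one parameter via the band table; v already snapped to the
# chart granularity. scale ("1"/"2") and on_oxygen are per-observation
# vectors.
.band_points <- function(tab, parameter, v, scale, on_oxygen) {
  rows <- tab[tab$parameter == parameter, , drop = FALSE]
  pts <- rep(NA_integer_, length(v))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    ok <- v >= r$lower & v <= r$upper &
      (r$scale == "both" | r$scale == scale)
    if (r$on_oxygen == "air") ok <- ok & !on_oxygen
    if (r$on_oxygen == "oxygen") ok <- ok & on_oxygen
    pts[ok & is.na(pts)] <- r$points
  }
  pts
}

#' NEWS-2 score for observation sets
#'
#' Computes the seven per-parameter sub-scores and their total for each
#' (complete) observation set. Oxygen-saturation Scale 2 (target
#' saturations 88–92%) is applied when `chronic_resp` is `TRUE`; Scale 1
#' otherwise. The scale choice is episode-level: an episode with any
#' observation set labelled "O2 sats scale 2" is treated as chronic
#' respiratory disease throughout. Consciousness scores 0 for Alert and 3
#' for any other ACVPU level (new confusion is scored); supplemental
#' oxygen scores 2 for any delivery mode other than air.
#'
#' Measured values are snapped to the chart granularity before banding:
#' respiration, pulse, pressure and SpO2 to the nearest integer,
#' temperature to one decimal.
#'
#' @param obs observations data frame (one or more complete rows).
#' @param chronic_resp logical, recycled: score on SpO2 Scale 2?
#' @param bands band table, defaults to the packaged chart.
#' @return data frame with one row per observation: columns `resp_rate`,
#'   `spo2`, `supplemental_o2`, `sbp`, `heart_rate`, `consciousness`,
#'   `temperature` (sub-scores), `total`, and `scale_used`
#'   ("scale1"/"scale2").
#' @export
news2_score <- function(obs, chronic_resp = FALSE, bands = news2_bands()) {
  if (!all(is_complete_obs(obs))) {
    stop("news2_score requires complete observation sets; ",
         "apply filter_complete() first", call. = FALSE)
  }
  n <- nrow(obs)
  chronic_resp <- rep_len(chronic_resp, n)
  on_o2 <- obs$o2_mode != "air"
  scale <- ifelse(chronic_resp, "2", "1")

  rr  <- round(obs$resp_rate)
  hr  <- round(obs$heart_rate)
  sbp <- round(obs$sbp)
  sp  <- round(obs$spo2)
  tm  <- round(obs$temperature, 1)

  comp <- data.frame(
    resp_rate = .band_points(bands, "resp_rate", rr, scale, on_o2),
    spo2 = .band_points(bands, "spo2", sp, scale, on_o2),
    supplemental_o2 = .band_points(bands, "supplemental_o2",
                                   rep(0, n), scale, on_o2),
    sbp = .band_points(bands, "sbp", sbp, scale, on_o2),
    heart_rate = .band_points(bands, "heart_rate", hr, scale, on_o2),
    consciousness = .band_points(bands, "consciousness",
                                 acvpu_ordinal(obs$acvpu), scale, on_o2),
    temperature = .band_points(bands, "temperature", tm, scale, on_o2))
  if (anyNA(comp)) {
    stop("band table does not cover some observed values", call. = FALSE)
  }
  comp$total <- as.integer(rowSums(comp))
  comp$scale_used <- ifelse(chronic_resp, "scale2", "scale1")
  comp
}

#' Maximum NEWS-2 total over an episode's complete observation sets
#'
#' Used with a threshold (e.g. 10) as the episode-selection filter for
#' manual event annotation.
#'
#' @param episode_obs observations of one episode.
#' @param chronic_resp episode-level Scale 2 flag.
#' @param bands band table.
#' @return integer maximum total; errors if no complete observation set.
#' @export
max_news2 <- function(episode_obs, chronic_resp = FALSE,
                      bands = news2_bands()) {
  comp <- filter_complete(episode_obs)
  if (nrow(comp) == 0L) {
    stop("episode has no complete observation sets", call. = FALSE)
  }
  max(news2_score(comp, chronic_resp, bands)$total)
}

#' NEWS-2 totals for a whole cohort
#'
#' @param cohort a `dews_cohort`.
#' @return the cohort's complete observations with `news2_total` column
#'   appended (episode-level scale rule applied).
#' @export
news2_cohort <- function(cohort) {
  obs <- filter_complete(cohort$observations)
  flag <- cohort$episodes$chronic_resp_flag[
    match(obs$episode_id, cohort$episodes$episode_id)]
  obs$news2_total <- news2_score(obs, flag)$total
  obs
}
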