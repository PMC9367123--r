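## Seeded synthetic ward-cohort generator.
##
## Emulates the structure of electronic ward observations: admission
## episodes of irregularly spaced (~4-hourly) observation sets, an
## episode-level chronic-respiratory (SpO2 Scale 2) subgroup, rare
## deterioration outcomes, and deteriorations that manifest as
## linear-plus-noise trends in the vitals over a 6-24 h lead time
## superimposed on stationary AR(1) baselines. Oxygen therapy escalates
## with falling saturations, so the inspired-oxygen ordinal trends
## upward during deterioration.

#' Synthetic cohort configuration
#'
#' Defaults describe a plausible respiratory-ward cohort: ~20
#' observation sets per episode at a mean 4 h spacing, a quarter of
#' episodes with chronic respiratory disease (scored on SpO2 Scale 2),
#' 15% of episodes deteriorating with an 8-20 h vital-sign ramp before
#' the event, and archetype mixes (sepsis-like, respiratory-failure,
#' cardiovascular) that shape which vitals trend. About half of
#' deteriorating episodes end in death or ICU admission, giving a
#' 24-hour death/ICU label prevalence of a few percent of observation
#' sets.
#'
#' @param n_episodes number of admission episodes.
#' @param mean_obs mean observation sets per episode (minimum 6).
#' @param interval_hours mean spacing between observation sets.
#' @param interval_shape gamma shape of the spacing jitter.
#' @param chronic_resp_fraction fraction of episodes on SpO2 Scale 2.
#' @param p_deteriorate probability an episode deteriorates.
#' @param p_terminal probability a deterioration ends in death/ICU
#'   (otherwise the event is an annotated ward deterioration only).
#' @param p_death_given_terminal split of terminal events into death vs
#'   ICU admission.
#' @param lead_time_hours range of the deterioration ramp length.
#' @param severity_range multiplicative range of ramp steepness.
#' @param archetype_mix named probabilities over sepsis / resp_failure
#'   / cardiac (must sum to 1).
#' @param ar_phi AR(1) coefficient of the baseline vitals per step.
#' @param missing_rate per-row probability that one clinical field is
#'   blanked (exercises the complete-case filter).
#' @param start_date first possible admission instant (ISO-8601).
#' @param seed RNG seed; every draw flows from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_episodes = 500L, mean_obs = 20, interval_hours = 4,
                       interval_shape = 16, chronic_resp_fraction = 0.25,
                       p_deteriorate = 0.15, p_terminal = 0.5,
                       p_death_given_terminal = 0.4,
                       lead_time_hours = c(8, 20),
                       severity_range = c(0.6, 1.4),
                       archetype_mix = c(sepsis = 0.5, resp_failure = 0.3,
                                         cardiac = 0.2),
                       ar_phi = 0.7, missing_rate = 0.005,
                       start_date = "2024-01-01T00:00:00+00:00",
                       seed = 1L) {
  stopifnot(n_episodes >= 1, abs(sum(archetype_mix) - 1) < 1e-9,
            all(archetype_mix >= 0), p_deteriorate >= 0,
            p_deteriorate <= 1, lead_time_hours[1] > 0,
            lead_time_hours[2] >= lead_time_hours[1])
  if (lead_time_hours[2] > mean_obs * interval_hours) {
    stop("infeasible config: lead time exceeds the episode span",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

.csd_codes <- c("sepsis", "respiratory_failure", "arrhythmia",
                "hypotension", "cardiac_arrest")

# archetype -> per-hour trend multipliers on the base ramp slopes
.archetype_mult <- list(
  sepsis = c(hr = 1.2, rr = 1.0, sbp = 1.2, spo2 = 0.6, temp = 0.12),
  resp_failure = c(hr = 0.7, rr = 1.6, sbp = 0.4, spo2 = 1.8,
                   temp = 0.02),
  cardiac = c(hr = 1.8, rr = 0.6, sbp = 1.6, spo2 = 0.7, temp = -0.06))
.base_slopes <- c(hr = 2.0, rr = 0.5, sbp = -1.5, spo2 = -0.30)

# oxygen therapy escalation from the underlying saturation; chronic
# (Scale 2) patients are allowed lower saturations before escalation
.o2_therapy <- function(spo2, chronic) {
  thr <- if (chronic) -4 else 0
  if (spo2 >= 94 + thr) list(mode = "air", value = NA_real_)
  else if (spo2 >= 92 + thr) list(mode = "flow", value = 2)
  else if (spo2 >= 90 + thr) list(mode = "flow", value = 4)
  else if (spo2 >= 88 + thr) list(mode = "flow", value = 8)
  else if (spo2 >= 85 + thr) list(mode = "concentration", value = 60)
  else list(mode = "concentration", value = 85)
}

.rtnorm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, rnorm(n, mean, sd)))
}

#' Generate a synthetic ward cohort
#'
#' @param config a [sim_config()].
#' @return a `dews_cohort` with attribute `sim_truth` (per-episode
#'   data frame: archetype, deteriorated, onset/event times). The same
#'   config (same seed) always yields an identical cohort.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  t0 <- as.numeric(parse_timestamp(config$start_date))
  obs_list <- list(); ev_list <- list(); ep_list <- list()
  truth_list <- list()

  for (i in seq_len(config$n_episodes)) {
    ep_id <- sprintf("EP%05d", i)
    chronic <- runif(1) < config$chronic_resp_fraction
    n_obs <- 6L + stats::rpois(1, max(0, config$mean_obs - 6))
    gaps <- stats::rgamma(n_obs - 1L, shape = config$interval_shape,
                          rate = config$interval_shape /
                            config$interval_hours)
    gaps <- pmax(gaps, 0.5)
    admit <- t0 + runif(1, 0, 365 * 24) * 3600
    times <- admit + c(0, cumsum(gaps)) * 3600

    # stationary AR(1) baselines around per-patient set points
    mu <- c(hr = .rtnorm(1, 78, 10, 50, 115),
            rr = .rtnorm(1, 16, 2.5, 10, 26),
            sbp = .rtnorm(1, 125, 15, 85, 185),
            temp = .rtnorm(1, 36.8, 0.35, 35.8, 38.0),
            spo2 = if (chronic) .rtnorm(1, 91.5, 1.5, 86, 96)
                   else .rtnorm(1, 96.5, 1.5, 92, 100))
    innov <- c(hr = 3, rr = 1, sbp = 5, temp = 0.15, spo2 = 0.8)
    v <- sapply(names(mu), function(p) {
      x <- numeric(n_obs)
      x[1] <- mu[p] + rnorm(1, 0, innov[p])
      for (k in 2:n_obs) {
        x[k] <- mu[p] + config$ar_phi * (x[k - 1] - mu[p]) +
          rnorm(1, 0, innov[p])
      }
      x
    })

    deteriorate <- runif(1) < config$p_deteriorate
    archetype <- NA_character_; t_event <- NA_real_; onset <- NA_real_
    if (deteriorate) {
      archetype <- sample(names(config$archetype_mix), 1,
                          prob = config$archetype_mix)
      severity <- runif(1, config$severity_range[1],
                        config$severity_range[2])
      lead <- runif(1, config$lead_time_hours[1],
                    config$lead_time_hours[2])
      # event strikes in the later part of the stay, after the ramp has
      # room to develop on top of at least three baseline observations
      j <- sample(max(4L, ceiling(n_obs * 0.5)):n_obs, 1)
      t_event <- times[j] + runif(1, 0, 2) * 3600
      onset <- max(times[1], t_event - lead * 3600)
      mult <- .archetype_mult[[archetype]]
      hrs_in <- pmax(0, (times - onset) / 3600)
      for (p in c("hr", "rr", "sbp", "spo2")) {
        v[, p] <- v[, p] + severity * mult[p] * .base_slopes[p] * hrs_in
      }
      v[, "temp"] <- v[, "temp"] + severity * mult["temp"] * hrs_in
    }

    v[, "spo2"] <- pmin(v[, "spo2"], 100)
    v[, "hr"] <- pmax(v[, "hr"], 20)
    v[, "rr"] <- pmax(v[, "rr"], 5)
    v[, "sbp"] <- pmax(v[, "sbp"], 50)

    # oxygen therapy responds to the (pre-support) saturation and lifts
    # the measured value a little
    o2_mode <- character(n_obs); o2_val <- rep(NA_real_, n_obs)
    spo2_meas <- v[, "spo2"]
    for (k in seq_len(n_obs)) {
      th <- .o2_therapy(v[k, "spo2"], chronic)
      o2_mode[k] <- th$mode; o2_val[k] <- th$value
      if (th$mode == "flow") spo2_meas[k] <- min(100, spo2_meas[k] + 2)
      if (th$mode == "concentration") {
        spo2_meas[k] <- min(100, spo2_meas[k] + 3)
      }
    }

    # consciousness deteriorates late in the ramp
    acvpu <- rep("Alert", n_obs)
    if (deteriorate) {
      hrs_in <- pmax(0, (times - onset) / 3600)
      p_drop <- plogis(-5 + 0.35 * hrs_in)
      drop <- runif(n_obs) < p_drop
      acvpu[drop] <- sample(c("Confused", "Voice", "Pain"), sum(drop),
                            replace = TRUE, prob = c(0.7, 0.2, 0.1))
    }

    obs <- data.frame(
      episode_id = ep_id,
      timestamp = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
      heart_rate = round(v[, "hr"]),
      resp_rate = round(v[, "rr"]),
      sbp = round(v[, "sbp"]),
      temperature = round(v[, "temp"], 1),
      spo2 = round(spo2_meas),
      o2_mode = o2_mode,
      o2_value = o2_val,
      acvpu = acvpu,
      scale2_label = chronic,
      stringsAsFactors = FALSE)

    # sparse missingness: blank one clinical field on a few rows
    miss <- runif(n_obs) < config$missing_rate
    for (k in which(miss)) {
      f <- sample(c("heart_rate", "resp_rate", "sbp", "temperature",
                    "spo2", "acvpu"), 1)
      obs[k, f] <- NA
    }

    evs <- NULL
    if (deteriorate) {
      terminal <- runif(1) < config$p_terminal
      evs <- data.frame(
        episode_id = ep_id,
        timestamp = as.POSIXct(t_event, origin = "1970-01-01",
                               tz = "UTC"),
        kind = "csd",
        csd_code = switch(archetype,
                          sepsis = "sepsis",
                          resp_failure = "respiratory_failure",
                          cardiac = sample(c("arrhythmia", "hypotension"),
                                           1)),
        stringsAsFactors = FALSE)
      if (terminal) {
        kind <- if (runif(1) < config$p_death_given_terminal) "death"
                else "icu_admission"
        evs <- rbind(evs, data.frame(
          episode_id = ep_id,
          timestamp = as.POSIXct(t_event + 1800,
                                 origin = "1970-01-01", tz = "UTC"),
          kind = kind, csd_code = NA_character_,
          stringsAsFactors = FALSE))
        # stay ends shortly after a terminal event
        obs <- obs[times <= t_event + 1800, , drop = FALSE]
      }
    }

    obs_list[[i]] <- obs
    if (!is.null(evs)) ev_list[[length(ev_list) + 1L]] <- evs
    ep_list[[i]] <- data.frame(
      episode_id = ep_id,
      age = round(.rtnorm(1, 66, 17, 18, 99)),
      sex = sample(c("F", "M"), 1),
      chronic_resp_flag = chronic, stringsAsFactors = FALSE)
    truth_list[[i]] <- data.frame(
      episode_id = ep_id, deteriorated = deteriorate,
      archetype = archetype, onset = onset, t_event = t_event,
      stringsAsFactors = FALSE)
  }

  observations <- do.call(rbind, obs_list)
  rownames(observations) <- NULL
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(episode_id = character(),
               timestamp = as.POSIXct(character(), tz = "UTC"),
               kind = character(), csd_code = character(),
               stringsAsFactors = FALSE)
  events <- events[order(events$episode_id, events$timestamp,
                         method = "radix"), , drop = FALSE]
  rownames(events) <- NULL
  episodes <- do.call(rbind, ep_list)

  structure(list(observations = observations, events = events,
                 episodes = episodes),
            class = "dews_cohort",
            row_errors = data.frame(file = character(), line = integer(),
                                    message = character()),
            sim_truth = do.call(rbind, truth_list),
            config = config)
}

#' Default "truth" coefficient vector for parameter-recovery studies
#'
#' A sparse, physiologically signed coefficient vector on the
#' normalised 38-feature scale: risk rises with tachycardia, tachypnoea,
#' hypotension, desaturation, oxygen escalation, worsening trajectories
#' and recent change.
#'
#' @return named numeric vector over the 38-feature manifest.
#' @export
default_truth <- function() {
  truth <- setNames(numeric(length(feature_manifest())),
                    feature_manifest())
  truth["hr_high"] <- 0.9
  truth["rr_high"] <- 1.0
  truth["sbp_low"] <- 0.9
  truth["temp_low"] <- 0.5
  truth["spo2_low"] <- 0.7
  truth["fio2_ordinal"] <- 0.8
  truth["acvpu_ordinal"] <- 0.6
  truth["hr_delta"] <- 0.5
  truth["rr_delta"] <- 0.4
  truth["hr_rollsd"] <- 0.4
  truth["hr_slopecat"] <- 0.6
  truth["rr_slopecat"] <- 0.5
  truth["spo2_slopecat"] <- 0.4
  truth
}

#' Generate a cohort with labels drawn from a known logistic model
#'
#' Builds the synthetic cohort, engineers the 38 features, normalises
#' them over the whole cohort, and draws each row's label from
#' `Bernoulli(plogis(intercept + truth . z))`. The truth vector is the
#' oracle for parameter-recovery tests.
#'
#' @param config a [sim_config()].
#' @param truth named coefficient vector over the 38-feature manifest.
#' @param intercept intercept on the logistic scale (default
#'   `qlogis(0.05)` for ~5% base prevalence).
#' @return list: `cohort`, `features` (with `label` column),
#'   `normalizer`, `probabilities`, `truth`, `intercept`.
#' @export
generate_from_logistic_truth <- function(config = sim_config(),
                                         truth = default_truth(),
                                         intercept = stats::qlogis(0.05)) {
  manifest <- feature_manifest()
  if (!identical(sort(names(truth)), sort(manifest))) {
    stop("truth vector does not match the 38-feature manifest",
         call. = FALSE)
  }
  cohort <- generate_cohort(config)
  feats <- build_features(cohort)
  normalizer <- fit_normalizer(feats)
  Z <- apply_normalizer(normalizer, feats)
  eta <- intercept + as.numeric(Z %*% truth[colnames(Z)])
  p <- plogis(eta)
  set.seed(config$seed + 1L)
  feats$label <- rbinom(length(p), 1L, p)
  list(cohort = cohort, features = feats, normalizer = normalizer,
       probabilities = p, truth = truth, intercept = intercept)
}
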