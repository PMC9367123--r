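## Outcome labels and train/validation splits.

#' Outcome specification
#'
#' Two deterioration outcomes are supported: `d_icu` — death or ICU
#' admission within 24 hours of an observation set — and `csd` —
#' clinically significant deterioration (an annotated event requiring a
#' change in treatment) within 4 hours.
#'
#' @param name "d_icu" or "csd".
#' @param horizon_hours prediction horizon; defaults 24 (d_icu) / 4
#'   (csd).
#' @param kinds qualifying event kinds.
#' @return an `outcome_spec` list.
#' @export
outcome_spec <- function(name = c("d_icu", "csd"),
                         horizon_hours = NULL, kinds = NULL) {
  name <- match.arg(name)
  if (is.null(horizon_hours)) {
    horizon_hours <- if (name == "d_icu") 24 else 4
  }
  stopifnot(horizon_hours > 0)
  if (is.null(kinds)) {
    kinds <- if (name == "d_icu") c("death", "icu_admission") else "csd"
  }
  structure(list(name = name, horizon_hours = horizon_hours,
                 kinds = kinds), class = "outcome_spec")
}

#' Label observation sets against an outcome
#'
#' An observation set at time t is positive iff a qualifying event
#' occurs in the window (t, t + horizon]: strictly after the
#' observation (an event at the very instant is a concurrent detection,
#' not a prediction) and up to and including the horizon. Episodes can
#' contain several qualifying events; every observation is labelled
#' against all of them. Events timestamped before an episode's first
#' observation are ignored with a warning.
#'
#' By default an episode is truncated at its first death or ICU
#' admission: observation sets after that instant are not scoring rows.
#'
#' @param obs data frame of scoring rows (needs `episode_id`,
#'   `timestamp`), e.g. the output of [build_features()].
#' @param events events data frame of a `dews_cohort`.
#' @param spec an [outcome_spec()].
#' @param truncate_at_terminal drop rows after the episode's first
#'   death/ICU event (default TRUE).
#' @return `obs` with integer `label` column appended (rows after
#'   truncation removed).
#' @export
label_observations <- function(obs, events, spec,
                               truncate_at_terminal = TRUE) {
  stopifnot(inherits(spec, "outcome_spec"))
  ev <- events[events$kind %in% spec$kinds, , drop = FALSE]
  horizon <- spec$horizon_hours * 3600

  first_obs <- tapply(as.numeric(obs$timestamp), obs$episode_id, min)
  early <- !is.na(first_obs[ev$episode_id]) &
    as.numeric(ev$timestamp) <= unname(first_obs[ev$episode_id])
  early[is.na(early)] <- FALSE
  if (any(early)) {
    warning(sum(early), " event(s) at or before the episode's first ",
            "observation ignored for labelling", call. = FALSE)
    ev <- ev[!early, , drop = FALSE]
  }

  label <- integer(nrow(obs))
  if (nrow(ev) > 0L) {
    ev_by_ep <- split(as.numeric(ev$timestamp), ev$episode_id)
    t_obs <- as.numeric(obs$timestamp)
    for (ep in names(ev_by_ep)) {
      idx <- which(obs$episode_id == ep)
      if (length(idx) == 0L) next
      te <- ev_by_ep[[ep]]
      for (t_e in te) {
        hit <- t_obs[idx] < t_e & t_e <= t_obs[idx] + horizon
        label[idx[hit]] <- 1L
      }
    }
  }
  out <- obs
  out$label <- label

  if (truncate_at_terminal) {
    term <- events[events$kind %in% c("death", "icu_admission"), ,
                   drop = FALSE]
    if (nrow(term) > 0L) {
      t_term <- tapply(as.numeric(term$timestamp), term$episode_id, min)
      cut <- t_term[out$episode_id]
      keep <- is.na(cut) | as.numeric(out$timestamp) <= unname(cut)
      out <- out[keep, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Episode-level train/validation split
#'
#' Splits whole episodes (no episode straddles the two sides), either
#' temporally by each episode's last observation time against a cutoff
#' (training = at or before the cutoff), or at random with a
#' reproducible seed.
#'
#' @param cohort a `dews_cohort`.
#' @param mode "random" or "temporal".
#' @param n_train number of training episodes (random mode).
#' @param seed RNG seed (random mode).
#' @param cutoff POSIXct (or parseable ISO-8601 string) cutoff
#'   (temporal mode).
#' @return list of character vectors `train`, `validation` (episode
#'   ids).
#' @export
split_cohort <- function(cohort, mode = c("random", "temporal"),
                         n_train = NULL, seed = 1L, cutoff = NULL) {
  mode <- match.arg(mode)
  ids <- cohort$episodes$episode_id
  if (mode == "random") {
    stopifnot(!is.null(n_train), n_train >= 0, n_train <= length(ids))
    set.seed(seed)
    train <- sort(sample(ids, n_train))
    list(train = train, validation = sort(setdiff(ids, train)))
  } else {
    stopifnot(!is.null(cutoff))
    if (is.character(cutoff)) cutoff <- parse_timestamp(cutoff)
    last_t <- tapply(as.numeric(cohort$observations$timestamp),
                     cohort$observations$episode_id, max)[ids]
    train <- ids[unname(last_t) <= as.numeric(cutoff)]
    if (length(train) == 0L || length(train) == length(ids)) {
      warning("temporal cutoff leaves one side of the split empty",
              call. = FALSE)
    }
    list(train = sort(train), validation = sort(setdiff(ids, train)))
  }
}
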