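# Fixture builders: everything is constructed in code at test time.

# one observation row with every vital in its zero band unless overridden
make_obs <- function(episode_id = "E1", timestamp = "2024-01-01T00:00:00+00:00",
                     heart_rate = 70, resp_rate = 16, sbp = 120,
                     temperature = 37.0, spo2 = 97, o2_mode = "air",
                     o2_value = NA_real_, acvpu = "Alert",
                     scale2_label = FALSE) {
  data.frame(episode_id = episode_id,
             timestamp = dews::parse_timestamp(timestamp),
             heart_rate = heart_rate, resp_rate = resp_rate, sbp = sbp,
             temperature = temperature, spo2 = spo2, o2_mode = o2_mode,
             o2_value = o2_value, acvpu = acvpu,
             scale2_label = scale2_label, stringsAsFactors = FALSE)
}

# n normal observations spaced 4 h apart
make_episode_obs <- function(episode_id = "E1", n = 5,
                             start = "2024-01-01T00:00:00+00:00", ...) {
  t0 <- dews::parse_timestamp(start)
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_obs(episode_id = episode_id,
             timestamp = format(t0 + (i - 1) * 4 * 3600,
                                "%Y-%m-%dT%H:%M:%S+00:00"), ...)
  }))
}

make_events <- function(episode_id = character(), timestamp = character(),
                        kind = character(), csd_code = NA_character_) {
  data.frame(episode_id = episode_id,
             timestamp = dews::parse_timestamp(timestamp),
             kind = kind,
             csd_code = rep_len(csd_code, length(episode_id)),
             stringsAsFactors = FALSE)
}

make_cohort <- function(observations, events = NULL) {
  if (is.null(events)) {
    events <- make_events()
  }
  ids <- unique(observations$episode_id)
  flag <- vapply(split(observations$scale2_label,
                       observations$episode_id)[ids], any, logical(1))
  structure(list(
    observations = observations,
    events = events,
    episodes = data.frame(episode_id = ids, age = 65, sex = "F",
                          chronic_resp_flag = unname(flag),
                          stringsAsFactors = FALSE)),
    class = "dews_cohort",
    row_errors = data.frame(file = character(), line = integer(),
                            message = character()))
}

# brute-force AUROC: all positive-negative pairs, ties count one half
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# independent average-precision oracle: explicit threshold sweep, no
# cumulative-sum bookkeeping
brute_auprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0; prev_recall <- 0
  for (t in th) {
    call_pos <- scores >= t
    tp <- sum(call_pos & labels == 1)
    fp <- sum(call_pos & labels == 0)
    prec <- tp / (tp + fp)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * prec
    prev_recall <- recall
  }
  ap
}
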