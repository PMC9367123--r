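## Evaluation: ROC / precision-recall areas, bootstrap confidence
## intervals, operating-point tables, matched thresholds and 4-hour
## event-window detection.

#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney identity: the probability that a
#' random positive outscores a random negative, ties counted one half —
#' equivalently the trapezoidal integral of the ROC curve.
#'
#' @param scores numeric scores (higher = more at risk).
#' @param labels 0/1 labels.
#' @return AUROC in [0, 1]; errors when only one class is present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("auroc undefined: only one class present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-function (average-precision) summation over descending score
#' order, with tied scores handled as a block — no trapezoidal
#' interpolation, which is optimistic on heavily imbalanced data.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUPRC in (0, 1]; errors when there is no positive.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("auprc undefined: no positives", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # block boundaries: last index of each tie group
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  prec <- tp / (tp + fp)
  recall <- tp / n_pos
  d_rec <- diff(c(0, recall))
  sum(d_rec * prec)
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples observation sets with replacement (`unit = "observation"`)
#' or whole episodes (`unit = "episode"`, for clustering sensitivity)
#' and returns the percentile interval of the metric across resamples.
#' Resamples on which the metric is undefined (e.g. a single class drawn)
#' are dropped; if more than 20% are undefined the interval is an error.
#'
#' @param metric function(scores, labels) -> numeric.
#' @param scores,labels the data.
#' @param B number of bootstrap resamples (default 500).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @param unit resampling unit.
#' @param episode episode ids (required for `unit = "episode"`).
#' @return named numeric `c(lo, hi)` with attribute `B_used`.
#' @export
bootstrap_ci <- function(metric, scores, labels, B = 500L, level = 0.95,
                         seed = 1L, unit = c("observation", "episode"),
                         episode = NULL) {
  unit <- match.arg(unit)
  n <- length(scores)
  stopifnot(length(labels) == n)
  set.seed(seed)
  vals <- rep(NA_real_, B)
  if (unit == "observation") {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      vals[b] <- tryCatch(metric(scores[idx], labels[idx]),
                          error = function(e) NA_real_)
    }
  } else {
    stopifnot(!is.null(episode))
    eps <- unique(episode)
    idx_by_ep <- split(seq_len(n), episode)
    for (b in seq_len(B)) {
      draw <- sample(eps, length(eps), replace = TRUE)
      idx <- unlist(idx_by_ep[as.character(draw)], use.names = FALSE)
      vals[b] <- tryCatch(metric(scores[idx], labels[idx]),
                          error = function(e) NA_real_)
    }
  }
  bad <- sum(is.na(vals))
  if (bad > 0.2 * B) {
    stop("metric undefined in ", bad, " of ", B, " bootstrap resamples",
         call. = FALSE)
  }
  ci <- unname(quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, type = 7))
  structure(c(lo = ci[1], hi = ci[2]), B_used = B - bad)
}

#' Operating-point metrics at a threshold
#'
#' A positive call is `score >= threshold`. Sensitivity and specificity
#' are percentages of their classes; the false-positive and
#' false-negative rates follow the reporting convention of expressing
#' both as a percentage of ALL observation sets (so a "false alarm
#' rate" of 16.5 means 16.5% of every observation set taken).
#'
#' @param scores,labels the data.
#' @param threshold calling threshold.
#' @param name score name carried into the row.
#' @return one-row data frame: `score`, `threshold`, `sensitivity`,
#'   `specificity`, `fp_rate_pct_all_obs`, `fn_rate_pct_all_obs`.
#' @export
threshold_metrics <- function(scores, labels, threshold, name = "score") {
  labels <- as.integer(labels)
  call_pos <- scores >= threshold
  tp <- sum(call_pos & labels == 1L)
  fp <- sum(call_pos & labels == 0L)
  fn <- sum(!call_pos & labels == 1L)
  tn <- sum(!call_pos & labels == 0L)
  n <- length(labels)
  data.frame(
    score = name, threshold = threshold,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    fp_rate_pct_all_obs = 100 * fp / n,
    fn_rate_pct_all_obs = 100 * fn / n,
    stringsAsFactors = FALSE)
}

#' Candidate threshold matched to a reference operating point
#'
#' Finds the candidate-score cut-point whose sensitivity (or
#' specificity) matches that of a reference score at its reference
#' threshold, enabling a fair comparison of the other metric. With
#' `mode = "specificity"` the smallest candidate threshold whose
#' specificity is at least the reference specificity is returned (the
#' most sensitive cut-point that is no noisier than the reference);
#' with `mode = "sensitivity"` the largest threshold whose sensitivity
#' is at least the reference sensitivity. The search runs over the
#' observed candidate scores plus +Inf.
#'
#' @param ref_scores reference score vector (e.g. NEWS-2 totals).
#' @param cand_scores candidate score vector, aligned to the same
#'   labels.
#' @param labels 0/1 labels.
#' @param ref_threshold reference cut-point (e.g. 5).
#' @param mode which metric to match.
#' @return list: `threshold`, `achieved` (one-row data frame for the
#'   candidate at the matched threshold), `reference` (same for the
#'   reference), `attained` (FALSE when the target was unattainable and
#'   an extreme threshold was returned, with a warning).
#' @export
matched_threshold <- function(ref_scores, cand_scores, labels,
                              ref_threshold,
                              mode = c("specificity", "sensitivity")) {
  mode <- match.arg(mode)
  ref_row <- threshold_metrics(ref_scores, labels, ref_threshold,
                               name = "reference")
  cand <- sort(unique(c(cand_scores, Inf)))
  # sens is non-increasing, spec non-decreasing in the threshold
  if (mode == "specificity") {
    target <- ref_row$specificity
    ok <- vapply(cand, function(th)
      isTRUE(threshold_metrics(cand_scores, labels, th)$specificity >=
               target), logical(1))
    if (!any(ok)) {
      warning("target specificity unattainable; returning +Inf",
              call. = FALSE)
      th <- Inf; attained <- FALSE
    } else {
      th <- cand[which(ok)[1]]; attained <- TRUE
    }
  } else {
    target <- ref_row$sensitivity
    ok <- vapply(cand, function(th)
      isTRUE(threshold_metrics(cand_scores, labels, th)$sensitivity >=
               target), logical(1))
    if (!any(ok)) {
      warning("target sensitivity unattainable; returning -Inf",
              call. = FALSE)
      th <- -Inf; attained <- FALSE
    } else {
      th <- cand[max(which(ok))]; attained <- TRUE
    }
  }
  list(threshold = th,
       achieved = threshold_metrics(cand_scores, labels, th,
                                    name = "candidate"),
       reference = ref_row,
       attained = attained)
}

#' Event detection within a look-back window
#'
#' An event is detected iff any observation set of its episode with a
#' timestamp in `[t_event - window, t_event]` (at the time of the event
#' or within the previous `window` hours) has a score at or above the
#' threshold. Events with no observation in the window count as not
#' detected and are flagged.
#'
#' @param events events data frame (`episode_id`, `timestamp`).
#' @param scored data frame of scored observations (`episode_id`,
#'   `timestamp`, plus the score column).
#' @param score_col name of the score column in `scored`.
#' @param threshold calling threshold.
#' @param window_hours look-back window (default 4).
#' @return logical vector, one per event row, with attribute
#'   `no_obs_in_window` (logical vector flagging events that had no
#'   observation to detect them with).
#' @export
event_detection <- function(events, scored, score_col, threshold,
                            window_hours = 4) {
  w <- window_hours * 3600
  t_obs <- as.numeric(scored$timestamp)
  s <- scored[[score_col]]
  detected <- logical(nrow(events))
  no_obs <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    t_e <- as.numeric(events$timestamp[i])
    in_win <- scored$episode_id == events$episode_id[i] &
      t_obs >= t_e - w & t_obs <= t_e
    if (!any(in_win)) { no_obs[i] <- TRUE; next }
    detected[i] <- any(s[in_win] >= threshold)
  }
  structure(detected, no_obs_in_window = no_obs)
}

#' Cross-tabulate event detection by two scores
#'
#' @param events events data frame.
#' @param scored scored observations containing both score columns.
#' @param score_a,score_b score column names.
#' @param threshold_a,threshold_b calling thresholds.
#' @param window_hours look-back window (default 4).
#' @return list `both`, `only_a`, `only_b`, `neither`, `total` (cells
#'   sum to `total`).
#' @export
detection_cross_tab <- function(events, scored, score_a, score_b,
                                threshold_a, threshold_b,
                                window_hours = 4) {
  da <- event_detection(events, scored, score_a, threshold_a,
                        window_hours)
  db <- event_detection(events, scored, score_b, threshold_b,
                        window_hours)
  list(both = sum(da & db), only_a = sum(da & !db),
       only_b = sum(!da & db), neither = sum(!da & !db),
       total = nrow(events))
}

#' Full evaluation report for one or two scores
#'
#' Computes AUROC and AUPRC with bootstrap confidence intervals for a
#' primary score, optionally a comparison score with matched-threshold
#' operating points and the event-detection cross-tab.
#'
#' @param scores named list of score vectors (first = primary, e.g.
#'   `list(dews = ..., news2 = ...)`).
#' @param labels 0/1 labels aligned to every score vector.
#' @param B bootstrap resamples (default 500).
#' @param seed RNG seed for the bootstrap.
#' @param ref_thresholds reference cut-points on the LAST score in
#'   `scores` (the comparator, e.g. NEWS-2 5 and 7); ignored with a
#'   single score.
#' @param events,scored,window_hours optional event-level detection
#'   inputs (see [detection_cross_tab()]); `scored` must contain one
#'   column per score name.
#' @return an `eval_report` list mirroring the area table, threshold
#'   tables and cross-tab.
#' @export
evaluate_scores <- function(scores, labels, B = 500L, seed = 1L,
                            ref_thresholds = c(5, 7), events = NULL,
                            scored = NULL, window_hours = 4) {
  stopifnot(is.list(scores), length(scores) >= 1L)
  areas <- list()
  for (nm in names(scores)) {
    s <- scores[[nm]]
    ci_roc <- bootstrap_ci(auroc, s, labels, B = B, seed = seed)
    ci_pr <- bootstrap_ci(auprc, s, labels, B = B, seed = seed)
    areas[[nm]] <- list(
      auroc = auroc(s, labels), auroc_ci = as.numeric(ci_roc),
      auprc = auprc(s, labels), auprc_ci = as.numeric(ci_pr))
  }
  report <- list(areas = areas, thresholds = NULL, cross_tab = NULL,
                 B = B, seed = seed)
  if (length(scores) >= 2L) {
    cand_nm <- names(scores)[1]; ref_nm <- names(scores)[length(scores)]
    rows <- list(); ct <- list()
    for (th in ref_thresholds) {
      ref_row <- threshold_metrics(scores[[ref_nm]], labels, th,
                                   name = ref_nm)
      m_spec <- matched_threshold(scores[[ref_nm]], scores[[cand_nm]],
                                  labels, th, mode = "specificity")
      m_sens <- matched_threshold(scores[[ref_nm]], scores[[cand_nm]],
                                  labels, th, mode = "sensitivity")
      m_spec$achieved$score <- paste0(cand_nm, "_matched_spec")
      m_sens$achieved$score <- paste0(cand_nm, "_matched_sens")
      rows[[as.character(th)]] <- rbind(ref_row, m_spec$achieved,
                                        m_sens$achieved)
      if (!is.null(events) && !is.null(scored)) {
        ct[[as.character(th)]] <- detection_cross_tab(
          events, scored, score_a = cand_nm, score_b = ref_nm,
          threshold_a = m_spec$threshold, threshold_b = th,
          window_hours = window_hours)
      }
    }
    report$thresholds <- rows
    if (length(ct)) report$cross_tab <- ct
  }
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  for (nm in names(x$areas)) {
    a <- x$areas[[nm]]
    cat(sprintf("%s: AUROC %.3f (%.3f-%.3f), AUPRC %.3f (%.3f-%.3f)\n",
                nm, a$auroc, a$auroc_ci[1], a$auroc_ci[2],
                a$auprc, a$auprc_ci[1], a$auprc_ci[2]))
  }
  if (!is.null(x$thresholds)) {
    for (th in names(x$thresholds)) {
      cat(sprintf("-- reference threshold %s --\n", th))
      print(x$thresholds[[th]], row.names = FALSE)
    }
  }
  if (!is.null(x$cross_tab)) {
    for (th in names(x$cross_tab)) {
      ct <- x$cross_tab[[th]]
      cat(sprintf(
        "events (ref>=%s): both %d, only-candidate %d, only-ref %d, neither %d of %d\n",
        th, ct$both, ct$only_a, ct$only_b, ct$neither, ct$total))
    }
  }
  invisible(x)
}
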