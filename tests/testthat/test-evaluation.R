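test_that("auroc: separation, ties, and the 4-point case", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.3, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_equal(auroc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(auroc(1:3, c(1, 1, 1)), "one class")
})

test_that("auroc matches brute-force pair counting on random instances", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(5:200, 1)
    scores <- if (i %% 2 == 0) rnorm(n) else sample(0:10, n, TRUE)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), brute_auroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("auroc(s) + auroc(-s) = 1 on tie-free inputs", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(10:100, 1)
    scores <- rnorm(n)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    expect_equal(auroc(scores, labels) + auroc(-scores, labels), 1,
                 tolerance = 1e-12)
  }
})

test_that("auprc: perfect ranking, constant scores, 4-point case", {
  expect_equal(auprc(c(0.9, 0.8, 0.1, 0.2, 0.3), c(1, 1, 0, 0, 0)), 1.0)
  expect_equal(auprc(rep(0.5, 10), rep(c(1, 0), c(3, 7))), 0.3)
  # step-function average precision (no trapezoid): 1 * 1/2 + 2/3 * 1/2
  expect_equal(auprc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 5 / 6)
  expect_error(auprc(1:3, c(0, 0, 0)), "no positives")
})

test_that("auprc matches the threshold-sweep oracle on random instances", {
  set.seed(43)
  for (i in 1:60) {
    n <- sample(5:150, 1)
    scores <- if (i %% 2 == 0) rnorm(n) else sample(0:8, n, TRUE)
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0) next
    expect_equal(auprc(scores, labels), brute_auprc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap CI: degenerate data and determinism", {
  const_metric <- function(s, l) 0.42
  ci <- bootstrap_ci(const_metric, rnorm(50), rbinom(50, 1, 0.5),
                     B = 50, seed = 1)
  expect_equal(unname(ci["lo"]), 0.42)
  expect_equal(unname(ci["hi"]), 0.42)
  set.seed(10)
  s <- rnorm(200); l <- rbinom(200, 1, 0.3)
  ci1 <- bootstrap_ci(auroc, s, l, B = 100, seed = 7)
  ci2 <- bootstrap_ci(auroc, s, l, B = 100, seed = 7)
  expect_identical(ci1, ci2)
  expect_lt(ci1["lo"], ci1["hi"])
})

test_that("bootstrap errors when the metric is mostly undefined", {
  s <- rnorm(6); l <- c(1, 0, 0, 0, 0, 0)   # single positive: resamples
  expect_error(bootstrap_ci(auroc, s, l, B = 100, seed = 1), "undefined")
})

test_that("threshold metrics: 2x2 arithmetic and edge thresholds", {
  r <- threshold_metrics(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(r$sensitivity, 50)
  expect_equal(r$specificity, 50)
  expect_equal(r$fp_rate_pct_all_obs, 25)
  expect_equal(r$fn_rate_pct_all_obs, 25)
  all_pos <- threshold_metrics(c(0.9, 0.8, 0.7), c(1, 0, 0), 0)
  expect_equal(all_pos$sensitivity, 100)
  expect_equal(all_pos$specificity, 0)
  expect_equal(all_pos$fn_rate_pct_all_obs, 0)
  none <- threshold_metrics(c(0.9, 0.8, 0.7), c(1, 0, 0), 2)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 100)
})

test_that("threshold identities hold across thresholds", {
  set.seed(44)
  s <- rnorm(100); l <- rbinom(100, 1, 0.4)
  ths <- sort(unique(s))
  sens <- vapply(ths, function(t)
    threshold_metrics(s, l, t)$sensitivity, numeric(1))
  expect_true(all(diff(sens) <= 0))   # non-increasing in threshold
  for (t in ths[c(1, 50, 100)]) {
    r <- threshold_metrics(s, l, t)
    tp <- r$sensitivity / 100 * sum(l)
    fn <- r$fn_rate_pct_all_obs / 100 * length(l)
    expect_equal(tp + fn, sum(l), tolerance = 1e-9)
  }
})

test_that("matched threshold: identity and rank invariance", {
  set.seed(45)
  s <- rnorm(100); l <- rbinom(100, 1, 0.4)
  m <- matched_threshold(s, s, l, ref_threshold = 0.3,
                         mode = "specificity")
  ref <- threshold_metrics(s, l, 0.3)
  # the matched metric is attained exactly; the free metric can only
  # tie or improve (the search maximises it at the matched level)
  expect_equal(m$achieved$specificity, ref$specificity)
  expect_gte(m$achieved$sensitivity, ref$sensitivity)
  # strictly monotone transform: the matched cut-point attains exactly
  # the reference sensitivity; specificity can only tie or improve
  # (ties in the sensitivity ladder allow a higher threshold)
  trans <- plogis(s)
  m2 <- matched_threshold(s, trans, l, ref_threshold = 0.3,
                          mode = "sensitivity")
  expect_equal(m2$achieved$sensitivity, ref$sensitivity)
  expect_gte(m2$achieved$specificity, ref$specificity)
})

test_that("matched threshold agrees with an exhaustive scan", {
  set.seed(46)
  ref <- c(rnorm(10, 1), rnorm(10))
  cand <- c(rnorm(10, 1.5), rnorm(10))
  l <- rep(c(1, 0), each = 10)
  for (mode in c("specificity", "sensitivity")) {
    got <- matched_threshold(ref, cand, l, ref_threshold = 0.5,
                             mode = mode)
    target <- threshold_metrics(ref, l, 0.5)[[mode]]
    cuts <- sort(unique(c(cand, Inf)))
    ok <- vapply(cuts, function(t)
      threshold_metrics(cand, l, t)[[mode]] >= target, logical(1))
    want <- if (mode == "specificity") cuts[which(ok)[1]] else
      cuts[max(which(ok))]
    expect_equal(got$threshold, want)
  }
})

test_that("unattainable matched target warns and returns the extreme", {
  # with no positives the sensitivity target is undefined, so no
  # cut-point can attain it
  l <- c(0, 0, 0, 0)
  ref <- c(10, 9, 1, 2)
  cand <- c(1, 2, 10, 9)
  expect_warning(
    m <- matched_threshold(ref, cand, l, ref_threshold = 9,
                           mode = "sensitivity"),
    "unattainable")
  expect_false(m$attained)
  expect_identical(m$threshold, -Inf)
})

test_that("event detection honours the 4 h look-back window", {
  scored <- data.frame(
    episode_id = "E1",
    timestamp = parse_timestamp(c("2024-01-01T07:00:00+00:00",
                                  "2024-01-01T09:00:00+00:00")),
    s = c(9, 2), stringsAsFactors = FALSE)
  ev <- make_events("E1", "2024-01-01T12:00:00+00:00", "csd",
                    csd_code = "sepsis")
  # obs at 09:00 below threshold, obs at 07:00 outside the window
  expect_false(event_detection(ev, scored, "s", threshold = 5)[1])
  scored$s <- c(9, 9)
  expect_true(event_detection(ev, scored, "s", threshold = 5)[1])
  scored2 <- scored[1, ]; scored2$s <- 9
  expect_false(event_detection(ev, scored2, "s", threshold = 5)[1])
  # event with no observation in window is flagged
  ev_far <- make_events("E1", "2024-01-02T12:00:00+00:00", "csd",
                        csd_code = "sepsis")
  det <- event_detection(ev_far, scored, "s", threshold = 5)
  expect_false(det[1])
  expect_true(attr(det, "no_obs_in_window")[1])
})

test_that("cross-tab reproduces hand-assigned detections exactly", {
  # 10 events, one per episode; score columns a and b at the event
  # time: 6 both, 2 only-a, 1 only-b, 1 neither
  pat <- list(c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 1),
              c(1, 0), c(1, 0), c(0, 1), c(0, 0))
  scored <- do.call(rbind, lapply(seq_along(pat), function(i) {
    data.frame(episode_id = sprintf("E%02d", i),
               timestamp = parse_timestamp("2024-01-01T10:00:00+00:00"),
               a = ifelse(pat[[i]][1] == 1, 9, 1),
               b = ifelse(pat[[i]][2] == 1, 9, 1),
               stringsAsFactors = FALSE)
  }))
  ev <- make_events(sprintf("E%02d", 1:10),
                    rep("2024-01-01T12:00:00+00:00", 10),
                    rep("csd", 10), csd_code = "sepsis")
  ct <- detection_cross_tab(ev, scored, "a", "b", 5, 5)
  expect_equal(ct$both, 6L)
  expect_equal(ct$only_a, 2L)
  expect_equal(ct$only_b, 1L)
  expect_equal(ct$neither, 1L)
  expect_equal(ct$both + ct$only_a + ct$only_b + ct$neither, ct$total)
})

test_that("cross-tab cells always sum to the event total", {
  set.seed(47)
  for (i in 1:10) {
    n_ev <- sample(3:12, 1)
    scored <- data.frame(
      episode_id = sprintf("E%d", 1:n_ev),
      timestamp = parse_timestamp(rep("2024-01-01T10:00:00+00:00", n_ev)),
      a = runif(n_ev, 0, 10), b = runif(n_ev, 0, 10),
      stringsAsFactors = FALSE)
    ev <- make_events(sprintf("E%d", 1:n_ev),
                      rep("2024-01-01T11:00:00+00:00", n_ev),
                      rep("csd", n_ev), csd_code = "sepsis")
    ct <- detection_cross_tab(ev, scored, "a", "b", runif(1, 0, 10),
                              runif(1, 0, 10))
    expect_equal(ct$both + ct$only_a + ct$only_b + ct$neither, n_ev)
  }
})

test_that("evaluate_scores assembles areas, thresholds and cross-tab", {
  set.seed(48)
  n <- 300
  l <- rbinom(n, 1, 0.2)
  dews <- plogis(qlogis(0.2) + 2 * l + rnorm(n))
  news2 <- pmin(20, pmax(0, round(3 * l + rnorm(n, 3))))
  rep <- evaluate_scores(list(dews = dews, news2 = news2), l, B = 50,
                         seed = 1)
  expect_named(rep$areas, c("dews", "news2"))
  expect_true(rep$areas$dews$auroc > 0.5)
  expect_length(rep$areas$dews$auroc_ci, 2L)
  expect_named(rep$thresholds, c("5", "7"))
  expect_equal(nrow(rep$thresholds[["5"]]), 3L)
})
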