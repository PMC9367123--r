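test_that("inspired-oxygen ordinal follows the mapping table", {
  expect_equal(encode_fio2("air", NA), 0L)
  expect_equal(encode_fio2("flow", 2), 1L)
  expect_equal(encode_fio2("flow", 4), 2L)
  expect_equal(encode_fio2("flow", 8), 3L)
  expect_equal(encode_fio2("flow", 12), 4L)
  expect_equal(encode_fio2("flow", 20), 5L)
  expect_equal(encode_fio2("concentration", 24), 1L)
  expect_equal(encode_fio2("concentration", 35), 2L)
  expect_equal(encode_fio2("concentration", 60), 3L)
  expect_equal(encode_fio2("concentration", 85), 5L)
  expect_equal(encode_fio2(c("air", "flow", "concentration"),
                           c(NA, 2, 85)), c(0L, 1L, 5L))
  expect_error(encode_fio2("flow", NA), "o2_value")
})

test_that("hinge split: arithmetic, and low * high == 0 always", {
  expect_equal(hinge_split(70, c(51, 90)), list(low = 0, high = 0))
  expect_equal(hinge_split(120, c(51, 90)), list(low = 0, high = 30))
  expect_equal(hinge_split(85, c(111, 219)), list(low = 26, high = 0))
  set.seed(3)
  v <- runif(200, 0, 250)
  h <- hinge_split(v, c(51, 90))
  expect_true(all(h$low * h$high == 0))
  expect_true(all((h$low == 0 & h$high == 0) == (v >= 51 & v <= 90)))
  expect_true(all(h$low >= 0 & h$high >= 0))
})

test_that("delta is the difference from the previous observation", {
  expect_equal(delta_feature(c(65, 70)), c(0, 5))
  expect_equal(delta_feature(70), 0)
  expect_equal(delta_feature(c(90, 90)), c(0, 0))
})

test_that("rolling stats use the last five values, minimum three", {
  rs <- rolling_stats(c(70, 80, 90))
  expect_equal(rs$mean[3], 80)
  expect_equal(rs$sd[3], 10)          # sample SD
  expect_true(all(is.na(rs$mean[1:2])))
  rs2 <- rolling_stats(c(70, 70))
  expect_true(all(is.na(rs2$mean)))
  rs3 <- rolling_stats(c(60, 70, 80, 90, 100, 110))
  expect_equal(rs3$mean[6], 90)       # window = 70..110
  expect_equal(rs3$sd[6], sqrt(250))
  expect_equal(rs3$n[6], 5L)
})

test_that("slope categories encode normal/outside x stable/trend", {
  t0 <- parse_timestamp("2024-01-01T00:00:00+00:00")
  times <- t0 + c(0, 4, 8) * 3600
  band <- c(51, 90)
  expect_equal(slope_category(times, c(70, 72, 71), band)[3], 0L)
  expect_equal(slope_category(times, c(95, 105, 115), band)[3], 4L)
  expect_equal(slope_category(times, c(120, 110, 100), band)[3], 2L)
  # outside and flat -> outside-stable
  expect_equal(slope_category(times, c(100, 100, 100), band)[3], 3L)
  # inside but swinging -> normal-unstable (band width/8 = 4.875)
  expect_equal(slope_category(times, c(60, 85, 65), band)[3], 1L)
  # below the band and rising -> improving
  expect_equal(slope_category(times, c(30, 38, 46), band)[3], 2L)
  # fewer than three values -> 0 by convention
  expect_equal(slope_category(times[1:2], c(95, 105), band), c(0L, 0L))
})

test_that("slope categories are invariant to time translation", {
  set.seed(9)
  t0 <- parse_timestamp("2024-01-01T00:00:00+00:00")
  for (i in 1:20) {
    times <- t0 + cumsum(runif(6, 2, 6)) * 3600
    v <- rnorm(6, 95, 10)
    a <- slope_category(times, v, c(51, 90))
    b <- slope_category(times + 86400 * 365, v, c(51, 90))
    expect_equal(a, b)
  }
})

test_that("build_features returns exactly the 38-name manifest", {
  co <- make_cohort(make_episode_obs("E1", n = 6))
  f <- build_features(co)
  expect_equal(nrow(f), 4L)           # first two excluded
  expect_equal(setdiff(names(f), c("episode_id", "timestamp")),
               as.vector(feature_manifest()))
  expect_length(feature_manifest(), 38L)
})

test_that("constant history zeroes deltas, rolling SDs and slope cats", {
  co <- make_cohort(make_episode_obs("E1", n = 8))
  f <- build_features(co)
  dyn <- grep("_delta$|_rollsd$|_slopecat$", names(f), value = TRUE)
  expect_true(all(as.matrix(f[, dyn]) == 0))
  expect_true(all(f$hr_rollmean == 70))
})

test_that("third observation already has defined rolling stats", {
  co <- make_cohort(make_episode_obs("E1", n = 3, heart_rate = 70))
  co$observations$heart_rate <- c(70, 80, 90)
  f <- build_features(co)
  expect_equal(nrow(f), 1L)
  expect_equal(f$hr_rollmean, 80)
  expect_equal(f$hr_rollsd, 10)
  expect_equal(f$hr_delta, 10)
})

test_that("features never look into the future (truncation equivalence)", {
  cfg <- sim_config(n_episodes = 6, seed = 31)
  co <- generate_cohort(cfg)
  f_full <- build_features(co)
  ep <- f_full$episode_id[nrow(f_full)]
  cut_t <- f_full$timestamp[nrow(f_full) - 1L]
  trunc <- co
  keep <- trunc$observations$episode_id != ep |
    trunc$observations$timestamp <= cut_t
  trunc$observations <- trunc$observations[keep, , drop = FALSE]
  f_trunc <- build_features(trunc)
  shared <- paste(f_trunc$episode_id, f_trunc$timestamp)
  idx <- match(shared, paste(f_full$episode_id, f_full$timestamp))
  expect_false(anyNA(idx))
  expect_equal(f_trunc[, as.vector(feature_manifest())],
               f_full[idx, as.vector(feature_manifest())],
               ignore_attr = TRUE)
})

test_that("Scale 2 episodes use the 88-92 SpO2 band for hinges", {
  obs <- make_episode_obs("E1", n = 4, spo2 = 90, scale2_label = TRUE)
  f2 <- build_features(make_cohort(obs))
  expect_equal(f2$spo2_low, rep(0, 2))
  obs1 <- make_episode_obs("E2", n = 4, spo2 = 90)
  f1 <- build_features(make_cohort(obs1))
  expect_equal(f1$spo2_low, rep(6, 2))
})

test_that("normalizer: fit on training, apply with stored constants", {
  X <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "hr_high"))
  nz <- suppressWarnings(fit_normalizer(X))
  expect_equal(as.numeric(apply_normalizer(nz, X)), c(-1, 0, 1))
  held_out <- matrix(10, ncol = 1, dimnames = list(NULL, "hr_high"))
  expect_equal(as.numeric(apply_normalizer(nz, held_out)), (10 - 2) / 1)
  Xc <- cbind(X, matrix(5, 3, 1, dimnames = list(NULL, "rr_high")))
  expect_warning(nzc <- fit_normalizer(Xc), "constant")
  expect_equal(as.numeric(apply_normalizer(nzc, Xc)[, "rr_high"]),
               rep(0, 3))
  # transformed training matrix has mean 0, variance 1
  set.seed(2)
  M <- matrix(rnorm(200, 5, 3), 50, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  nzm <- fit_normalizer(M)
  Z <- apply_normalizer(nzm, M)
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_true(all(abs(apply(Z, 2, var) - 1) < 1e-9))
})
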