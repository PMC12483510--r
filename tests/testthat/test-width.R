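test_that("the width dataset computes cue distances and exclusions", {
  st <- fixture_stages()
  res <- fixture_result()
  ev <- res$events[res$events$category %in% c("BTSP", "NON_BTSP"), ]
  wd <- build_width_dataset(ev, st$binned, st$session$behavior,
                            st$session$corridor)
  expect_equal(nrow(wd), nrow(ev))
  # cue distance is the along-track distance to the nearest landmark
  for (i in seq_len(nrow(wd))) {
    center <- ((ev$left_bin[i] + ev$right_bin[i]) / 2 - 0.5) * 4.24
    expect_equal(wd$cue_distance_cm[i],
                 min(abs(center - st$session$corridor$landmarks_cm)))
  }
  # landmark at 200, field center at 180: distance 20
  spec <- corridor_spec(length_cm = 400, bin_width_cm = 4,
                        landmarks_cm = 200, reward_zone_cm = c(350, 390))
  ev1 <- data.frame(roi = 1L, category = "BTSP", formation_lap = 1L,
                    left_bin = 43L, right_bin = 48L, width_cm = 24)
  beh <- simulate_behavior(spec, n_laps = 2, seed = 1)
  b1 <- bin_session(beh, matrix(0, nrow(beh), 1), spec)
  wd1 <- build_width_dataset(ev1, b1, beh, spec)
  expect_equal(wd1$cue_distance_cm, 20, tolerance = 1e-9)

  # fields touching the corridor edges are excluded
  ev2 <- data.frame(roi = 1L, category = "BTSP", formation_lap = 1L,
                    left_bin = 1L, right_bin = 6L, width_cm = 24)
  expect_true(build_width_dataset(ev2, b1, beh, spec)$excluded)
  expect_equal(build_width_dataset(ev2, b1, beh, spec)$reason,
               "touches_corridor_edge")
})

test_that("slow formation traversals are excluded at 5 cm/s", {
  spec <- corridor_spec(length_cm = 100, bin_width_cm = 10,
                        landmarks_cm = 50, reward_zone_cm = c(80, 95))
  beh <- simulate_behavior(spec, n_laps = 2, speed_range_cm_s = c(4, 4),
                           speed_jitter_sd = 0, slowdown_factor = 1,
                           seed = 1)
  b <- bin_session(beh, matrix(0, nrow(beh), 1), spec, 0)
  ev <- data.frame(roi = 1L, category = "BTSP", formation_lap = 1L,
                   left_bin = 4L, right_bin = 6L, width_cm = 30)
  wd <- build_width_dataset(ev, b, beh, spec)
  expect_true(wd$excluded)
  expect_equal(wd$reason, "low_speed")
})

test_that("LOO explained variance approaches 1 for exact linear data", {
  d <- data.frame(width_cm = 10 + 0.8 * (20:69),
                  speed_cm_s = as.numeric(20:69))
  ev <- loo_explained_variance(d, "speed")
  expect_gt(ev$ev, 1 - 1e-9)
  expect_lte(ev$ev, 1)
})

test_that("LOO predictions equal a naive refit-per-observation oracle", {
  set.seed(21)
  n <- 40
  d <- data.frame(width_cm = rnorm(n, 40, 10),
                  speed_cm_s = rnorm(n, 35, 5),
                  cue_distance_cm = runif(n, 0, 60))
  ev <- loo_explained_variance(d, c("speed", "cue_distance"))
  oracle <- numeric(n)
  for (i in seq_len(n)) {
    fit <- lm(width_cm ~ speed_cm_s + cue_distance_cm, data = d[-i, ])
    oracle[i] <- predict(fit, d[i, ])
  }
  expect_equal(ev$predictions, oracle, tolerance = 1e-10)
  expect_equal(ev$ev, 1 - mean((d$width_cm - oracle)^2) / var(d$width_cm),
               tolerance = 1e-10)
})

test_that("an uninformative predictor has non-positive expected EV", {
  set.seed(31)
  evs <- vapply(1:100, function(i) {
    d <- data.frame(width_cm = rnorm(30, 40, 10),
                    speed_cm_s = rnorm(30, 35, 5))
    loo_explained_variance(d, "speed")$ev
  }, numeric(1))
  expect_lt(mean(evs), 0)
})

test_that("EV is invariant to affine rescaling of predictors", {
  set.seed(41)
  d <- data.frame(width_cm = rnorm(50, 40, 8),
                  speed_cm_s = rnorm(50, 35, 5),
                  cue_distance_cm = runif(50, 0, 60))
  a <- loo_explained_variance(d, c("speed", "cue_distance"))
  d2 <- d
  d2$speed_cm_s <- 3.6 * d$speed_cm_s + 100
  d2$cue_distance_cm <- 0.01 * d$cue_distance_cm - 5
  b <- loo_explained_variance(d2, c("speed", "cue_distance"))
  expect_equal(a$ev, b$ev, tolerance = 1e-10)
})

test_that("the start-offset search recovers a known origin shift", {
  spec <- corridor_spec()
  set.seed(51)
  n <- 120
  center <- runif(n, 60, 700)
  true_offset <- 30
  cue <- vapply(center, function(p) {
    min(abs((p - true_offset) - spec$landmarks_cm))
  }, numeric(1))
  width <- 20 + 0.5 * cue + rnorm(n, 0, 2)
  speed <- rnorm(n, 35, 4)
  builder <- function(off) {
    d <- data.frame(width_cm = width, speed_cm_s = speed,
                    cue_distance_cm = vapply(center, function(p) {
                      min(abs((p - off) - spec$landmarks_cm))
                    }, numeric(1)))
    d
  }
  opt <- optimize_start_offset(builder, step_cm = 1)
  expect_lte(abs(opt$best_offset_cm - true_offset), 1)
  # offset-free data: the grid prefers the smallest (zero) offset on ties
  expect_equal(optimize_start_offset(function(o) builder(true_offset),
                                     step_cm = 10)$best_offset_cm, 0)
  expect_equal(range(opt$curve$offset_cm), c(0, 50))
})

test_that("subsampling at full size collapses the CI to the point estimate", {
  set.seed(61)
  d <- data.frame(width_cm = rnorm(40, 40, 10),
                  speed_cm_s = rnorm(40, 35, 5))
  d$width_cm <- d$width_cm + 0.9 * d$speed_cm_s
  out <- subsample_regression_comparison(d, nrow(d), n_resamples = 50,
                                         seed = 5)
  ct <- suppressWarnings(cor.test(d$width_cm, d$speed_cm_s,
                                  method = "spearman"))
  expect_equal(unname(out$r_ci[1]), unname(ct$estimate), tolerance = 1e-12)
  expect_equal(unname(out$r_ci[2]), unname(ct$estimate), tolerance = 1e-12)
  expect_error(subsample_regression_comparison(d, 2), ">= 3")
})

test_that("same-population comparisons fall inside the subsample CI", {
  # with a large parent set the subsample CI approximates the sampling
  # distribution of an equally sized independent draw; coverage for a
  # same-population comparison then sits near (slightly below) 95%
  set.seed(71)
  inside <- vapply(1:30, function(i) {
    base <- data.frame(speed_cm_s = rnorm(350, 35, 5))
    base$width_cm <- 30 + 0.6 * base$speed_cm_s + rnorm(350, 0, 6)
    comp_idx <- sample.int(350, 50)
    out <- subsample_regression_comparison(base[-comp_idx, ], 50,
                                           comparison = base[comp_idx, ],
                                           n_resamples = 300, seed = i)
    !out$r_outside
  }, logical(1))
  expect_gte(mean(inside), 0.85)
})
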