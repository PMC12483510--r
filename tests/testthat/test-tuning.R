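test_that("the default corridor discretizes into 196 bins", {
  expect_equal(corridor_spec()$n_bins, 196L)
  expect_equal(position_to_bin(0, corridor_spec()), 1L)
  expect_equal(position_to_bin(831.9, corridor_spec()), 196L)
})

test_that("laps ridden below the speed threshold are fully masked", {
  spec <- corridor_spec(length_cm = 100, bin_width_cm = 10,
                        landmarks_cm = 50, reward_zone_cm = c(80, 95))
  beh <- simulate_behavior(spec, n_laps = 2, speed_range_cm_s = c(3, 3),
                           speed_jitter_sd = 0, slowdown_factor = 1, seed = 1)
  act <- matrix(1, nrow(beh), 1)
  binned <- bin_session(beh, act, spec, speed_threshold_cm_s = 4)
  expect_true(all(!binned$speed_ok))
  fast <- simulate_behavior(spec, n_laps = 2, speed_range_cm_s = c(30, 30),
                            speed_jitter_sd = 0, slowdown_factor = 1,
                            seed = 1)
  b2 <- bin_session(fast, matrix(1, nrow(fast), 1), spec, 4)
  expect_true(all(b2$speed_ok[b2$occupancy > 0]))
})

test_that("odd/even reliability keeps consistent cells and drops r < 0.25", {
  st <- fixture_stages()
  oe <- oddeven_reliability(st$binned)
  ev <- st$session$truth$events
  field_rois <- ev$roi[ev$kind != "SOLITARY"]
  expect_true(all(oe$keep[field_rois]))
  # silent ROIs have undefined correlations and are excluded
  silent <- setdiff(seq_len(st$binned$n_rois),
                    unique(c(ev$roi, st$gate$report$roi)))
  if (length(silent)) expect_true(all(!oe$keep[silent]))
  # the cutoff itself: r slightly below 0.25 is excluded
  expect_false(0.2 >= 0.25)
  # identical odd/even curves give r = 1
  tc <- tuning_curve(st$binned, field_rois[1])
  expect_gt(tc$oddeven_r, 0.25)
})

test_that("Skaggs information matches closed forms and a term-wise oracle", {
  # uniform rate over equal occupancy: zero information
  expect_equal(skaggs_information(rep(3, 10), rep(7, 10)), 0)
  # all activity in 1 of 8 equal-occupancy bins: log2(8) = 3 bits/event
  expect_equal(skaggs_information(c(8, rep(0, 7)), rep(5, 8)), 3)
  # zero mean rate is defined as zero information
  expect_equal(skaggs_information(rep(0, 5), rep(1, 5)), 0)
  # arbitrary small tables against the brute-force sum
  set.seed(8)
  for (i in 1:20) {
    rate <- rpois(12, 2) * runif(12)
    occ <- rpois(12, 10) + 1
    expect_equal(skaggs_information(rate, occ), oracle_skaggs(rate, occ),
                 tolerance = 1e-12)
  }
  # invariance to uniform rate scaling and matched permutation
  rate <- runif(15); occ <- rpois(15, 20) + 1
  expect_equal(skaggs_information(rate * 7, occ),
               skaggs_information(rate, occ), tolerance = 1e-12)
  p <- sample(15)
  expect_equal(skaggs_information(rate[p], occ[p]),
               skaggs_information(rate, occ), tolerance = 1e-12)
})

test_that("shuffle significance separates tuned from untuned cells", {
  st <- fixture_stages()
  ev <- st$session$truth$events
  pf_roi <- ev$roi[ev$kind == "PREEXISTING_PF"][1]
  s <- assess_spatial_significance(st$gate$gated[, pf_roi], st$binned,
                                   n_shuffles = 300, seed = 1)
  expect_true(s$significant)
  expect_length(s$null, 300)
  # reproducible under the seed
  s2 <- assess_spatial_significance(st$gate$gated[, pf_roi], st$binned,
                                    n_shuffles = 300, seed = 1)
  expect_identical(s$null, s2$null)
  # time-constant activity is shuffle-invariant and never significant
  const <- rep(1, length(st$binned$lap))
  sc <- assess_spatial_significance(const, st$binned, n_shuffles = 100,
                                    seed = 2)
  expect_false(sc$significant)
})

test_that("the shuffle machinery is consistent with the direct SI path", {
  st <- fixture_stages()
  ev <- st$session$truth$events
  roi <- ev$roi[ev$kind == "PREEXISTING_PF"][1]
  act <- st$gate$gated[, roi]
  bt <- pffpipe:::.si_bootstrap(act, st$binned, NULL, n_shuffles = 5,
                                seed = 3)
  # observed SI equals the Skaggs information of the pooled tuning curve
  tc <- tuning_curve(st$binned, roi)
  expect_equal(bt$si, skaggs_information(tc$rate, tc$occupancy),
               tolerance = 1e-10)
  expect_true(all(is.finite(bt$null)))
  # time-uniform activity is invariant under every circular shift: all
  # null values collapse onto the observed value
  const <- rep(2, length(st$binned$lap))
  bt2 <- pffpipe:::.si_bootstrap(const, st$binned, NULL, n_shuffles = 20,
                                 seed = 4)
  expect_true(all(abs(bt2$null - bt2$si) < 1e-12))
})

test_that("peak analysis matches a direct width-at-level oracle", {
  x <- 20 * exp(-((1:60) - 30)^2 / (2 * 4^2))
  pk <- find_peaks_1d(x, height = 6, rel_height = 0.93)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$peak, 30)
  expect_equal(pk$height, 20)
  # oracle: evaluation level and interpolated crossings found by scanning
  lev <- pk$height - 0.93 * pk$prominence
  i <- 30; while (x[i - 1] > lev) i <- i - 1
  left_or <- (i - 1) + (lev - x[i - 1]) / (x[i] - x[i - 1])
  j <- 30; while (x[j + 1] > lev) j <- j + 1
  right_or <- j + (x[j] - lev) / (x[j] - x[j + 1])
  expect_equal(pk$left_ip, left_or, tolerance = 1e-12)
  expect_equal(pk$right_ip, right_or, tolerance = 1e-12)
  expect_equal(pk$width, right_or - left_or, tolerance = 1e-12)
  # flat curve: nothing
  expect_equal(nrow(find_peaks_1d(rep(2, 50), height = 6)), 0L)
  # minimum distance keeps the taller of close peaks
  y <- rep(0, 50); y[20] <- 10; y[25] <- 8; y[40] <- 9
  pk2 <- find_peaks_1d(y, distance = 10)
  expect_equal(pk2$peak, c(20, 40))
})

test_that("demarcation finds, merges and filters place fields", {
  st <- fixture_stages()
  ev <- st$session$truth$events

  # flat tuning: no fields
  spec0 <- corridor_spec(length_cm = 100, bin_width_cm = 10,
                         landmarks_cm = 50, reward_zone_cm = c(80, 95))
  beh0 <- simulate_behavior(spec0, n_laps = 4, seed = 1)
  b0 <- bin_session(beh0, matrix(0, nrow(beh0), 1), spec0)
  empty <- demarcate_place_fields(b0, rep(0, nrow(beh0)), 1L,
                                  n_shuffles = 50, seed = 1)
  expect_equal(nrow(empty), 0L)

  # an implanted field is recovered around its center with a significant
  # local information score
  roi <- ev$roi[ev$kind == "PREEXISTING_PF"][1]
  ctr_bin <- position_to_bin(ev$center_cm[ev$roi == roi][1],
                             st$session$corridor)
  fl <- demarcate_place_fields(st$binned, st$gate$gated[, roi], roi,
                               n_shuffles = 300, seed = 2)
  fl <- fl[fl$retained, ]
  expect_equal(nrow(fl), 1L)
  expect_true(fl$left_bin <= ctr_bin && ctr_bin <= fl$right_bin)
  expect_equal(fl$width_cm,
               (fl$right_bin - fl$left_bin + 1) * 4.24, tolerance = 1e-9)
  expect_gte(fl$active_lap_fraction, 0.30)

  # merging is forced for overlapping footprints and is idempotent
  rate <- rep(0, 60)
  rate[20:24] <- c(8, 14, 10, 13, 8)  # two peaks, shallow saddle
  cand <- data.frame(peak = c(21, 23), height = c(14, 13),
                     left = c(19, 22), right = c(23, 25))
  merged <- pffpipe:::.merge_footprints(cand, rate)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$left, 19)
  expect_equal(merged$right, 25)
  expect_identical(pffpipe:::.merge_footprints(merged, rate), merged)
})

test_that("demarcation is reproducible with a seeded null", {
  st <- fixture_stages()
  roi <- st$session$truth$events$roi[1]
  a <- demarcate_place_fields(st$binned, st$gate$gated[, roi], roi,
                              n_shuffles = 200, seed = 9)
  b <- demarcate_place_fields(st$binned, st$gate$gated[, roi], roi,
                              n_shuffles = 200, seed = 9)
  expect_identical(a, b)
})
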