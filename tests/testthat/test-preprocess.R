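test_that("neuropil correction applies the scaled subtraction exactly", {
  expect_equal(neuropil_correct(matrix(100), matrix(20))[1, 1], 86)
  f_raw <- matrix(rnorm(1000 * 50, 200, 20), 1000, 50)
  expect_equal(neuropil_correct(f_raw, matrix(0, 1000, 50)), f_raw)
  f_neu <- matrix(rnorm(1000 * 50, 100, 10), 1000, 50)
  oracle <- matrix(NA_real_, 1000, 50)
  for (j in 1:50) for (i in 1:1000) {
    oracle[i, j] <- f_raw[i, j] - 0.7 * f_neu[i, j]
  }
  expect_equal(neuropil_correct(f_raw, f_neu), oracle, tolerance = 1e-12)
  expect_error(neuropil_correct(f_raw, f_neu[, 1:10]), "shape")
})

test_that("linear scaling propagates through correction and cancels in dF/F", {
  set.seed(1)
  f_raw <- matrix(rnorm(1500, 300, 10))
  f_neu <- matrix(rnorm(1500, 100, 5))
  f1 <- neuropil_correct(f_raw, f_neu)
  f2 <- neuropil_correct(3 * f_raw, 3 * f_neu)
  expect_equal(f2, 3 * f1, tolerance = 1e-12)
  expect_equal(compute_dff(f2, 200L)$dff, compute_dff(f1, 200L)$dff,
               tolerance = 1e-12)
})

test_that("event gating accepts real transients and rejects flat traces", {
  # all-zero deconvolved: nothing to gate
  f <- matrix(rnorm(400, 100, 1))
  g0 <- gate_inferred_events(f, matrix(0, 400, 1))
  expect_true(all(g0$gated == 0))
  expect_equal(nrow(g0$report), 0L)

  # exactly linear baseline (SD_local = 0) and a step far above the global
  # noise: the candidate must be accepted with F_base equal to the linear
  # prediction at t - 20
  n <- 400
  fv <- 100 + 0.1 * seq_len(n)
  fv[201:260] <- fv[201:260] + 50
  d <- matrix(0, n, 1)
  d[201, 1] <- 10
  g <- gate_inferred_events(matrix(fv), d)
  expect_true(g$report$accepted[1])
  expect_equal(g$report$sd_local[1], 0, tolerance = 1e-9)
  expect_equal(g$report$f_base[1], 100 + 0.1 * 181, tolerance = 1e-9)
  pk <- 200L + which.max(fv[201:210])
  expect_equal(g$report$f_max[1], mean(fv[(pk - 1):(pk + 1)]),
               tolerance = 1e-9)
  expect_equal(g$gated[201, 1], 10)

  # flat fluorescence with noise: amplitude ~0 cannot clear a positive gate
  set.seed(4)
  fv2 <- rnorm(n, 100, 2)
  g2 <- gate_inferred_events(matrix(fv2), d)
  expect_false(g2$report$accepted[1])
  expect_equal(g2$gated[201, 1], 0)
})

test_that("gating never creates activity outside the input support", {
  set.seed(11)
  n <- 600
  f <- matrix(rnorm(n * 3, 100, 5), n, 3)
  d <- matrix(0, n, 3)
  d[sample.int(n * 3, 40)] <- runif(40, 1, 50)
  g <- gate_inferred_events(f, d)
  expect_true(all(g$gated[d == 0] == 0))
  expect_true(all(g$gated %in% c(0, d)))
  # events too close to the trace start are rejected, not an error
  d2 <- matrix(0, n, 1)
  d2[3, 1] <- 5
  expect_silent(g3 <- gate_inferred_events(f[, 1, drop = FALSE], d2))
  expect_false(g3$report$accepted[1])
})

test_that("dF/F uses the preceding-window rolling median baseline", {
  # constant trace: dff identically zero
  expect_true(all(compute_dff(matrix(5, 1200, 1))$dff == 0))

  # step trace: settled baseline after the window, brute-force oracle in
  # the transition zone
  n <- 7000
  x <- c(rep(10, 4999), rep(20, n - 4999))
  res <- compute_dff(matrix(x), window = 1000L)
  expect_true(all(res$f0[6000:n] == 20))
  expect_true(all(res$dff[6000:n] == 0))
  expect_equal(as.numeric(res$f0), oracle_f0(x, 1000L), tolerance = 1e-12)

  # noisy trace against the oracle, including the leading forward window
  set.seed(2)
  y <- rnorm(2500, 50, 5)
  res2 <- compute_dff(y, window = 1000L)
  f0_or <- oracle_f0(y, 1000L)
  expect_equal(as.numeric(res2$f0), f0_or, tolerance = 1e-12)
  expect_equal(as.numeric(res2$dff), (y - f0_or) / f0_or, tolerance = 1e-12)

  # traces shorter than the window fall back to the whole-trace median
  z <- rnorm(500, 30, 2)
  expect_equal(as.numeric(compute_dff(z)$f0), rep(median(z), 500))

  # non-positive baseline is flagged and zeroed
  w <- c(rep(-5, 300), rep(1, 300))
  r3 <- compute_dff(w, window = 100L)
  expect_gt(r3$n_bad_f0, 0)
  expect_true(all(is.finite(r3$dff)))
})

test_that("transient alignment finds the steepest rise and measures peaks", {
  # flat traces align at their midpoints with near-zero amplitudes
  flat <- lapply(1:4, function(i) rep(0.01 * i, 301))
  al <- align_and_measure_transients(flat, rep(FALSE, 4))
  expect_equal(al$alignment_index, rep(151L, 4))
  expect_true(all(abs(al$peak_amplitude) < 1e-9))
  expect_equal(ncol(al$windows), 201L)

  # ramp-then-plateau: alignment equals the argmax of the explicitly
  # computed smoothed 4-lag difference sequence (midpoint convention)
  x <- c(rep(0, 120), seq(0, 4, length.out = 30), rep(4, 150))
  sm <- vapply(seq_along(x), function(i) {
    mean(x[max(1, i - 2):min(length(x), i + 2)])
  }, numeric(1))
  d <- sm[-(1:4)] - sm[seq_len(length(sm) - 4)]
  expected <- which.max(d) + 2L
  al2 <- align_and_measure_transients(list(x), TRUE)
  expect_equal(al2$alignment_index, expected)

  # translation equivariance: shifting the segment shifts the alignment
  x_shift <- c(rep(0, 37), x)
  al3 <- align_and_measure_transients(list(x_shift), TRUE)
  expect_equal(al3$alignment_index, expected + 37L)

  # empty input
  al4 <- align_and_measure_transients(list(), logical(0))
  expect_equal(nrow(al4$windows), 0L)
})
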