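# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture_cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small session with implanted events of every kind.
fixture_session <- function() {
  fixture_cached("session", function() {
    make_session(
      n_rois = 30, n_laps = 35, seed = 101,
      truth_args = list(n_btsp = 3, n_non_btsp = 3, n_solitary = 2,
                        n_preexisting = 5, formation_lap_range = c(19, 24)))
  })
}

# Reduced-shuffle config keeps module tests quick; the acceptance tests use
# the full defaults.
fixture_config <- function() {
  pff_config(n_shuffles = 300L, bootstrap_n_null = 300L, seed = 7L)
}

fixture_result <- function() {
  fixture_cached("result", function() {
    run_pipeline(fixture_session(), fixture_config())
  })
}

# Preprocessed stages of the fixture session.
fixture_stages <- function() {
  fixture_cached("stages", function() {
    ses <- fixture_session()
    f <- neuropil_correct(ses$F_raw, ses$F_neu)
    gate <- gate_inferred_events(f, ses$deconvolved)
    binned <- bin_session(ses$behavior, gate$gated, ses$corridor)
    list(session = ses, f = f, gate = gate, binned = binned)
  })
}

# Hand-rolled Skaggs information, term by term.
oracle_skaggs <- function(rate, occupancy) {
  ok <- !is.na(rate) & occupancy > 0
  rate <- rate[ok]; occupancy <- occupancy[ok]
  p <- occupancy / sum(occupancy)
  rbar <- sum(p * rate)
  if (rbar <= 0) return(0)
  s <- 0
  for (i in seq_along(rate)) {
    if (rate[i] > 0) {
      s <- s + p[i] * (rate[i] / rbar) * log2(rate[i] / rbar)
    }
  }
  s
}

# Brute-force preceding/following rolling-median baseline.
oracle_f0 <- function(x, window = 1000L) {
  n <- length(x)
  if (n < window) return(rep(median(x), n))
  vapply(seq_len(n), function(t) {
    if (t > window) {
      median(x[(t - window):(t - 1L)])
    } else if (t + window <= n) {
      median(x[(t + 1L):(t + window)])
    } else {
      median(x[(t + 1L):n])
    }
  }, numeric(1))
}

# Brute-force per-frame binning oracle: mean activity and occupancy.
oracle_binning <- function(behavior, activity, spec) {
  n_laps <- attr(behavior, "n_laps")
  n_bins <- spec$n_bins
  sums <- array(0, c(n_laps, n_bins, ncol(activity)))
  occ <- matrix(0L, n_laps, n_bins)
  for (i in seq_len(nrow(behavior))) {
    l <- behavior$lap[i]
    b <- position_to_bin(behavior$position_cm[i], spec)
    occ[l, b] <- occ[l, b] + 1L
    sums[l, b, ] <- sums[l, b, ] + activity[i, ]
  }
  mean_act <- sums / array(ifelse(occ > 0, occ, NA_real_),
                           dim = dim(sums))
  list(mean = mean_act, occupancy = occ)
}

# A deterministic hand-built PF activity matrix (laps x bins) for the
# classification truth-table tests. Values are already >= 64 or 0.
pfm_from_matrix <- function(m, bin_width_cm = 4.24, left_bin = 1L) {
  bins <- seq.int(left_bin, left_bin + ncol(m) - 1L)
  structure(list(m = m, bins = bins, left_bin = left_bin,
                 right_bin = bins[length(bins)],
                 right_ext = bins[length(bins)],
                 threshold_au = 64, bin_width_cm = bin_width_cm),
            class = "pf_activity_matrix")
}
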