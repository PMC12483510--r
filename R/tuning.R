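#' Bin a session's activity by lap and spatial bin
#'
#' Computes per-lap, per-bin mean activity (a.u./frame) and frame occupancy
#' for every ROI, plus the low-speed exclusion mask: lap x bin cells whose
#' mean running speed is below `speed_threshold_cm_s` are masked out of all
#' tuning statistics (the raw means are kept so that stages that do not
#' speed-filter, such as the place-field activity matrix, can reuse them).
#'
#' @param behavior A `behavior_trace`.
#' @param activity frames x ROIs matrix (typically the gated activity).
#' @param spec A [corridor_spec()].
#' @param speed_threshold_cm_s Minimum mean bin speed (default 4 cm/s).
#' @return A `binned_session` list: `activity` (laps x bins x ROIs mean,
#'   `NA` where occupancy is 0), `occupancy` (laps x bins frame counts),
#'   `speed_ok` (laps x bins mask), `lap`, `frame_bin` (per-frame vectors),
#'   `n_laps`, `n_bins`, `spec`.
#' @export
bin_session <- function(behavior, activity, spec, speed_threshold_cm_s = 4) {
  if (nrow(activity) != nrow(behavior)) {
    stop("'activity' and 'behavior' must be frame-aligned", call. = FALSE)
  }
  n_laps <- attr(behavior, "n_laps")
  n_bins <- spec$n_bins
  fb <- frame_bins(behavior, spec)
  grp <- (behavior$lap - 1L) * n_bins + fb
  ng <- n_laps * n_bins
  occ <- tabulate(grp, nbins = ng)
  sums <- rowsum(activity, grp, reorder = FALSE)
  full <- matrix(0, ng, ncol(activity))
  full[as.integer(rownames(sums)), ] <- sums
  spd <- numeric(ng)
  spd_s <- rowsum(behavior$speed_cm_s, grp, reorder = FALSE)
  spd[as.integer(rownames(spd_s))] <- spd_s
  mean_act <- full / ifelse(occ > 0, occ, NA_real_)
  act <- array(mean_act, dim = c(n_bins, n_laps, ncol(activity)))
  act <- aperm(act, c(2, 1, 3))
  occ_m <- t(matrix(occ, n_bins, n_laps))
  spd_m <- t(matrix(spd / ifelse(occ > 0, occ, NA_real_), n_bins, n_laps))
  speed_ok <- !is.na(spd_m) & spd_m >= speed_threshold_cm_s
  out <- list(activity = act, occupancy = occ_m, speed_ok = speed_ok,
              lap = behavior$lap, frame_bin = fb,
              lap_index = split(seq_along(fb), behavior$lap),
              n_laps = n_laps, n_bins = n_bins, n_rois = ncol(activity),
              spec = spec)
  class(out) <- "binned_session"
  out
}

#' @export
print.binned_session <- function(x, ...) {
  cat(sprintf("<binned_session> %d laps x %d bins x %d ROIs (%.1f%% bins speed-masked)\n",
              x$n_laps, x$n_bins, x$n_rois, 100 * mean(!x$speed_ok)))
  invisible(x)
}

# Pooled (occupancy-weighted) tuning curve over a lap subset, honoring the
# speed mask; returns per-bin mean activity, NA where no unmasked frames.
pooled_tuning <- function(binned, roi, laps = seq_len(binned$n_laps)) {
  occ <- binned$occupancy[laps, , drop = FALSE]
  ok <- binned$speed_ok[laps, , drop = FALSE]
  a <- binned$activity[laps, , roi, drop = FALSE]
  dim(a) <- dim(occ)
  sums <- a * occ
  sums[!ok | is.na(sums)] <- 0
  occ_ok <- occ * ok
  tot <- colSums(occ_ok)
  colSums(sums) / ifelse(tot > 0, tot, NA_real_)
}

#' Tuning curve of one ROI
#'
#' Mean gated activity per spatial bin across laps (occupancy-weighted,
#' speed-masked bins excluded), with odd- and even-lap curves and their
#' Pearson correlation.
#'
#' @param binned A [bin_session()] result.
#' @param roi ROI index.
#' @return A `tuning_curve` list: `rate` (per bin), `odd`, `even`,
#'   `oddeven_r`, `occupancy` (unmasked frame counts per bin).
#' @export
tuning_curve <- function(binned, roi) {
  laps <- seq_len(binned$n_laps)
  rate <- pooled_tuning(binned, roi)
  odd <- pooled_tuning(binned, roi, laps[laps %% 2L == 1L])
  even <- pooled_tuning(binned, roi, laps[laps %% 2L == 0L])
  ok <- !is.na(odd) & !is.na(even)
  r <- safe_cor(odd[ok], even[ok])
  occ <- colSums(binned$occupancy * binned$speed_ok)
  structure(list(rate = rate, odd = odd, even = even, oddeven_r = r,
                 occupancy = occ, roi = roi),
            class = "tuning_curve")
}

#' Odd/even-lap tuning reliability filter
#'
#' Pearson correlation between odd- and even-lap tuning curves per ROI;
#' ROIs with `r < threshold` (or an undefined correlation, e.g. a silent
#' cell) are excluded from place-field analysis.
#'
#' @param binned A [bin_session()] result.
#' @param threshold Correlation cutoff (default 0.25).
#' @return data.frame with `roi`, `oddeven_r`, `keep`.
#' @export
oddeven_reliability <- function(binned, threshold = 0.25) {
  res <- vapply(seq_len(binned$n_rois), function(r) {
    tuning_curve(binned, r)$oddeven_r
  }, numeric(1))
  data.frame(roi = seq_len(binned$n_rois), oddeven_r = res,
             keep = !is.na(res) & res >= threshold)
}

#' Skaggs spatial information
#'
#' `SI = sum_i p_i * (r_i / rbar) * log2(r_i / rbar)` (bits/event), where
#' `p_i` is the occupancy fraction of bin i, `r_i` the mean activity in bin
#' i, and `rbar = sum_i p_i r_i`. Bins with zero rate contribute 0; if the
#' overall mean rate is 0 the information is defined as 0.
#'
#' @param rate Per-bin mean activity (NA bins are dropped together with
#'   their occupancy).
#' @param occupancy Per-bin occupancy (frame counts or fractions).
#' @return Spatial information in bits per event.
#' @examples
#' skaggs_information(c(8, 0, 0, 0), rep(1, 4))  # log2(4) = 2 bits
#' @export
skaggs_information <- function(rate, occupancy) {
  stopifnot(length(rate) == length(occupancy))
  ok <- !is.na(rate) & !is.na(occupancy) & occupancy > 0
  rate <- rate[ok]
  occupancy <- occupancy[ok]
  tot <- sum(occupancy)
  if (tot <= 0) return(0)
  p <- occupancy / tot
  rbar <- sum(p * rate)
  if (rbar <= 0) return(0)
  nz <- rate > 0
  sum(p[nz] * (rate[nz] / rbar) * log2(rate[nz] / rbar))
}

# Shared circular-shift bootstrap machinery. Within each lap the activity
# is circularly shifted in time by an independent uniform amount per lap
# and per shuffle, re-binned, and the Skaggs information recomputed. With
# a bin subset (local field test) the circular domain is the lap's
# traversal of that region, so the region's per-lap activity mass is
# conserved under shuffling. Returns observed SI and the null vector.
.si_bootstrap <- function(activity, binned, bins_subset = NULL,
                          n_shuffles = 1500L, seed = NULL) {
  n_bins <- binned$n_bins
  lap <- binned$lap
  fb <- binned$frame_bin
  keep_cell <- binned$speed_ok  # laps x bins
  sub <- if (is.null(bins_subset)) seq_len(n_bins) else sort(bins_subset)
  in_sub <- logical(n_bins)
  in_sub[sub] <- TRUE

  occ_bins <- numeric(n_bins)
  obs <- numeric(n_bins)
  acc <- numeric(n_bins * n_shuffles)
  with_seed(seed, {
    for (l in seq_len(binned$n_laps)) {
      fr <- binned$lap_index[[l]]
      if (!length(fr)) next
      pb_all <- fb[fr]
      fr <- fr[in_sub[pb_all]]  # circular domain: traversal of the region
      n_l <- length(fr)
      if (!n_l) next
      pb <- fb[fr]
      keep_fr <- keep_cell[l, pb]
      occ_bins <- occ_bins + tabulate(pb[keep_fr], nbins = n_bins)
      a <- activity[fr]
      nz <- which(a != 0)
      obs_keep <- nz[keep_fr[nz]]
      if (length(obs_keep)) {
        .cum_add(obs, pb[obs_keep], a[obs_keep])
      }
      if (!length(nz)) next
      u <- sample.int(n_l, n_shuffles, replace = TRUE) - 1L
      idx <- (outer(nz - 1L, u, "+") %% n_l) + 1L  # nz x shuffles
      b <- pb[idx]
      ok <- keep_fr[idx]
      grp <- b + n_bins * (col(idx) - 1L)
      .cum_add(acc, grp[ok], rep(a[nz], times = n_shuffles)[ok])
    }
  })
  dim(acc) <- c(n_bins, n_shuffles)
  occ_sub <- occ_bins[sub]
  tot <- sum(occ_sub)
  si_of <- function(v_sub) {
    if (tot <= 0) return(0)
    p <- occ_sub / tot
    r <- v_sub / ifelse(occ_sub > 0, occ_sub, NA_real_)
    r[occ_sub == 0] <- 0
    rbar <- sum(p * r)
    if (rbar <= 0) return(0)
    nz <- r > 0
    sum(p[nz] * (r[nz] / rbar) * log2(r[nz] / rbar))
  }
  si_obs <- si_of(obs[sub])
  # vectorized null SI
  null <- if (tot <= 0) {
    rep(0, n_shuffles)
  } else {
    p <- occ_sub / tot
    r <- acc[sub, , drop = FALSE] / ifelse(occ_sub > 0, occ_sub, 1)
    r[occ_sub == 0, ] <- 0
    rbar <- colSums(p * r)
    lr <- r / rep(rbar, each = length(sub))
    term <- p * lr * log2(lr)
    term[!is.finite(term)] <- 0  # zero-rate bins contribute 0
    out <- colSums(term)
    out[rbar <= 0] <- 0
    out
  }
  list(si = si_obs, null = null)
}

#' Shuffle test of spatial tuning significance
#'
#' The frame-level activity of each lap is circularly shifted in time by an
#' independent uniform amount, re-binned, and the Skaggs information
#' recomputed `n_shuffles` times (default 1500) to build a null
#' distribution. The ROI is significant when the observed information
#' exceeds the stated percentile (default 99) of the null.
#'
#' @param activity Frame-level gated activity vector for one ROI.
#' @param binned A [bin_session()] result (provides laps, bins, speed mask).
#' @param n_shuffles Number of shuffles.
#' @param percentile Null percentile defining the criterion.
#' @param seed Integer seed; the null is reproducible.
#' @return List with `si`, `null`, `threshold`, `significant`.
#' @export
assess_spatial_significance <- function(activity, binned,
                                        n_shuffles = 1500L,
                                        percentile = 99,
                                        seed = NULL) {
  if (n_shuffles < 1L) stop("'n_shuffles' must be >= 1", call. = FALSE)
  bt <- .si_bootstrap(activity, binned, NULL, n_shuffles, seed)
  thr <- as.numeric(quantile(bt$null, percentile / 100))
  list(si = bt$si, null = bt$null, threshold = thr,
       significant = bt$si > thr)
}

# Merge overlapping/shallow-saddle footprints until stable.
.merge_footprints <- function(cand, rate) {
  repeat {
    if (nrow(cand) < 2L) return(cand)
    cand <- cand[order(cand$left), , drop = FALSE]
    merged <- FALSE
    for (i in seq_len(nrow(cand) - 1L)) {
      a <- cand[i, ]; b <- cand[i + 1L, ]
      overlap <- b$left <= a$right
      saddle <- FALSE
      if (!overlap) {
        between <- rate[a$peak:b$peak]
        saddle <- min(between, na.rm = TRUE) > 0.5 * max(a$height, b$height)
      }
      if (overlap || saddle) {
        keep <- if (a$height >= b$height) a else b
        new <- data.frame(peak = keep$peak, height = keep$height,
                          left = min(a$left, b$left),
                          right = max(a$right, b$right))
        cand <- rbind(cand[-c(i, i + 1L), , drop = FALSE], new)
        merged <- TRUE
        break
      }
    }
    if (!merged) return(cand)
  }
}

#' Demarcate significant place fields of one ROI
#'
#' Peaks in the tuning curve with height >= `peak_height` are found and
#' their footprints measured at relative height `rel_height` of the
#' prominence; adjacent peaks are merged when their footprints overlap or
#' the intervening minimum exceeds half the larger peak's amplitude
#' (repeated until stable). Each candidate footprint is extended by half
#' its width on both sides (clipped to the corridor) and a local Skaggs
#' information bootstrap (circular time shifts, `n_shuffles` iterations,
#' `local_percentile`th percentile) is run on the extended region. Retained
#' fields must additionally be active (>= 1 gated event within the field
#' bounds) in at least `active_lap_frac` of the laps.
#'
#' @param binned A [bin_session()] result.
#' @param activity Frame-level gated activity vector of the ROI.
#' @param roi ROI index (bookkeeping only).
#' @param peak_height Minimum tuning-curve peak height (a.u./frame).
#' @param rel_height Relative height for footprint width.
#' @param n_shuffles,local_percentile Local null parameters.
#' @param active_lap_frac Minimum fraction of active laps.
#' @param seed Integer seed for the local nulls.
#' @return data.frame (class `pff_fields`): one row per candidate with
#'   bounds, extended bounds, width, local significance and retention flag.
#' @export
demarcate_place_fields <- function(binned, activity, roi,
                                   peak_height = 6,
                                   rel_height = 0.93,
                                   n_shuffles = 1500L,
                                   local_percentile = 95,
                                   active_lap_frac = 0.30,
                                   seed = NULL) {
  empty <- data.frame(roi = integer(), left_bin = integer(),
                      right_bin = integer(), ext_left = integer(),
                      ext_right = integer(), width_cm = numeric(),
                      peak_bin = integer(), peak_height = numeric(),
                      si_local = numeric(), si_threshold = numeric(),
                      local_significant = logical(),
                      active_lap_fraction = numeric(), retained = logical())
  class(empty) <- c("pff_fields", "data.frame")
  tc <- tuning_curve(binned, roi)
  rate <- tc$rate
  rate[is.na(rate)] <- 0
  if (length(rate) < 3L) return(empty)
  pk <- find_peaks_1d(rate, height = peak_height, rel_height = rel_height)
  if (!nrow(pk)) return(empty)
  cand <- data.frame(peak = pk$peak, height = pk$height,
                     left = pmax(1L, as.integer(floor(pk$left_ip))),
                     right = pmin(binned$n_bins,
                                  as.integer(ceiling(pk$right_ip))))
  cand <- .merge_footprints(cand, rate)
  n <- nrow(cand)
  out <- empty[rep(1L, 0L), ]
  for (i in seq_len(n)) {
    width_bins <- cand$right[i] - cand$left[i] + 1L
    half <- as.integer(ceiling(width_bins / 2))
    el <- max(1L, cand$left[i] - half)
    er <- min(binned$n_bins, cand$right[i] + half)
    bt <- .si_bootstrap(activity, binned, bins_subset = el:er,
                        n_shuffles = n_shuffles,
                        seed = derive_seed(seed, i))
    thr <- as.numeric(quantile(bt$null, local_percentile / 100))
    sig <- bt$si > thr
    sub <- binned$activity[, cand$left[i]:cand$right[i], roi, drop = FALSE]
    dim(sub) <- dim(sub)[1:2]
    lap_active <- apply(sub, 1, function(v) any(!is.na(v) & v > 0))
    frac <- mean(lap_active)
    out <- rbind(out, data.frame(
      roi = roi, left_bin = cand$left[i], right_bin = cand$right[i],
      ext_left = el, ext_right = er,
      width_cm = width_bins * binned$spec$bin_width_cm,
      peak_bin = cand$peak[i], peak_height = cand$height[i],
      si_local = bt$si, si_threshold = thr, local_significant = sig,
      active_lap_fraction = frac,
      retained = sig && frac >= active_lap_frac))
  }
  class(out) <- c("pff_fields", "data.frame")
  out[order(out$left_bin), ]
}
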