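#' Place-field activity matrix
#'
#' Lap x bin mean gated activity within a field's spatial bounds extended
#' forward (to the right) by `extend_bins` bins (clipped at the corridor
#' end, so that formation events occurring forward of the field center are
#' captured), with an absolute amplitude floor applied: entries below
#' `threshold_au` are set to zero. No running-speed filtering is applied at
#' this stage.
#'
#' @param binned A [bin_session()] result.
#' @param roi ROI index.
#' @param left_bin,right_bin Inclusive field bounds (bins).
#' @param threshold_au Activity floor (default 64 a.u.).
#' @param extend_bins Forward extension (default 5 bins).
#' @return A `pf_activity_matrix`: list with `m` (laps x bins), `bins`
#'   (absolute bin indices), `left_bin`, `right_bin`, `threshold_au`.
#' @export
build_pf_activity_matrix <- function(binned, roi, left_bin, right_bin,
                                     threshold_au = 64, extend_bins = 5L) {
  if (left_bin < 1L || right_bin > binned$n_bins || left_bin > right_bin) {
    stop("invalid field bounds", call. = FALSE)
  }
  right_ext <- min(binned$n_bins, right_bin + extend_bins)
  bins <- left_bin:right_ext
  m <- binned$activity[, bins, roi, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m[is.na(m)] <- 0
  m[m < threshold_au] <- 0
  structure(list(m = m, bins = bins, left_bin = left_bin,
                 right_bin = right_bin, right_ext = right_ext,
                 threshold_au = threshold_au,
                 bin_width_cm = binned$spec$bin_width_cm),
            class = "pf_activity_matrix")
}

#' Temporal demarcation: formation and end lap of a new field
#'
#' The candidate formation lap is the earliest lap with activity after the
#' first `min_prior_laps` laps (default 17; 0 for novel-extension
#' analyses) such that no more than 10% of the preceding laps have a mean
#' activity exceeding 1% of the candidate lap's mean activity. The field
#' ends at the lap preceding the first run of at least `end_silent_laps`
#' consecutive laps with no activity after formation, or at the final lap.
#'
#' @param pfm A [build_pf_activity_matrix()] result.
#' @param min_prior_laps Minimum pre-formation lap count (default 17).
#' @param max_prior_active_frac Allowed fraction of pre-formation laps with
#'   activity above the 1% criterion (default 0.10).
#' @param prior_activity_frac Pre-silence amplitude criterion relative to
#'   the candidate lap mean (default 0.01).
#' @param end_silent_laps Consecutive silent laps terminating the field.
#' @return List with `formation_lap` (NA if none qualifies) and `end_lap`.
#' @export
find_formation_and_end <- function(pfm,
                                   min_prior_laps = 17L,
                                   max_prior_active_frac = 0.10,
                                   prior_activity_frac = 0.01,
                                   end_silent_laps = 5L) {
  m <- pfm$m
  n_laps <- nrow(m)
  lap_mean <- rowMeans(m)
  lap_any <- lap_mean > 0
  formation <- NA_integer_
  for (l in seq_len(n_laps)) {
    if (l <= min_prior_laps || !lap_any[l]) next
    prev <- lap_mean[seq_len(l - 1L)]
    n_exceed <- sum(prev > prior_activity_frac * lap_mean[l])
    if (n_exceed <= max_prior_active_frac * length(prev)) {
      formation <- l
      break
    }
  }
  if (is.na(formation)) {
    return(list(formation_lap = NA_integer_, end_lap = NA_integer_))
  }
  end_lap <- n_laps
  run <- 0L
  for (l in seq.int(formation + 1L, length.out = max(0L, n_laps - formation))) {
    if (!lap_any[l]) {
      run <- run + 1L
      if (run >= end_silent_laps) {
        end_lap <- l - end_silent_laps
        break
      }
    } else {
      run <- 0L
    }
  }
  list(formation_lap = formation, end_lap = end_lap)
}

#' Lifetime and consistency filters for a new field
#'
#' A field is kept when its lifetime (`end - formation + 1`) is at least
#' `min_lifetime` laps and the number of silent laps within the lifetime
#' (lap maximum below `silent_frac` of the peak lap maximum) does not
#' exceed `max_silent_laps`.
#'
#' @param pfm A [build_pf_activity_matrix()] result.
#' @param formation_lap,end_lap Temporal demarcation.
#' @param min_lifetime Minimum lifetime in laps (default 9).
#' @param max_silent_laps Maximum silent laps (default 8).
#' @param silent_frac Normalized-activity silence criterion (default 0.10).
#' @return List with `keep` and `reason` (`""`, `"EXCLUDED_SHORT"` or
#'   `"EXCLUDED_INCONSISTENT"`).
#' @export
apply_pf_filters <- function(pfm, formation_lap, end_lap,
                             min_lifetime = 9L,
                             max_silent_laps = 8L,
                             silent_frac = 0.10) {
  lifetime <- end_lap - formation_lap + 1L
  if (lifetime < min_lifetime) {
    return(list(keep = FALSE, reason = "EXCLUDED_SHORT"))
  }
  lap_max <- apply(pfm$m[formation_lap:end_lap, , drop = FALSE], 1, max)
  pk <- max(lap_max)
  if (pk <= 0) return(list(keep = FALSE, reason = "EXCLUDED_INCONSISTENT"))
  n_silent <- sum(lap_max / pk < silent_frac)
  if (n_silent > max_silent_laps) {
    return(list(keep = FALSE, reason = "EXCLUDED_INCONSISTENT"))
  }
  list(keep = TRUE, reason = "")
}

# COM (cm) of each lap's activity inside the matrix; NA for silent laps.
.lap_coms <- function(pfm) {
  centers <- (pfm$bins - 0.5) * pfm$bin_width_cm
  apply(pfm$m, 1, function(v) {
    s <- sum(v)
    if (s <= 0) return(NA_real_)
    sum(v * centers) / s
  })
}

#' Classify a place-field formation event
#'
#' Computes the three BTSP criteria on the thresholded field activity
#' matrix:
#' \itemize{
#'   \item gain: the formation-lap peak activity exceeds the mean of the
#'     peak activities of the next three active laps;
#'   \item backward shift: the mean smoothed COM (running average, kernel
#'     3, over active laps) of the first three post-formation active laps
#'     lies behind the formation location (the raw formation-lap COM);
#'   \item drift: the linear regression of the smoothed COM from the
#'     fourth post-formation active lap onward, extrapolated back to the
#'     first post-formation active lap, exceeds the formation location AND
#'     the Spearman correlation of those COM values with their ordinals is
#'     significantly negative (p < 0.05).
#' }
#' Category: `BTSP` when gain and shift hold without drift; `NON_BTSP`
#' when neither gain nor shift holds (drift ignored); otherwise an
#' `EXCLUDED_*` label.
#'
#' @param pfm A [build_pf_activity_matrix()] result.
#' @param formation_lap,end_lap Temporal demarcation (laps).
#' @param drift_alpha Significance level of the drift test.
#' @return A `pff_event` list: flags `gain`, `backward_shift`, `drift`,
#'   `category`, plus `formation_com_cm`, `post_com_cm` (mean of first
#'   three post-formation smoothed COMs), `active_laps`, `classifiable`.
#' @export
classify_pff <- function(pfm, formation_lap, end_lap = nrow(pfm$m),
                         drift_alpha = 0.05) {
  m <- pfm$m[seq_len(end_lap), , drop = FALSE]
  lap_max <- apply(m, 1, max)
  active <- which(lap_max > 0)
  active <- active[active >= formation_lap]
  post <- active[active > formation_lap]
  out <- list(formation_lap = formation_lap, end_lap = end_lap,
              gain = NA, backward_shift = NA, drift = NA,
              category = "EXCLUDED_INCONSISTENT",
              formation_com_cm = NA_real_, post_com_cm = NA_real_,
              active_laps = active, classifiable = FALSE)
  class(out) <- "pff_event"
  if (lap_max[formation_lap] <= 0 || length(post) < 3L) return(out)

  gain <- lap_max[formation_lap] > mean(lap_max[post[1:3]])

  coms <- .lap_coms(pfm)[seq_len(end_lap)]
  com_active <- coms[active]
  smoothed <- running_mean(com_active, 3L)
  formation_com <- com_active[1L]  # raw COM of the formation lap
  post_idx <- which(active > formation_lap)
  post_sm <- smoothed[post_idx]
  post_com <- mean(post_sm[1:3])
  backward <- post_com < formation_com

  drift <- FALSE
  if (length(post_idx) >= 4L) {
    tail_idx <- post_idx[-(1:3)]
    y <- smoothed[tail_idx]
    ordinal <- seq_along(post_idx)[-(1:3)]
    if (length(y) >= 3L && sd(y) > 0) {
      fit <- lm.fit(cbind(1, ordinal), y)
      extrap <- fit$coefficients[1] + fit$coefficients[2] * 1
      rs <- suppressWarnings(cor.test(y, ordinal, method = "spearman"))
      drift <- isTRUE(extrap > formation_com) &&
        isTRUE(!is.na(rs$estimate) && rs$estimate < 0 &&
                 rs$p.value < drift_alpha)
    }
  }

  category <- if (gain && backward && !drift) {
    "BTSP"
  } else if (!gain && !backward) {
    "NON_BTSP"
  } else if (gain && backward && drift) {
    "EXCLUDED_DRIFT"
  } else if (gain && !backward) {
    "EXCLUDED_GAIN_NO_SHIFT"
  } else {
    "EXCLUDED_NOSHIFT_ONLY_PARTIAL"  # shift without gain
  }
  out$gain <- gain
  out$backward_shift <- backward
  out$drift <- drift
  out$category <- category
  out$formation_com_cm <- formation_com
  out$post_com_cm <- post_com
  out$classifiable <- TRUE
  out
}

#' @export
print.pff_event <- function(x, ...) {
  cat(sprintf("<pff_event> formation lap %s, category %s (gain=%s shift=%s drift=%s)\n",
              x$formation_lap, x$category, x$gain, x$backward_shift, x$drift))
  invisible(x)
}

#' Misclassification bootstrap for a non-BTSP event
#'
#' Tests whether a non-BTSP-like formation could be a misclassified BTSP
#' event preceded by chance activity. Laps are masked sequentially from the
#' formation lap until the re-detected event shows a BTSP signature or the
#' field ends. If no signature is ever found the transformation probability
#' is 0. Otherwise, the mean activity and the fraction of active laps in
#' the test area (non-BTSP start up to the first BTSP-like formation lap)
#' are compared to a null of equal-sized lap x bin segments sampled outside
#' all fields; the event is unlikely to be misclassified when fewer than
#' `alpha` (5%) of the null samples reach or exceed both metrics.
#'
#' @param pfm A [build_pf_activity_matrix()] result of the non-BTSP field.
#' @param formation_lap,end_lap Temporal demarcation of the non-BTSP event.
#' @param binned A [bin_session()] result (for null sampling).
#' @param fields data.frame of retained fields (columns `roi`, `ext_left`,
#'   `ext_right`) defining the excluded areas.
#' @param n_null Number of null segments (default 1000).
#' @param alpha Criterion fraction (default 0.05).
#' @param threshold_au Activity floor applied to null segments.
#' @param min_prior_laps Passed to the masked re-detection.
#' @param seed Integer seed.
#' @return List with `probability` (fraction of null samples >= on both
#'   metrics; 0 when no BTSP signature is reachable), `unlikely_misclassified`,
#'   `btsp_reachable`, `test_laps`.
#' @export
misclassification_bootstrap <- function(pfm, formation_lap, end_lap,
                                        binned, fields,
                                        n_null = 1000L, alpha = 0.05,
                                        threshold_au = 64,
                                        min_prior_laps = 17L,
                                        seed = NULL) {
  btsp_lap <- NA_integer_
  masked <- pfm
  for (k in seq.int(formation_lap, end_lap)) {
    masked$m[formation_lap:k, ] <- 0
    dem <- find_formation_and_end(masked, min_prior_laps = min_prior_laps)
    if (is.na(dem$formation_lap)) next
    ev <- classify_pff(masked, dem$formation_lap, dem$end_lap)
    if (identical(ev$category, "BTSP")) {
      btsp_lap <- dem$formation_lap
      break
    }
  }
  if (is.na(btsp_lap)) {
    return(list(probability = 0, unlikely_misclassified = TRUE,
                btsp_reachable = FALSE, test_laps = integer()))
  }
  test_laps <- formation_lap:(btsp_lap - 1L)
  test <- pfm$m[test_laps, , drop = FALSE]
  t_mean <- mean(test)
  t_frac <- mean(apply(test, 1, max) > 0)

  n_l <- length(test_laps)
  n_b <- ncol(test)
  # admissible outside-field bin windows per ROI
  excl <- vector("list", binned$n_rois)
  if (nrow(fields)) {
    for (i in seq_len(nrow(fields))) {
      r <- fields$roi[i]
      excl[[r]] <- c(excl[[r]], fields$ext_left[i]:fields$ext_right[i])
    }
  }
  ok_starts <- lapply(seq_len(binned$n_rois), function(r) {
    bad <- logical(binned$n_bins)
    if (length(excl[[r]])) bad[excl[[r]]] <- TRUE
    starts <- seq_len(binned$n_bins - n_b + 1L)
    starts[vapply(starts, function(s) !any(bad[s:(s + n_b - 1L)]), logical(1))]
  })
  candidates <- which(lengths(ok_starts) > 0)
  if (!length(candidates) || binned$n_laps < n_l) {
    stop(sprintf("insufficient outside-field area for null sampling (%d candidate ROIs)",
                 length(candidates)), call. = FALSE)
  }
  act <- binned$activity
  with_seed(seed, {
    n_mean <- n_frac <- numeric(n_null)
    rois <- sample(candidates, n_null, replace = TRUE)
    for (i in seq_len(n_null)) {
      r <- rois[i]
      s <- ok_starts[[r]][sample.int(length(ok_starts[[r]]), 1L)]
      l0 <- sample.int(binned$n_laps - n_l + 1L, 1L)
      seg <- act[l0:(l0 + n_l - 1L), s:(s + n_b - 1L), r, drop = FALSE]
      dim(seg) <- c(n_l, n_b)
      seg[is.na(seg)] <- 0
      seg[seg < threshold_au] <- 0
      n_mean[i] <- mean(seg)
      n_frac[i] <- mean(apply(seg, 1, max) > 0)
    }
    p <- mean(n_mean >= t_mean & n_frac >= t_frac)
    list(probability = p, unlikely_misclassified = p < alpha,
         btsp_reachable = TRUE, test_laps = test_laps)
  })
}
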