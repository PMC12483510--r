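#' Build the place-field width dataset
#'
#' One row per classified formation event with the field width, the mean
#' running speed during the field traversal on the formation lap, and the
#' along-track distance from the field center to the nearest visual
#' landmark centroid (in a 1-D corridor the Euclidean distance reduces to
#' the absolute along-track distance). Exclusions, recorded rather than
#' dropped: fields whose bounds touch the corridor start or end (truncated
#' widths) and events with formation-lap speed below `min_speed_cm_s`.
#'
#' @param events data.frame of events with `roi`, `category`,
#'   `formation_lap`, `left_bin`, `right_bin`, `width_cm`.
#' @param binned A [bin_session()] result.
#' @param behavior The session's `behavior_trace`.
#' @param spec A [corridor_spec()] (provides the landmarks).
#' @param min_speed_cm_s Formation-lap speed cutoff (default 5 cm/s).
#' @param start_offset_cm Offset subtracted from track positions before
#'   measuring cue distance (see [optimize_start_offset()]).
#' @return data.frame (class `width_dataset`): `roi`, `category`,
#'   `width_cm`, `speed_cm_s`, `cue_distance_cm`, `excluded`, `reason`.
#' @export
build_width_dataset <- function(events, binned, behavior, spec,
                                min_speed_cm_s = 5,
                                start_offset_cm = 0) {
  if (!length(spec$landmarks_cm)) stop("corridor has no landmarks",
                                       call. = FALSE)
  n <- nrow(events)
  speed <- cue <- rep(NA_real_, n)
  excluded <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    e <- events[i, ]
    fr <- .traversal_frames(binned, e$formation_lap, e$left_bin:e$right_bin)
    speed[i] <- if (length(fr)) mean(behavior$speed_cm_s[fr]) else NA_real_
    center <- ((e$left_bin + e$right_bin) / 2 - 0.5) * spec$bin_width_cm
    cue[i] <- min(abs((center - start_offset_cm) - spec$landmarks_cm))
    if (e$left_bin <= 1L || e$right_bin >= binned$n_bins) {
      excluded[i] <- TRUE
      reason[i] <- "touches_corridor_edge"
    } else if (is.na(speed[i]) || speed[i] < min_speed_cm_s) {
      excluded[i] <- TRUE
      reason[i] <- "low_speed"
    }
  }
  out <- data.frame(roi = events$roi, category = events$category,
                    width_cm = events$width_cm, speed_cm_s = speed,
                    cue_distance_cm = cue, excluded = excluded,
                    reason = reason)
  class(out) <- c("width_dataset", "data.frame")
  out
}

#' Leave-one-out explained variance of field width
#'
#' Ordinary least-squares linear models of width on the chosen predictors,
#' evaluated by leave-one-out cross-validation: each event is predicted
#' from a model fitted to the others, and the explained-variance fraction
#' is `EV = 1 - MSE_loo / var(width)`. Implemented through the exact
#' closed-form LOO identity `e_i / (1 - h_ii)` of least squares.
#'
#' @param dataset A [build_width_dataset()] result (excluded rows are
#'   dropped) or any data.frame with `width_cm` and the predictor columns.
#' @param predictors Subset of `c("speed", "cue_distance")`.
#' @return List (class `ev_report`): `ev`, `mse`, `predictions`, `n`,
#'   `predictors`.
#' @export
loo_explained_variance <- function(dataset,
                                   predictors = c("speed", "cue_distance")) {
  predictors <- match.arg(predictors, several.ok = TRUE)
  d <- dataset
  if (!is.null(d$excluded)) d <- d[!d$excluded, , drop = FALSE]
  cols <- c(speed = "speed_cm_s", cue_distance = "cue_distance_cm")[predictors]
  d <- d[stats::complete.cases(d[, c("width_cm", unname(cols))]), ,
         drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 retained events", call. = FALSE)
  X <- cbind(1, as.matrix(d[, cols, drop = FALSE]))
  y <- d$width_cm
  for (j in seq_len(ncol(X))[-1]) {
    if (sd(X[, j]) == 0) {
      warning("degenerate predictor (zero variance): ",
              colnames(X)[j], call. = FALSE)
    }
  }
  qr_x <- qr(X)
  beta <- qr.coef(qr_x, y)
  beta[is.na(beta)] <- 0
  fitted <- as.numeric(X %*% beta)
  h <- rowSums(qr.Q(qr_x)^2)
  e_loo <- (y - fitted) / (1 - h)
  pred <- y - e_loo
  mse <- mean(e_loo^2)
  ev <- 1 - mse / var(y)
  structure(list(ev = ev, mse = mse, predictions = pred, n = length(y),
                 predictors = predictors),
            class = "ev_report")
}

#' @export
print.ev_report <- function(x, ...) {
  cat(sprintf("<ev_report> EV = %.3f (LOO, n = %d, predictors: %s)\n",
              x$ev, x$n, paste(x$predictors, collapse = " + ")))
  invisible(x)
}

#' Optimize the corridor start offset for the cue-distance model
#'
#' The animal's subjective track origin is ambiguous; candidate start
#' offsets within the first `range_cm` of the corridor are scanned on a
#' grid and the offset maximizing the combined (speed + cue distance)
#' leave-one-out explained variance is selected (ties broken toward the
#' smallest offset).
#'
#' @param builder Function `(offset_cm) -> width_dataset`.
#' @param range_cm Search interval (default `c(0, 50)` cm).
#' @param step_cm Grid step (default 1 cm).
#' @param predictors Model to score (default both predictors).
#' @return List: `best_offset_cm`, `best_ev`, `curve` (data.frame
#'   `offset_cm`, `ev`).
#' @export
optimize_start_offset <- function(builder, range_cm = c(0, 50), step_cm = 1,
                                  predictors = c("speed", "cue_distance")) {
  if (step_cm <= 0) stop("'step_cm' must be positive", call. = FALSE)
  offsets <- seq(range_cm[1], range_cm[2], by = step_cm)
  evs <- vapply(offsets, function(o) {
    loo_explained_variance(builder(o), predictors = predictors)$ev
  }, numeric(1))
  best <- which.max(evs)  # which.max returns the first (smallest offset) tie
  list(best_offset_cm = offsets[best], best_ev = evs[best],
       curve = data.frame(offset_cm = offsets, ev = evs))
}

#' Subsampled regression comparison between event groups
#'
#' Repeatedly subsamples the larger (BTSP) group to the size of the
#' comparison group and recomputes the Spearman correlation between width
#' and speed, yielding bootstrap confidence intervals for `r` and its
#' p-value; a comparison group whose own (r, p) fall outside both CIs
#' differs robustly from the subsampled group.
#'
#' @param btsp_set data.frame with `width_cm` and `speed_cm_s`.
#' @param n_target Subsample size (<= rows of `btsp_set`).
#' @param comparison Optional data.frame with the same columns.
#' @param n_resamples Number of subsamples (default 10000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List: `r_ci`, `p_ci`, `r_samples` summary, `comparison_r`,
#'   `comparison_p`, `r_outside`, `p_outside`, `verdict` (TRUE when both
#'   fall outside).
#' @export
subsample_regression_comparison <- function(btsp_set, n_target,
                                            comparison = NULL,
                                            n_resamples = 10000L,
                                            conf = 0.95, seed = NULL) {
  if (n_target < 3L) stop("'n_target' must be >= 3", call. = FALSE)
  if (n_target > nrow(btsp_set)) {
    stop("'n_target' exceeds the BTSP sample size", call. = FALSE)
  }
  sp_cor <- function(d) {
    ct <- suppressWarnings(cor.test(d$width_cm, d$speed_cm_s,
                                    method = "spearman"))
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  with_seed(seed, {
    rs <- matrix(NA_real_, n_resamples, 2L)
    for (i in seq_len(n_resamples)) {
      idx <- sample.int(nrow(btsp_set), n_target)
      rs[i, ] <- sp_cor(btsp_set[idx, , drop = FALSE])
    }
    a <- (1 - conf) / 2
    r_ci <- quantile(rs[, 1], c(a, 1 - a), na.rm = TRUE)
    p_ci <- quantile(rs[, 2], c(a, 1 - a), na.rm = TRUE)
    out <- list(r_ci = r_ci, p_ci = p_ci,
                r_mean = mean(rs[, 1], na.rm = TRUE),
                comparison_r = NA_real_, comparison_p = NA_real_,
                r_outside = NA, p_outside = NA, verdict = NA)
    if (!is.null(comparison)) {
      cp <- sp_cor(comparison)
      out$comparison_r <- cp[["r"]]
      out$comparison_p <- cp[["p"]]
      out$r_outside <- cp[["r"]] < r_ci[1] || cp[["r"]] > r_ci[2]
      out$p_outside <- cp[["p"]] < p_ci[1] || cp[["p"]] > p_ci[2]
      out$verdict <- out$r_outside && out$p_outside
    }
    out
  })
}
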