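#' Neuropil correction
#'
#' Subtracts a scaled copy of the neuropil fluorescence from the raw ROI
#' fluorescence: `F = F_raw - coef * F_neu` (elementwise).
#'
#' @param F_raw,F_neu frames x ROIs matrices of equal shape (a.u.).
#' @param coef Neuropil coefficient (default 0.7).
#' @return The corrected fluorescence matrix `F`.
#' @examples
#' neuropil_correct(matrix(100), matrix(20))  # 86
#' @export
neuropil_correct <- function(F_raw, F_neu, coef = 0.7) {
  if (!identical(dim(F_raw), dim(F_neu))) {
    stop("'F_raw' and 'F_neu' must have identical shapes", call. = FALSE)
  }
  F_raw - coef * F_neu
}

# Per-ROI global noise: SD of F values in a median-relative range.
# interpretation "median": F in [median*(1-1.5), median*(1+0.5)]
# interpretation "sd":     F in [median - 1.5*SD(F), median + 0.5*SD(F)]
global_noise_sd <- function(f, interpretation = c("median", "sd")) {
  interpretation <- match.arg(interpretation)
  m <- median(f)
  rng <- if (interpretation == "median") {
    c(m * (1 - 1.5), m * (1 + 0.5))
  } else {
    s <- sd(f)
    c(m - 1.5 * s, m + 0.5 * s)
  }
  sel <- f >= min(rng) & f <= max(rng)
  if (sum(sel) < 2L) return(Inf)
  sd(f[sel])
}

#' Noise-gate deconvolved events against the fluorescence trace
#'
#' Keeps a nonzero deconvolved entry only when the associated fluorescence
#' transient clears both a local and a global noise estimate. For each
#' candidate frame t: the local maximum of F between t and t+9 is found and
#' replaced by the mean of the three samples around it (`F_max`); a linear
#' baseline is fitted to F over frames t-30..t-20 (11 samples) whose RMSE is
#' the local noise and whose prediction at t-20 is `F_base`; the global
#' noise is the SD of F within a median-relative range of the whole trace.
#' The entry is kept iff `F_max - F_base` exceeds both noise values.
#'
#' Edge rule: candidates near the trace start use the available prefix of
#' the baseline window (at least 5 samples, otherwise the event is
#' rejected); the peak search truncates at the trace end.
#'
#' @param f frames x ROIs neuropil-corrected fluorescence.
#' @param deconvolved frames x ROIs deconvolved activity; same shape.
#' @param global_interpretation How the median-relative global-noise range
#'   is read: `"median"` (multiples of the median, the default) or `"sd"`
#'   (median plus/minus multiples of the trace SD).
#' @return List with `gated` (matrix; rejected entries zeroed) and `report`
#'   (data.frame of all candidates: `roi`, `frame`, `f_max`, `f_base`,
#'   `sd_local`, `sd_global`, `accepted`).
#' @export
gate_inferred_events <- function(f, deconvolved,
                                 global_interpretation = c("median", "sd")) {
  if (!identical(dim(f), dim(deconvolved))) {
    stop("'f' and 'deconvolved' must have identical shapes", call. = FALSE)
  }
  global_interpretation <- match.arg(global_interpretation)
  n_fr <- nrow(f)
  gated <- deconvolved
  reports <- vector("list", ncol(f))
  for (r in seq_len(ncol(f))) {
    cand <- which(deconvolved[, r] != 0)
    if (!length(cand)) next
    fv <- f[, r]
    sd_g <- global_noise_sd(fv, global_interpretation)
    n_c <- length(cand)
    f_max <- f_base <- sd_l <- numeric(n_c)
    acc <- logical(n_c)
    for (k in seq_len(n_c)) {
      t <- cand[k]
      seg <- t:min(n_fr, t + 9L)
      pk <- seg[which.max(fv[seg])]
      pk_win <- max(1L, pk - 1L):min(n_fr, pk + 1L)
      f_max[k] <- mean(fv[pk_win])
      b_idx <- max(1L, t - 30L):(t - 20L)
      if (t - 20L < 1L || length(b_idx) < 5L) {
        f_base[k] <- NA_real_
        sd_l[k] <- NA_real_
        acc[k] <- FALSE
        next
      }
      xs <- as.numeric(b_idx)
      ys <- fv[b_idx]
      mx <- mean(xs); my <- mean(ys)
      dx <- xs - mx
      slope <- sum(dx * (ys - my)) / sum(dx * dx)
      pred <- my + slope * (xs - mx)
      sd_l[k] <- sqrt(mean((ys - pred)^2))
      f_base[k] <- my + slope * ((t - 20L) - mx)
      amp <- f_max[k] - f_base[k]
      acc[k] <- amp > sd_l[k] && amp > sd_g
    }
    gated[cand[!acc], r] <- 0
    reports[[r]] <- data.frame(roi = r, frame = cand, f_max = f_max,
                               f_base = f_base, sd_local = sd_l,
                               sd_global = sd_g, accepted = acc)
  }
  report <- if (any(!vapply(reports, is.null, logical(1)))) {
    do.call(rbind, reports[!vapply(reports, is.null, logical(1))])
  } else {
    data.frame(roi = integer(), frame = integer(), f_max = numeric(),
               f_base = numeric(), sd_local = numeric(),
               sd_global = numeric(), accepted = logical())
  }
  rownames(report) <- NULL
  list(gated = gated, report = report)
}

#' Baseline-normalized fluorescence (dF/F)
#'
#' `dff = (F - F0) / F0` where `F0` is, for each frame, the rolling median
#' of the preceding `window` fluorescence values; frames earlier than the
#' window use the median of the following `window` values (truncated to the
#' trace if needed). Traces shorter than the window fall back to the
#' whole-trace median. Frames with `F0 <= 0` get `dff = 0` and are flagged.
#'
#' @param f frames x ROIs (or vector) neuropil-corrected fluorescence.
#' @param window Rolling-median window length in samples (default 1000).
#' @return List with `dff` and `f0` (same shape as `f`) and `n_bad_f0`, the
#'   count of frames where the baseline was non-positive.
#' @examples
#' compute_dff(matrix(5, nrow = 10))$dff  # constant trace -> all zero
#' @export
compute_dff <- function(f, window = 1000L) {
  vec_in <- is.null(dim(f))
  f <- as.matrix(f)
  n <- nrow(f)
  f0 <- matrix(NA_real_, n, ncol(f))
  for (r in seq_len(ncol(f))) {
    x <- f[, r]
    if (n < window) {
      f0[, r] <- median(x)
      next
    }
    sm <- .sliding_median(x, as.integer(window))  # sm[i] = med(x[i..i+w-1])
    col <- numeric(n)
    for (t in seq_len(n)) {
      if (t > window) {
        col[t] <- sm[t - window]          # preceding window t-w .. t-1
      } else if (t + window <= n) {
        col[t] <- sm[t + 1L]              # following window t+1 .. t+w
      } else {
        col[t] <- median(x[(t + 1L):n])   # truncated following window
      }
    }
    f0[, r] <- col
  }
  bad <- f0 <= 0
  dff <- (f - f0) / f0
  dff[bad] <- 0
  if (vec_in) {
    dff <- drop(dff)
    f0 <- drop(f0)
  }
  list(dff = dff, f0 = f0, n_bad_f0 = sum(bad))
}

#' Align transient traces and measure peak amplitudes
#'
#' Each dF/F segment with an inferred event is smoothed with a five-point
#' symmetric moving average; the difference between each smoothed point and
#' the fourth point before it locates the steepest rise, whose index is the
#' alignment point. Segments without events align at their midpoint. An
#' asymmetric window of -50..+150 samples (201 points) around the alignment
#' point is extracted (missing samples are NA). The mean trace is computed
#' across segments, and each segment's peak amplitude is its value at the
#' index of the mean-trace maximum minus the median of its own isolated
#' window.
#'
#' @param segments List of numeric dF/F traces.
#' @param has_event Logical vector, one flag per segment.
#' @param pre,post Window extent before/after the alignment point.
#' @return A `transient_alignment` list: `windows` (segments x 201 matrix),
#'   `alignment_index`, `peak_amplitude`, `mean_trace`, `sd_trace`,
#'   `peak_index` (index of the mean-trace maximum within the window).
#' @export
align_and_measure_transients <- function(segments, has_event,
                                         pre = 50L, post = 150L) {
  if (length(segments) == 0L) {
    return(structure(list(windows = matrix(numeric(), 0, pre + post + 1L),
                          alignment_index = integer(),
                          peak_amplitude = numeric(),
                          mean_trace = numeric(), sd_trace = numeric(),
                          peak_index = NA_integer_),
                     class = "transient_alignment"))
  }
  stopifnot(length(has_event) == length(segments))
  w_len <- pre + post + 1L
  offs <- seq.int(-pre, post)
  win <- matrix(NA_real_, length(segments), w_len)
  align_idx <- integer(length(segments))
  for (i in seq_along(segments)) {
    x <- as.numeric(segments[[i]])
    if (has_event[i] && length(x) >= 5L) {
      sm <- running_mean(x, 5L)
      d <- sm[-seq_len(4L)] - sm[seq_len(length(sm) - 4L)]
      # difference at position j+4 relative to j; midpoint of the rise
      align_idx[i] <- which.max(d) + 2L
    } else {
      align_idx[i] <- as.integer(ceiling(length(x) / 2))
    }
    src <- align_idx[i] + offs
    ok <- src >= 1L & src <= length(x)
    win[i, ok] <- x[src[ok]]
  }
  mean_trace <- colMeans(win, na.rm = TRUE)
  sd_trace <- apply(win, 2, sd, na.rm = TRUE)
  peak_index <- which.max(mean_trace)
  peak_amp <- vapply(seq_len(nrow(win)), function(i) {
    v <- win[i, peak_index]
    if (is.na(v)) return(NA_real_)
    v - median(win[i, ], na.rm = TRUE)
  }, numeric(1))
  structure(list(windows = win, alignment_index = align_idx,
                 peak_amplitude = peak_amp, mean_trace = mean_trace,
                 sd_trace = sd_trace, peak_index = peak_index),
            class = "transient_alignment")
}

#' @export
print.transient_alignment <- function(x, ...) {
  cat(sprintf("<transient_alignment> %d traces, window %d samples, mean peak %.3f\n",
              nrow(x$windows), ncol(x$windows),
              mean(x$peak_amplitude, na.rm = TRUE)))
  invisible(x)
}
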