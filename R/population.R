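#' Lap-by-lap population-vector correlogram
#'
#' For every lap pair and spatial bin, the Pearson correlation of the
#' across-ROI activity vectors (non-thresholded mean gated activity) is
#' computed; the correlogram entry for a lap pair is the average of these
#' bin-wise correlations over the bins where the correlation is defined
#' (bins with zero across-ROI variance in either lap are skipped, not
#' imputed).
#'
#' @param binned A [bin_session()] result (built from non-thresholded
#'   gated activity).
#' @return A `pv_correlogram`: laps x laps matrix with attribute
#'   `n_bins_used` (laps x laps count of contributing bins).
#' @export
pv_correlogram <- function(binned) {
  n_laps <- binned$n_laps
  n_bins <- binned$n_bins
  if (n_laps < 2L || binned$n_rois < 2L) {
    stop("need at least 2 laps and 2 ROIs", call. = FALSE)
  }
  acc <- matrix(0, n_laps, n_laps)
  cnt <- matrix(0L, n_laps, n_laps)
  for (b in seq_len(n_bins)) {
    x <- binned$activity[, b, ]  # laps x ROIs
    x[is.na(x)] <- NA_real_
    ok_lap <- rowSums(is.na(x)) == 0
    if (sum(ok_lap) < 2L) next
    xs <- x[ok_lap, , drop = FALSE]
    sds <- apply(xs, 1, sd)
    def <- sds > 0
    if (sum(def) < 2L) next
    sel <- which(ok_lap)[def]
    cm <- suppressWarnings(cor(t(x[sel, , drop = FALSE])))
    acc[sel, sel] <- acc[sel, sel] + cm
    cnt[sel, sel] <- cnt[sel, sel] + 1L
  }
  m <- acc / ifelse(cnt > 0, cnt, NA_real_)
  structure(m, n_bins_used = cnt, class = c("pv_correlogram", "matrix"))
}

#' @export
print.pv_correlogram <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("<pv_correlogram> %d laps, mean off-diagonal r = %.3f\n",
              nrow(x), mean(off, na.rm = TRUE)))
  invisible(x)
}

#' Heatmap of a population-vector correlogram
#'
#' @param x A [pv_correlogram()].
#' @param ... Passed to [graphics::image()].
#' @importFrom graphics image axis
#' @export
plot.pv_correlogram <- function(x, ...) {
  n <- nrow(x)
  m <- unclass(x)
  attr(m, "n_bins_used") <- NULL
  image(seq_len(n), seq_len(n), m[, n:1], zlim = c(-1, 1),
        xlab = "lap", ylab = "lap", ...)
  invisible(x)
}

#' Locate a representational switch in a correlogram
#'
#' Convenience utility for locating a switch numerically (switches are
#' conventionally identified by eye on the correlogram): for every
#' candidate split lap,
#' the contrast between the mean within-block and the mean between-block
#' correlation of the two-block partition is computed; the split with the
#' maximum contrast is reported when it exceeds `min_contrast`.
#'
#' @param correlogram A [pv_correlogram()].
#' @param min_contrast Minimum contrast for a detection (default 0.2).
#' @param min_block Minimum laps per block (default 3).
#' @return List with `switch_lap` (first lap of the new block; `NA` if no
#'   split exceeds the threshold) and `contrast`.
#' @export
locate_switch <- function(correlogram, min_contrast = 0.2, min_block = 3L) {
  n <- nrow(correlogram)
  if (n < 2L * min_block) stop("correlogram too small", call. = FALSE)
  m <- unclass(correlogram)
  diag(m) <- NA_real_
  best_lap <- NA_integer_
  best_contrast <- -Inf
  for (s in seq.int(min_block + 1L, n - min_block + 1L)) {
    a <- seq_len(s - 1L)
    b <- s:n
    within <- c(m[a, a], m[b, b])
    between <- m[a, b]
    ctr <- mean(within, na.rm = TRUE) - mean(between, na.rm = TRUE)
    if (is.finite(ctr) && ctr > best_contrast) {
      best_contrast <- ctr
      best_lap <- s
    }
  }
  if (!is.finite(best_contrast) || best_contrast < min_contrast) {
    return(list(switch_lap = NA_integer_, contrast = best_contrast))
  }
  list(switch_lap = best_lap, contrast = best_contrast)
}

#' Odd/even population-vector correlations across a corridor extension
#'
#' Compares population codes between a familiar corridor segment and a
#' novel extension of matched length: per-ROI mean activity vectors are
#' computed for odd and even laps on each segment, and the bin-wise
#' across-ROI Pearson correlations (averaged over defined bins) are
#' returned for the three comparisons.
#'
#' @param binned_orig [bin_session()] of the pre-extension session.
#' @param binned_ext [bin_session()] of the extension session.
#' @param bins_orig,bins_ext Matched spatial-bin windows (equal lengths;
#'   e.g. the first 6 m, excluding the reward zone).
#' @return Named numeric vector: `orig_odd_even`, `orig_odd_ext_even`,
#'   `ext_odd_even`.
#' @export
oddeven_pv_extension <- function(binned_orig, binned_ext,
                                 bins_orig, bins_ext) {
  if (length(bins_orig) != length(bins_ext)) {
    stop("segment bin windows must have equal length", call. = FALSE)
  }
  if (binned_orig$n_rois != binned_ext$n_rois) {
    stop("sessions must share the ROI population", call. = FALSE)
  }
  seg_mean <- function(binned, bins, parity) {
    laps <- which(seq_len(binned$n_laps) %% 2L == parity)
    sapply(bins, function(b) {
      a <- binned$activity[laps, b, ]
      occ <- binned$occupancy[laps, b]
      a[is.na(a)] <- 0
      colSums(a * occ) / max(sum(occ), 1)
    })  # ROIs x bins
  }
  mean_bin_cor <- function(A, B) {
    rs <- vapply(seq_len(ncol(A)), function(j) safe_cor(A[, j], B[, j]),
                 numeric(1))
    mean(rs, na.rm = TRUE)
  }
  oo <- seg_mean(binned_orig, bins_orig, 1L)
  oe <- seg_mean(binned_orig, bins_orig, 0L)
  xo <- seg_mean(binned_ext, bins_ext, 1L)
  xe <- seg_mean(binned_ext, bins_ext, 0L)
  c(orig_odd_even = mean_bin_cor(oo, oe),
    orig_odd_ext_even = mean_bin_cor(oo, xe),
    ext_odd_even = mean_bin_cor(xo, xe))
}
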