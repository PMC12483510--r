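#' Local-coherence image of a movie segment
#'
#' For every pixel of a frames x H x W movie, the Pearson correlations
#' between its intensity time series and those of its eight nearest
#' neighbors are averaged (edge pixels use their existing 3 or 5
#' neighbors); pixels belonging to an active cell light up because their
#' time series co-fluctuate. Undefined correlations (constant pixels) count
#' as 0. The raw coherence map is contrast-enhanced with a sigmoid
#' `1 / (1 + exp(gain * (cutoff - I)))`.
#'
#' @param movie Numeric array `frames x H x W` with >= 2 frames.
#' @param cutoff,gain Sigmoid contrast parameters (defaults 0.8, 20).
#' @return List (class `coherence_image`): `coherence` (H x W, in
#'   `[-1, 1]`), `adjusted` (H x W, in `[0, 1]`).
#' @export
local_coherence_image <- function(movie, cutoff = 0.8, gain = 20) {
  d <- dim(movie)
  if (length(d) != 3L || d[1] < 2L) {
    stop("'movie' must be a frames x H x W array with >= 2 frames",
         call. = FALSE)
  }
  n_t <- d[1]; h <- d[2]; w <- d[3]
  x <- matrix(movie, n_t, h * w)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sds <- sqrt(colSums(xc^2))
  const <- sds == 0
  z <- sweep(xc, 2, ifelse(const, 1, sds), "/")  # unit-norm; corr = z_p . z_q
  zp <- array(z, c(n_t, h, w))
  acc <- matrix(0, h, w)
  cnt <- matrix(0L, h, w)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      r1 <- max(1L, 1L + dr):min(h, h + dr)
      c1 <- max(1L, 1L + dc):min(w, w + dc)
      r0 <- r1 - dr
      c0 <- c1 - dc
      prod_sum <- apply(zp[, r0, c0, drop = FALSE] *
                          zp[, r1, c1, drop = FALSE], c(2, 3), sum)
      constm <- matrix(const, h, w)
      valid <- !(constm[r0, c0] | constm[r1, c1])
      prod_sum[!valid] <- 0
      acc[r0, c0] <- acc[r0, c0] + prod_sum
      cnt[r0, c0] <- cnt[r0, c0] + valid
    }
  }
  coh <- acc / ifelse(cnt > 0, cnt, 1)
  coh[matrix(const, h, w)] <- 0
  adjusted <- 1 / (1 + exp(gain * (cutoff - coh)))
  structure(list(coherence = coh, adjusted = adjusted,
                 cutoff = cutoff, gain = gain),
            class = "coherence_image")
}

#' @export
print.coherence_image <- function(x, ...) {
  cat(sprintf("<coherence_image> %d x %d, coherence range [%.2f, %.2f]\n",
              nrow(x$coherence), ncol(x$coherence),
              min(x$coherence), max(x$coherence)))
  invisible(x)
}

#' Temporal center-of-mass pseudocoloring
#'
#' Assigns each pixel the center of mass of its intensity time series,
#' `COM = sum_t t I(t) / sum_t I(t)` (frame units, 1-based), after
#' subtracting the per-pixel minimum so intensities are nonnegative.
#' Subregions of a well-isolated cell share one activation time and hence
#' one color; multicolored footprints reveal overlapping cells.
#'
#' @param movie Numeric array `frames x H x W`.
#' @return List (class `temporal_com_image`): `com` (H x W frame indices;
#'   NA where total intensity is 0), `hue` (H x W in `[0, 1)`, cyclic map
#'   of COM over the movie duration; NA pixels get the neutral hue 0).
#' @export
temporal_com_pseudocolor <- function(movie) {
  d <- dim(movie)
  if (length(d) != 3L) stop("'movie' must be frames x H x W", call. = FALSE)
  n_t <- d[1]
  x <- matrix(movie, n_t, d[2] * d[3])
  x <- sweep(x, 2, apply(x, 2, min))
  tot <- colSums(x)
  com <- colSums(x * seq_len(n_t)) / ifelse(tot > 0, tot, NA_real_)
  hue <- (com - 1) / n_t
  hue[is.na(hue)] <- 0
  structure(list(com = matrix(com, d[2], d[3]),
                 hue = matrix(hue, d[2], d[3])),
            class = "temporal_com_image")
}

#' Write a QC footprint overlay as PNG
#'
#' Renders the contrast-adjusted coherence map as brightness and the
#' temporal-COM hue as color (HSV). Requires the `png` package.
#'
#' @param coherence A [local_coherence_image()] result.
#' @param com A [temporal_com_pseudocolor()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @importFrom grDevices hsv col2rgb
#' @export
write_footprint_png <- function(coherence, com, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG output", call. = FALSE)
  }
  v <- coherence$adjusted
  hue <- com$hue
  cols <- hsv(h = pmin(pmax(hue, 0), 0.999), s = 0.85, v = pmin(pmax(v, 0), 1))
  rgb <- col2rgb(cols) / 255
  img <- array(0, c(nrow(v), ncol(v), 3))
  img[, , 1] <- matrix(rgb[1, ], nrow(v))
  img[, , 2] <- matrix(rgb[2, ], nrow(v))
  img[, , 3] <- matrix(rgb[3, ], nrow(v))
  png::writePNG(img, path)
  invisible(path)
}

#' Synthetic ROI movie for QC tests
#'
#' Generates a small movie with a disc of pixels sharing a common transient
#' over independent Gaussian noise (a minimal stand-in for a motion-
#' corrected two-photon segment around one cell).
#'
#' @param n_frames,h,w Movie dimensions.
#' @param center,radius Disc geometry (pixels).
#' @param onset_frame Transient onset.
#' @param amplitude,noise_sd Signal and noise scales.
#' @param decay Transient decay per frame.
#' @param seed Integer seed.
#' @return frames x H x W array with attribute `disc` (logical H x W).
#' @export
simulate_roi_movie <- function(n_frames = 60, h = 24, w = 24,
                               center = c(12, 12), radius = 5,
                               onset_frame = 20, amplitude = 8,
                               noise_sd = 1, decay = 0.85, seed = NULL) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  disc <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
  tr <- numeric(n_frames)
  tr[onset_frame:n_frames] <- amplitude * decay^(seq_len(n_frames - onset_frame + 1L) - 1L)
  with_seed(seed, {
    movie <- array(rnorm(n_frames * h * w, 0, noise_sd), c(n_frames, h, w))
    for (t in seq_len(n_frames)) {
      movie[t, , ][disc] <- movie[t, , ][disc] + tr[t]
    }
    attr(movie, "disc") <- disc
    movie
  })
}
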