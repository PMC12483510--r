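#' Virtual corridor layout
#'
#' Describes the linear virtual-reality corridor: total length, spatial bin
#' width, the centroids of the discrete visual landmarks on the corridor
#' wall, and the reward zone at the end of the track. Defaults follow an
#' 832-cm corridor discretized into 4.24-cm bins (196 bins) with six
#' landmarks, the last of which marks the reward zone.
#'
#' @param length_cm Corridor length in cm.
#' @param bin_width_cm Spatial bin width in cm.
#' @param landmarks_cm Numeric vector of landmark centroid positions (cm).
#' @param reward_zone_cm Length-2 interval (cm) of the reward zone.
#' @return An object of class `corridor_spec`.
#' @examples
#' spec <- corridor_spec()
#' spec$n_bins  # 196
#' @export
corridor_spec <- function(length_cm = 832,
                          bin_width_cm = 4.24,
                          landmarks_cm = c(70, 204, 338, 472, 606, 740),
                          reward_zone_cm = c(740, 810)) {
  stopifnot_scalar(length_cm, "length_cm", positive = TRUE)
  stopifnot_scalar(bin_width_cm, "bin_width_cm", positive = TRUE)
  if (bin_width_cm >= length_cm) {
    stop("'bin_width_cm' must be smaller than 'length_cm'", call. = FALSE)
  }
  if (any(landmarks_cm < 0 | landmarks_cm > length_cm)) {
    stop("landmark centroids must lie within [0, length_cm]", call. = FALSE)
  }
  if (length(reward_zone_cm) != 2L || reward_zone_cm[1] >= reward_zone_cm[2]) {
    stop("'reward_zone_cm' must be an increasing length-2 interval",
         call. = FALSE)
  }
  out <- list(
    length_cm = length_cm,
    bin_width_cm = bin_width_cm,
    landmarks_cm = sort(as.numeric(landmarks_cm)),
    reward_zone_cm = as.numeric(reward_zone_cm),
    n_bins = as.integer(floor(length_cm / bin_width_cm))
  )
  class(out) <- "corridor_spec"
  out
}

#' @export
print.corridor_spec <- function(x, ...) {
  cat(sprintf("<corridor_spec> %.0f cm, %d bins of %.2f cm, %d landmarks, RZ [%.0f, %.0f] cm\n",
              x$length_cm, x$n_bins, x$bin_width_cm, length(x$landmarks_cm),
              x$reward_zone_cm[1], x$reward_zone_cm[2]))
  invisible(x)
}

#' Map positions to spatial bins
#'
#' Bins are 1-based and inclusive; the residual track beyond
#' `n_bins * bin_width_cm` is assigned to the last bin.
#'
#' @param position_cm Numeric vector of positions (cm).
#' @param spec A [corridor_spec()].
#' @return Integer vector of bin indices in `1:spec$n_bins`.
#' @export
position_to_bin <- function(position_cm, spec) {
  b <- floor(position_cm / spec$bin_width_cm) + 1L
  pmin.int(pmax.int(as.integer(b), 1L), spec$n_bins)
}

# Centers (cm) of the spatial bins.
bin_centers <- function(spec) {
  (seq_len(spec$n_bins) - 0.5) * spec$bin_width_cm
}
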