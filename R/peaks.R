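#' One-dimensional peak detection with prominences and widths
#'
#' Local-maxima detection in the style common to signal-processing
#' toolkits: a peak is a sample strictly greater than its neighbors
#' (plateaus report their middle sample). Optional filters: minimum
#' `height`, minimum horizontal `distance` between retained peaks (smaller
#' peaks within the distance of a larger one are dropped), and minimum
#' topographic `prominence`. For retained peaks the width is measured at an
#' evaluation level `height - rel_height * prominence`, with linearly
#' interpolated crossing positions bounded by the peak's bases.
#'
#' @param x Numeric vector (e.g. a spatial tuning curve or a dF/F trace).
#' @param height Minimum peak height, or `NULL`.
#' @param distance Minimum index separation between peaks, or `NULL`.
#' @param prominence Minimum prominence, or `NULL`.
#' @param rel_height Relative height for width measurement (default 0.93).
#' @return data.frame with one row per retained peak: `peak` (index),
#'   `height`, `prominence`, `left_base`, `right_base`, `width`,
#'   `left_ip`, `right_ip` (interpolated crossings, index units).
#' @examples
#' tc <- dnorm(1:50, 25, 4) * 100
#' find_peaks_1d(tc, height = 6)
#' @export
find_peaks_1d <- function(x, height = NULL, distance = NULL,
                          prominence = NULL, rel_height = 0.93) {
  n <- length(x)
  if (n < 3L) {
    return(data.frame(peak = integer(), height = numeric(),
                      prominence = numeric(), left_base = integer(),
                      right_base = integer(), width = numeric(),
                      left_ip = numeric(), right_ip = numeric()))
  }
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        peaks <- c(peaks, (i + j) %/% 2L)
        i <- j + 1L
        next
      }
      i <- j + 1L
      next
    }
    i <- i + 1L
  }
  if (!is.null(height)) peaks <- peaks[x[peaks] >= height]
  if (length(peaks) && !is.null(distance) && distance > 1) {
    ord <- order(x[peaks], decreasing = TRUE)
    keep <- rep(TRUE, length(peaks))
    for (k in ord) {
      if (!keep[k]) next
      close <- abs(peaks - peaks[k]) < distance & seq_along(peaks) != k
      keep[close & x[peaks] <= x[peaks[k]]] <- FALSE
    }
    peaks <- peaks[keep]
  }
  if (!length(peaks)) {
    return(data.frame(peak = integer(), height = numeric(),
                      prominence = numeric(), left_base = integer(),
                      right_base = integer(), width = numeric(),
                      left_ip = numeric(), right_ip = numeric()))
  }
  prom <- numeric(length(peaks))
  lb <- rb <- integer(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    # left base: minimum between p and the previous sample higher than x[p]
    ileft <- p
    lmin <- x[p]
    lbase <- p
    while (ileft > 1L && x[ileft - 1L] <= x[p]) {
      ileft <- ileft - 1L
      if (x[ileft] < lmin) {
        lmin <- x[ileft]
        lbase <- ileft
      }
    }
    iright <- p
    rmin <- x[p]
    rbase <- p
    while (iright < n && x[iright + 1L] <= x[p]) {
      iright <- iright + 1L
      if (x[iright] < rmin) {
        rmin <- x[iright]
        rbase <- iright
      }
    }
    prom[k] <- x[p] - max(lmin, rmin)
    lb[k] <- lbase
    rb[k] <- rbase
  }
  sel <- if (is.null(prominence)) rep(TRUE, length(peaks)) else prom >= prominence
  peaks <- peaks[sel]; prom <- prom[sel]; lb <- lb[sel]; rb <- rb[sel]
  width <- l_ip <- r_ip <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    h <- x[p] - rel_height * prom[k]
    i <- p
    while (i > lb[k] && x[i - 1L] > h) i <- i - 1L
    l_ip[k] <- if (i > lb[k] && x[i - 1L] <= h) {
      (i - 1L) + (h - x[i - 1L]) / (x[i] - x[i - 1L])
    } else {
      as.numeric(lb[k])
    }
    i <- p
    while (i < rb[k] && x[i + 1L] > h) i <- i + 1L
    r_ip[k] <- if (i < rb[k] && x[i + 1L] <= h) {
      i + (x[i] - h) / (x[i] - x[i + 1L])
    } else {
      as.numeric(rb[k])
    }
    width[k] <- r_ip[k] - l_ip[k]
  }
  data.frame(peak = peaks, height = x[peaks], prominence = prom,
             left_base = lb, right_base = rb, width = width,
             left_ip = l_ip, right_ip = r_ip)
}
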