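# Frames of one lap spent inside a bin range.
.traversal_frames <- function(binned, lap, bins) {
  fr <- binned$lap_index[[lap]]
  fr[binned$frame_bin[fr] %in% bins]
}

#' Detect solitary calcium transients
#'
#' For each ROI carrying at least one BTSP-like formation event, the
#' reference amplitude is the maximum dF/F recorded while the animal
#' traversed the field (extended `extend_bins` bins to the right, clipped
#' at the corridor end) on the formation lap; with several BTSP events the
#' largest reference is used. Peaks in the ROI's dF/F trace (prominence >=
#' `prominence`, minimum separation `distance` samples) at least as large
#' as the reference are candidate solitary events. Candidates are excluded
#' if they fall within the spatial bounds of any of the ROI's fields, or if
#' the maximum dF/F in the surrounding context (the previous and following
#' `context_laps` laps within `context_bins` bins centered on the peak's
#' bin) exceeds the ROI's session median plus two SD of dF/F. Only the
#' largest surviving peak per ROI is reported (ties broken by earliest
#' lap).
#'
#' @param dff frames x ROIs dF/F matrix.
#' @param binned A [bin_session()] result.
#' @param events data.frame of classified events with columns `roi`,
#'   `category`, `formation_lap`, `left_bin`, `right_bin`.
#' @param fields data.frame of retained fields (`roi`, `left_bin`,
#'   `right_bin`) whose bounds exclude candidates.
#' @param prominence,distance Peak-detection parameters (1, 20 samples).
#' @param context_laps,context_bins Context window (5 laps, 11 bins).
#' @param context_sd_mult Context threshold: median + this many SD.
#' @param extend_bins Forward extension of the reference traversal.
#' @return data.frame (one row per ROI with a detection): `roi`, `frame`,
#'   `lap`, `bin`, `amplitude`, `reference`.
#' @export
detect_solitary_events <- function(dff, binned, events, fields,
                                   prominence = 1, distance = 20L,
                                   context_laps = 5L, context_bins = 11L,
                                   context_sd_mult = 2,
                                   extend_bins = 5L) {
  btsp <- events[events$category == "BTSP", , drop = FALSE]
  out <- list()
  half_ctx <- (context_bins - 1L) %/% 2L
  for (r in unique(btsp$roi)) {
    rows <- btsp[btsp$roi == r, , drop = FALSE]
    ref <- -Inf
    for (i in seq_len(nrow(rows))) {
      bins <- rows$left_bin[i]:min(binned$n_bins, rows$right_bin[i] + extend_bins)
      fr <- .traversal_frames(binned, rows$formation_lap[i], bins)
      if (length(fr)) ref <- max(ref, max(dff[fr, r]))
    }
    if (!is.finite(ref)) next
    x <- dff[, r]
    loc <- find_peaks_1d_tall(x, min_height = ref, distance = distance,
                              prominence = prominence)
    if (!length(loc)) next
    med <- median(x)
    thr_ctx <- med + context_sd_mult * sd(x)
    own_fields <- fields[fields$roi == r, , drop = FALSE]
    cand <- data.frame(frame = loc, amp = x[loc],
                       lap = binned$lap[loc], bin = binned$frame_bin[loc])
    keep <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      b <- cand$bin[i]
      inside <- nrow(own_fields) > 0 &&
        any(b >= own_fields$left_bin & b <= own_fields$right_bin)
      if (inside) {
        keep[i] <- FALSE
        next
      }
      laps <- setdiff(max(1L, cand$lap[i] - context_laps):
                        min(binned$n_laps, cand$lap[i] + context_laps),
                      cand$lap[i])
      bins <- max(1L, b - half_ctx):min(binned$n_bins, b + half_ctx)
      ctx <- unlist(binned$lap_index[laps], use.names = FALSE)
      ctx <- ctx[binned$frame_bin[ctx] %in% bins]
      if (length(ctx) && max(x[ctx]) > thr_ctx) keep[i] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) next
    best <- cand[order(-cand$amp, cand$lap), ][1L, ]
    out[[length(out) + 1L]] <- data.frame(
      roi = r, frame = best$frame, lap = best$lap, bin = best$bin,
      amplitude = best$amp, reference = ref)
  }
  if (!length(out)) {
    return(data.frame(roi = integer(), frame = integer(), lap = integer(),
                      bin = integer(), amplitude = numeric(),
                      reference = numeric()))
  }
  do.call(rbind, out)
}

# Tall-peak shortcut: local maxima at least min_height high, then the
# distance filter (only taller peaks can evict a candidate, and any such
# peak is itself above min_height, so pre-filtering by height is exact),
# then the prominence filter.
find_peaks_1d_tall <- function(x, min_height, distance, prominence) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  core <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  core <- core[x[core] >= min_height]
  # drop plateau duplicates (equal neighbors): keep first of each run
  if (length(core) > 1L) core <- core[c(TRUE, diff(core) > 1L)]
  if (!length(core)) return(integer(0))
  ord <- order(x[core], decreasing = TRUE)
  keep <- rep(TRUE, length(core))
  for (k in ord) {
    if (!keep[k]) next
    close <- abs(core - core[k]) < distance & seq_along(core) != k
    keep[close & x[core] <= x[core[k]]] <- FALSE
  }
  core <- core[keep]
  proms <- vapply(core, function(p) {
    i <- p
    lmin <- x[p]
    while (i > 1L && x[i - 1L] <= x[p]) {
      i <- i - 1L
      lmin <- min(lmin, x[i])
    }
    j <- p
    rmin <- x[p]
    while (j < n && x[j + 1L] <= x[p]) {
      j <- j + 1L
      rmin <- min(rmin, x[j])
    }
    x[p] - max(lmin, rmin)
  }, numeric(1))
  core[proms >= prominence]
}

#' Concordance between inferred spikes and fluorescence within fields
#'
#' For one ROI with at least one retained field, the field windows are
#' concatenated and, for every lap, the maximum dF/F during the traversal
#' of those bins and the maximum bin-wise mean gated activity are
#' extracted. The two per-lap series are correlated (Pearson), and a null
#' distribution is built from all lap-wise circular permutations of the
#' activity series.
#'
#' @param dff frames x ROIs dF/F matrix.
#' @param binned A [bin_session()] result.
#' @param fields Retained fields of the ROI (`left_bin`, `right_bin`).
#' @param roi ROI index.
#' @return List with `r`, `null` (length `n_laps`, one value per circular
#'   permutation including the identity at shift 0), `n_laps`, or `NULL`
#'   (flagged) when fewer than 3 laps have data.
#' @export
spike_fluorescence_concordance <- function(dff, binned, fields, roi) {
  bins <- sort(unique(unlist(mapply(
    function(l, r) l:r, fields$left_bin, fields$right_bin,
    SIMPLIFY = FALSE))))
  if (!length(bins)) return(NULL)
  n_laps <- binned$n_laps
  max_dff <- rep(NA_real_, n_laps)
  for (l in seq_len(n_laps)) {
    fr <- .traversal_frames(binned, l, bins)
    if (length(fr)) max_dff[l] <- max(dff[fr, roi])
  }
  a <- binned$activity[, bins, roi, drop = FALSE]
  dim(a) <- dim(a)[1:2]
  a[is.na(a)] <- 0
  max_act <- apply(a, 1, max)
  ok <- !is.na(max_dff)
  if (sum(ok) < 3L) return(NULL)
  v_dff <- max_dff[ok]
  v_act <- max_act[ok]
  n <- length(v_act)
  null <- vapply(seq_len(n) - 1L, function(s) {
    perm <- v_act[((seq_len(n) - 1L + s) %% n) + 1L]
    r <- safe_cor(v_dff, perm)
    if (is.na(r)) 0 else r
  }, numeric(1))
  list(r = null[1L], null = null, n_laps = n)
}
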