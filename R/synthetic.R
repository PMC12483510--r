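#' Ground truth table for a synthetic session
#'
#' Builds the table of implanted events. Event kinds:
#' \describe{
#'   \item{BTSP}{large formation-lap burst centered forward of the stable
#'     field center, followed by smaller per-lap events at the center, i.e.
#'     a backward center-of-mass shift of `com_shift_cm`.}
#'   \item{NON_BTSP}{uniform-amplitude events at a fixed center from the
#'     formation lap onward; no gain, no shift.}
#'   \item{SOLITARY}{a single isolated large burst with silent spatial
#'     context, on an ROI that also carries a BTSP event.}
#'   \item{PREEXISTING_PF}{a field active from lap 1 (optionally remapping
#'     to `center_post_switch_cm` at `switch_lap`).}
#' }
#'
#' @param events data.frame with columns `roi`, `kind`, `formation_lap`,
#'   `center_cm`, `formation_amplitude_au`, `post_amplitude_au`,
#'   `com_shift_cm`, `drift_cm_per_lap` and optionally
#'   `center_post_switch_cm`.
#' @param switch_lap Optional lap at which PREEXISTING_PF fields remap.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(events, switch_lap = NA_integer_) {
  need <- c("roi", "kind", "formation_lap", "center_cm",
            "formation_amplitude_au", "post_amplitude_au",
            "com_shift_cm", "drift_cm_per_lap")
  if (nrow(events) > 0) {
    miss <- setdiff(need, names(events))
    if (length(miss)) {
      stop("ground truth misses columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (any(events$formation_lap < 1)) stop("formation_lap must be >= 1")
    if (any(events$formation_amplitude_au < 0) ||
        any(events$post_amplitude_au < 0)) stop("amplitudes must be >= 0")
    kinds <- c("BTSP", "NON_BTSP", "SOLITARY", "PREEXISTING_PF")
    if (!all(events$kind %in% kinds)) {
      stop("unknown event kind", call. = FALSE)
    }
  }
  if (is.null(events$center_post_switch_cm)) {
    events$center_post_switch_cm <- rep(NA_real_, nrow(events))
  }
  out <- list(events = events, switch_lap = switch_lap)
  class(out) <- "ground_truth"
  out
}

#' Default randomized ground truth
#'
#' Draws event positions and laps for a session with the given ROI budget.
#' Formation laps fall in `formation_lap_range` (after the minimum
#' pre-formation lap count used by temporal demarcation); centers avoid the
#' corridor edges so that fields are not truncated. Each SOLITARY event is
#' placed on a BTSP ROI at least `solitary_gap_cm` away from that field.
#'
#' @param spec A [corridor_spec()].
#' @param n_rois Total ROIs in the session.
#' @param n_btsp,n_non_btsp,n_solitary,n_preexisting Event counts.
#' @param n_laps Session laps.
#' @param formation_lap_range Inclusive lap range for formation laps.
#' @param formation_amplitude_au,post_amplitude_au Deconvolved-activity
#'   amplitudes (a.u.) of the formation burst and the per-lap events.
#' @param solitary_amplitude_au Amplitude of solitary bursts; defaults to
#'   1.5x the formation amplitude so the solitary fluorescence peak exceeds
#'   the formation-lap reference.
#' @param com_shift_cm Implanted backward shift of BTSP fields (cm).
#' @param switch_lap Optional remapping lap for PREEXISTING_PF fields.
#' @param solitary_gap_cm Minimum distance between a solitary burst and the
#'   host ROI's field center.
#' @param seed Integer seed.
#' @return A `ground_truth` object.
#' @export
make_ground_truth <- function(spec,
                              n_rois = 200,
                              n_btsp = max(1L, round(0.06 * n_rois)),
                              n_non_btsp = max(1L, round(0.06 * n_rois)),
                              n_solitary = min(n_btsp,
                                               max(1L, round(0.04 * n_rois))),
                              n_preexisting = round(0.2 * n_rois),
                              n_laps = 60,
                              formation_lap_range = c(min(20, n_laps),
                                                      max(min(20, n_laps),
                                                          min(38, n_laps - 9))),
                              formation_amplitude_au = 600,
                              post_amplitude_au = 150,
                              solitary_amplitude_au = 1.5 * formation_amplitude_au,
                              com_shift_cm = 12.72,
                              switch_lap = NA_integer_,
                              solitary_gap_cm = 170,
                              seed = NULL) {
  n_events <- n_btsp + n_non_btsp + n_preexisting
  if (n_events > n_rois) stop("more events than ROIs", call. = FALSE)
  if (n_solitary > n_btsp) stop("each SOLITARY event needs its own BTSP ROI",
                                call. = FALSE)
  with_seed(seed, {
    # keep implants in the constant-speed section: fields inside the
    # pre-reward slow-down would accumulate occupancy-inflated
    # fluorescence, distorting amplitude comparisons across track positions
    lo <- 50
    hi <- min(spec$length_cm - 60, spec$reward_zone_cm[1] - 80)
    kind <- c(rep("BTSP", n_btsp), rep("NON_BTSP", n_non_btsp),
              rep("PREEXISTING_PF", n_preexisting))
    ev <- data.frame(
      roi = seq_len(n_events),
      kind = kind,
      formation_lap = ifelse(
        kind == "PREEXISTING_PF", 1L,
        sample(seq.int(formation_lap_range[1], formation_lap_range[2]),
               n_events, replace = TRUE)),
      center_cm = runif(n_events, lo, hi),
      formation_amplitude_au = ifelse(kind == "BTSP",
                                      formation_amplitude_au, 0),
      post_amplitude_au = post_amplitude_au,
      com_shift_cm = ifelse(kind == "BTSP", com_shift_cm, 0),
      drift_cm_per_lap = 0,
      center_post_switch_cm = NA_real_
    )
    if (!is.na(switch_lap)) {
      pre <- ev$kind == "PREEXISTING_PF"
      ev$center_post_switch_cm[pre] <- runif(sum(pre), lo, hi)
    }
    if (n_solitary > 0) {
      host <- sample(which(ev$kind == "BTSP"), n_solitary)
      sol_center <- vapply(host, function(i) {
        repeat {
          p <- runif(1, lo, hi)
          if (abs(p - ev$center_cm[i]) >= solitary_gap_cm) return(p)
        }
      }, numeric(1))
      sol <- data.frame(
        roi = ev$roi[host],
        kind = "SOLITARY",
        formation_lap = sample(seq.int(formation_lap_range[1] + 2, n_laps - 6),
                               n_solitary, replace = TRUE),
        center_cm = sol_center,
        formation_amplitude_au = solitary_amplitude_au,
        post_amplitude_au = 0,
        com_shift_cm = 0,
        drift_cm_per_lap = 0,
        center_post_switch_cm = NA_real_
      )
      ev <- rbind(ev, sol)
    }
    ground_truth(ev, switch_lap = switch_lap)
  })
}

# Fixed 3-bin amplitude envelope (relative weights) of an implanted event.
.event_envelope <- c(0.6, 1, 0.6)

# Frame indices and amplitudes of one per-lap event: the envelope value is
# emitted on every frame the animal spends in each envelope bin, so the
# lap x bin mean activity equals the envelope exactly, independent of
# occupancy. Returns NULL or a list(frames, values).
.event_deposit <- function(behavior, spec, lap, center_cm, amplitude,
                           lap_index) {
  fr <- lap_index[[lap]]
  if (!length(fr)) return(NULL)
  bins <- position_to_bin(behavior$position_cm[fr], spec)
  cbin <- position_to_bin(center_cm, spec)
  env <- .event_envelope * amplitude
  tgt <- cbin + seq_along(env) - (length(env) + 1L) %/% 2L
  keep <- tgt >= 1L & tgt <= spec$n_bins & env > 0
  if (!any(keep)) return(NULL)
  sel <- bins %in% tgt[keep]
  if (!any(sel)) return(NULL)
  val <- env[match(bins[sel], tgt)]
  list(frames = fr[sel], values = val)
}

#' Implant labelled events into a deconvolved-activity matrix
#'
#' Writes the ground-truth events into a frames x ROIs deconvolved activity
#' matrix aligned with `behavior`. BTSP events emit a large formation-lap
#' burst centered `com_shift_cm` forward of the stable center followed by
#' smaller per-lap events at the center (lognormal per-lap gain jitter);
#' NON_BTSP events emit constant-amplitude events with zero shift; SOLITARY
#' events emit one isolated burst; PREEXISTING_PF events are active from
#' lap 1. Event ROIs are otherwise silent; `background_rate` adds sparse
#' random activity on the remaining ROIs. Amplitudes are calibrated (a.u.
#' scale ~100-1000) so single events clear the downstream 64 a.u. floor.
#'
#' @param behavior A `behavior_trace`.
#' @param truth A [ground_truth()].
#' @param spec A [corridor_spec()].
#' @param n_rois Number of ROIs (columns).
#' @param active_prob Per-lap probability that a field emits an event.
#' @param gain_sd Lognormal SD of the per-lap amplitude gain for BTSP and
#'   PREEXISTING_PF events (non-BTSP events are noise-free in amplitude so
#'   that their zero gain / zero shift phenotype is well defined).
#' @param background_rate Per-frame probability of a background spike on
#'   non-event ROIs.
#' @param background_amplitude_meanlog,background_amplitude_sdlog Lognormal
#'   parameters of background spike amplitudes (a.u.).
#' @param seed Integer seed.
#' @return frames x ROIs numeric matrix; attribute `implants` records every
#'   deposited (roi, lap, kind) event for calibration tests.
#' @export
implant_events <- function(behavior, truth, spec, n_rois,
                           active_prob = 0.9,
                           gain_sd = 0.2,
                           background_rate = 0.003,
                           background_amplitude_meanlog = log(90),
                           background_amplitude_sdlog = 0.5,
                           seed = NULL) {
  ev <- truth$events
  n_laps <- attr(behavior, "n_laps")
  if (nrow(ev) > 0) {
    if (any(ev$roi > n_rois)) stop("event roi exceeds n_rois", call. = FALSE)
    if (any(ev$formation_lap > n_laps)) {
      stop("event formation_lap exceeds the session laps", call. = FALSE)
    }
    if (any(ev$center_cm < 0 | ev$center_cm > spec$length_cm)) {
      stop("event center outside the corridor", call. = FALSE)
    }
  }
  deconv <- matrix(0, nrow = nrow(behavior), ncol = n_rois)
  lap_index <- split(seq_len(nrow(behavior)), behavior$lap)
  dep_roi <- dep_lap <- dep_kind <- integer(0)
  dep_center <- numeric(0)
  dep <- list()  # per deposit: roi, frames, values
  kinds <- character(0)
  add_dep <- function(roi, lap, kind, center, d) {
    if (is.null(d)) return(invisible())
    dep[[length(dep) + 1L]] <<- list(roi = roi, frames = d$frames,
                                     values = d$values)
    dep_roi <<- c(dep_roi, roi)
    dep_lap <<- c(dep_lap, lap)
    kinds <<- c(kinds, kind)
    dep_center <<- c(dep_center, center)
    invisible()
  }

  with_seed(seed, {
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      if (e$kind == "SOLITARY") {
        add_dep(e$roi, e$formation_lap, e$kind, e$center_cm,
                .event_deposit(behavior, spec, e$formation_lap, e$center_cm,
                               e$formation_amplitude_au, lap_index))
        next
      }
      if (e$kind == "BTSP") {
        ctr <- e$center_cm + e$com_shift_cm
        add_dep(e$roi, e$formation_lap, e$kind, ctr,
                .event_deposit(behavior, spec, e$formation_lap, ctr,
                               e$formation_amplitude_au, lap_index))
      }
      if (e$kind == "NON_BTSP") {
        # formation lap of a non-BTSP field: same amplitude as later laps
        add_dep(e$roi, e$formation_lap, e$kind, e$center_cm,
                .event_deposit(behavior, spec, e$formation_lap, e$center_cm,
                               e$post_amplitude_au, lap_index))
      }
      first_post <- if (e$kind == "PREEXISTING_PF") e$formation_lap
                    else e$formation_lap + 1L
      if (first_post > n_laps) next
      laps <- seq.int(first_post, n_laps)
      active <- runif(length(laps)) < active_prob
      # classification needs the first three post-formation laps
      active[seq_len(min(3L, length(active)))] <- TRUE
      gains <- if (e$kind == "NON_BTSP") rep(1, length(laps))
               else exp(rnorm(length(laps), -gain_sd^2 / 2, gain_sd))
      for (j in seq_along(laps)) {
        if (!active[j]) next
        center <- e$center_cm - e$drift_cm_per_lap * (laps[j] - e$formation_lap)
        if (e$kind == "PREEXISTING_PF" && !is.na(truth$switch_lap) &&
            laps[j] >= truth$switch_lap && !is.na(e$center_post_switch_cm)) {
          center <- e$center_post_switch_cm
        }
        add_dep(e$roi, laps[j], e$kind, center,
                .event_deposit(behavior, spec, laps[j], center,
                               e$post_amplitude_au * gains[j], lap_index))
      }
    }
    # write all deposits per ROI in one pass
    n_overlap <- 0L
    first_overlap <- ""
    for (r in unique(dep_roi)) {
      ids <- which(dep_roi == r)
      frames <- unlist(lapply(dep[ids], `[[`, "frames"))
      values <- unlist(lapply(dep[ids], `[[`, "values"))
      if (anyDuplicated(frames)) {
        n_overlap <- n_overlap + sum(duplicated(frames))
        if (first_overlap == "") first_overlap <- sprintf("roi %d", r)
        agg <- rowsum(values, frames)
        deconv[as.integer(rownames(agg)), r] <- agg[, 1]
      } else {
        deconv[frames, r] <- values
      }
    }
    if (n_overlap > 0L) {
      warning(sprintf("%d overlapping implant frames; amplitudes summed (%s)",
                      n_overlap, first_overlap), call. = FALSE)
    }
    event_rois <- unique(ev$roi)
    bg_rois <- setdiff(seq_len(n_rois), event_rois)
    if (length(bg_rois) && background_rate > 0) {
      n_fr <- nrow(behavior)
      for (r in bg_rois) {
        hits <- which(runif(n_fr) < background_rate)
        if (length(hits)) {
          deconv[hits, r] <- exp(rnorm(length(hits),
                                       background_amplitude_meanlog,
                                       background_amplitude_sdlog))
        }
      }
    }
  })
  attr(deconv, "implants") <- if (length(dep)) {
    data.frame(roi = dep_roi, lap = dep_lap, kind = kinds,
               center_cm = dep_center)
  } else {
    data.frame(roi = integer(), lap = integer(), kind = character(),
               center_cm = numeric())
  }
  deconv
}

#' Render fluorescence traces from deconvolved activity
#'
#' Forward model inverse to the preprocessing: each ROI's activity is
#' convolved with a double-exponential GCaMP6s-like kernel (rise 0.18 s,
#' decay 1.8 s, unit peak) and added to a per-ROI baseline; a shared
#' low-pass-filtered neuropil signal enters `F_raw` scaled by the neuropil
#' coefficient, and i.i.d. Gaussian noise is added. `F_neu` carries the
#' shared neuropil signal so that the standard 0.7x subtraction removes it.
#'
#' @param deconvolved frames x ROIs activity matrix (a.u.).
#' @param frame_rate_hz Frame rate (Hz).
#' @param rise_s,decay_s Kernel time constants (s); must be positive with
#'   `decay_s > rise_s`.
#' @param baseline_mean,baseline_sd Per-ROI baseline fluorescence (a.u.).
#' @param neuropil_coef Scale of the neuropil contribution to `F_raw`.
#' @param neuropil_sd Amplitude (a.u.) of the shared neuropil fluctuation.
#' @param noise_sd Gaussian noise SD (a.u.) on `F_raw`.
#' @param seed Integer seed.
#' @return List with matrices `F_raw` and `F_neu`.
#' @export
render_traces <- function(deconvolved,
                          frame_rate_hz = 31,
                          rise_s = 0.18,
                          decay_s = 1.8,
                          baseline_mean = 400,
                          baseline_sd = 40,
                          neuropil_coef = 0.7,
                          neuropil_sd = 15,
                          noise_sd = 20,
                          seed = NULL) {
  if (rise_s <= 0 || decay_s <= 0 || decay_s <= rise_s) {
    stop("kernel constants must satisfy 0 < rise_s < decay_s", call. = FALSE)
  }
  if (noise_sd < 0 || neuropil_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  n_fr <- nrow(deconvolved)
  n_roi <- ncol(deconvolved)
  dt <- 1 / frame_rate_hz
  a_d <- exp(-dt / decay_s)
  a_r <- exp(-dt / rise_s)
  # unit-peak normalization of k(t) = exp(-t/decay) - exp(-t/rise)
  t_pk <- log(decay_s / rise_s) / (1 / rise_s - 1 / decay_s)
  k_pk <- exp(-t_pk / decay_s) - exp(-t_pk / rise_s)
  conv <- matrix(0, n_fr, n_roi)
  for (r in seq_len(n_roi)) {
    x <- deconvolved[, r]
    if (any(x != 0)) {
      y <- (stats::filter(x, a_d, method = "recursive") -
              stats::filter(x, a_r, method = "recursive")) / k_pk
      conv[, r] <- as.numeric(y)
    }
  }
  with_seed(seed, {
    baseline <- rnorm(n_roi, baseline_mean, baseline_sd)
    # shared slow neuropil fluctuation: heavily smoothed white noise
    npl_raw <- rnorm(n_fr, 0, 1)
    alpha <- exp(-dt / 2)  # ~2 s time constant low-pass
    npl <- as.numeric(stats::filter(npl_raw * (1 - alpha), alpha,
                                    method = "recursive"))
    npl <- npl / max(sd(npl), 1e-12) * neuropil_sd
    noise <- if (noise_sd > 0) {
      matrix(rnorm(n_fr * n_roi, 0, noise_sd), n_fr, n_roi)
    } else {
      0
    }
    F_neu <- matrix(npl, n_fr, n_roi) +
      matrix(rep(baseline * 0.5, each = n_fr), n_fr, n_roi)
    F_raw <- conv + matrix(rep(baseline, each = n_fr), n_fr, n_roi) +
      neuropil_coef * F_neu + noise
    list(F_raw = F_raw, F_neu = F_neu)
  })
}

#' Build a complete synthetic session
#'
#' Ties together behavior simulation, ground-truth generation, event
#' implantation and fluorescence rendering into a fully populated session.
#' All randomness derives from `seed`; identical `(config, seed)` give
#' identical sessions.
#'
#' @param n_rois,n_laps Session dimensions.
#' @param spec A [corridor_spec()].
#' @param truth Optional [ground_truth()]; by default drawn with
#'   [make_ground_truth()] under the same seed.
#' @param switch_lap Optional representational-switch lap passed to
#'   [make_ground_truth()].
#' @param noise_sd Fluorescence noise SD (a.u.); 0 gives a noiseless session.
#' @param behavior_args,truth_args,implant_args,render_args Named lists of
#'   extra arguments for the respective stages.
#' @param seed Integer root seed; stage seeds are derived from it.
#' @return A `pff_session` list with elements `behavior`, `F_raw`, `F_neu`,
#'   `deconvolved`, `truth`, `corridor`, `seed`.
#' @examples
#' ses <- make_session(n_rois = 20, n_laps = 25, seed = 1,
#'                     truth_args = list(n_btsp = 2, n_non_btsp = 2,
#'                                       n_solitary = 1, n_preexisting = 4))
#' ses
#' @export
make_session <- function(n_rois = 200,
                         n_laps = 60,
                         spec = corridor_spec(),
                         truth = NULL,
                         switch_lap = NA_integer_,
                         noise_sd = 20,
                         behavior_args = list(),
                         truth_args = list(),
                         implant_args = list(),
                         render_args = list(),
                         seed = NULL) {
  behavior <- do.call(simulate_behavior, c(
    list(spec = spec, n_laps = n_laps, seed = derive_seed(seed, 1L)),
    behavior_args))
  if (is.null(truth)) {
    truth <- do.call(make_ground_truth, c(
      list(spec = spec, n_rois = n_rois, n_laps = n_laps,
           switch_lap = switch_lap, seed = derive_seed(seed, 2L)),
      truth_args))
  }
  deconv <- do.call(implant_events, c(
    list(behavior = behavior, truth = truth, spec = spec, n_rois = n_rois,
         seed = derive_seed(seed, 3L)),
    implant_args))
  tr <- do.call(render_traces, c(
    list(deconvolved = deconv, noise_sd = noise_sd,
         frame_rate_hz = attr(behavior, "frame_rate_hz"),
         seed = derive_seed(seed, 4L)),
    render_args))
  out <- list(
    behavior = behavior,
    F_raw = tr$F_raw,
    F_neu = tr$F_neu,
    deconvolved = deconv,
    truth = truth,
    corridor = spec,
    seed = seed
  )
  class(out) <- "pff_session"
  out
}

#' @export
print.pff_session <- function(x, ...) {
  cat(sprintf("<pff_session> %d frames, %d ROIs, %d laps, %d implanted events\n",
              nrow(x$F_raw), ncol(x$F_raw), attr(x$behavior, "n_laps"),
              nrow(x$truth$events)))
  if (!is.na(x$truth$switch_lap)) {
    cat(sprintf("  representational switch at lap %d\n", x$truth$switch_lap))
  }
  invisible(x)
}
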