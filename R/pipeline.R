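#' Run the full analysis pipeline on a session
#'
#' Executes, in order: neuropil correction, event gating, dF/F,
#' lap x bin binning, odd/even reliability filtering, Skaggs-information
#' shuffle significance, place-field demarcation, temporal demarcation and
#' BTSP / non-BTSP classification of new fields, the misclassification
#' bootstrap for non-BTSP events, solitary-transient detection, the
#' population-vector correlogram with switch localization, spike-
#' fluorescence concordance, and the width dataset with leave-one-out
#' explained variances. Deterministic for a fixed `config$seed`: all stage
#' seeds are derived from it.
#'
#' @param session A `pff_session` (from [make_session()] or
#'   [load_session()]).
#' @param config A [pff_config()].
#' @param verbose Emit per-stage progress messages.
#' @return A `pff_result` list; see the elements `events`, `fields`,
#'   `solitary`, `pv`, `switch`, `ev`, `counts`.
#' @export
run_pipeline <- function(session, config = pff_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  spec <- session$corridor
  seed <- config$seed

  say("neuropil correction + event gating")
  f <- neuropil_correct(session$F_raw, session$F_neu, config$neuropil_coef)
  gate <- gate_inferred_events(f, session$deconvolved,
                               config$global_noise_interpretation)
  say("  %d/%d candidate events accepted",
      sum(gate$report$accepted), nrow(gate$report))

  binned <- bin_session(session$behavior, gate$gated, spec,
                        config$speed_threshold_cm_s)

  say("odd/even reliability")
  oe <- oddeven_reliability(binned, config$oddeven_threshold)
  tuned_rois <- oe$roi[oe$keep]
  say("  %d/%d ROIs pass r >= %.2f", length(tuned_rois), nrow(oe),
      config$oddeven_threshold)

  say("Skaggs significance (%d shuffles)", config$n_shuffles)
  si_rows <- lapply(tuned_rois, function(r) {
    s <- assess_spatial_significance(gate$gated[, r], binned,
                                     n_shuffles = config$n_shuffles,
                                     percentile = config$si_percentile,
                                     seed = derive_seed(seed, 1000L + r))
    data.frame(roi = r, si = s$si, threshold = s$threshold,
               significant = s$significant)
  })
  si_table <- if (length(si_rows)) do.call(rbind, si_rows) else
    data.frame(roi = integer(), si = numeric(), threshold = numeric(),
               significant = logical())
  sig_rois <- si_table$roi[si_table$significant]
  say("  %d ROIs spatially significant", length(sig_rois))

  say("place-field demarcation")
  field_rows <- lapply(sig_rois, function(r) {
    demarcate_place_fields(binned, gate$gated[, r], r,
                           peak_height = config$peak_height,
                           rel_height = config$rel_height,
                           n_shuffles = config$n_shuffles,
                           local_percentile = config$local_percentile,
                           active_lap_frac = config$active_lap_frac,
                           seed = derive_seed(seed, 2000L + r))
  })
  fields <- if (length(field_rows)) do.call(rbind, field_rows) else NULL
  if (is.null(fields) || !nrow(fields)) {
    fields <- data.frame(roi = integer(), left_bin = integer(),
                         right_bin = integer(), ext_left = integer(),
                         ext_right = integer(), width_cm = numeric(),
                         peak_bin = integer(), peak_height = numeric(),
                         si_local = numeric(), si_threshold = numeric(),
                         local_significant = logical(),
                         active_lap_fraction = numeric(),
                         retained = logical())
  }
  retained <- fields[fields$retained, , drop = FALSE]
  say("  %d candidate fields, %d retained", nrow(fields), nrow(retained))

  # dF/F is consumed only by the event-amplitude, solitary and concordance
  # stages, all of which operate on ROIs with retained fields
  dff <- matrix(NA_real_, nrow(f), ncol(f))
  need_dff <- unique(retained$roi)
  if (length(need_dff)) {
    dff[, need_dff] <- compute_dff(f[, need_dff, drop = FALSE],
                                   config$dff_window)$dff
  }

  say("temporal demarcation + classification")
  ev_rows <- list()
  for (i in seq_len(nrow(retained))) {
    fl <- retained[i, ]
    pfm <- build_pf_activity_matrix(binned, fl$roi, fl$left_bin,
                                    fl$right_bin, config$threshold_au,
                                    config$extend_bins)
    dem <- find_formation_and_end(pfm,
                                  min_prior_laps = config$min_prior_laps,
                                  max_prior_active_frac = config$max_prior_active_frac,
                                  prior_activity_frac = config$prior_activity_frac,
                                  end_silent_laps = config$end_silent_laps)
    if (is.na(dem$formation_lap)) next  # not a new field in this session
    filt <- apply_pf_filters(pfm, dem$formation_lap, dem$end_lap,
                             min_lifetime = config$min_lifetime,
                             max_silent_laps = config$max_silent_laps,
                             silent_frac = config$silent_frac)
    if (filt$keep) {
      cls <- classify_pff(pfm, dem$formation_lap, dem$end_lap,
                          drift_alpha = config$drift_alpha)
      category <- cls$category
      gain <- cls$gain; shift <- cls$backward_shift; drift <- cls$drift
      fcom <- cls$formation_com_cm; pcom <- cls$post_com_cm
    } else {
      category <- filt$reason
      gain <- shift <- drift <- NA
      fcom <- pcom <- NA_real_
    }
    fr <- .traversal_frames(binned, dem$formation_lap,
                            fl$left_bin:pfm$right_ext)
    ev_rows[[length(ev_rows) + 1L]] <- data.frame(
      roi = fl$roi, left_bin = fl$left_bin, right_bin = fl$right_bin,
      width_cm = fl$width_cm,
      formation_lap = dem$formation_lap, end_lap = dem$end_lap,
      lifetime = dem$end_lap - dem$formation_lap + 1L,
      gain = gain, backward_shift = shift, drift = drift,
      category = category,
      formation_com_cm = fcom, post_com_cm = pcom,
      formation_speed_cm_s = if (length(fr))
        mean(session$behavior$speed_cm_s[fr]) else NA_real_,
      formation_amplitude_dff = if (length(fr)) max(dff[fr, fl$roi])
        else NA_real_)
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(roi = integer(), left_bin = integer(), right_bin = integer(),
               width_cm = numeric(), formation_lap = integer(),
               end_lap = integer(), lifetime = integer(), gain = logical(),
               backward_shift = logical(), drift = logical(),
               category = character(), formation_com_cm = numeric(),
               post_com_cm = numeric(), formation_speed_cm_s = numeric(),
               formation_amplitude_dff = numeric())
  class(events) <- c("pff_events", "data.frame")
  say("  %d formation events (%s)", nrow(events),
      paste(names(table(events$category)), table(events$category),
            sep = ":", collapse = " "))

  say("misclassification bootstrap")
  boot_rows <- list()
  nb <- which(events$category == "NON_BTSP")
  for (i in nb) {
    e <- events[i, ]
    pfm <- build_pf_activity_matrix(binned, e$roi, e$left_bin, e$right_bin,
                                    config$threshold_au, config$extend_bins)
    b <- tryCatch(
      misclassification_bootstrap(pfm, e$formation_lap, e$end_lap, binned,
                                  retained,
                                  n_null = config$bootstrap_n_null,
                                  alpha = config$bootstrap_alpha,
                                  threshold_au = config$threshold_au,
                                  min_prior_laps = config$min_prior_laps,
                                  seed = derive_seed(seed, 3000L + e$roi)),
      error = function(err) NULL)
    if (!is.null(b)) {
      boot_rows[[length(boot_rows) + 1L]] <- data.frame(
        roi = e$roi, formation_lap = e$formation_lap,
        probability = b$probability,
        unlikely_misclassified = b$unlikely_misclassified,
        btsp_reachable = b$btsp_reachable)
    }
  }
  bootstrap <- if (length(boot_rows)) do.call(rbind, boot_rows) else
    data.frame(roi = integer(), formation_lap = integer(),
               probability = numeric(), unlikely_misclassified = logical(),
               btsp_reachable = logical())

  say("solitary transients")
  solitary <- detect_solitary_events(
    dff, binned, events, retained,
    prominence = config$solitary_prominence,
    distance = config$solitary_distance,
    context_laps = config$context_laps,
    context_bins = config$context_bins,
    context_sd_mult = config$context_sd_mult,
    extend_bins = config$extend_bins)

  say("population-vector correlogram")
  pv <- pv_correlogram(binned)
  switch_res <- tryCatch(locate_switch(pv),
                         error = function(e) list(switch_lap = NA_integer_,
                                                  contrast = NA_real_))

  say("spike-fluorescence concordance")
  conc_rows <- list()
  for (r in unique(retained$roi)) {
    cc <- spike_fluorescence_concordance(
      dff, binned, retained[retained$roi == r, , drop = FALSE], r)
    if (!is.null(cc)) {
      conc_rows[[length(conc_rows) + 1L]] <- data.frame(
        roi = r, r = cc$r, null_mean = mean(cc$null),
        null_q95 = as.numeric(quantile(cc$null, 0.95)), n_laps = cc$n_laps)
    }
  }
  concordance <- if (length(conc_rows)) do.call(rbind, conc_rows) else
    data.frame(roi = integer(), r = numeric(), null_mean = numeric(),
               null_q95 = numeric(), n_laps = integer())

  say("width model")
  cls_events <- events[events$category %in% c("BTSP", "NON_BTSP"), ,
                       drop = FALSE]
  width_data <- build_width_dataset(cls_events, binned, session$behavior,
                                    spec,
                                    min_speed_cm_s = config$width_min_speed_cm_s)
  ev_fit <- lapply(list(speed = "speed", cue_distance = "cue_distance",
                        both = c("speed", "cue_distance")),
                   function(p) {
                     tryCatch(loo_explained_variance(width_data, p)$ev,
                              error = function(e) NA_real_)
                   })

  counts <- c(
    n_rois = binned$n_rois,
    n_tuned = length(tuned_rois),
    n_significant = length(sig_rois),
    n_fields = nrow(fields),
    n_retained_fields = nrow(retained),
    n_events = nrow(events),
    n_btsp = sum(events$category == "BTSP"),
    n_non_btsp = sum(events$category == "NON_BTSP"),
    n_excluded = sum(startsWith(events$category, "EXCLUDED")),
    n_solitary = nrow(solitary))

  out <- list(events = events, fields = fields, si_table = si_table,
              oddeven = oe, bootstrap = bootstrap, solitary = solitary,
              pv = pv, switch = switch_res, concordance = concordance,
              width_data = width_data, ev = ev_fit, counts = counts,
              gate_report = gate$report, binned = binned, dff = dff,
              config = config)
  class(out) <- "pff_result"
  out
}

#' @export
print.pff_result <- function(x, ...) {
  cat("<pff_result>\n")
  cat(sprintf("  ROIs: %d total, %d tuned, %d spatially significant\n",
              x$counts["n_rois"], x$counts["n_tuned"],
              x$counts["n_significant"]))
  cat(sprintf("  fields: %d candidates, %d retained\n",
              x$counts["n_fields"], x$counts["n_retained_fields"]))
  cat(sprintf("  formation events: %d (BTSP %d, non-BTSP %d, excluded %d)\n",
              x$counts["n_events"], x$counts["n_btsp"],
              x$counts["n_non_btsp"], x$counts["n_excluded"]))
  cat(sprintf("  solitary transients: %d\n", x$counts["n_solitary"]))
  if (!is.na(x$switch$switch_lap)) {
    cat(sprintf("  representational switch at lap %d (contrast %.2f)\n",
                x$switch$switch_lap, x$switch$contrast))
  }
  invisible(x)
}

#' @export
summary.pff_result <- function(object, ...) {
  cat("Place-field formation summary\n")
  print(table(object$events$category))
  cat("\nLOO explained variance of field width:\n")
  for (nm in names(object$ev)) {
    cat(sprintf("  %-14s %.3f\n", nm, object$ev[[nm]]))
  }
  invisible(object)
}
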