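#' Save a session to a plain-text container
#'
#' Writes the session as a directory of CSV matrices plus a JSON metadata
#' file (`meta.json` carries the corridor layout, seed, ground truth and a
#' container version). The layout is:
#' `behavior.csv`, `F_raw.csv`, `F_neu.csv`, `deconvolved.csv`,
#' `meta.json`.
#'
#' @param session A `pff_session` (or compatible list).
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(as.data.frame(session$behavior),
                     file.path(path, "behavior.csv"))
  for (nm in c("F_raw", "F_neu", "deconvolved")) {
    data.table::fwrite(data.table::as.data.table(session[[nm]]),
                       file.path(path, sprintf("%s.csv", nm)))
  }
  truth_events <- if (!is.null(session$truth)) session$truth$events else NULL
  meta <- list(
    container_version = "1",
    frame_rate_hz = attr(session$behavior, "frame_rate_hz"),
    n_laps = attr(session$behavior, "n_laps"),
    seed = session$seed,
    corridor = list(
      length_cm = session$corridor$length_cm,
      bin_width_cm = session$corridor$bin_width_cm,
      landmarks_cm = session$corridor$landmarks_cm,
      reward_zone_cm = session$corridor$reward_zone_cm
    ),
    truth = list(
      events = truth_events,
      switch_lap = if (!is.null(session$truth)) session$truth$switch_lap
                   else NA_integer_
    )
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       dataframe = "columns", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a session from the plain-text container
#'
#' Validates shapes on load: the fluorescence and deconvolved matrices
#' must have one row per behavior frame and identical ROI counts; a clear
#' error names the failing invariant otherwise.
#'
#' @param path Directory written by [save_session()].
#' @return A `pff_session`.
#' @export
load_session <- function(path) {
  need <- c("behavior.csv", "F_raw.csv", "F_neu.csv", "deconvolved.csv",
            "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    stop("session container misses: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  behavior <- as.data.frame(data.table::fread(file.path(path, "behavior.csv")))
  attr(behavior, "frame_rate_hz") <- meta$frame_rate_hz
  attr(behavior, "n_laps") <- as.integer(meta$n_laps)
  class(behavior) <- c("behavior_trace", "data.frame")
  mats <- lapply(c("F_raw", "F_neu", "deconvolved"), function(nm) {
    as.matrix(data.table::fread(file.path(path, sprintf("%s.csv", nm))))
  })
  names(mats) <- c("F_raw", "F_neu", "deconvolved")
  for (nm in names(mats)) {
    dimnames(mats[[nm]]) <- NULL
    if (nrow(mats[[nm]]) != nrow(behavior)) {
      stop(sprintf("%s has %d frames but behavior has %d",
                   nm, nrow(mats[[nm]]), nrow(behavior)), call. = FALSE)
    }
    if (ncol(mats[[nm]]) != ncol(mats$F_raw)) {
      stop(sprintf("%s has %d ROIs but F_raw has %d",
                   nm, ncol(mats[[nm]]), ncol(mats$F_raw)), call. = FALSE)
    }
  }
  spec <- corridor_spec(length_cm = meta$corridor$length_cm,
                        bin_width_cm = meta$corridor$bin_width_cm,
                        landmarks_cm = meta$corridor$landmarks_cm,
                        reward_zone_cm = meta$corridor$reward_zone_cm)
  truth <- if (!is.null(meta$truth$events) && length(meta$truth$events)) {
    ev <- as.data.frame(meta$truth$events)
    sl <- meta$truth$switch_lap
    ground_truth(ev, switch_lap = if (is.null(sl) || is.na(sl)) NA_integer_
                 else as.integer(sl))
  } else {
    ground_truth(data.frame(roi = integer(), kind = character(),
                            formation_lap = integer(), center_cm = numeric(),
                            formation_amplitude_au = numeric(),
                            post_amplitude_au = numeric(),
                            com_shift_cm = numeric(),
                            drift_cm_per_lap = numeric()))
  }
  out <- list(behavior = behavior, F_raw = mats$F_raw, F_neu = mats$F_neu,
              deconvolved = mats$deconvolved, truth = truth,
              corridor = spec, seed = meta$seed)
  class(out) <- "pff_session"
  out
}
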