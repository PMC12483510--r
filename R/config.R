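#' Pipeline configuration
#'
#' All numeric constants of the analysis in one overridable list. The
#' defaults: 0.7 neuropil coefficient; 1000-sample rolling
#' median; 4.24-cm bins in an 832-cm corridor; 4 cm/s speed mask; 0.25
#' odd/even correlation cutoff; 1500 shuffles at the 99th (global) and
#' 95th (local) percentiles; tuning-peak height 6 and relative width 0.93;
#' 30% active laps; 64 a.u. activity floor; 5-bin forward extension; 17
#' pre-formation laps; 5 silent laps ending a field; lifetime >= 9 laps and
#' <= 8 silent laps; COM smoothing kernel 3; 5% misclassification
#' criterion; solitary peak prominence 1 and distance 20 with a +/-5 lap x
#' 11 bin context at median + 2 SD; 5 cm/s width-model speed cutoff; 50-cm
#' start-offset search; 10000 regression subsamples.
#'
#' @param ... Named overrides of any default.
#' @return A `pff_config` list.
#' @examples
#' cfg <- pff_config(n_shuffles = 200)
#' cfg$threshold_au  # 64
#' @export
pff_config <- function(...) {
  cfg <- list(
    neuropil_coef = 0.7,
    global_noise_interpretation = "median",
    dff_window = 1000L,
    speed_threshold_cm_s = 4,
    oddeven_threshold = 0.25,
    n_shuffles = 1500L,
    si_percentile = 99,
    local_percentile = 95,
    peak_height = 6,
    rel_height = 0.93,
    active_lap_frac = 0.30,
    threshold_au = 64,
    extend_bins = 5L,
    min_prior_laps = 17L,
    max_prior_active_frac = 0.10,
    prior_activity_frac = 0.01,
    end_silent_laps = 5L,
    min_lifetime = 9L,
    max_silent_laps = 8L,
    silent_frac = 0.10,
    com_kernel = 3L,
    drift_alpha = 0.05,
    bootstrap_alpha = 0.05,
    bootstrap_n_null = 1000L,
    solitary_prominence = 1,
    solitary_distance = 20L,
    context_laps = 5L,
    context_bins = 11L,
    context_sd_mult = 2,
    width_min_speed_cm_s = 5,
    offset_range_cm = c(0, 50),
    offset_step_cm = 1,
    n_resamples = 10000L,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "pff_config"
  cfg
}

#' @export
print.pff_config <- function(x, ...) {
  cat("<pff_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg A [pff_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the parsed `pff_config` (round trips exactly).
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  int_keys <- c("dff_window", "n_shuffles", "extend_bins", "min_prior_laps",
                "end_silent_laps", "min_lifetime", "max_silent_laps",
                "com_kernel", "bootstrap_n_null", "solitary_distance",
                "context_laps", "context_bins", "n_resamples", "seed")
  for (k in intersect(int_keys, names(vals))) {
    vals[[k]] <- as.integer(vals[[k]])
  }
  do.call(pff_config, vals)
}
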