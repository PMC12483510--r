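#' Simulate running behavior in the virtual corridor
#'
#' Generates a per-frame behavior trace for `n_laps` traversals of the
#' corridor at the imaging frame rate. Each lap runs at a lap-specific mean
#' speed drawn uniformly from `speed_range_cm_s` (well-trained animals run
#' at a relatively constant 30-40 cm/s), with optional small frame-to-frame
#' speed jitter and a smooth slow-down ramp before the reward zone. Upon
#' reaching the corridor end the animal is teleported back to the start and
#' the lap index increments.
#'
#' @param spec A [corridor_spec()].
#' @param n_laps Number of laps (>= 1).
#' @param speed_range_cm_s Length-2 range the per-lap mean speed is drawn
#'   from (cm/s).
#' @param speed_jitter_sd Frame-to-frame speed jitter SD (cm/s).
#' @param slowdown_factor Multiplicative speed factor reached at the reward
#'   zone entrance (1 = no slow-down). The ramp starts `slowdown_ramp_cm`
#'   before the reward zone.
#' @param slowdown_ramp_cm Length of the slow-down ramp (cm).
#' @param frame_rate_hz Imaging frame rate (Hz).
#' @param seed Integer seed; the trace is deterministic for a fixed seed.
#' @return A `behavior_trace` data.frame with columns `time_s`,
#'   `position_cm`, `speed_cm_s`, `lap` and attributes `frame_rate_hz`,
#'   `n_laps`.
#' @examples
#' beh <- simulate_behavior(corridor_spec(), n_laps = 3, seed = 1)
#' table(beh$lap)
#' @export
simulate_behavior <- function(spec,
                              n_laps,
                              speed_range_cm_s = c(30, 40),
                              speed_jitter_sd = 1.5,
                              slowdown_factor = 0.5,
                              slowdown_ramp_cm = 60,
                              frame_rate_hz = 31,
                              seed = NULL) {
  if (n_laps < 1L) stop("'n_laps' must be >= 1", call. = FALSE)
  if (any(speed_range_cm_s <= 0) || min(speed_range_cm_s) <= 0) {
    stop("speeds must be positive", call. = FALSE)
  }
  if (speed_jitter_sd < 0) stop("'speed_jitter_sd' must be >= 0", call. = FALSE)
  dt <- 1 / frame_rate_hz
  rz_start <- spec$reward_zone_cm[1]

  with_seed(seed, {
    pos_l <- vector("list", n_laps)
    spd_l <- vector("list", n_laps)
    for (lap in seq_len(n_laps)) {
      v_lap <- runif(1, speed_range_cm_s[1], speed_range_cm_s[2])
      # generous frame budget; lap ends at teleport
      n_max <- ceiling(spec$length_cm / (v_lap * slowdown_factor * dt)) + 50L
      pos <- numeric(n_max)
      spd <- numeric(n_max)
      p <- 0
      i <- 0L
      while (p < spec$length_cm) {
        i <- i + 1L
        ramp <- 1
        if (p > rz_start - slowdown_ramp_cm) {
          frac <- min(1, (p - (rz_start - slowdown_ramp_cm)) / slowdown_ramp_cm)
          ramp <- 1 - (1 - slowdown_factor) * frac
        }
        v <- v_lap * ramp + if (speed_jitter_sd > 0) rnorm(1, 0, speed_jitter_sd) else 0
        v <- max(v, 1)
        pos[i] <- p
        spd[i] <- v
        p <- p + v * dt
      }
      pos_l[[lap]] <- pos[seq_len(i)]
      spd_l[[lap]] <- spd[seq_len(i)]
    }
    position <- unlist(pos_l)
    speed <- unlist(spd_l)
    lap <- rep.int(seq_len(n_laps), lengths(pos_l))
    out <- data.frame(
      time_s = (seq_along(position) - 1) * dt,
      position_cm = position,
      speed_cm_s = speed,
      lap = lap
    )
    attr(out, "frame_rate_hz") <- frame_rate_hz
    attr(out, "n_laps") <- as.integer(n_laps)
    class(out) <- c("behavior_trace", "data.frame")
    out
  })
}

# Frame indices of one lap.
lap_frames <- function(behavior, lap) which(behavior$lap == lap)

#' Per-frame occupancy oracle helper
#'
#' Counts frames per (lap, bin); used both by binning and by tests.
#' @keywords internal
#' @noRd
frame_bins <- function(behavior, spec) position_to_bin(behavior$position_cm, spec)
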