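# Internal: evaluate code under a given seed without disturbing the caller's
# RNG stream.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the behavioral-state trajectory simulator
#'
#' Defines a generative model of single-fly locomotion with three behavioral
#' states per frame step: WALK (correlated random walk: heading diffuses by a
#' Gaussian increment, step length is the walk speed times lognormal noise),
#' FREEZE (no displacement, heading held; geometric dwell times via the
#' enter/exit probabilities), and BURST (a single-frame multiplicative speed
#' spike accompanied by a large heading kick, the simulated counterpart of the
#' abrupt accelerations-with-direction-change that characterise dyskinetic
#' movement, and the intended AIM-qualifying events).
#'
#' The scalar \code{dose} in [0, 1] stands in for levodopa exposure
#' (concentration or diet duration) and maps linearly onto four effects:
#' reduced walk speed, increased freeze entry, increased turning, and
#' increased burst rate (see \code{\link{effective_parameters}} for the exact
#' mapping). Identical seed and configuration always reproduce the identical
#' trajectory.
#'
#' @param n_frames integer, recording length in frames (default 9018, a
#'   5-minute recording at 30.06 frames/s).
#' @param frame_rate frames per second (default 30.06).
#' @param walk_speed_mm_s mean walking speed at dose 0, mm/s.
#' @param speed_noise_cv coefficient of variation of the lognormal step-length
#'   noise (mean held at 1).
#' @param freeze_enter_p,freeze_exit_p per-frame probabilities of entering and
#'   leaving FREEZE at dose 0; dwell times are geometric and the stationary
#'   freeze occupancy is enter/(enter + exit).
#' @param turn_sd_deg SD of the per-frame heading increment at dose 0,
#'   degrees.
#' @param burst_rate_per_min expected bursts per minute at dose 0.
#' @param burst_gain multiplicative speed spike of a burst frame (> 1).
#' @param burst_turn_deg magnitude of the heading kick on a burst frame,
#'   degrees (random sign).
#' @param dose scalar in [0, 1].
#' @param arena_radius_mm circular arena radius; positions reflect off the
#'   wall.
#' @param seed integer RNG seed.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_frames = 9018L, frame_rate = 30.06,
                              walk_speed_mm_s = 8, speed_noise_cv = 0.3,
                              freeze_enter_p = 0.01, freeze_exit_p = 0.15,
                              turn_sd_deg = 8, burst_rate_per_min = 0.2,
                              burst_gain = 6, burst_turn_deg = 90,
                              dose = 0, arena_radius_mm = 44, seed = 1L) {
  cfg <- list(n_frames = as.integer(n_frames), frame_rate = frame_rate,
              walk_speed_mm_s = walk_speed_mm_s,
              speed_noise_cv = speed_noise_cv,
              freeze_enter_p = freeze_enter_p, freeze_exit_p = freeze_exit_p,
              turn_sd_deg = turn_sd_deg,
              burst_rate_per_min = burst_rate_per_min,
              burst_gain = burst_gain, burst_turn_deg = burst_turn_deg,
              dose = dose, arena_radius_mm = arena_radius_mm,
              seed = as.integer(seed))
  nums <- cfg[setdiff(names(cfg), "seed")]
  if (!all(vapply(nums, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1L))))
    stop("all simulation parameters must be finite scalars", call. = FALSE)
  if (cfg$n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  if (cfg$frame_rate <= 0) stop("frame_rate must be > 0", call. = FALSE)
  if (cfg$walk_speed_mm_s <= 0) stop("walk_speed_mm_s must be > 0", call. = FALSE)
  if (cfg$speed_noise_cv < 0) stop("speed_noise_cv must be >= 0", call. = FALSE)
  if (cfg$freeze_enter_p < 0 || cfg$freeze_enter_p > 1 ||
      cfg$freeze_exit_p < 0 || cfg$freeze_exit_p > 1)
    stop("freeze probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$turn_sd_deg < 0) stop("turn_sd_deg must be >= 0", call. = FALSE)
  if (cfg$burst_rate_per_min < 0) stop("burst_rate_per_min must be >= 0", call. = FALSE)
  if (cfg$burst_gain <= 1) stop("burst_gain must be > 1", call. = FALSE)
  if (cfg$burst_turn_deg < 0) stop("burst_turn_deg must be >= 0", call. = FALSE)
  if (cfg$dose < 0 || cfg$dose > 1) stop("dose must lie in [0, 1]", call. = FALSE)
  if (cfg$arena_radius_mm <= 0) stop("arena_radius_mm must be > 0", call. = FALSE)
  if (is.na(cfg$seed)) stop("seed must be an integer", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  eff <- effective_parameters(x)
  cat(sprintf("Simulation config: %d frames at %.2f frames/s, dose %.2f, seed %d\n",
              x$n_frames, x$frame_rate, x$dose, x$seed))
  cat(sprintf("  effective: walk %.2f mm/s, freeze occupancy %.3f, turn SD %.1f deg, %.1f bursts/min\n",
              eff$walk_speed_mm_s, eff$freeze_occupancy, eff$turn_sd_deg,
              eff$burst_rate_per_min))
  invisible(x)
}

#' Dose-adjusted simulator parameters
#'
#' Applies the linear dose mapping and returns the effective per-frame
#' parameters the simulator draws from, together with closed-form expected
#' values used for parameter-recovery checks:
#' \itemize{
#'   \item walk speed: \code{walk_speed_mm_s * (1 - 0.5 * dose)}
#'   \item freeze entry: \code{freeze_enter_p * (1 + 3 * dose)} (capped at 1)
#'   \item turn SD: \code{turn_sd_deg * (1 + 2.5 * dose)}
#'   \item burst rate: \code{burst_rate_per_min + 20 * dose}
#' }
#' \code{freeze_occupancy} is the stationary occupancy
#' enter/(enter + exit) of the two-state walk/freeze chain;
#' \code{burst_p_per_frame} the per-walk-frame burst probability;
#' \code{expected_mean_speed_mm_s} the occupancy-weighted expected mean
#' instantaneous speed
#' \code{walk_speed * (1 - occupancy) * (1 + p_burst * (gain - 1))}
#' (step-length noise has mean 1; wall reflections shorten the occasional
#' step slightly, so measured means sit marginally below this value).
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a list of effective parameters and expectations.
#' @export
effective_parameters <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  d <- config$dose
  walk <- config$walk_speed_mm_s * (1 - 0.5 * d)
  enter <- min(1, config$freeze_enter_p * (1 + 3 * d))
  exitp <- config$freeze_exit_p
  turn <- config$turn_sd_deg * (1 + 2.5 * d)
  rate <- config$burst_rate_per_min + 20 * d
  occ <- if (enter == 0 && exitp == 0) 0 else enter / (enter + exitp)
  p_burst <- min(1, rate / (config$frame_rate * 60))
  list(walk_speed_mm_s = walk,
       freeze_enter_p = enter,
       freeze_exit_p = exitp,
       turn_sd_deg = turn,
       burst_rate_per_min = rate,
       burst_p_per_frame = p_burst,
       freeze_occupancy = occ,
       expected_mean_speed_mm_s =
         walk * (1 - occ) * (1 + p_burst * (config$burst_gain - 1)))
}

#' Simulate a single-fly trajectory
#'
#' Generates one trajectory from a \code{\link{simulation_config}}:
#' a walk/freeze two-state Markov chain (geometric dwell times, started from
#' its stationary distribution) with single-frame bursts superimposed on walk
#' steps; heading diffuses on walk steps and is held during freezes; positions
#' reflect off the circular arena wall. The hidden behavioral state of every
#' step ("WALK", "FREEZE" or "BURST") is attached as
#' \code{attr(trajectory, "states")} for ground-truth testing, and the config
#' as \code{attr(trajectory, "config")}. The same seed and config always give
#' a bit-identical trajectory.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{\link{fly_trajectory}} (positions in mm) with attributes
#'   \code{states} (character, length \code{n_frames - 1}) and \code{config}.
#' @examples
#' tr <- simulate_trajectory(simulation_config(n_frames = 300, seed = 7))
#' table(attr(tr, "states"))
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  eff <- effective_parameters(config)
  n_steps <- config$n_frames - 1L
  .with_seed(config$seed, {
    frozen <- logical(n_steps)
    frozen[1L] <- stats::runif(1) < eff$freeze_occupancy
    u <- stats::runif(n_steps)
    for (i in seq_len(n_steps - 1L)) {
      frozen[i + 1L] <- if (frozen[i]) u[i] >= eff$freeze_exit_p
                        else u[i] < eff$freeze_enter_p
    }
    burst <- !frozen & stats::runif(n_steps) < eff$burst_p_per_frame
    turns <- stats::rnorm(n_steps, 0, eff$turn_sd_deg)
    turns[frozen] <- 0
    turns[burst] <- turns[burst] +
      sample(c(-1, 1), sum(burst), replace = TRUE) * config$burst_turn_deg
    base_len <- eff$walk_speed_mm_s / config$frame_rate
    if (config$speed_noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$speed_noise_cv^2))
      noise <- stats::rlnorm(n_steps, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else noise <- rep(1, n_steps)
    len <- base_len * noise
    len[frozen] <- 0
    len[burst] <- len[burst] * config$burst_gain
    heading <- stats::runif(1, -180, 180)
    R <- config$arena_radius_mm
    x <- y <- numeric(config$n_frames)
    ori <- numeric(config$n_frames)
    ori[1L] <- heading
    for (i in seq_len(n_steps)) {
      heading <- heading + turns[i]
      cx <- x[i] + len[i] * cospi(heading / 180)
      cy <- y[i] + len[i] * sinpi(heading / 180)
      r <- sqrt(cx^2 + cy^2)
      if (r > R) {
        # radial mirror back inside the wall; heading follows the realized step
        scale <- (2 * R - r) / r
        cx <- cx * scale
        cy <- cy * scale
        heading <- atan2(cy - y[i], cx - x[i]) * 180 / pi
      }
      x[i + 1L] <- cx
      y[i + 1L] <- cy
      ori[i + 1L] <- heading
    }
    traj <- fly_trajectory(frame = 0:(config$n_frames - 1L), x = x, y = y,
                           orientation = ori,
                           calibration = arena_calibration(
                             pixels_per_mm = 1,
                             frame_rate = config$frame_rate,
                             arena_diameter_mm = 2 * R))
    attr(traj, "states") <- ifelse(frozen, "FREEZE",
                                   ifelse(burst, "BURST", "WALK"))
    attr(traj, "config") <- config
    traj
  })
}

# Deterministic, order-independent per-fly seed derived from the master seed.
.derive_seed <- function(master, fly_index, dose_index) {
  as.integer((abs(as.numeric(master)) * 2654435761 + fly_index * 40503 +
                dose_index * 2246822519 + 374761393) %% 2147483647)
}

#' Simulate a cohort of flies across dose levels
#'
#' Generates \code{n_flies} independent trajectories at each dose level,
#' with per-fly seeds derived deterministically from the master seed in
#' \code{config} (counter-based splitting, so the cohort is reproducible and
#' each fly's trajectory does not depend on generation order).
#'
#' @param config a \code{\link{simulation_config}}; its \code{dose} field is
#'   overridden by \code{dose_levels} and its \code{seed} is the master seed.
#' @param n_flies integer >= 1, flies per dose level.
#' @param dose_levels numeric vector of doses in [0, 1].
#' @return an object of class \code{fly_cohort}: a list with one element per
#'   fly, each a list \code{(fly_id, dose, seed, trajectory)}.
#' @export
simulate_cohort <- function(config, n_flies, dose_levels) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(dose_levels) < 1L) stop("dose_levels must be non-empty", call. = FALSE)
  if (n_flies < 1L) stop("n_flies must be >= 1", call. = FALSE)
  if (any(!is.finite(dose_levels)) || any(dose_levels < 0 | dose_levels > 1))
    stop("dose levels must lie in [0, 1]", call. = FALSE)
  out <- list()
  for (di in seq_along(dose_levels)) {
    for (fi in seq_len(n_flies)) {
      cfg_i <- config
      cfg_i$dose <- dose_levels[di]
      cfg_i$seed <- .derive_seed(config$seed, fi, di)
      out[[length(out) + 1L]] <- list(
        fly_id = sprintf("dose%g_fly%02d", dose_levels[di], fi),
        dose = dose_levels[di],
        seed = cfg_i$seed,
        trajectory = simulate_trajectory(cfg_i))
    }
  }
  structure(out, class = "fly_cohort", master_seed = config$seed,
            dose_levels = dose_levels, n_flies = as.integer(n_flies))
}

#' @export
print.fly_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d flies x %d dose level(s) (master seed %d)\n",
              attr(x, "n_flies"), length(attr(x, "dose_levels")),
              attr(x, "master_seed")))
  cat("  doses:", paste(attr(x, "dose_levels"), collapse = ", "), "\n")
  invisible(x)
}
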