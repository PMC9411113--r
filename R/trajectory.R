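#' Arena and recording calibration
#'
#' Bundles the recording constants needed to interpret a tracked trajectory:
#' the spatial calibration (pixels per mm), the camera frame rate, and
#' optionally the arena diameter for bounds checking. The default frame rate
#' is 30.06 frames/s, the rate of the 5-minute single-fly recordings this
#' package targets (9018 frames, 0.033 s per frame).
#'
#' @param pixels_per_mm positive scalar; tracker pixels per millimetre.
#'   Use 1 when the trajectory file is already in mm.
#' @param frame_rate positive scalar, frames per second.
#' @param arena_diameter_mm optional positive scalar, arena diameter in mm,
#'   used only to sanity-check loaded coordinates.
#' @return an object of class \code{arena_calibration}.
#' @examples
#' arena_calibration(pixels_per_mm = 12.5)
#' @export
arena_calibration <- function(pixels_per_mm = 1, frame_rate = 30.06,
                              arena_diameter_mm = NULL) {
  stopifnot(is.numeric(pixels_per_mm), length(pixels_per_mm) == 1L,
            is.finite(pixels_per_mm),
            is.numeric(frame_rate), length(frame_rate) == 1L,
            is.finite(frame_rate))
  if (pixels_per_mm <= 0) stop("pixels_per_mm must be > 0", call. = FALSE)
  if (frame_rate <= 0) stop("frame_rate must be > 0", call. = FALSE)
  if (!is.null(arena_diameter_mm)) {
    stopifnot(is.numeric(arena_diameter_mm), length(arena_diameter_mm) == 1L)
    if (!is.finite(arena_diameter_mm) || arena_diameter_mm <= 0)
      stop("arena_diameter_mm must be a positive number", call. = FALSE)
  }
  structure(list(pixels_per_mm = as.numeric(pixels_per_mm),
                 frame_rate = as.numeric(frame_rate),
                 arena_diameter_mm = arena_diameter_mm),
            class = "arena_calibration")
}

#' @export
print.arena_calibration <- function(x, ...) {
  cat("Arena calibration:", x$pixels_per_mm, "px/mm,",
      x$frame_rate, "frames/s")
  if (!is.null(x$arena_diameter_mm))
    cat(", arena diameter", x$arena_diameter_mm, "mm")
  cat("\n")
  invisible(x)
}

#' Single-fly trajectory
#'
#' Constructs and validates a per-frame trajectory of one walking fly:
#' 0-based frame index increasing strictly by 1, x/y centroid position in mm,
#' and body orientation in degrees wrapped to [-180, 180). Positions are
#' always stored in mm; \code{source_units} records whether the input was
#' pixels (converted on load) or mm.
#'
#' @param frame integer vector of frame indices, starting at 0 and increasing
#'   by exactly 1.
#' @param x,y numeric vectors of positions (mm after calibration).
#' @param orientation numeric vector of body headings in degrees; wrapped to
#'   [-180, 180) by the constructor.
#' @param calibration an \code{\link{arena_calibration}}.
#' @param source_units "mm" or "px"; provenance flag only, positions are
#'   already in mm.
#' @return an object of class \code{fly_trajectory} with elements
#'   \code{frame}, \code{x}, \code{y}, \code{orientation}, \code{n_frames},
#'   \code{calibration}, \code{source_units}.
#' @examples
#' tr <- fly_trajectory(0:2, x = c(0, 3, 3), y = c(0, 4, 4),
#'                      orientation = c(0, 45, 45),
#'                      calibration = arena_calibration())
#' tr$n_frames
#' @export
fly_trajectory <- function(frame, x, y, orientation,
                           calibration = arena_calibration(),
                           source_units = "mm") {
  if (!inherits(calibration, "arena_calibration"))
    stop("calibration must be an arena_calibration object", call. = FALSE)
  source_units <- match.arg(source_units, c("mm", "px"))
  n <- length(frame)
  if (n < 2L) stop("a trajectory needs at least 2 frames", call. = FALSE)
  if (length(x) != n || length(y) != n || length(orientation) != n)
    stop("frame, x, y and orientation must have equal length", call. = FALSE)
  if (!all(is.finite(frame)) || !all(is.finite(x)) || !all(is.finite(y)) ||
      !all(is.finite(orientation)))
    stop("trajectory fields must be finite", call. = FALSE)
  frame <- as.integer(round(frame))
  .check_frame_sequence(frame)
  structure(list(frame = frame,
                 x = as.numeric(x),
                 y = as.numeric(y),
                 orientation = wrap_degrees(as.numeric(orientation)),
                 n_frames = n,
                 calibration = calibration,
                 source_units = source_units),
            class = "fly_trajectory")
}

# frames must run 0,1,2,...; name the first offending frame on failure
.check_frame_sequence <- function(frame) {
  if (frame[1L] != 0L)
    stop("frame indices must start at 0 (got ", frame[1L], ")", call. = FALSE)
  d <- diff(frame)
  bad <- which(d != 1L)
  if (length(bad)) {
    i <- bad[1L]
    if (d[i] > 1L)
      stop("missing frame ", frame[i] + 1L, call. = FALSE)
    stop("duplicated or out-of-order frame ", frame[i + 1L], call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.fly_trajectory <- function(x, ...) {
  dur <- (x$n_frames - 1L) / x$calibration$frame_rate
  cat(sprintf("Fly trajectory: %d frames (%.1f s at %.2f frames/s), units mm (from %s)\n",
              x$n_frames, dur, x$calibration$frame_rate, x$source_units))
  cat(sprintf("  x range [%.2f, %.2f] mm, y range [%.2f, %.2f] mm\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' @export
as.data.frame.fly_trajectory <- function(x, ...) {
  data.frame(frame = x$frame, x = x$x, y = x$y, orientation = x$orientation)
}

#' Plot a fly trajectory path
#'
#' @param x a \code{fly_trajectory}.
#' @param ... further arguments passed to \code{plot}.
#' @export
plot.fly_trajectory <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "l", asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)", ...)
  graphics::points(x$x[1L], x$y[1L], pch = 16, col = "forestgreen")
  graphics::points(x$x[x$n_frames], x$y[x$n_frames], pch = 4, col = "firebrick")
  invisible(x)
}

#' Read a tracked trajectory from delimited text
#'
#' Reads a per-frame trajectory in the documented CSV layout (header
#' \code{frame,x,y,orientation}, rows sorted by frame) as produced by
#' exporting Ctrax-style tracking output, validates it, and returns a
#' \code{\link{fly_trajectory}} in mm. Missing or duplicated frames and
#' non-numeric cells are hard errors naming the offending frame or row;
#' data are never silently repaired.
#'
#' @param path path to a CSV file.
#' @param calibration an \code{\link{arena_calibration}}; when
#'   \code{units = "px"}, positions are divided by
#'   \code{calibration$pixels_per_mm} on load.
#' @param units units of the x/y columns in the file, "mm" (default) or "px".
#' @return a validated \code{fly_trajectory} (positions in mm).
#' @seealso \code{\link{write_trajectory}}
#' @export
read_trajectory <- function(path, calibration = arena_calibration(),
                            units = c("mm", "px")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  needed <- c("frame", "x", "y", "orientation")
  if (!all(needed %in% names(raw)))
    stop("header must declare columns frame,x,y,orientation; found: ",
         paste(names(raw), collapse = ","), call. = FALSE)
  if (nrow(raw) < 2L)
    stop("a trajectory needs at least 2 frames", call. = FALSE)
  num <- lapply(needed, function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data row ", bad[1L],
           ": '", raw[[col]][bad[1L]], "'", call. = FALSE)
    v
  })
  names(num) <- needed
  if (units == "px") {
    num$x <- num$x / calibration$pixels_per_mm
    num$y <- num$y / calibration$pixels_per_mm
  }
  fly_trajectory(frame = num$frame, x = num$x, y = num$y,
                 orientation = num$orientation,
                 calibration = calibration, source_units = units)
}

#' Write a trajectory to delimited text
#'
#' Writes the canonical CSV layout (\code{frame,x,y,orientation}, positions
#' in mm, orientation wrapped to [-180, 180), 6 decimal places) so that
#' \code{read_trajectory(write_trajectory(tr))} reproduces \code{tr} to
#' within 1e-6 on every field.
#'
#' @param traj a \code{\link{fly_trajectory}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (!inherits(traj, "fly_trajectory"))
    stop("traj must be a fly_trajectory", call. = FALSE)
  df <- data.frame(frame = traj$frame,
                   x = sprintf("%.6f", traj$x),
                   y = sprintf("%.6f", traj$y),
                   orientation = sprintf("%.6f", wrap_degrees(traj$orientation)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run-parameter configuration file
#'
#' Reads a YAML configuration holding the calibration and analysis
#' parameters shared across the pipeline. Recognised keys:
#' \code{pixels_per_mm}, \code{frame_rate}, \code{window_s},
#' \code{threshold_c}, \code{freeze_epsilon_mm}; unknown keys are kept
#' verbatim. Missing keys fall back to package defaults.
#'
#' @param path path to a YAML file.
#' @return a list with elements \code{calibration}
#'   (\code{\link{arena_calibration}}), \code{aim}
#'   (\code{\link{aim_params}}), \code{freeze_epsilon_mm}, and \code{extra}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  get <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  cal <- arena_calibration(pixels_per_mm = get("pixels_per_mm", 1),
                           frame_rate = get("frame_rate", 30.06))
  aim <- aim_params(window_s = get("window_s", 21L),
                    threshold_c = get("threshold_c", 0.4))
  eps <- get("freeze_epsilon_mm", 0.05)
  if (!is.numeric(eps) || eps < 0)
    stop("freeze_epsilon_mm must be a non-negative number", call. = FALSE)
  known <- c("pixels_per_mm", "frame_rate", "window_s", "threshold_c",
             "freeze_epsilon_mm")
  list(calibration = cal, aim = aim, freeze_epsilon_mm = eps,
       extra = cfg[setdiff(names(cfg), known)])
}
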