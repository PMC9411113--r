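#' Per-step kinematics of a trajectory
#'
#' Differences a trajectory into its per-frame-step kinematic series: the
#' displacement d_i between consecutive centroid positions (mm), the
#' instantaneous speed v_i = d_i * frame_rate (mm/s), and the signed yaw
#' (change in body heading, degrees wrapped to [-180, 180)). A trajectory of
#' n frames yields n - 1 steps.
#'
#' @param traj a \code{\link{fly_trajectory}}.
#' @return an object of class \code{kinematic_series} with elements
#'   \code{displacement_mm}, \code{speed_mm_s}, \code{yaw_deg},
#'   \code{n_steps}, \code{frame_rate}.
#' @examples
#' tr <- fly_trajectory(0:2, c(0, 3, 3), c(0, 4, 4), c(0, 90, 90))
#' kinematic_series(tr)$displacement_mm  # 5 then 0
#' @export
kinematic_series <- function(traj) {
  if (!inherits(traj, "fly_trajectory"))
    stop("traj must be a fly_trajectory", call. = FALSE)
  if (traj$n_frames < 2L)
    stop("need at least 2 frames to form kinematic steps", call. = FALSE)
  d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  fr <- traj$calibration$frame_rate
  yaw <- angle_diff(traj$orientation[-traj$n_frames], traj$orientation[-1L])
  structure(list(displacement_mm = d,
                 speed_mm_s = d * fr,
                 yaw_deg = yaw,
                 n_steps = traj$n_frames - 1L,
                 frame_rate = fr),
            class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("Kinematic series: %d steps at %.2f frames/s\n", x$n_steps,
              x$frame_rate))
  cat(sprintf("  mean speed %.3f mm/s, mean |yaw| %.2f deg/frame\n",
              mean(x$speed_mm_s), mean(abs(x$yaw_deg))))
  invisible(x)
}

#' Displacement series of a trajectory
#'
#' Convenience accessor for the per-step Euclidean displacement (mm).
#'
#' @param traj a \code{\link{fly_trajectory}}.
#' @return numeric vector of length \code{n_frames - 1}.
#' @export
displacement_series <- function(traj) {
  kinematic_series(traj)$displacement_mm
}

#' Yaw series of a trajectory
#'
#' Convenience accessor for the per-step signed heading change (degrees,
#' wrapped to [-180, 180)).
#'
#' @param traj a \code{\link{fly_trajectory}}.
#' @return numeric vector of length \code{n_frames - 1}.
#' @export
yaw_series <- function(traj) {
  kinematic_series(traj)$yaw_deg
}

.as_kinematics <- function(x) {
  if (inherits(x, "fly_trajectory")) return(kinematic_series(x))
  if (inherits(x, "kinematic_series")) return(x)
  stop("expected a fly_trajectory or kinematic_series", call. = FALSE)
}

#' Mean locomotor speed
#'
#' Mean of the per-step instantaneous speed, in mm/s. Reporting per second
#' (displacement per frame times frame rate) makes the value frame-rate
#' independent.
#'
#' @param x a \code{\link{kinematic_series}} or \code{fly_trajectory}.
#' @return scalar mean speed in mm/s.
#' @export
mean_speed <- function(x) {
  k <- .as_kinematics(x)
  if (k$n_steps < 1L) stop("empty kinematic series", call. = FALSE)
  mean(k$speed_mm_s)
}

#' Yawing metric
#'
#' Aggregate turning measure: by default the mean absolute per-step heading
#' change in degrees per frame. The per-step sum and a per-second rate are
#' available as alternative aggregations.
#'
#' @param x a \code{\link{kinematic_series}} or \code{fly_trajectory}.
#' @param aggregate "mean" (deg/frame, default), "sum" (deg), or
#'   "rate" (deg/s).
#' @return scalar yawing value.
#' @export
yawing_metric <- function(x, aggregate = c("mean", "sum", "rate")) {
  aggregate <- match.arg(aggregate)
  k <- .as_kinematics(x)
  if (k$n_steps < 1L) stop("empty kinematic series", call. = FALSE)
  a <- abs(k$yaw_deg)
  switch(aggregate,
         mean = mean(a),
         sum = sum(a),
         rate = mean(a) * k$frame_rate)
}

#' Freezing fraction
#'
#' Fraction of frame steps with (near-)zero displacement: displacement
#' less than or equal to \code{epsilon_mm}. With \code{epsilon_mm = 0} this
#' is the literal fraction of steps with d = 0; the default 0.05 mm
#' tolerates centroid jitter in real tracking output, where positions never
#' repeat exactly.
#'
#' @param x a \code{\link{kinematic_series}} or \code{fly_trajectory}.
#' @param epsilon_mm non-negative displacement tolerance in mm.
#' @return scalar in [0, 1].
#' @export
freezing_fraction <- function(x, epsilon_mm = 0.05) {
  if (!is.numeric(epsilon_mm) || length(epsilon_mm) != 1L ||
      !is.finite(epsilon_mm) || epsilon_mm < 0)
    stop("epsilon_mm must be a non-negative number", call. = FALSE)
  k <- .as_kinematics(x)
  if (k$n_steps < 1L) stop("empty kinematic series", call. = FALSE)
  mean(k$displacement_mm <= epsilon_mm)
}
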