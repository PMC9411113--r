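#' AIM scoring parameters
#'
#' Parameters of the abnormal involuntary movement (AIM) score: the sliding
#' window width \code{window_s} (odd number of frames, default 21, i.e. 10
#' frames either side of the scored frame), the log10-ratio threshold
#' \code{threshold_c} (default 0.4), and a zero-speed guard
#' \code{epsilon_speed} below which a frame's instantaneous or window-mean
#' speed is treated as stationary and the frame excluded from scoring (the
#' log ratio is undefined at zero; stationary frames are already captured by
#' the freezing fraction).
#'
#' Only odd windows are accepted: a centred window of s frames spans
#' (s-1)/2 frames before and after the scored frame, so the two half-window
#' sums cover exactly s frames only when s is odd.
#'
#' @param window_s odd integer >= 3; sliding-window width in frames.
#' @param threshold_c positive scalar; threshold on |log10(v_i/v_s)|.
#' @param epsilon_speed non-negative scalar (mm/s); zero-speed guard.
#' @param n_frames_expected integer; expected recording length in frames
#'   (default 9018, a 5-minute recording at 30.06 frames/s), used only for
#'   diagnostics.
#' @return an object of class \code{aim_params}.
#' @export
aim_params <- function(window_s = 21L, threshold_c = 0.4,
                       epsilon_speed = 1e-9, n_frames_expected = 9018L) {
  window_s <- as.integer(window_s)
  stopifnot(length(window_s) == 1L, length(threshold_c) == 1L,
            is.numeric(threshold_c), is.finite(threshold_c),
            length(epsilon_speed) == 1L, is.numeric(epsilon_speed))
  if (is.na(window_s) || window_s < 3L || window_s %% 2L == 0L)
    stop("window_s must be an odd integer >= 3", call. = FALSE)
  if (threshold_c <= 0) stop("threshold_c must be > 0", call. = FALSE)
  if (!is.finite(epsilon_speed) || epsilon_speed < 0)
    stop("epsilon_speed must be non-negative", call. = FALSE)
  structure(list(window_s = window_s,
                 threshold_c = as.numeric(threshold_c),
                 epsilon_speed = as.numeric(epsilon_speed),
                 n_frames_expected = as.integer(n_frames_expected)),
            class = "aim_params")
}

#' @export
print.aim_params <- function(x, ...) {
  cat(sprintf("AIM parameters: window %d frames, threshold c = %g, zero-speed guard %g mm/s\n",
              x$window_s, x$threshold_c, x$epsilon_speed))
  invisible(x)
}

#' Sliding-window mean speed
#'
#' For every frame step i with a full centred window, the mean v_s of the
#' instantaneous speeds over the \code{window_s} steps
#' i - (s-1)/2, ..., i, ..., i + (s-1)/2. Edge steps lacking a full window
#' are unscored (NA): windows never shrink, so scores are comparable across
#' equal-length recordings.
#'
#' @param x a \code{\link{kinematic_series}} or \code{fly_trajectory}.
#' @param params an \code{\link{aim_params}}.
#' @return numeric vector of length \code{n_steps}; NA where no full window
#'   exists.
#' @export
sliding_mean_speed <- function(x, params = aim_params()) {
  k <- .as_kinematics(x)
  s <- params$window_s
  v <- k$speed_mm_s
  n <- length(v)
  if (n < s)
    stop("series has ", n, " steps; need at least window_s = ", s,
         call. = FALSE)
  half <- (s - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  vs <- rep(NA_real_, n)
  idx <- (half + 1L):(n - half)
  vs[idx] <- (cs[idx + half + 1L] - cs[idx - half]) / s
  vs
}

#' AIM score of a recording
#'
#' Counts the frames whose instantaneous speed deviates from the local mean
#' speed beyond a log-ratio threshold: the raw AIM score H is the number of
#' scorable frame steps with |log10(v_i / v_s)| > c, where v_s is the
#' centred sliding-window mean speed (\code{\link{sliding_mean_speed}}).
#' The ratio v_i/v_s makes H invariant under uniform speed scaling. With
#' \code{mode = "signed"} only accelerations (log10(v_i/v_s) > c) score, a
#' sensitivity-analysis variant; the default scores both abrupt
#' accelerations and decelerations.
#'
#' Steps without a full window are unscored. Steps where v_i or v_s falls
#' at or below \code{params$epsilon_speed} are skipped (the log ratio is
#' undefined); they are reported in \code{skipped_frame_count}. If every
#' windowed step is skipped the result carries \code{all_skipped = TRUE},
#' a warning is raised, and H is 0.
#'
#' @param x a \code{\link{kinematic_series}} or \code{fly_trajectory}.
#' @param params an \code{\link{aim_params}}.
#' @param mode "absolute" (default) or "signed".
#' @return an object of class \code{aim_result}: \code{raw_H},
#'   \code{qualifying_frames} (1-based step indices), \code{log_ratio}
#'   (per step, NA where unscored or skipped), \code{window_mean_speed},
#'   \code{scored_frame_count}, \code{skipped_frame_count},
#'   \code{all_skipped}, \code{params}, \code{mode}.
#' @examples
#' v <- rep(1, 200); v[c(30, 50, 70, 90, 110, 130, 150)] <- 10
#' k <- structure(list(displacement_mm = v / 30.06, speed_mm_s = v,
#'                     yaw_deg = rep(0, 200), n_steps = 200L,
#'                     frame_rate = 30.06), class = "kinematic_series")
#' aim_score(k)$raw_H  # 7
#' @export
aim_score <- function(x, params = aim_params(),
                      mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  k <- .as_kinematics(x)
  vs <- sliding_mean_speed(k, params)
  v <- k$speed_mm_s
  windowed <- !is.na(vs)
  eps <- params$epsilon_speed
  skipped <- windowed & (v <= eps | vs <= eps)
  scorable <- windowed & !skipped
  log_ratio <- rep(NA_real_, length(v))
  log_ratio[scorable] <- log10(v[scorable] / vs[scorable])
  stat <- if (mode == "absolute") abs(log_ratio) else log_ratio
  qualifies <- which(scorable & stat > params$threshold_c)
  all_skipped <- sum(windowed) > 0L && sum(scorable) == 0L
  if (all_skipped)
    warning("all windowed frames were skipped by the zero-speed guard; AIM score is 0",
            call. = FALSE)
  structure(list(raw_H = length(qualifies),
                 qualifying_frames = qualifies,
                 log_ratio = log_ratio,
                 window_mean_speed = vs,
                 scored_frame_count = sum(scorable),
                 skipped_frame_count = sum(skipped),
                 all_skipped = all_skipped,
                 params = params,
                 mode = mode),
            class = "aim_result")
}

#' @export
print.aim_result <- function(x, ...) {
  cat(sprintf("AIM score: H = %d over %d scored frames (%d skipped by zero-speed guard)\n",
              x$raw_H, x$scored_frame_count, x$skipped_frame_count))
  cat(sprintf("  window %d frames, c = %g, %s log ratio\n",
              x$params$window_s, x$params$threshold_c, x$mode))
  if (x$all_skipped) cat("  NOTE: all frames skipped (stationary recording)\n")
  invisible(x)
}

#' Normalize AIM scores against a control cohort
#'
#' Subtracts the mean raw AIM score of the designated control flies, so that
#' the mean normalized control score is exactly 0. The baseline is always
#' the control group measured within the same experiment/batch, never a
#' global constant.
#'
#' @param raw_scores numeric vector of raw AIM scores to normalize.
#' @param control_raw_scores numeric vector of raw AIM scores of control
#'   flies (length >= 1).
#' @return numeric vector: \code{raw_scores - mean(control_raw_scores)}.
#' @export
normalize_aim <- function(raw_scores, control_raw_scores) {
  if (length(control_raw_scores) < 1L)
    stop("need at least one control fly to set the baseline", call. = FALSE)
  if (!is.numeric(raw_scores) || !is.numeric(control_raw_scores))
    stop("AIM scores must be numeric", call. = FALSE)
  raw_scores - mean(control_raw_scores)
}

#' Peak speed deviation
#'
#' The maximal percent deviation of instantaneous speed from the local mean
#' speed: max over scorable frames of (v_i - v_s) / v_s * 100. A constant
#' speed gives 0%; a frame moving at twice the local mean gives 100%.
#'
#' @param x a \code{\link{kinematic_series}} or \code{fly_trajectory}.
#' @param params an \code{\link{aim_params}}.
#' @return scalar percent deviation.
#' @export
peak_deviation <- function(x, params = aim_params()) {
  k <- .as_kinematics(x)
  vs <- sliding_mean_speed(k, params)
  ok <- !is.na(vs) & vs > params$epsilon_speed
  if (!any(ok))
    stop("no scored frames: window-mean speed never exceeds the zero-speed guard",
         call. = FALSE)
  max((k$speed_mm_s[ok] - vs[ok]) / vs[ok]) * 100
}

#' Derive an AIM threshold from a control cohort
#'
#' Convenience helper for choosing a threshold c from wild-type control
#' recordings: pools |log10(v_i/v_s)| over all scorable frames of the
#' control series and returns an upper quantile (default 0.999, i.e. about
#' 9 qualifying frames per 9018-frame control recording before
#' normalization). This is one documented convention, not a recapitulation
#' of any previously published calibration; the packaged default c = 0.4
#' is independent of this helper.
#'
#' @param control_series list of \code{\link{kinematic_series}} or
#'   \code{fly_trajectory} objects from control flies.
#' @param params an \code{\link{aim_params}} (window and guard are used).
#' @param probability quantile of the pooled |log10(v_i/v_s)| distribution.
#' @return scalar threshold.
#' @export
threshold_from_controls <- function(control_series, params = aim_params(),
                                    probability = 0.999) {
  if (!is.list(control_series) || length(control_series) < 1L)
    stop("control_series must be a non-empty list", call. = FALSE)
  pooled <- unlist(lapply(control_series, function(s) {
    r <- aim_score(s, params)
    abs(r$log_ratio[!is.na(r$log_ratio)])
  }))
  if (!length(pooled)) stop("no scorable control frames", call. = FALSE)
  as.numeric(stats::quantile(pooled, probability, names = FALSE))
}
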