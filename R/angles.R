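#' Wrap angles in degrees to [-180, 180)
#'
#' One wrap convention is used throughout the package: headings and angular
#' differences are degrees in the half-open interval \code{[-180, 180)}.
#'
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped to \code{[-180, 180)}.
#' @examples
#' wrap_degrees(c(-190, 170, 360, 180))
#' @export
wrap_degrees <- function(deg) {
  if (!is.numeric(deg)) stop("angles must be numeric", call. = FALSE)
  ((deg + 180) %% 360) - 180
}

#' Signed angular difference in degrees
#'
#' Difference `to - from` wrapped to [-180, 180), so a heading change from
#' 350 to 10 degrees is +20, not -340.
#'
#' @param from,to numeric vectors of angles in degrees.
#' @return signed differences in degrees, in [-180, 180).
#' @export
angle_diff <- function(from, to) {
  wrap_degrees(to - from)
}
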