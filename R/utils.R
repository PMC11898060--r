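# Internal numeric helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap values into a half-open interval
#'
#' @param x numeric vector.
#' @param min,max interval bounds; `max - min` is the period.
#' @return values wrapped into `[min, max)`.
#' @keywords internal
wrap_period <- function(x, min = 0, max = 2 * pi) {
  min + (x - min) %% (max - min)
}

# Minimum-image difference a - b on a periodic interval of width `period`.
min_image <- function(a, b, period) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

# Great-circle distance (radians) between points on the unit sphere given as
# polar angle theta in [0, pi] and azimuth phi (both radians).
great_circle <- function(theta1, phi1, theta2, phi2) {
  c_ang <- cos(theta1) * cos(theta2) + sin(theta1) * sin(theta2) * cos(phi1 - phi2)
  acos(pmin(1, pmax(-1, c_ang)))
}

# Column presence check with a uniform error message.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
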