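#' ERB-number (Cam) cochlear frequency scale
#'
#' Constructor for the quasilogarithmic cochlear frequency scale on which all
#' tuning computations in this package operate. Positions on the scale are
#' expressed in Cam units (ERB-numbers): one Cam step corresponds to one
#' normal cochlear filter bandwidth (ERB_N). The scale is
#' `E(f) = a * log10(b * f + 1)` with the standard constants `a = 21.4`,
#' `b = 0.00437` (f in Hz), and the filter bandwidth at centre frequency `f`
#' is `ERB_N(f) = erb_k1 * (erb_k2 * f / 1000 + 1)`.
#'
#' @param a Dimensionless scale constant (default 21.4).
#' @param b Per-Hz constant (default 0.00437).
#' @param erb_k1 Bandwidth constant in Hz (default 24.7).
#' @param erb_k2 Bandwidth constant per kHz (default 4.37).
#' @return An object of class `cochlear_scale`.
#' @examples
#' sc <- cochlear_scale()
#' hz_to_cam(1000, sc)      # ~15.62 Cam
#' erb_hz(1000, sc)         # ~132.6 Hz
#' @export
cochlear_scale <- function(a = 21.4, b = 0.00437, erb_k1 = 24.7, erb_k2 = 4.37) {
  stopifnot(a > 0, b > 0, erb_k1 > 0, erb_k2 > 0)
  structure(list(a = a, b = b, erb_k1 = erb_k1, erb_k2 = erb_k2),
            class = "cochlear_scale")
}

#' @export
print.cochlear_scale <- function(x, ...) {
  cat(sprintf("ERB-number scale: E(f) = %g*log10(%g*f + 1); ERB_N(f) = %g*(%g*f/1000 + 1)\n",
              x$a, x$b, x$erb_k1, x$erb_k2))
  invisible(x)
}

#' Convert frequency in Hz to cochlear-scale position (Cam)
#'
#' @param f Frequencies in Hz (vector, all `>= 0`).
#' @param scale A [cochlear_scale()] object.
#' @return Positions in Cam units; strictly increasing in `f`, 0 at `f = 0`.
#' @export
hz_to_cam <- function(f, scale = cochlear_scale()) {
  if (any(f < 0, na.rm = TRUE)) stop("hz_to_cam: frequencies must be non-negative")
  scale$a * log10(scale$b * f + 1)
}

#' Convert cochlear-scale position (Cam) to frequency in Hz
#'
#' Exact inverse of [hz_to_cam()] within floating-point tolerance.
#'
#' @param cam Positions in Cam units (vector, all `>= 0`).
#' @inheritParams hz_to_cam
#' @return Frequencies in Hz.
#' @export
cam_to_hz <- function(cam, scale = cochlear_scale()) {
  if (any(cam < 0, na.rm = TRUE)) stop("cam_to_hz: Cam values must be non-negative")
  (10^(cam / scale$a) - 1) / scale$b
}

#' Equivalent rectangular bandwidth (ERB_N) at a centre frequency
#'
#' @inheritParams hz_to_cam
#' @return Bandwidths in Hz; positive and strictly increasing in `f`.
#' @export
erb_hz <- function(f, scale = cochlear_scale()) {
  if (any(f < 0, na.rm = TRUE)) stop("erb_hz: frequencies must be non-negative")
  scale$erb_k1 * (scale$erb_k2 * f / 1000 + 1)
}

#' Frequencies evenly spaced on the cochlear (ERB-number) scale
#'
#' Returns `n` frequencies between `f_min` and `f_max` (inclusive) whose Cam
#' positions are equally spaced. With the defaults of the stimulation
#' protocol (251 to 6009 Hz, n = 7) the interior values round to
#' 507, 899, 1501, 2424 and 3839 Hz.
#'
#' @param f_min,f_max Range endpoints in Hz, `0 <= f_min < f_max`.
#' @param n Number of frequencies, `>= 2`.
#' @param round_hz Round the returned values to the nearest Hz (presentation
#'   convention; internal computations never round). Default `FALSE`.
#' @inheritParams hz_to_cam
#' @return Numeric vector of `n` frequencies in Hz.
#' @export
spaced_frequencies <- function(f_min, f_max, n, scale = cochlear_scale(),
                               round_hz = FALSE) {
  if (n < 2) stop("spaced_frequencies: n must be at least 2")
  if (!(f_min >= 0 && f_min < f_max)) stop("spaced_frequencies: need 0 <= f_min < f_max")
  cams <- seq(hz_to_cam(f_min, scale), hz_to_cam(f_max, scale), length.out = n)
  f <- cam_to_hz(cams, scale)
  f[1] <- f_min
  f[n] <- f_max
  if (round_hz) round(f) else f
}

#' Default stimulus frequencies of the tonotopy protocol
#'
#' Seven narrowband-noise centre frequencies between 251 and 6009 Hz, evenly
#' spaced on the ERB-number scale.
#'
#' @inheritParams hz_to_cam
#' @param round_hz Round to nearest Hz (default `TRUE`, the presented values).
#' @return Numeric vector of 7 frequencies in Hz.
#' @export
default_stim_frequencies <- function(scale = cochlear_scale(), round_hz = TRUE) {
  spaced_frequencies(251, 6009, 7, scale = scale, round_hz = round_hz)
}
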