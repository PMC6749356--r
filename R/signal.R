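#' Low-pass elliptic filter specification
#'
#' Specification of the low-pass elliptic (Cauer) design used to split raw
#' acceleration into gravity and linear acceleration. Gravity is quasi-DC, so
#' the default cutoff sits at the low end of the admissible 0.3-20 Hz range.
#' With `zero_phase = TRUE` the filter is applied forward and backward
#' (no group delay); the effective magnitude response is then the square of
#' the designed response.
#'
#' @param order filter order (default 3).
#' @param cutoff_hz cutoff frequency in Hz, within `[0.3, 20]`.
#' @param ripple_db passband ripple in dB.
#' @param stopband_db stopband attenuation in dB.
#' @param zero_phase apply forward-backward (zero-phase) filtering.
#' @return A `har_filter_spec` list.
#' @export
filter_spec <- function(order = 3, cutoff_hz = 0.3, ripple_db = 0.01,
                        stopband_db = 60, zero_phase = TRUE) {
  if (order < 1) abort("filter order must be >= 1", class = "har_config_error")
  if (cutoff_hz < 0.3 || cutoff_hz > 20) {
    abort("cutoff_hz must lie in [0.3, 20] Hz", class = "har_config_error")
  }
  if (ripple_db <= 0 || stopband_db <= 0) {
    abort("ripple_db and stopband_db must be positive",
          class = "har_config_error")
  }
  structure(list(order = order, cutoff_hz = cutoff_hz, ripple_db = ripple_db,
                 stopband_db = stopband_db, zero_phase = isTRUE(zero_phase)),
            class = "har_filter_spec")
}

design_lpef <- function(spec, rate) {
  signal::ellip(spec$order, spec$ripple_db, spec$stopband_db,
                spec$cutoff_hz / (rate / 2))
}

# forward-backward (zero-phase) IIR application with odd-reflection padding
# and steady-state initial conditions, so a constant input passes exactly
# and edge transients stay local
zero_phase_apply <- function(b, a, x, pad = 150) {
  n <- length(x)
  lp <- min(pad, n - 1)
  k <- max(length(a), length(b)) - 1
  xext <- c(2 * x[1] - x[(lp + 1):2], x, 2 * x[n] - x[(n - 1):(n - lp)])
  dcg <- sum(b) / sum(a)
  one_pass <- function(s) {
    as.numeric(signal::filter(b, a, s,
                              init.x = rep(s[1], k),
                              init.y = rep(s[1] * dcg, k)))
  }
  y <- rev(one_pass(rev(one_pass(xext))))
  y[(lp + 1):(lp + n)]
}

#' Split raw acceleration into gravity and linear acceleration
#'
#' Applies the low-pass elliptic filter to each acceleration axis; the
#' low-pass output is the gravity estimate and the residual
#' `acc - gravity` is the linear acceleration, so the two components always
#' recompose to the input exactly.
#'
#' @param acc data frame or matrix with 3 acceleration columns (m/s^2).
#' @param spec a [filter_spec()].
#' @param rate sampling frequency in Hz.
#' @return List with tibbles `gravity` and `linear`, same column names as
#'   the input.
#' @export
gravity_split <- function(acc, spec = filter_spec(), rate) {
  x <- as.matrix(acc)
  if (ncol(x) != 3) abort("acc must have exactly 3 columns")
  if (nrow(x) <= 3 * spec$order) {
    abort(sprintf(
      "series too short for zero-phase filtering: need > %d samples",
      3 * spec$order), class = "har_length_error")
  }
  if (spec$cutoff_hz >= rate / 2) {
    abort("cutoff frequency must be below the Nyquist frequency",
          class = "har_config_error")
  }
  flt <- design_lpef(spec, rate)
  gravity <- apply(x, 2, function(col) {
    if (spec$zero_phase) zero_phase_apply(flt$b, flt$a, col)
    else as.numeric(signal::filter(flt, col))
  })
  nm <- colnames(x) %||% c("x", "y", "z")
  colnames(gravity) <- nm
  linear <- x - gravity
  list(gravity = as_tibble(gravity),
       linear = as_tibble(as.data.frame(linear)))
}

#' Elementwise absolute acceleration
#'
#' @param acc data frame or matrix of acceleration channels.
#' @return Tibble of `|acc|`, same shape and names.
#' @export
abs_acceleration <- function(acc) {
  x <- as.matrix(acc)
  out <- abs(x)
  colnames(out) <- colnames(x) %||% paste0("a", seq_len(ncol(x)))
  as_tibble(as.data.frame(out))
}

#' Sum of the three angular-velocity channels
#'
#' @param gyro data frame or matrix with 3 gyroscope columns (rad/s).
#' @return Numeric vector, the per-sample sum.
#' @export
gyro_sum <- function(gyro) {
  x <- as.matrix(gyro)
  if (ncol(x) != 3) abort("gyro must have exactly 3 columns")
  as.numeric(rowSums(x))
}

#' AHRS fusion configuration
#'
#' @param algorithm fusion algorithm identifier; only
#'   `"madgwick"` (gradient-descent complementary fusion) is implemented.
#' @param gain fusion gain (rad/s); the rate at which the orientation
#'   estimate is pulled toward the accelerometer/magnetometer directions.
#' @param initial_orientation unit quaternion `(w, x, y, z)`.
#' @param sample_rate sampling frequency in Hz.
#' @return A `har_ahrs_config` list.
#' @export
ahrs_config <- function(algorithm = "madgwick", gain = 0.1,
                        initial_orientation = c(1, 0, 0, 0),
                        sample_rate = 50) {
  if (!identical(algorithm, "madgwick")) {
    abort("unknown AHRS algorithm", class = "har_config_error")
  }
  if (gain <= 0) abort("gain must be positive", class = "har_config_error")
  q0 <- as.numeric(initial_orientation)
  if (length(q0) != 4 || abs(sqrt(sum(q0^2)) - 1) > 1e-6) {
    abort("initial_orientation must be a unit quaternion",
          class = "har_config_error")
  }
  structure(list(algorithm = algorithm, gain = gain,
                 initial_orientation = q0, sample_rate = sample_rate),
            class = "har_ahrs_config")
}

#' Orientation from 9-axis sensor fusion
#'
#' Estimates per-sample device orientation by integrating the gyroscope and
#' correcting the estimate toward the accelerometer gravity direction and
#' the magnetometer north direction (gradient-descent complementary fusion).
#' Magnetic declination is absorbed into yaw. Samples with a zero-norm
#' accelerometer reading skip the correction step and are reported.
#'
#' @param acc,gyro,mag data frames or matrices with 3 columns each, equal
#'   length.
#' @param cfg an [ahrs_config()].
#' @param rate sampling frequency in Hz; defaults to `cfg$sample_rate`.
#' @return Tibble with columns `roll`, `pitch`, `yaw` (radians, intrinsic
#'   Z-Y-X convention); the quaternion trajectory is attached as attribute
#'   `"quaternion"`.
#' @export
ahrs_orientation <- function(acc, gyro, mag, cfg = ahrs_config(),
                             rate = cfg$sample_rate) {
  a <- as.matrix(acc); g <- as.matrix(gyro); m <- as.matrix(mag)
  if (nrow(a) != nrow(g) || nrow(a) != nrow(m)) {
    abort("acc, gyro and mag must have equal length")
  }
  if (rate <= 0) abort("rate must be positive", class = "har_config_error")
  res <- ahrs_fuse(a, g, m, cfg$gain, 1 / rate, cfg$initial_orientation)
  if (length(res$skipped) > 0) {
    rlang::inform(sprintf(
      "AHRS: correction skipped for %d zero-norm accelerometer sample(s)",
      length(res$skipped)))
  }
  out <- as_tibble(as.data.frame(res$euler))
  names(out) <- c("roll", "pitch", "yaw")
  attr(out, "quaternion") <- res$quaternion
  attr(out, "skipped") <- res$skipped
  out
}

#' Extend a 9-channel recording to the 19-channel signal matrix
#'
#' Appends to the raw channels: linear acceleration (raw minus low-pass
#' gravity), elementwise absolute acceleration, the angular-velocity sum,
#' and the three orientation angles from the AHRS fusion — 19 channels in
#' the fixed order of [extended_channels()]. Labels (and a `subject` column,
#' if present) are carried through unchanged. The first and last second are
#' flagged as filter edge transients (attribute `edge_samples`); windows cut
#' by [segment_recording()] avoid them by default.
#'
#' @param rec a [har_recording()].
#' @param fspec a [filter_spec()].
#' @param acfg an [ahrs_config()]; its sample rate is overridden by the
#'   recording's.
#' @return A tibble of class `har_extended` with columns `t`, the 19
#'   channels, and `label`.
#' @export
extend_signals <- function(rec, fspec = filter_spec(), acfg = ahrs_config()) {
  fs <- sample_rate(rec) %||% abort("recording has no sample_rate attribute")
  acc <- rec[c("ax", "ay", "az")]
  gyr <- rec[c("gx", "gy", "gz")]
  mag <- rec[c("mx", "my", "mz")]

  gs <- gravity_split(acc, fspec, fs)
  ori <- ahrs_orientation(acc, gyr, mag, acfg, rate = fs)

  out <- tibble(t = rec$t)
  out[RAW_CHANNELS] <- rec[RAW_CHANNELS]
  out[c("lax", "lay", "laz")] <- gs$linear
  out[c("aax", "aay", "aaz")] <- abs_acceleration(acc)
  out$gsum <- gyro_sum(gyr)
  out[c("roll", "pitch", "yaw")] <- ori
  out$label <- rec$label
  if ("subject" %in% names(rec)) out$subject <- rec$subject

  structure(out,
            sample_rate = fs,
            vocabulary = vocabulary(rec),
            gravity = gs$gravity,
            edge_samples = round(fs),
            class = c("har_extended", class(tibble())))
}
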