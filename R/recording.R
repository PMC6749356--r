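#' Construct a labelled IMU recording
#'
#' A recording is a tibble with one row per sample: time `t` (seconds,
#' strictly increasing), tri-axial accelerometer `ax,ay,az` (m/s^2),
#' gyroscope `gx,gy,gz` (rad/s), magnetometer `mx,my,mz` (uT) and a
#' per-sample `label` drawn from the vocabulary. The sample rate and
#' vocabulary travel along as attributes.
#'
#' @param data data frame with columns `t`, `ax..az`, `gx..gz`, `mx..mz`,
#'   `label` (and optionally `subject`).
#' @param sample_rate sampling frequency in Hz; inferred from the median
#'   timestamp spacing when `NULL`.
#' @param vocabulary ordered character vector of admissible labels.
#' @return A tibble of class `har_recording`.
#' @export
har_recording <- function(data, sample_rate = NULL,
                          vocabulary = activity_vocabulary()) {
  data <- as_tibble(data)
  needed <- c("t", RAW_CHANNELS, "label")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0("recording is missing column(s): ",
                 paste(missing, collapse = ", ")), class = "har_schema_error")
  }
  check_vocabulary(vocabulary)
  if (is.null(sample_rate)) {
    if (nrow(data) < 2) abort("cannot infer sample_rate from < 2 samples")
    sample_rate <- 1 / median(diff(data$t))
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    abort("sample_rate must be a positive number")
  }
  validate_recording(data, sample_rate, vocabulary)
  new_recording(data, sample_rate, vocabulary)
}

new_recording <- function(data, sample_rate, vocabulary) {
  structure(as_tibble(data),
            sample_rate = sample_rate,
            vocabulary = vocabulary,
            class = c("har_recording", class(as_tibble(data))))
}

validate_recording <- function(data, sample_rate, vocabulary) {
  n <- nrow(data)
  if (n == 0) return(invisible(TRUE))
  if (n >= 2) {
    dt <- diff(data$t)
    bad <- which(dt <= 0)
    if (length(bad) > 0) {
      abort(paste0("timestamps not strictly increasing at row(s): ",
                   paste(head(bad + 1, 5), collapse = ", ")),
            class = "har_validation_error")
    }
    expected <- 1 / sample_rate
    if (any(abs(dt - expected) > 0.01 * expected)) {
      abort(sprintf(
        "timestamp spacing deviates from 1/%g s by more than 1%%", sample_rate),
        class = "har_validation_error")
    }
  }
  unknown <- setdiff(unique(data$label), vocabulary)
  if (length(unknown) > 0) {
    abort(paste0("label(s) not in vocabulary: ",
                 paste(unknown, collapse = ", ")),
          class = "har_validation_error")
  }
  invisible(TRUE)
}

#' Sampling frequency attached to a recording or segment set
#' @param x a `har_recording`, extended recording, or `har_segments` object.
#' @return Sampling frequency in Hz.
#' @export
sample_rate <- function(x) attr(x, "sample_rate")

#' Vocabulary attached to a recording or segment set
#' @param x a `har_recording`, extended recording, or `har_segments` object.
#' @return Character vector of class labels.
#' @export
vocabulary <- function(x) attr(x, "vocabulary")
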