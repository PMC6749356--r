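#' Channel presets for classifier inputs
#'
#' Four named input configurations: `acc` (raw acceleration, 3 channels),
#' `acc_gyro` (6), `acc_gyro_mag` (all raw sensors, 9), and `our`
#' (the processed 9: linear acceleration, elementwise absolute acceleration,
#' angular-velocity sum, and the pitch/yaw orientation channels).
#'
#' @return Named list of channel-name vectors.
#' @export
channel_presets <- function() {
  list(
    acc = c("ax", "ay", "az"),
    acc_gyro = c("ax", "ay", "az", "gx", "gy", "gz"),
    acc_gyro_mag = RAW_CHANNELS,
    our = c("lax", "lay", "laz", "aax", "aay", "aaz", "gsum", "pitch", "yaw")
  )
}

#' Restrict a segment set to a channel preset
#'
#' A pure projection: each output value sits at the same (channel, time)
#' position of the input, labels and segment count are unchanged.
#'
#' @param set a `har_segments` object.
#' @param selection a preset name (see [channel_presets()]) or an explicit
#'   character vector of channel names.
#' @return A `har_segments` with the selected channels, in the preset's
#'   order.
#' @export
select_channels <- function(set, selection = "our") {
  if (is.character(selection) && length(selection) == 1 &&
      selection %in% names(channel_presets())) {
    chans <- channel_presets()[[selection]]
  } else if (is.character(selection) && length(selection) >= 1) {
    chans <- selection
  } else {
    abort("selection must be a preset name or a character vector of channels",
          class = "har_config_error")
  }
  have <- channel_names(set)
  missing <- setdiff(chans, have)
  if (length(missing) > 0) {
    abort(paste0("segment set lacks channel(s): ",
                 paste(missing, collapse = ", ")),
          class = "har_config_error")
  }
  rows <- match(chans, have)
  out <- set
  out$data <- lapply(set$data, function(d) d[rows, , drop = FALSE])
  new_segment_set(as_tibble(out), channel_names = chans,
                  ld = segment_length(set), sample_rate = sample_rate(set),
                  vocabulary = vocabulary(set),
                  provenance = attr(set, "provenance"))
}
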