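#' Activity label vocabulary
#'
#' The ordered set of class labels the pipeline recognises: six static
#' postures, five dynamic exercises, and `"transfer"` for the interval while
#' the subject moves between two activities. The order is fixed and defines
#' the axis order of every confusion matrix produced by [evaluate_classifier()].
#'
#' @return A character vector of 12 unique class names.
#' @export
#' @examples
#' activity_vocabulary()
activity_vocabulary <- function() {
  c("sit", "stand", "jump", "jog", "walk", "upstairs", "downstairs",
    "lying-left", "lying-right", "lying-supine", "lying-prone", "transfer")
}

check_vocabulary <- function(vocabulary) {
  if (!is.character(vocabulary) || anyDuplicated(vocabulary) ||
      length(vocabulary) < 2) {
    abort("vocabulary must be a character vector of >= 2 unique class names")
  }
  vocabulary
}

# raw channel names in fixed CSV column order
RAW_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")

# extended channel names in fixed order:
# raw acc, raw gyro, raw mag, linear acc, |acc|, gyro sum, orientation
EXT_CHANNELS <- c(RAW_CHANNELS,
                  "lax", "lay", "laz", "aax", "aay", "aaz", "gsum",
                  "roll", "pitch", "yaw")

#' Channel names of the 19-channel extended signal
#'
#' Fixed order: raw acceleration (`ax,ay,az`), raw angular velocity
#' (`gx,gy,gz`), raw magnetic field (`mx,my,mz`), linear acceleration
#' (`lax,lay,laz`), elementwise absolute acceleration (`aax,aay,aaz`), the
#' angular-velocity sum (`gsum`) and orientation Euler angles
#' (`roll,pitch,yaw`, radians, intrinsic Z-Y-X).
#'
#' @return Character vector of length 19.
#' @export
extended_channels <- function() EXT_CHANNELS
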