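#' Read a labelled IMU recording from CSV
#'
#' The expected schema is one row per sample with columns `t` (seconds),
#' `ax,ay,az` (m/s^2 unless `acc_units = "g"`), `gx,gy,gz` (rad/s),
#' `mx,my,mz` (uT) and `label`; extra columns (e.g. `subject`) are kept.
#' Column names can be remapped through `schema`.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping canonical names
#'   (`t`, `ax`, ..., `label`) to the file's column names.
#' @param sample_rate Hz; inferred from the timestamps when `NULL`.
#' @param vocabulary admissible labels.
#' @param acc_units `"ms2"` (default) or `"g"`; g-unit acceleration is
#'   converted by the standard gravity 9.81 m/s^2.
#' @return A validated [har_recording()].
#' @export
read_recording <- function(path, schema = NULL, sample_rate = NULL,
                           vocabulary = activity_vocabulary(),
                           acc_units = c("ms2", "g")) {
  acc_units <- match.arg(acc_units)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  canonical <- c("t", RAW_CHANNELS, "label")
  schema <- schema %||% stats::setNames(canonical, canonical)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0("unparseable row(s) at line(s): ",
                 paste(unique(probs$row), collapse = ", ")),
          class = "har_format_error")
  }
  missing <- setdiff(unname(schema), names(df))
  if (length(missing) > 0) {
    abort(paste0("file is missing mapped column(s): ",
                 paste(missing, collapse = ", ")),
          class = "har_schema_error")
  }
  extra <- setdiff(names(df), unname(schema))
  out <- df[unname(schema)]
  names(out) <- names(schema)
  if (length(extra) > 0) out[extra] <- df[extra]
  if (acc_units == "g") {
    out[c("ax", "ay", "az")] <- out[c("ax", "ay", "az")] * GRAVITY
  }
  har_recording(out, sample_rate = sample_rate, vocabulary = vocabulary)
}

#' Write a recording to CSV
#'
#' Columns are written in the fixed order
#' `t,ax,ay,az,gx,gy,gz,mx,my,mz,label` (plus `subject` last, when present)
#' at full float precision, so write-then-read round-trips exactly.
#'
#' @param rec a [har_recording()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (dir.exists(path)) {
    abort(paste0("path is a directory: ", path), class = "har_io_error")
  }
  if (!dir.exists(dirname(path))) {
    abort(paste0("directory does not exist: ", dirname(path)),
          class = "har_io_error")
  }
  cols <- c("t", RAW_CHANNELS, "label")
  if ("subject" %in% names(rec)) cols <- c(cols, "subject")
  readr::write_csv(as_tibble(rec)[cols], path, progress = FALSE)
  invisible(path)
}

SEGMENT_FORMAT <- "harpipe_segments"
SEGMENT_FORMAT_VERSION <- 1L

#' Save / load a segment set
#'
#' Segments are stored in R's native serialisation with embedded metadata
#' (channel names, window length, sample rate, vocabulary, provenance) and a
#' format tag, so a round-trip is bit-identical and a corrupted or
#' inconsistent container is rejected with a format error.
#'
#' @param set a `har_segments`.
#' @param path file path (conventionally `.rds`).
#' @return `save_segments` returns the path invisibly; `load_segments`
#'   returns the `har_segments`.
#' @export
save_segments <- function(set, path) {
  if (dir.exists(path)) {
    abort(paste0("path is a directory: ", path), class = "har_io_error")
  }
  payload <- list(format = SEGMENT_FORMAT, version = SEGMENT_FORMAT_VERSION,
                  channel_names = channel_names(set),
                  ld = segment_length(set),
                  sample_rate = sample_rate(set),
                  vocabulary = vocabulary(set),
                  provenance = attr(set, "provenance"),
                  table = as_tibble(set))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_segments
#' @export
load_segments <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  payload <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("not a readable segment container: ", conditionMessage(e)),
          class = "har_format_error")
  })
  if (!is.list(payload) || !identical(payload$format, SEGMENT_FORMAT)) {
    abort("file is not a harpipe segment container",
          class = "har_format_error")
  }
  set <- new_segment_set(payload$table, payload$channel_names, payload$ld,
                         payload$sample_rate, payload$vocabulary,
                         payload$provenance)
  validate_segment_set(set)
  set
}
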