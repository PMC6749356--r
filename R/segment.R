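#' Cut a recording into fixed-length labelled windows
#'
#' Slides a window of `ld` samples over the recording at the given stride
#' (non-overlapping by default) and labels each window from its per-sample
#' labels. The `"majority"` rule takes the modal label, breaking ties by the
#' earliest-occurring label in the window; the `"purity"` rule additionally
#' drops windows whose modal label covers less than `purity` of the samples.
#' Windows are drawn from `[trim + 1, N - trim]` so that filter edge
#' transients flagged by [extend_signals()] are avoided.
#'
#' @param rec an extended recording (or any tibble whose non-`t`/`label`/
#'   `subject` columns are signal channels).
#' @param ld window length in samples (150 = 3 s at 50 Hz).
#' @param stride window start spacing in samples; defaults to `ld`.
#' @param label_rule `"majority"` or `"purity"`.
#' @param purity minimum modal-label fraction for the purity rule.
#' @param trim samples excluded at both ends; defaults to the recording's
#'   `edge_samples` attribute (0 if absent).
#' @param channels channel names to keep, in order; defaults to every signal
#'   column.
#' @return A `har_segments` tibble with columns `segment_id`, `label`,
#'   `subject`, `start` (1-based sample index) and the list-column `data` of
#'   `m x ld` channel-by-time matrices.
#' @export
segment_recording <- function(rec, ld = 150, stride = ld,
                              label_rule = c("majority", "purity"),
                              purity = 0.8, trim = NULL, channels = NULL) {
  label_rule <- match.arg(label_rule)
  if (ld < 1 || stride < 1) abort("ld and stride must be >= 1")
  channels <- channels %||% setdiff(names(rec), c("t", "label", "subject"))
  trim <- trim %||% attr(rec, "edge_samples") %||% 0L
  n <- nrow(rec)
  usable <- n - 2 * trim
  if (ld > usable) {
    abort(sprintf("window length %d exceeds usable recording length %d",
                  ld, usable), class = "har_length_error")
  }
  X <- t(as.matrix(rec[channels]))
  labels <- rec$label
  subject <- if ("subject" %in% names(rec)) rec$subject else NA_character_

  starts <- seq.int(trim + 1L, n - trim - ld + 1L, by = stride)
  keep <- logical(length(starts))
  seg_label <- character(length(starts))
  data <- vector("list", length(starts))

  for (k in seq_along(starts)) {
    s <- starts[k]
    win <- s:(s + ld - 1L)
    lab <- window_label(labels[win])
    keep[k] <- label_rule == "majority" || lab$fraction >= purity
    seg_label[k] <- lab$label
    if (keep[k]) data[[k]] <- X[, win, drop = FALSE]
  }

  idx <- which(keep)
  new_segment_set(
    tibble(segment_id = seq_along(idx),
           label = seg_label[idx],
           subject = if (length(subject) > 1) subject[starts[idx]] else subject,
           start = starts[idx],
           data = data[idx]),
    channel_names = channels,
    ld = as.integer(ld),
    sample_rate = sample_rate(rec),
    vocabulary = vocabulary(rec) %||% sort(unique(labels))
  )
}

# modal label of a window; ties broken by earliest occurrence in the window
window_label <- function(labs) {
  counts <- table(labs)
  top <- max(counts)
  cand <- names(counts)[counts == top]
  lab <- if (length(cand) == 1) cand else labs[min(match(cand, labs))]
  list(label = lab, fraction = top / length(labs))
}

new_segment_set <- function(table, channel_names, ld, sample_rate = NULL,
                            vocabulary = activity_vocabulary(),
                            provenance = list()) {
  structure(as_tibble(table),
            channel_names = channel_names,
            ld = as.integer(ld),
            sample_rate = sample_rate,
            vocabulary = vocabulary,
            provenance = provenance,
            class = c("har_segments", class(tibble())))
}

#' Channel names of a segment set
#' @param set a `har_segments` object.
#' @return Character vector of channel names (row order of the segment
#'   matrices).
#' @export
channel_names <- function(set) attr(set, "channel_names")

#' Window length of a segment set
#' @param set a `har_segments` object.
#' @return Integer window length in samples.
#' @export
segment_length <- function(set) attr(set, "ld")

validate_segment_set <- function(set) {
  m <- length(channel_names(set))
  ld <- segment_length(set)
  ok <- vapply(set$data, function(d) is.matrix(d) && nrow(d) == m &&
                 ncol(d) == ld, logical(1))
  if (!all(ok)) {
    abort("segment matrices do not match channel/window metadata",
          class = "har_format_error")
  }
  bad <- setdiff(unique(set$label), vocabulary(set))
  if (length(bad) > 0) {
    abort(paste0("segment label(s) not in vocabulary: ",
                 paste(bad, collapse = ", ")), class = "har_validation_error")
  }
  invisible(set)
}

# subset rows while keeping segment-set metadata
subset_segments <- function(set, idx) {
  new_segment_set(as_tibble(set)[idx, , drop = FALSE],
                  channel_names = channel_names(set),
                  ld = segment_length(set),
                  sample_rate = sample_rate(set),
                  vocabulary = vocabulary(set),
                  provenance = attr(set, "provenance"))
}

#' Combine segment sets (e.g., from several subjects)
#'
#' @param ... `har_segments` objects sharing channel names, window length
#'   and vocabulary.
#' @return A single `har_segments` with renumbered `segment_id`.
#' @export
bind_segment_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "har_segments")) {
    sets <- sets[[1]]
  }
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(channel_names(s), channel_names(ref)) ||
        !identical(segment_length(s), segment_length(ref))) {
      abort("segment sets have incompatible channels or window length",
            class = "har_format_error")
    }
  }
  tab <- dplyr::bind_rows(lapply(sets, as_tibble))
  tab$segment_id <- seq_len(nrow(tab))
  new_segment_set(tab, channel_names(ref), segment_length(ref),
                  sample_rate(ref), vocabulary(ref),
                  attr(ref, "provenance"))
}

#' @export
print.har_segments <- function(x, ...) {
  cat(sprintf("<har_segments: %d segments, %d channels x %d samples>\n",
              nrow(x), length(channel_names(x)), segment_length(x)))
  print(as_tibble(x), ...)
  invisible(x)
}
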