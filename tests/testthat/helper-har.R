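# Shared fixtures, all built in code.

# a minimal constant recording (device flat, z up)
make_static_recording <- function(n = 10, label = "stand", rate = 50) {
  har_recording(tibble::tibble(
    t = (seq_len(n) - 1) / rate,
    ax = 0, ay = 0, az = 9.81,
    gx = 0, gy = 0, gz = 0,
    mx = 25, my = 0, mz = -40,
    label = label
  ), sample_rate = rate)
}

# a segment set built from explicit matrices
make_segment_set <- function(mats, labels, channels = NULL, subjects = NULL,
                             vocabulary = activity_vocabulary()) {
  m <- nrow(mats[[1]])
  channels <- channels %||% paste0("ch", seq_len(m))
  harpipe:::new_segment_set(
    tibble::tibble(
      segment_id = seq_along(mats),
      label = labels,
      subject = subjects %||% NA_character_,
      start = seq_along(mats),
      data = mats),
    channel_names = channels, ld = ncol(mats[[1]]),
    sample_rate = 50, vocabulary = vocabulary)
}

`%||%` <- rlang::`%||%`

# a quick 4-activity protocol for pipeline-level tests
test_protocol <- function(bout = 12, transition = 2) {
  har_protocol(bouts = tibble::tibble(
    activity = rep(c("stand", "walk", "lying-left", "jog"), 2),
    duration = bout), transition_duration = transition)
}

# a small, well-separated 4-class segment set for classifier tests
make_easy_set <- function(n_per_class = 12, ld = 30, seed = 20,
                          noise = 0) {
  set.seed(seed)
  protos <- list(
    sit = function(t) outer(1:9 / 9, rep(1, length(t))),
    walk = function(t) outer(1:9 / 9, sin(2 * pi * 2 * t)),
    jog = function(t) outer(9:1 / 9, sin(2 * pi * 5 * t)),
    stand = function(t) matrix(0, 9, length(t))
  )
  t <- (0:(ld - 1)) / 50
  mats <- list(); labels <- character(0)
  for (cls in names(protos)) {
    for (i in seq_len(n_per_class)) {
      mats[[length(mats) + 1]] <- protos[[cls]](t) +
        matrix(rnorm(9 * ld, 0, noise), 9, ld)
      labels <- c(labels, cls)
    }
  }
  ord <- sample(length(mats))
  make_segment_set(mats[ord], labels[ord])
}

# independent brute-force oracle for the greedy compression rule:
# plain loops and scalar cosines, no shared code with the implementation
brute_force_retained <- function(mats, labels, rho, zeta) {
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  keep <- logical(length(mats))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    L <- length(idx)
    cap <- L - ceiling(zeta * L)
    retained <- integer(0)
    removed <- 0L
    for (j in idx) {
      is_dup <- FALSE
      if (removed < cap) {
        for (i in retained) {
          v1 <- as.vector(t(mats[[i]])); v2 <- as.vector(t(mats[[j]]))
          if (cosine(v1, v2) >= rho) { is_dup <- TRUE; break }
        }
      }
      if (is_dup) removed <- removed + 1L else retained <- c(retained, j)
    }
    keep[retained] <- TRUE
  }
  which(keep)
}
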