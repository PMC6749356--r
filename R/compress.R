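#' Cosine similarity of two flattened segments
#'
#' `rho = <a, b> / (||a|| ||b||)`, the cosine of the angle between two
#' non-zero vectors; near 1 for near-duplicate segments.
#'
#' @param a,b numeric vectors of equal length with non-zero norm.
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1))  # 1/sqrt(2)
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) abort("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    abort("cosine similarity is undefined for zero-norm vectors",
          class = "har_zero_norm_error")
  }
  sum(a * b) / (na * nb)
}

# flatten a channels x time matrix row-major (channel blocks concatenated)
flatten_segment <- function(m) as.vector(t(m))

#' Prune near-duplicate same-label segments
#'
#' Within each label class, a single greedy pass in original order drops a
#' segment when its cosine similarity to any already-retained segment of the
#' same class reaches the threshold. The compression degree `zeta` caps the
#' removal: at least `ceiling(zeta * L)` of the `L` class members are always
#' retained, so with mutually near-identical segments and `zeta = 0.5`
#' exactly 50% are removed. The similarity rule alone never forces
#' dissimilar deletions; with `force_zeta = TRUE` the least-distinct retained
#' segments (highest similarity to the rest) are additionally dropped until
#' the `ceiling(zeta * L)` target is met exactly. Classes are never emptied
#' and cross-label pairs are never compared.
#'
#' @param set a `har_segments` object.
#' @param rho_threshold cosine-similarity cutoff (default 0.99).
#' @param zeta compression degree in `(0, 1]`: target retained fraction per
#'   class.
#' @param force_zeta drop least-distinct segments to hit the target exactly.
#' @param direction `">="` treats similarities at or above the threshold as
#'   duplicates (the default); `"<="` inverts the comparison.
#' @return List of class `har_compression` with elements `segments` (the
#'   pruned `har_segments`) and `report` (per-class before/after tibble).
#' @export
compress_segments <- function(set, rho_threshold = 0.99, zeta = 1,
                              force_zeta = FALSE,
                              direction = c(">=", "<=")) {
  direction <- match.arg(direction)
  if (!is.numeric(zeta) || zeta <= 0 || zeta > 1) {
    abort("zeta must lie in (0, 1]", class = "har_config_error")
  }
  if (rho_threshold < -1 || rho_threshold > 1) {
    abort("rho_threshold must lie in [-1, 1]", class = "har_config_error")
  }
  if (nrow(set) == 0) abort("segment set is empty")

  labels <- set$label
  keep <- logical(nrow(set))
  forced <- integer(0)
  rep_rows <- list()

  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    L <- length(idx)
    target <- ceiling(zeta * L)
    cap <- L - target

    V <- vapply(set$data[idx], flatten_segment,
                numeric(length(flatten_segment(set$data[[idx[1]]]))))
    norms <- sqrt(colSums(V^2))
    zero <- norms == 0
    if (any(zero)) {
      rlang::warn(sprintf(
        "%d zero-norm segment(s) in class '%s' retained without comparison",
        sum(zero), cls))
    }
    Vn <- V
    Vn[, !zero] <- sweep(V[, !zero, drop = FALSE], 2, norms[!zero], "/")
    G <- crossprod(Vn)
    similar <- if (direction == ">=") G >= rho_threshold else G <= rho_threshold

    retained <- integer(0)
    removed_sim <- 0L
    for (j in seq_len(L)) {
      drop <- FALSE
      if (removed_sim < cap && !zero[j] && length(retained) > 0) {
        comp <- retained[!zero[retained]]
        drop <- length(comp) > 0 && any(similar[comp, j])
      }
      if (drop) removed_sim <- removed_sim + 1L else retained <- c(retained, j)
    }

    n_forced <- 0L
    if (force_zeta && length(retained) > target) {
      # distinctness score: highest similarity to the other retained members;
      # drop the least distinct first (ties: the later segment goes first)
      Gr <- G[retained, retained, drop = FALSE]
      diag(Gr) <- -Inf
      score <- apply(Gr, 2, max)
      ord <- order(score, seq_along(retained), decreasing = TRUE)
      n_forced <- length(retained) - target
      victims <- ord[seq_len(n_forced)]
      forced <- c(forced, idx[retained[victims]])
      retained <- sort(retained[-victims])
    }

    keep[idx[retained]] <- TRUE
    rep_rows[[cls]] <- tibble(
      label = cls, n_before = L, n_after = length(retained),
      n_removed = L - length(retained),
      removed_similar = removed_sim, removed_forced = n_forced)
  }

  report <- dplyr::bind_rows(rep_rows)
  out <- subset_segments(set, which(keep))
  out$segment_id <- seq_len(nrow(out))
  structure(list(segments = out, report = report,
                 spec = list(rho_threshold = rho_threshold, zeta = zeta,
                             force_zeta = force_zeta, direction = direction)),
            class = "har_compression")
}

#' @export
print.har_compression <- function(x, ...) {
  cat(sprintf(
    "<har_compression: rho %s %.4g, zeta = %.3g%s>\n",
    x$spec$direction, x$spec$rho_threshold, x$spec$zeta,
    if (x$spec$force_zeta) ", forced" else ""))
  cat(sprintf("retained %d / %d segments (%.1f%% removed)\n",
              sum(x$report$n_after), sum(x$report$n_before),
              100 * sum(x$report$n_removed) / sum(x$report$n_before)))
  print(x$report, ...)
  invisible(x)
}

#' @export
tidy.har_compression <- function(x, ...) x$report
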