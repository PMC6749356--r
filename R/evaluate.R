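#' Evaluate a classifier on a labelled segment set
#'
#' Builds the confusion matrix in vocabulary order (rows = true, columns =
#' predicted) with a row summary (per-class recall, %) and a column summary
#' (per-class precision, %), as well as the overall accuracy
#' (trace / total).
#'
#' @param clf a fitted `har_dcnn`.
#' @param test_set a non-empty `har_segments` with the same vocabulary.
#' @return A `har_eval` object: confusion matrix, accuracy, per-class
#'   tibble, `n_test`.
#' @export
evaluate_classifier <- function(clf, test_set) {
  if (nrow(test_set) == 0) abort("test set is empty")
  if (!identical(vocabulary(test_set), clf$vocabulary)) {
    abort("test-set vocabulary does not match the classifier's",
          class = "har_validation_error")
  }
  preds <- predict(clf, test_set)
  eval_from_labels(test_set$label, preds$.pred_class, clf$vocabulary)
}

# confusion/accuracy machinery shared with hand-built predictions in tests
eval_from_labels <- function(truth, predicted, vocab) {
  confusion <- table(
    true = factor(truth, levels = vocab),
    predicted = factor(predicted, levels = vocab))
  confusion <- unclass(confusion)
  n_test <- sum(confusion)
  accuracy <- sum(diag(confusion)) / n_test
  rs <- rowSums(confusion); cs <- colSums(confusion)
  per_class <- tibble(
    class = vocab,
    n_true = as.integer(unname(rs)),
    n_predicted = as.integer(unname(cs)),
    recall_pct = unname(ifelse(rs > 0, 100 * diag(confusion) / rs, 0)),
    precision_pct = unname(ifelse(cs > 0, 100 * diag(confusion) / cs, 0)),
    zero_denominator = unname(rs == 0 | cs == 0))
  structure(list(confusion = confusion, accuracy = accuracy,
                 per_class = per_class, n_test = n_test),
            class = "har_eval")
}

#' @export
print.har_eval <- function(x, ...) {
  cat(sprintf("<har_eval: %d test segments, accuracy %.2f%%>\n",
              x$n_test, 100 * x$accuracy))
  print(x$confusion)
  cat("\nper-class summaries (%):\n")
  pc <- x$per_class
  pc$recall_pct <- sprintf("%.1f", pc$recall_pct)
  pc$precision_pct <- sprintf("%.1f", pc$precision_pct)
  print(pc, n = nrow(pc))
  invisible(x)
}

#' @rdname evaluate_classifier
#' @param x a `har_eval` object.
#' @param ... unused.
#' @export
tidy.har_eval <- function(x, ...) x$per_class

#' @rdname evaluate_classifier
#' @export
glance.har_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, error = 1 - x$accuracy, n_test = x$n_test,
         n_classes = nrow(x$per_class))
}

#' Split a segment set into training and test parts
#'
#' `"chronological"` keeps the first `floor(train_fraction * M)` segments
#' for training and the rest for testing; `"subject"` holds out whole
#' subjects (the last `n_test_subjects` unique ids, or an explicit set).
#'
#' @param set a `har_segments`.
#' @param train_fraction fraction of segments (or subjects) for training.
#' @param method `"chronological"` or `"subject"`.
#' @param test_subjects explicit subject ids for the test side (subject
#'   method).
#' @param n_test_subjects number of subjects held out (subject method);
#'   defaults to `round((1 - train_fraction) * n_subjects)`.
#' @return List with `har_segments` elements `train` and `test`.
#' @export
split_segments <- function(set, train_fraction = 0.8,
                           method = c("chronological", "subject"),
                           test_subjects = NULL, n_test_subjects = NULL) {
  method <- match.arg(method)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie in (0, 1)", class = "har_config_error")
  }
  M <- nrow(set)
  if (method == "chronological") {
    n_train <- floor(train_fraction * M)
    if (n_train == 0 || n_train == M) {
      abort("split leaves one side empty", class = "har_config_error")
    }
    idx_train <- seq_len(n_train)
    idx_test <- setdiff(seq_len(M), idx_train)
  } else {
    if (!"subject" %in% names(set) || all(is.na(set$subject))) {
      abort("subject-wise split needs a subject column",
            class = "har_config_error")
    }
    subjects <- unique(set$subject)
    if (is.null(test_subjects)) {
      n_test_subjects <- n_test_subjects %||%
        max(1L, round((1 - train_fraction) * length(subjects)))
      test_subjects <- tail(subjects, n_test_subjects)
    }
    idx_test <- which(set$subject %in% test_subjects)
    idx_train <- which(!set$subject %in% test_subjects)
    if (length(idx_train) == 0 || length(idx_test) == 0) {
      abort("split leaves one side empty", class = "har_config_error")
    }
  }
  list(train = subset_segments(set, idx_train),
       test = subset_segments(set, idx_test))
}

#' Sweep the compression degree
#'
#' For each compression degree `zeta`, repeatedly compress the training set,
#' train the classifier with a fresh seed, and evaluate on the fixed test
#' set; errors are `1 - accuracy`. When `subsample_per_class` is given, each
#' repetition first draws a seeded stratified subsample of the training set,
#' so the quartile band reflects both data and initialisation variation.
#'
#' @param train,test `har_segments` sets.
#' @param zetas compression degrees in `(0, 1]`.
#' @param config a [dcnn_config()]; its seed is re-derived per repetition.
#' @param reps repetitions per `zeta`.
#' @param seed base seed; repetition `r` uses `seed + r`.
#' @param rho_threshold,force_zeta passed to [compress_segments()].
#' @param subsample_per_class optional cap on training segments per class
#'   drawn before compression.
#' @return A `har_sweep` tibble with one row per (`zeta`, `rep`):
#'   `n_train`, `train_error`, `test_error`.
#' @export
zeta_sweep <- function(train, test, zetas = seq(0.1, 0.9, by = 0.2),
                       config = dcnn_config(), reps = 20, seed = 1L,
                       rho_threshold = 0.99, force_zeta = TRUE,
                       subsample_per_class = NULL) {
  if (any(zetas <= 0 | zetas > 1)) {
    abort("every zeta must lie in (0, 1]", class = "har_config_error")
  }
  if (reps < 1) abort("reps must be >= 1", class = "har_config_error")
  rows <- list()
  for (r in seq_len(reps)) {
    seed_r <- seed + r
    train_r <- train
    if (!is.null(subsample_per_class)) {
      set.seed(seed_r)
      idx <- unlist(lapply(split(seq_len(nrow(train)), train$label),
                           function(i) {
                             if (length(i) > subsample_per_class) {
                               sort(sample(i, subsample_per_class))
                             } else i
                           }), use.names = FALSE)
      train_r <- subset_segments(train, sort(idx))
    }
    for (z in zetas) {
      comp <- compress_segments(train_r, rho_threshold = rho_threshold,
                                zeta = z, force_zeta = force_zeta)
      cfg_r <- config
      cfg_r$seed <- seed_r
      clf <- train_dcnn(comp$segments, cfg_r)
      ev_test <- evaluate_classifier(clf, test)
      ev_train <- evaluate_classifier(clf, train_r)
      rows[[length(rows) + 1]] <- tibble(
        zeta = z, rep = r, seed = seed_r, n_train = nrow(comp$segments),
        train_error = 1 - ev_train$accuracy,
        test_error = 1 - ev_test$accuracy)
    }
  }
  structure(dplyr::bind_rows(rows),
            class = c("har_sweep", class(tibble())))
}

#' @rdname zeta_sweep
#' @param x a `har_sweep` object.
#' @param ... unused.
#' @export
tidy.har_sweep <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$zeta),
    reps = dplyr::n(),
    median_test_error = median(.data$test_error),
    q25_test_error = quantile(.data$test_error, 0.25),
    q75_test_error = quantile(.data$test_error, 0.75),
    median_train_error = median(.data$train_error),
    median_n_train = median(.data$n_train),
    .groups = "drop")
}
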