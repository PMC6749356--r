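#' Configuration of the convolutional classifier
#'
#' The network stacks `n_conv_modules` convolutional modules — each a valid
#' (unpadded) 2D convolution, batch normalisation and ReLU; the last module
#' adds max-pooling — followed by dropout, a fully-connected layer and a
#' softmax output. With `kernel = c(3, 3)` the feature map after module `k`
#' is `(m - 2k) x (Ld - 2k)`. Training uses Adam with a piecewise-constant
#' learning rate (dropped by `lr_drop_factor` every `lr_drop_period` epochs)
#' and categorical cross-entropy loss.
#'
#' @param n_conv_modules number of convolutional modules.
#' @param kernel convolution kernel size `(rows, cols)`.
#' @param filters filters per module; length must equal `n_conv_modules`
#'   (defaults to 5, 10, 15, ...).
#' @param dropout dropout fraction on the pooled feature vector.
#' @param learn_rate initial Adam learning rate.
#' @param lr_drop_factor,lr_drop_period learning-rate schedule: multiply by
#'   the factor every `lr_drop_period` epochs.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param normalize z-score each channel using training-set statistics
#'   (stored in the fitted model).
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @return A `har_dcnn_config` list.
#' @export
dcnn_config <- function(n_conv_modules = 4, kernel = c(3, 3),
                        filters = NULL, dropout = 0.5,
                        learn_rate = 0.001, lr_drop_factor = 0.1,
                        lr_drop_period = 100, batch_size = 50,
                        epochs = 60, normalize = TRUE, seed = 1L) {
  if (n_conv_modules < 1) abort("need at least one conv module",
                                class = "har_config_error")
  filters <- filters %||% (5L * seq_len(n_conv_modules))
  if (length(filters) != n_conv_modules) {
    abort("filters must have one entry per conv module",
          class = "har_config_error")
  }
  if (dropout < 0 || dropout >= 1) {
    abort("dropout must lie in [0, 1)", class = "har_config_error")
  }
  structure(list(n_conv_modules = as.integer(n_conv_modules),
                 kernel = as.integer(kernel), filters = as.integer(filters),
                 dropout = dropout, learn_rate = learn_rate,
                 lr_drop_factor = lr_drop_factor,
                 lr_drop_period = lr_drop_period,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 normalize = isTRUE(normalize), seed = as.integer(seed)),
            class = "har_dcnn_config")
}

#' Describe the network for a given input shape
#'
#' Computes the per-module feature-map sizes and the total trainable
#' parameter count without training; errors name the module whose feature
#' map would collapse below 1.
#'
#' @param config a [dcnn_config()].
#' @param input_shape integer `(m, ld)`: channels and window length.
#' @param n_classes number of output classes.
#' @return A `har_dcnn_arch` list with elements `shapes` (tibble of module,
#'   height, width) and `n_params`.
#' @export
build_dcnn <- function(config, input_shape, n_classes) {
  shapes <- cnn_shapes(as.integer(input_shape), config)
  structure(list(config = config, input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes), shapes = shapes,
                 n_params = cnn_n_params(config, as.integer(input_shape),
                                         n_classes)),
            class = "har_dcnn_arch")
}

#' @export
print.har_dcnn_arch <- function(x, ...) {
  cat(sprintf("<dcnn architecture: input %d x %d, %d classes, %d parameters>\n",
              x$input_shape[1], x$input_shape[2], x$n_classes, x$n_params))
  print(x$shapes, ...)
  invisible(x)
}

segments_to_array <- function(set) {
  m <- length(channel_names(set))
  ld <- segment_length(set)
  x <- array(0, dim = c(m, ld, 1L, nrow(set)))
  for (i in seq_len(nrow(set))) x[, , 1L, i] <- set$data[[i]]
  x
}

#' Train the convolutional classifier
#'
#' Fits the network on a labelled segment set. Training is fully seeded:
#' the same data, configuration and seed give identical fitted weights.
#'
#' @param train_set a `har_segments` object with at least two classes.
#' @param config a [dcnn_config()].
#' @return A fitted `har_dcnn` object holding the weights, the label
#'   vocabulary, channel names, normalisation statistics and the per-epoch
#'   loss curve.
#' @export
train_dcnn <- function(train_set, config = dcnn_config()) {
  if (nrow(train_set) == 0) abort("training set is empty")
  vocab <- vocabulary(train_set)
  y_index <- match(train_set$label, vocab)
  if (length(unique(y_index)) < 2) {
    abort("training set must contain at least two classes")
  }
  m <- length(channel_names(train_set))
  ld <- segment_length(train_set)
  arch <- build_dcnn(config, c(m, ld), length(vocab))

  x <- segments_to_array(train_set)
  if (config$normalize) {
    ch_mean <- apply(x, 1, mean)
    ch_sd <- pmax(apply(x, 1, sd), 1e-8)
    x <- sweep(sweep(x, 1, ch_mean, "-"), 1, ch_sd, "/")
  } else {
    ch_mean <- numeric(m); ch_sd <- rep(1, m)
  }

  set.seed(config$seed)
  params <- init_cnn_params(config, c(m, ld), length(vocab))
  state <- adam_init(params)
  n <- nrow(train_set)
  loss_curve <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    lr <- config$learn_rate *
      config$lr_drop_factor^((epoch - 1) %/% config$lr_drop_period)
    perm <- sample.int(n)
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y_index[idx]
      drop_mask <- if (config$dropout > 0) {
        matrix(runif(params$n_feat * length(idx)) >= config$dropout,
               params$n_feat, length(idx))
      } else NULL
      fwd <- cnn_forward(params, config, xb, train = TRUE,
                         drop_mask = drop_mask)
      losses[bi] <- cnn_loss(fwd$probs, yb)
      if (!is.finite(losses[bi])) {
        abort(sprintf(
          "training diverged: non-finite loss at epoch %d, batch %d",
          epoch, bi))
      }
      grads <- cnn_backward(params, config, fwd, yb, drop_mask)
      st <- adam_step(params, grads, state, lr)
      params <- st$params; state <- st$state
      for (k in seq_len(config$n_conv_modules)) {
        params <- update_running_stats(params, k, fwd$caches[[k]]$bn)
      }
    }
    loss_curve[epoch] <- mean(losses)
  }

  clf <- structure(list(params = params, config = config,
                        input_shape = c(m, ld), vocabulary = vocab,
                        channel_names = channel_names(train_set),
                        norm = list(mean = ch_mean, sd = ch_sd),
                        n_params = arch$n_params, shapes = arch$shapes,
                        loss_curve = loss_curve, n_train = n),
                   class = "har_dcnn")
  preds <- predict(clf, train_set)
  clf$train_accuracy <- mean(preds$.pred_class == train_set$label)
  clf
}

#' Predict activity labels for segments
#'
#' @param object a fitted `har_dcnn`.
#' @param new_data a `har_segments` whose channels and window length match
#'   the classifier's input shape.
#' @param ... unused.
#' @return A tibble with `segment_id`, `.pred_class` (argmax label; ties go
#'   to the lowest vocabulary index) and one probability column per class
#'   (prefix `.prob_`), each row summing to 1.
#' @export
predict.har_dcnn <- function(object, new_data, ...) {
  m <- length(channel_names(new_data))
  ld <- segment_length(new_data)
  if (!identical(c(m, ld), object$input_shape)) {
    abort(sprintf("segment shape %d x %d does not match classifier input %d x %d",
                  m, ld, object$input_shape[1], object$input_shape[2]),
          class = "har_shape_error")
  }
  x <- segments_to_array(new_data)
  x <- sweep(sweep(x, 1, object$norm$mean, "-"), 1, object$norm$sd, "/")
  n <- dim(x)[4]
  probs <- matrix(0, length(object$vocabulary), n)
  # predict in chunks to bound memory
  chunk <- 256L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    fwd <- cnn_forward(object$params, object$config,
                       x[, , , s:e, drop = FALSE], train = FALSE)
    probs[, s:e] <- fwd$probs
  }
  pred <- object$vocabulary[apply(probs, 2, which.max)]
  out <- tibble(segment_id = new_data$segment_id, .pred_class = pred)
  pm <- t(probs)
  colnames(pm) <- paste0(".prob_", object$vocabulary)
  dplyr::bind_cols(out, as_tibble(pm))
}

#' @export
print.har_dcnn <- function(x, ...) {
  cat(sprintf(
    "<har_dcnn: %d x %d input, %d classes, %d conv modules, %d parameters>\n",
    x$input_shape[1], x$input_shape[2], length(x$vocabulary),
    x$config$n_conv_modules, x$n_params))
  cat(sprintf("trained %d epochs on %d segments; final loss %.4f; train accuracy %.3f\n",
              x$config$epochs, x$n_train, tail(x$loss_curve, 1),
              x$train_accuracy))
  invisible(x)
}

#' @rdname train_dcnn
#' @param x a fitted `har_dcnn`.
#' @param ... unused.
#' @export
tidy.har_dcnn <- function(x, ...) {
  kh <- x$config$kernel[1]; kw <- x$config$kernel[2]
  cin <- c(1L, head(x$config$filters, -1))
  conv <- tibble(layer = paste0("conv", seq_len(x$config$n_conv_modules)),
                 height = x$shapes$height, width = x$shapes$width,
                 filters = x$config$filters,
                 n_params = kh * kw * cin * x$config$filters +
                   3L * x$config$filters)
  fc <- tibble(layer = "fc", height = 1L, width = 1L,
               filters = length(x$vocabulary),
               n_params = length(x$params$fc$W) + length(x$params$fc$b))
  dplyr::bind_rows(conv, fc)
}

#' @rdname train_dcnn
#' @export
glance.har_dcnn <- function(x, ...) {
  tibble(n_params = x$n_params, epochs = x$config$epochs,
         n_train = x$n_train, n_classes = length(x$vocabulary),
         final_loss = tail(x$loss_curve, 1),
         train_accuracy = x$train_accuracy)
}
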