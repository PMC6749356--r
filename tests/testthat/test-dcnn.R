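test_that("feature-map arithmetic matches the printed size formulas", {
  cfg <- dcnn_config()
  arch <- build_dcnn(cfg, c(9, 150), 12)
  expect_identical(arch$shapes$height, c(7L, 5L, 3L, 1L))
  expect_identical(arch$shapes$width, c(148L, 146L, 144L, 142L))

  # general property: module k yields (m - 2k) x (Ld - 2k)
  set.seed(2)
  for (i in 1:10) {
    m <- sample(9:16, 1)
    ld <- sample(40:200, 1)
    depth <- sample(1:4, 1)
    arch <- build_dcnn(dcnn_config(n_conv_modules = depth), c(m, ld), 5)
    expect_identical(arch$shapes$height, m - 2L * seq_len(depth))
    expect_identical(arch$shapes$width, ld - 2L * seq_len(depth))
  }
})

test_that("too-small inputs raise a shape error naming the module", {
  expect_error(build_dcnn(dcnn_config(), c(3, 150), 12),
               "module 2", class = "har_shape_error")
  expect_error(build_dcnn(dcnn_config(), c(9, 7), 12),
               class = "har_shape_error")
})

test_that("parameter count is a deterministic function of the architecture", {
  # regression against hand-computed counts for the default network:
  # conv: 3*3*cin*f + f biases + 2f batch-norm; fc: 20*71 pooled features
  cfg <- dcnn_config()
  arch <- build_dcnn(cfg, c(9, 150), 12)
  conv_params <- (9 * 1 * 5 + 3 * 5) + (9 * 5 * 10 + 3 * 10) +
    (9 * 10 * 15 + 3 * 15) + (9 * 15 * 20 + 3 * 20)
  fc_params <- (20 * 71) * 12 + 12
  expect_identical(arch$n_params, conv_params + fc_params)

  set <- make_easy_set(n_per_class = 3)
  clf <- train_dcnn(set, dcnn_config(n_conv_modules = 2, filters = c(4, 6),
                                     epochs = 1, batch_size = 8, seed = 1))
  expect_identical(sum(tidy(clf)$n_params), clf$n_params)
})

test_that("a single conv module network trains and predicts", {
  set <- make_easy_set(n_per_class = 6, ld = 20)
  cfg <- dcnn_config(n_conv_modules = 1, filters = 5, epochs = 3,
                     batch_size = 8, seed = 2)
  clf <- train_dcnn(set, cfg)
  expect_s3_class(clf, "har_dcnn")
  preds <- predict(clf, set)
  expect_identical(nrow(preds), nrow(set))
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("harpipe")
  cfg <- dcnn_config(n_conv_modules = 2, filters = c(3, 4), dropout = 0,
                     batch_size = 4, epochs = 1, seed = 3)
  m <- 7; ld <- 13; ncls <- 3; B <- 4
  set.seed(42)
  params <- ns$init_cnn_params(cfg, c(m, ld), ncls)
  x <- array(rnorm(m * ld * B), dim = c(m, ld, 1, B))
  y <- sample(ncls, B, replace = TRUE)
  fwd <- ns$cnn_forward(params, cfg, x, train = TRUE)
  gr <- ns$cnn_backward(params, cfg, fwd, y, NULL)
  loss_at <- function(p) {
    f <- ns$cnn_forward(p, cfg, x, train = TRUE)
    ns$cnn_loss(f$probs, y)
  }
  eps <- 1e-5
  # conv bias is checked for near-zero gradient separately: batch norm makes
  # the loss invariant to it, so relative error there is 0/0
  checks <- list(
    list(get = function(p) p$conv[[1]]$W,
         set = function(p, v) { p$conv[[1]]$W[] <- v; p },
         analytic = gr$conv[[1]]$W),
    list(get = function(p) p$conv[[2]]$W,
         set = function(p, v) { p$conv[[2]]$W[] <- v; p },
         analytic = gr$conv[[2]]$W),
    list(get = function(p) p$conv[[1]]$gamma,
         set = function(p, v) { p$conv[[1]]$gamma <- v; p },
         analytic = gr$conv[[1]]$gamma),
    list(get = function(p) p$conv[[2]]$beta,
         set = function(p, v) { p$conv[[2]]$beta <- v; p },
         analytic = gr$conv[[2]]$beta),
    list(get = function(p) p$fc$W,
         set = function(p, v) { p$fc$W[] <- v; p },
         analytic = gr$fc$W)
  )
  for (chk in checks) {
    v <- chk$get(params)
    idx <- sample(length(v), min(6, length(v)))
    for (i in idx) {
      p1 <- params; v1 <- chk$get(p1); v1[i] <- v1[i] + eps
      p1 <- chk$set(p1, v1)
      p2 <- params; v2 <- chk$get(p2); v2[i] <- v2[i] - eps
      p2 <- chk$set(p2, v2)
      num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      expect_equal(chk$analytic[i], num, tolerance = 1e-4)
    }
  }
  expect_lt(max(abs(gr$conv[[1]]$b)), 1e-8)
})

test_that("softmax outputs live on the probability simplex", {
  set <- make_easy_set(n_per_class = 5, ld = 20, noise = 0.3)
  clf <- train_dcnn(set, dcnn_config(n_conv_modules = 2, filters = c(3, 5),
                                     epochs = 2, batch_size = 10, seed = 4))
  preds <- predict(clf, set)
  probs <- as.matrix(preds[grep("^\\.prob_", names(preds))])
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-6)
  # argmax consistent with .pred_class under the lowest-index tie-break
  vocab <- sub("^\\.prob_", "", colnames(probs))
  expect_identical(preds$.pred_class, vocab[apply(probs, 1, which.max)])
})

test_that("an easy separable problem is fit almost perfectly", {
  set <- make_easy_set(n_per_class = 12, ld = 30, noise = 0.02)
  clf <- train_dcnn(set, dcnn_config(n_conv_modules = 2, filters = c(4, 8),
                                     epochs = 12, batch_size = 16, seed = 5))
  expect_gte(clf$train_accuracy, 0.99)
  preds <- predict(clf, set)
  expect_gte(mean(preds$.pred_class == set$label), 0.99)
})

test_that("training is seed-deterministic and predictions are pure", {
  set <- make_easy_set(n_per_class = 4, ld = 20)
  cfg <- dcnn_config(n_conv_modules = 1, filters = 4, epochs = 2,
                     batch_size = 8, seed = 11)
  clf1 <- train_dcnn(set, cfg)
  clf2 <- train_dcnn(set, cfg)
  expect_identical(clf1$params, clf2$params)
  expect_identical(clf1$loss_curve, clf2$loss_curve)

  # a duplicated segment receives the identical prediction
  dup <- make_segment_set(c(set$data[1], set$data[1]),
                          c(set$label[1], set$label[1]))
  preds <- predict(clf1, dup)
  expect_identical(preds[1, -1], preds[2, -1])
})

test_that("degenerate training sets are rejected", {
  set <- make_easy_set(n_per_class = 4, ld = 20)
  single <- harpipe:::subset_segments(set, which(set$label == "sit"))
  expect_error(train_dcnn(single, dcnn_config(epochs = 1)),
               "two classes")
  empty <- harpipe:::subset_segments(set, integer(0))
  expect_error(train_dcnn(empty, dcnn_config(epochs = 1)), "empty")
})

test_that("prediction rejects mismatched segment shapes", {
  set <- make_easy_set(n_per_class = 4, ld = 20)
  clf <- train_dcnn(set, dcnn_config(n_conv_modules = 1, filters = 4,
                                     epochs = 1, batch_size = 8, seed = 1))
  other <- make_easy_set(n_per_class = 2, ld = 24)
  expect_error(predict(clf, other), class = "har_shape_error")
})
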