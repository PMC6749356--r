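test_that("confusion matrix and summaries match a hand-counted example", {
  # two classes, TP = 3, FN = 1, FP = 0, TN = 2 for class "sit"
  vocab <- c("sit", "stand")
  truth <- c("sit", "sit", "sit", "sit", "stand", "stand")
  pred <- c("sit", "sit", "sit", "stand", "stand", "stand")
  ev <- harpipe:::eval_from_labels(truth, pred, vocab)
  expect_equal(ev$accuracy, 5 / 6)
  expect_identical(ev$n_test, 6L)
  expect_identical(unname(ev$confusion["sit", ]), c(3L, 1L))
  expect_equal(ev$per_class$recall_pct[1], 75)          # row summary
  expect_equal(ev$per_class$precision_pct[1], 100)      # column summary
  expect_equal(ev$per_class$precision_pct[2], 100 * 2 / 3)
  expect_identical(sum(ev$confusion), ev$n_test)
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
})

test_that("a perfect predictor gives a diagonal matrix and accuracy 1", {
  vocab <- activity_vocabulary()
  truth <- rep(vocab, times = 3)
  ev <- harpipe:::eval_from_labels(truth, truth, vocab)
  expect_equal(ev$accuracy, 1.0)
  expect_true(all(ev$confusion[upper.tri(ev$confusion)] == 0))
  expect_true(all(ev$confusion[lower.tri(ev$confusion)] == 0))
  expect_true(all(ev$per_class$recall_pct == 100))
})

test_that("evaluation is invariant to test-set order and flags empty classes", {
  vocab <- c("sit", "stand", "walk")
  truth <- c("sit", "stand", "sit", "stand", "sit")
  pred <- c("sit", "sit", "sit", "stand", "stand")
  ev1 <- harpipe:::eval_from_labels(truth, pred, vocab)
  perm <- c(3, 1, 5, 2, 4)
  ev2 <- harpipe:::eval_from_labels(truth[perm], pred[perm], vocab)
  expect_identical(ev1$confusion, ev2$confusion)
  expect_equal(ev1$accuracy, ev2$accuracy)
  # "walk" never occurs: summaries are 0 and flagged
  expect_equal(ev1$per_class$recall_pct[3], 0)
  expect_true(ev1$per_class$zero_denominator[3])
})

test_that("chronological split keeps order and conserves the set", {
  set <- make_segment_set(replicate(10, matrix(rnorm(6), 2, 3),
                                    simplify = FALSE),
                          rep(c("sit", "stand"), 5))
  parts <- split_segments(set, 0.8, "chronological")
  expect_identical(nrow(parts$train), 8L)
  expect_identical(nrow(parts$test), 2L)
  expect_identical(parts$train$start, set$start[1:8])
  expect_identical(parts$test$start, set$start[9:10])
  # disjoint union
  expect_setequal(c(parts$train$start, parts$test$start), set$start)
})

test_that("subject-wise split holds out whole subjects", {
  subjects <- rep(sprintf("S%02d", 1:20), each = 3)
  set <- make_segment_set(replicate(60, matrix(rnorm(6), 2, 3),
                                    simplify = FALSE),
                          rep("walk", 60), subjects = subjects)
  parts <- split_segments(set, 0.9, "subject")
  expect_setequal(unique(parts$test$subject), c("S19", "S20"))
  expect_identical(length(unique(parts$train$subject)), 18L)
  expect_identical(nrow(parts$train) + nrow(parts$test), 60L)
  expect_length(intersect(parts$train$segment_id, parts$test$segment_id), 0)
})

test_that("split validates its inputs", {
  set <- make_segment_set(replicate(4, matrix(1, 2, 3), simplify = FALSE),
                          rep("sit", 4))
  expect_error(split_segments(set, 1.2), class = "har_config_error")
  expect_error(split_segments(set, 0.1, "chronological"),
               class = "har_config_error")  # empty train side
  expect_error(split_segments(set, 0.8, "subject"),
               class = "har_config_error")  # no subject column
})

test_that("zeta sweep is structured, seeded and honours the zeta = 1 limit", {
  set.seed(33)
  proto <- test_protocol()
  segs <- segment_recording(extend_signals(simulate_recording(proto, seed = 40)))
  parts <- split_segments(segs, 0.7, "chronological")
  train <- select_channels(parts$train, "our")
  test <- select_channels(parts$test, "our")
  cfg <- dcnn_config(n_conv_modules = 2, filters = c(3, 5), epochs = 2,
                     batch_size = 16)
  sweep <- zeta_sweep(train, test, zetas = c(0.5, 1), cfg, reps = 2,
                      seed = 100)
  expect_identical(nrow(sweep), 4L)
  expect_setequal(unique(sweep$zeta), c(0.5, 1))
  s <- tidy(sweep)
  expect_identical(nrow(s), 2L)
  expect_true(all(c("median_test_error", "q25_test_error",
                    "q75_test_error") %in% names(s)))

  # reproducibility: same seeds, same result
  sweep2 <- zeta_sweep(train, test, zetas = c(0.5, 1), cfg, reps = 2,
                       seed = 100)
  expect_identical(as.data.frame(sweep), as.data.frame(sweep2))

  # zeta = 1 equals the uncompressed run with the same training seed
  cfg1 <- cfg
  cfg1$seed <- 101L
  clf <- train_dcnn(train, cfg1)
  ev <- evaluate_classifier(clf, test)
  z1 <- sweep[sweep$zeta == 1 & sweep$rep == 1, ]
  expect_identical(z1$n_train, nrow(train))
  expect_equal(z1$test_error, 1 - ev$accuracy)
})

test_that("evaluate_classifier validates vocabulary compatibility", {
  set <- make_easy_set(n_per_class = 4, ld = 20)
  clf <- train_dcnn(set, dcnn_config(n_conv_modules = 1, filters = 4,
                                     epochs = 1, batch_size = 8, seed = 1))
  other <- make_segment_set(set$data[1:2], set$label[1:2],
                            vocabulary = c("sit", "stand"))
  expect_error(evaluate_classifier(clf, other),
               class = "har_validation_error")
})
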