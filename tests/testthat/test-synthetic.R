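test_that("default models cover the vocabulary with the expected geometry", {
  models <- activity_models()
  expect_setequal(names(models), activity_vocabulary())

  # all gravity directions are unit vectors
  for (m in models) {
    expect_equal(sqrt(sum(m$gravity_direction^2)), 1, tolerance = 1e-9)
  }
  # lying left/right are antiparallel
  expect_equal(models[["lying-left"]]$gravity_direction,
               -models[["lying-right"]]$gravity_direction, tolerance = 1e-12)
  # six static postures have six distinct gravity directions
  statics <- c("sit", "stand", "lying-left", "lying-right",
               "lying-supine", "lying-prone")
  dirs <- sapply(models[statics], `[[`, "gravity_direction")
  expect_equal(qr(dirs)$rank, 3)
  expect_true(min(dist(t(dirs))) > 0.1)
  for (s in statics) expect_true(all(models[[s]]$osc_amp == 0))
})

test_that("sample count equals round(total duration x sample rate)", {
  proto <- har_protocol(
    bouts = tibble::tibble(activity = c("stand", "walk"),
                           duration = c(7.3, 4.2)),
    transition_duration = 1.7)
  rec <- simulate_recording(proto, seed = 1)
  expect_identical(nrow(rec), as.integer(round((7.3 + 1.7 + 4.2) * 50)))

  # a 25-minute protocol yields 75,000 samples at 50 Hz
  proto25 <- har_protocol(
    bouts = tibble::tibble(activity = rep(c("stand", "walk"), 15),
                           duration = 50),
    transition_duration = 0)
  expect_identical(nrow(simulate_recording(proto25, seed = 1)), 75000L)
})

test_that("the default protocol matches the stated collection session", {
  proto <- har_protocol()
  rec <- simulate_recording(proto, seed = 2)
  total_min <- nrow(rec) / sample_rate(rec) / 60
  expect_gt(total_min, 25)        # 25-30 min of data per subject
  expect_lt(total_min, 32)
  expect_gt(nrow(rec), 5e4)       # more than 5e4 samples at 50 Hz
  expect_setequal(unique(rec$label), activity_vocabulary())
})

test_that("noiseless static bout is the closed-form signal", {
  models <- activity_models()
  models$stand$noise_sd[] <- 0
  proto <- har_protocol(bouts = tibble::tibble(activity = "stand",
                                               duration = 10))
  rec <- simulate_recording(proto, models, seed = 1)
  expect_equal(unique(rec$label), "stand")
  expect_equal(max(abs(rec$ax)), 0)
  expect_equal(max(abs(rec$ay)), 0)
  expect_equal(unique(rec$az), 9.81)
  expect_true(all(as.matrix(rec[c("gx", "gy", "gz")]) == 0))
  # mean |acc| over a noiseless static bout is exactly gravity
  expect_equal(mean(sqrt(rec$ax^2 + rec$ay^2 + rec$az^2)), 9.81,
               tolerance = 1e-9)

  # dynamic bout spot-check against the generator formula
  models$walk$noise_sd[] <- 0
  proto2 <- har_protocol(bouts = tibble::tibble(activity = "walk",
                                                duration = 4))
  rec2 <- simulate_recording(proto2, models, seed = 9)
  set.seed(9)
  ph_a <- runif(3, 0, 2 * pi)
  m <- models$walk
  i <- 37
  ti <- (i - 1) / 50
  expected_az <- 9.81 + m$osc_amp[3] *
    (sin(2 * pi * m$osc_freq * ti + ph_a[3]) +
       0.3 * sin(4 * pi * m$osc_freq * ti + 2 * ph_a[3]))
  expect_equal(rec2$az[i], expected_az, tolerance = 1e-12)
})

test_that("labels partition time as scheduled and transfer sits between bouts", {
  proto <- test_protocol(bout = 6, transition = 2)
  rec <- simulate_recording(proto, seed = 4)
  runs <- rle(rec$label)
  # alternating bout / transfer / bout / ...
  expect_identical(runs$values[seq(2, length(runs$values), by = 2)],
                   rep("transfer", (length(runs$values) - 1) / 2))
  expect_false(runs$values[1] == "transfer")
  expect_false(tail(runs$values, 1) == "transfer")
  # transfer runs are exactly transition_duration long
  expect_true(all(runs$lengths[runs$values == "transfer"] == 2 * 50))
})

test_that("simulation is seed-deterministic", {
  proto <- test_protocol()
  a <- simulate_recording(proto, seed = 77)
  b <- simulate_recording(proto, seed = 77)
  d <- simulate_recording(proto, seed = 78)
  expect_identical(a, b)
  expect_false(identical(a$ax, d$ax))
})

test_that("missing model and invalid durations are configuration errors", {
  proto <- har_protocol(bouts = tibble::tibble(activity = "cartwheel",
                                               duration = 5))
  expect_error(simulate_recording(proto, seed = 1), "cartwheel",
               class = "har_config_error")
  expect_error(har_protocol(bouts = tibble::tibble(activity = "sit",
                                                   duration = 0)),
               class = "har_config_error")
})

test_that("subjects differ but are individually reproducible", {
  proto <- test_protocol()
  recs <- simulate_subjects(3, proto, seed = 10)
  expect_length(recs, 3)
  expect_identical(unique(recs[[2]]$subject), "S02")
  expect_false(identical(recs[[1]]$ax, recs[[2]]$ax))
  recs2 <- simulate_subjects(3, proto, seed = 10)
  expect_identical(recs[[3]], recs2[[3]])
})
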