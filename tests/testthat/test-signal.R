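test_that("gravity split preserves DC and recomposes exactly", {
  n <- 1000
  acc <- cbind(x = rep(0, n), y = rep(0, n), z = rep(9.81, n))
  gs <- gravity_split(acc, filter_spec(), rate = 50)
  mid <- 200:800  # away from edge transients
  expect_lt(max(abs(gs$linear$z[mid])), 1e-6)
  expect_equal(mean(gs$gravity$z[mid]), 9.81, tolerance = 1e-6)
  # conservation holds everywhere by construction
  expect_equal(as.matrix(gs$gravity) + as.matrix(gs$linear),
               unname(acc), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("stopband attenuation matches the designed response", {
  # DC + 5 Hz sinusoid; the zero-phase (forward-backward) gravity output
  # attenuates the sinusoid by the squared designed magnitude at 5 Hz.
  # Hann-windowed quadrature projection suppresses leakage from the
  # (slow, off-frequency) edge transients into the -120 dB measurement.
  rate <- 50
  n <- 60 * rate
  t <- (0:(n - 1)) / rate
  amp <- 0.5
  acc <- cbind(9.81 + amp * sin(2 * pi * 5 * t), rep(0, n), rep(1, n))
  spec <- filter_spec()
  gs <- gravity_split(acc, spec, rate)
  mid <- (10 * rate):(50 * rate - 1)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_along(mid) / length(mid))
  resid <- gs$gravity[[1]][mid] - mean(gs$gravity[[1]][mid])
  meas <- 2 * sqrt(sum(w * resid * sin(2 * pi * 5 * t[mid]))^2 +
                     sum(w * resid * cos(2 * pi * 5 * t[mid]))^2) / sum(w)
  flt <- harpipe:::design_lpef(spec, rate)
  ejw <- exp(-1i * 2 * pi * 5 / rate * (0:3))
  designed <- abs(sum(flt$b * ejw) / sum(flt$a * ejw))^2
  expect_equal(meas / amp, designed, tolerance = 0.05 * designed)

  # DC component itself is preserved exactly
  expect_equal(mean(gs$gravity[[1]][mid]), 9.81, tolerance = 1e-9)
})

test_that("zero-phase filtering is time-reversal symmetric and lag-free", {
  set.seed(1)
  rate <- 50
  n <- 600
  acc <- cbind(9.81 + cumsum(rnorm(n, 0, 0.02)), rnorm(n, 0, 0.1),
               rnorm(n, 0, 0.1))
  gs_fwd <- gravity_split(acc, filter_spec(), rate)
  gs_rev <- gravity_split(acc[n:1, ], filter_spec(), rate)
  # symmetric away from the flagged edge-transient zone
  mid <- 51:550
  diffs <- abs(as.matrix(gs_rev$gravity)[n:1, ][mid, ] -
                 as.matrix(gs_fwd$gravity)[mid, ])
  expect_lt(max(diffs), 1e-3)

  # no group delay: cross-correlation of DC-removed input/output peaks at 0
  x <- acc[, 1] - mean(acc[, 1])
  y <- gs_fwd$gravity[[1]] - mean(gs_fwd$gravity[[1]])
  cc <- stats::ccf(x, y, lag.max = 25, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("filter preconditions are enforced", {
  acc <- matrix(1, 5, 3)
  expect_error(gravity_split(acc, filter_spec(order = 3), rate = 50),
               class = "har_length_error")
  expect_error(filter_spec(cutoff_hz = 25), class = "har_config_error")
  expect_error(gravity_split(matrix(1, 100, 3), filter_spec(cutoff_hz = 20),
                             rate = 30),
               class = "har_config_error")  # cutoff >= Nyquist
})

test_that("abs_acceleration and gyro_sum are the stated elementwise maps", {
  expect_equal(as.numeric(as.matrix(abs_acceleration(matrix(c(-1, 2, -3), 1)))),
               c(1, 2, 3))
  z <- matrix(0, 4, 3)
  expect_true(all(as.matrix(abs_acceleration(z)) == 0))
  set.seed(2)
  x <- matrix(rnorm(60), 20, 3)
  expect_identical(as.matrix(abs_acceleration(abs_acceleration(x))),
                   as.matrix(abs_acceleration(x)))

  expect_equal(gyro_sum(matrix(c(1, 2, 3), 1)), 6)
  a <- rnorm(10)
  expect_equal(gyro_sum(cbind(a, -a, 0)), rep(0, 10))
  # brute-force loop oracle
  oracle <- vapply(seq_len(nrow(x)), function(i) {
    s <- 0
    for (j in 1:3) s <- s + x[i, j]
    s
  }, numeric(1))
  expect_equal(gyro_sum(x), oracle, tolerance = 1e-12)
})

test_that("extend_signals yields 19 channels with the stated identities", {
  proto <- test_protocol()
  rec <- simulate_recording(proto, seed = 6)
  ext <- extend_signals(rec)
  chans <- setdiff(names(ext), c("t", "label", "subject"))
  expect_identical(chans, extended_channels())
  expect_length(chans, 19)
  expect_identical(ext$label, rec$label)

  # S_alpha2 >= 0; S_beta1 = sum of gyro channels; linear + gravity = raw
  expect_true(min(ext$aax, ext$aay, ext$aaz) >= 0)
  expect_equal(ext$gsum, ext$gx + ext$gy + ext$gz, tolerance = 1e-9)
  g <- attr(ext, "gravity")
  for (ax in c("x", "y", "z")) {
    expect_equal(ext[[paste0("la", ax)]] + g[[paste0("a", ax)]],
                 ext[[paste0("a", ax)]], tolerance = 1e-9)
  }
})

test_that("a noiseless static recording extends to constant channels", {
  models <- activity_models()
  models$stand$noise_sd[] <- 0
  proto <- har_protocol(bouts = tibble::tibble(activity = "stand",
                                               duration = 20))
  # declination-free field so yaw has no constant offset to converge to
  ext <- extend_signals(simulate_recording(proto, models, seed = 1,
                                           earth_field = c(25, 0, -40)))
  mid <- 200:800
  expect_lt(max(abs(ext$lax[mid])), 1e-6)
  expect_lt(max(abs(ext$gsum[mid])), 1e-12)
  expect_lt(diff(range(ext$roll[mid])), 1e-6)
  expect_lt(diff(range(ext$yaw[mid])), 1e-6)
})
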