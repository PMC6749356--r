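#' Per-activity signal models for the synthetic IMU generator
#'
#' Each activity is modelled as a rigid device at a posture-dependent
#' orientation. Static postures differ by the direction of gravity in the
#' device frame; dynamic exercises add sinusoidal acceleration and
#' angular-velocity oscillations (fundamental plus a weaker first harmonic)
#' with activity-specific frequency and per-axis amplitudes. The magnetometer
#' sees the Earth field rotated into the device frame. White Gaussian noise
#' is added per sensor.
#'
#' @param name class label the model generates.
#' @param gravity_direction unit 3-vector: direction of the gravity reaction
#'   in the device frame (normalised internally).
#' @param osc_freq oscillation fundamental in Hz (0 for static postures).
#' @param osc_amp per-axis acceleration oscillation amplitude, m/s^2.
#' @param gyro_amp per-axis angular-velocity oscillation amplitude, rad/s.
#' @param noise_sd named numeric: standard deviations `acc` (m/s^2),
#'   `gyro` (rad/s), `mag` (uT).
#' @return An `activity_model` list.
#' @export
activity_model <- function(name, gravity_direction,
                           osc_freq = 0,
                           osc_amp = c(0, 0, 0),
                           gyro_amp = c(0, 0, 0),
                           noise_sd = c(acc = 0.25, gyro = 0.03, mag = 0.6)) {
  g <- as.numeric(gravity_direction)
  nrm <- sqrt(sum(g^2))
  if (nrm == 0) abort("gravity_direction must be non-zero")
  g <- g / nrm
  if (any(osc_amp < 0) || any(gyro_amp < 0) || osc_freq < 0) {
    abort("frequencies and amplitudes must be non-negative")
  }
  structure(list(name = name, gravity_direction = g,
                 osc_freq = osc_freq, osc_amp = as.numeric(osc_amp),
                 gyro_amp = as.numeric(gyro_amp),
                 noise_sd = noise_sd),
            class = "activity_model")
}

#' Default activity models
#'
#' One model per vocabulary class: six static postures with six distinct
#' gravity directions (the four lying positions put gravity along the
#' device x/y axes; `lying-left`/`lying-right` are antiparallel), five
#' dynamic exercises with distinct oscillation frequencies and amplitudes,
#' and a nominal `transfer` entry whose noise levels apply during the
#' smoothly interpolated transitions.
#'
#' @return Named list of [activity_model()] objects covering
#'   [activity_vocabulary()].
#' @export
activity_models <- function() {
  dyn_noise <- c(acc = 0.35, gyro = 0.05, mag = 0.8)
  models <- list(
    activity_model("sit", c(0, 0.342, 0.940)),
    activity_model("stand", c(0, 0, 1)),
    activity_model("jump", c(0, 0, 1), osc_freq = 1.0,
                   osc_amp = c(1.0, 1.0, 6.0), gyro_amp = c(0.4, 0.4, 0.3),
                   noise_sd = dyn_noise),
    activity_model("jog", c(0, 0, 1), osc_freq = 2.6,
                   osc_amp = c(2.0, 1.5, 4.0), gyro_amp = c(0.8, 0.7, 0.5),
                   noise_sd = dyn_noise),
    activity_model("walk", c(0, 0, 1), osc_freq = 1.8,
                   osc_amp = c(0.8, 0.6, 1.5), gyro_amp = c(0.3, 0.25, 0.2),
                   noise_sd = dyn_noise),
    activity_model("upstairs", c(0, 0.17, 0.985), osc_freq = 1.5,
                   osc_amp = c(0.9, 0.7, 1.8), gyro_amp = c(0.5, 0.35, 0.25),
                   noise_sd = dyn_noise),
    activity_model("downstairs", c(0, -0.17, 0.985), osc_freq = 2.1,
                   osc_amp = c(1.1, 0.8, 2.0), gyro_amp = c(0.45, 0.5, 0.3),
                   noise_sd = dyn_noise),
    activity_model("lying-left", c(-1, 0, 0)),
    activity_model("lying-right", c(1, 0, 0)),
    activity_model("lying-supine", c(0, -1, 0)),
    activity_model("lying-prone", c(0, 1, 0)),
    activity_model("transfer", c(0, 0, 1),
                   noise_sd = c(acc = 0.35, gyro = 0.05, mag = 0.8))
  )
  stats::setNames(models, vapply(models, `[[`, "", "name"))
}

#' Collection protocol for the synthetic generator
#'
#' The default schedule mirrors the original collection order: three
#' sit/stand alternations, three jump/jog repetitions with short standing
#' breaks, the four lying postures twice, and three walk/upstairs/downstairs
#' repetitions with standing breaks. Main bouts last 50 s, breaks 15 s, and
#' every change of activity is bridged by a smooth `transition_duration`-long
#' reorientation labelled `"transfer"`. One run lasts about 30 minutes.
#'
#' @param bouts tibble with columns `activity` and `duration` (seconds);
#'   `NULL` for the default schedule.
#' @param transition_duration seconds of labelled transition inserted between
#'   consecutive bouts.
#' @param sample_rate sampling frequency in Hz.
#' @param bout_duration,break_duration durations (s) used to build the
#'   default schedule.
#' @return A `har_protocol` list.
#' @export
har_protocol <- function(bouts = NULL, transition_duration = 2.5,
                         sample_rate = 50, bout_duration = 50,
                         break_duration = 15) {
  if (is.null(bouts)) {
    act <- c(
      rep(c("sit", "stand"), 3),
      rep(c("jump", "stand", "jog", "stand"), 3),
      rep(c("lying-left", "lying-right", "lying-supine", "lying-prone"), 2),
      rep(c("walk", "stand", "upstairs", "stand", "downstairs", "stand"), 3)
    )
    dur <- rep(bout_duration, length(act))
    # standing breaks inside the exercise blocks are shorter
    brk <- c(rep(FALSE, 6),
             rep(c(FALSE, TRUE), 6),
             rep(FALSE, 8),
             rep(c(FALSE, TRUE), 9))
    dur[brk] <- break_duration
    bouts <- tibble(activity = act, duration = dur)
  }
  bouts <- as_tibble(bouts)
  if (!all(c("activity", "duration") %in% names(bouts))) {
    abort("bouts needs columns 'activity' and 'duration'",
          class = "har_config_error")
  }
  if (any(bouts$duration <= 0)) {
    abort("bout durations must be positive", class = "har_config_error")
  }
  if (transition_duration < 0 || sample_rate <= 0) {
    abort("transition_duration must be >= 0 and sample_rate > 0",
          class = "har_config_error")
  }
  structure(list(bouts = bouts, transition_duration = transition_duration,
                 sample_rate = sample_rate),
            class = "har_protocol")
}

# expand a protocol into the full schedule, inserting transitions
protocol_schedule <- function(protocol) {
  b <- protocol$bouts
  n <- nrow(b)
  if (n == 0) abort("protocol has no bouts", class = "har_config_error")
  act <- character(0); dur <- numeric(0); from <- character(0)
  for (i in seq_len(n)) {
    if (i > 1 && protocol$transition_duration > 0) {
      act <- c(act, "transfer")
      dur <- c(dur, protocol$transition_duration)
      from <- c(from, b$activity[i - 1])
    }
    act <- c(act, b$activity[i])
    dur <- c(dur, b$duration[i])
    from <- c(from, b$activity[i])
  }
  tibble(activity = act, duration = dur, prev = dplyr::lag(from))
}

#' Simulate a labelled 9-channel IMU recording
#'
#' Generates the closed-form signal implied by the activity models plus
#' seeded Gaussian noise. The accelerometer reads the gravity reaction
#' rotated into the device frame plus the activity oscillation; the
#' gyroscope reads the oscillation (and, during transitions, the true body
#' angular velocity of the slerp reorientation); the magnetometer reads the
#' Earth field rotated into the device frame. Per-sample labels follow the
#' schedule exactly and `"transfer"` appears only between bouts.
#'
#' @param protocol a [har_protocol()].
#' @param models named list of [activity_model()]s covering every protocol
#'   activity (see [activity_models()]).
#' @param seed integer; fixes all randomness.
#' @param subject optional subject identifier stored in a `subject` column.
#' @param earth_field Earth magnetic field in the world frame, uT.
#' @return A [har_recording()] with `round(total_duration * sample_rate)`
#'   rows.
#' @export
simulate_recording <- function(protocol = har_protocol(),
                               models = activity_models(),
                               seed = 1L, subject = NULL,
                               earth_field = c(22, 5, -42)) {
  sched <- protocol_schedule(protocol)
  missing <- setdiff(unique(sched$activity), names(models))
  if (length(missing) > 0) {
    abort(paste0("no activity model for: ", paste(missing, collapse = ", ")),
          class = "har_config_error")
  }
  set.seed(seed)
  fs <- protocol$sample_rate
  total <- sum(sched$duration)
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  starts <- cumsum(c(0, sched$duration[-nrow(sched)]))
  item <- findInterval(t, starts)

  # posture attitude (sensor -> earth) per activity
  att <- lapply(models, function(m) quat_conj(quat_minrot_to(m$gravity_direction)))

  acc <- matrix(0, n, 3); gyro <- matrix(0, n, 3); mag <- matrix(0, n, 3)
  label <- character(n)

  for (i in seq_len(nrow(sched))) {
    idx <- which(item == i)
    if (length(idx) == 0) next
    a <- sched$activity[i]
    m <- models[[a]]
    ti <- t[idx] - starts[i]
    label[idx] <- a

    if (a == "transfer") {
      q1 <- att[[sched$prev[i]]]
      q2 <- att[[sched$activity[i + 1]]]
      s <- ti / sched$duration[i]
      qs <- quat_slerp(q1, q2, s)
      v <- quat_log(quat_mult(quat_conj(q1), q2))
      omega <- v / sched$duration[i]        # constant body rate of the slerp
      for (k in seq_along(idx)) {
        R <- quat_to_matrix(qs[k, ])        # sensor -> earth
        acc[idx[k], ] <- crossprod(R, c(0, 0, GRAVITY))
        mag[idx[k], ] <- crossprod(R, earth_field)
      }
      gyro[idx, ] <- matrix(omega, length(idx), 3, byrow = TRUE)
    } else {
      R <- quat_to_matrix(att[[a]])
      acc[idx, ] <- matrix(crossprod(R, c(0, 0, GRAVITY)), length(idx), 3,
                           byrow = TRUE)
      mag[idx, ] <- matrix(crossprod(R, earth_field), length(idx), 3,
                           byrow = TRUE)
      if (m$osc_freq > 0) {
        ph_a <- runif(3, 0, 2 * pi)
        ph_g <- runif(3, 0, 2 * pi)
        for (ax in 1:3) {
          osc <- m$osc_amp[ax] * (sin(2 * pi * m$osc_freq * ti + ph_a[ax]) +
                                    0.3 * sin(4 * pi * m$osc_freq * ti + 2 * ph_a[ax]))
          acc[idx, ax] <- acc[idx, ax] + osc
          gyro[idx, ax] <- gyro[idx, ax] +
            m$gyro_amp[ax] * sin(2 * pi * m$osc_freq * ti + ph_g[ax])
        }
      }
    }
    sds <- m$noise_sd
    if (sds[["acc"]] > 0) acc[idx, ] <- acc[idx, ] + rnorm(3 * length(idx), 0, sds[["acc"]])
    if (sds[["gyro"]] > 0) gyro[idx, ] <- gyro[idx, ] + rnorm(3 * length(idx), 0, sds[["gyro"]])
    if (sds[["mag"]] > 0) mag[idx, ] <- mag[idx, ] + rnorm(3 * length(idx), 0, sds[["mag"]])
  }

  out <- tibble(t = t,
                ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
                mx = mag[, 1], my = mag[, 2], mz = mag[, 3],
                label = label)
  if (!is.null(subject)) out$subject <- subject
  vocab <- union(activity_vocabulary(), unique(label))
  new_recording(out, fs, vocab)
}

#' Simulate a cohort of subjects
#'
#' Subjects share the protocol but differ by a seeded perturbation of the
#' model parameters: oscillation frequency and amplitudes get multiplicative
#' log-normal jitter and the posture orientation is tilted by a small random
#' rotation, emulating inter-individual variation in gait and device
#' placement.
#'
#' @param n_subjects number of subjects to simulate.
#' @inheritParams simulate_recording
#' @param freq_sd,amp_sd log-scale standard deviations of the frequency and
#'   amplitude jitter.
#' @param tilt_sd standard deviation (degrees) of the posture tilt.
#' @return A list of [har_recording()]s, one per subject, with `subject`
#'   columns `"S01"`, `"S02"`, ...
#' @export
simulate_subjects <- function(n_subjects, protocol = har_protocol(),
                              models = activity_models(), seed = 1L,
                              freq_sd = 0.04, amp_sd = 0.08, tilt_sd = 3,
                              earth_field = c(22, 5, -42)) {
  set.seed(seed)
  sub_seeds <- sample.int(10^8, n_subjects)
  pert_seeds <- sample.int(10^8, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    set.seed(pert_seeds[i])
    mod_i <- lapply(models, function(m) {
      axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
      tilt <- quat_from_axis_angle(axis, rnorm(1, 0, tilt_sd * pi / 180))
      g <- as.numeric(quat_to_matrix(tilt) %*% m$gravity_direction)
      activity_model(m$name, g,
                     osc_freq = m$osc_freq * exp(rnorm(1, 0, freq_sd)),
                     osc_amp = m$osc_amp * exp(rnorm(3, 0, amp_sd)),
                     gyro_amp = m$gyro_amp * exp(rnorm(3, 0, amp_sd)),
                     noise_sd = m$noise_sd)
    })
    simulate_recording(protocol, mod_i, seed = sub_seeds[i],
                       subject = sprintf("S%02d", i),
                       earth_field = earth_field)
  })
}
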