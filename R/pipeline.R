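#' Pipeline configuration
#'
#' One nested configuration for the whole simulate -> preprocess -> segment
#' -> split -> compress -> select -> train -> evaluate chain. Unknown keys
#' are rejected. A configuration can also be loaded from a YAML file with
#' [read_pipeline_config()].
#'
#' @param seed global seed; stage seeds are derived from it.
#' @param simulate list: `n_subjects`, and optional [har_protocol()]
#'   arguments `bout_duration`, `break_duration`, `transition_duration`,
#'   `sample_rate`.
#' @param filter list of [filter_spec()] arguments.
#' @param ahrs list of [ahrs_config()] arguments.
#' @param segment list: `ld`, `stride`, `label_rule`.
#' @param split list: `method`, `train_fraction`, `n_test_subjects`.
#' @param compress list: `rho_threshold`, `zeta`, `force_zeta`.
#' @param select list: `preset`.
#' @param dcnn list of [dcnn_config()] arguments.
#' @return A `har_pipeline_config` nested list.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = list(),
                            filter = list(),
                            ahrs = list(),
                            segment = list(),
                            split = list(),
                            compress = list(),
                            select = list(),
                            dcnn = list()) {
  defaults <- list(
    seed = 1L,
    simulate = list(n_subjects = 20L, bout_duration = 50,
                    break_duration = 15, transition_duration = 2.5,
                    sample_rate = 50),
    filter = list(order = 3, cutoff_hz = 0.3, ripple_db = 0.01,
                  stopband_db = 60, zero_phase = TRUE),
    ahrs = list(gain = 0.1),
    segment = list(ld = 150L, stride = 150L, label_rule = "majority"),
    split = list(method = "subject", train_fraction = 0.9,
                 n_test_subjects = 2L),
    compress = list(rho_threshold = 0.99, zeta = 0.5, force_zeta = TRUE),
    select = list(preset = "our"),
    dcnn = list(epochs = 10L, batch_size = 50L)
  )
  allowed <- list(
    simulate = c("n_subjects", "bout_duration", "break_duration",
                 "transition_duration", "sample_rate"),
    filter = names(formals(filter_spec)),
    ahrs = c("algorithm", "gain", "initial_orientation"),
    segment = c("ld", "stride", "label_rule", "purity"),
    split = c("method", "train_fraction", "n_test_subjects"),
    compress = c("rho_threshold", "zeta", "force_zeta"),
    select = "preset",
    dcnn = setdiff(names(formals(dcnn_config)), "seed")
  )
  user <- list(seed = seed, simulate = simulate, filter = filter,
               ahrs = ahrs, segment = segment, split = split,
               compress = compress, select = select, dcnn = dcnn)
  cfg <- defaults
  cfg$seed <- as.integer(user$seed)
  for (section in setdiff(names(defaults), "seed")) {
    unknown <- setdiff(names(user[[section]]), allowed[[section]])
    if (length(unknown) > 0) {
      abort(sprintf("unknown key(s) in '%s': %s", section,
                    paste(unknown, collapse = ", ")),
            class = "har_config_error")
    }
    cfg[[section]][names(user[[section]])] <- user[[section]]
  }
  structure(cfg, class = "har_pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the same nested sections.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c("seed", "simulate", "filter", "ahrs",
                                   "segment", "split", "compress", "select",
                                   "dcnn"))
  if (length(unknown) > 0) {
    abort(paste0("unknown top-level key(s): ", paste(unknown, collapse = ", ")),
          class = "har_config_error")
  }
  do.call(pipeline_config, raw)
}

#' Run the full pipeline on synthetic data
#'
#' Simulates the configured cohort, extends and segments every subject's
#' recording, splits into training and test sets, compresses the training
#' set, applies the channel preset, trains the classifier and evaluates it.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage progress messages.
#' @return A `har_pipeline_result` list: `report` (a `har_eval`), `model`,
#'   `compression` report, the `train`/`test` segment sets and the `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) rlang::inform(sprintf(...))
  sim <- config$simulate
  protocol <- har_protocol(bout_duration = sim$bout_duration,
                           break_duration = sim$break_duration,
                           transition_duration = sim$transition_duration,
                           sample_rate = sim$sample_rate)
  say("simulate: %d subjects, seed %d", sim$n_subjects, config$seed)
  recs <- simulate_subjects(sim$n_subjects, protocol, seed = config$seed)

  fspec <- do.call(filter_spec, config$filter)
  acfg <- do.call(ahrs_config, c(config$ahrs,
                                 list(sample_rate = sim$sample_rate)))
  say("preprocess + segment: ld = %d, stride = %d",
      config$segment$ld, config$segment$stride)
  sets <- lapply(recs, function(rec) {
    ext <- extend_signals(rec, fspec, acfg)
    do.call(segment_recording, c(list(ext), config$segment))
  })
  segs <- bind_segment_sets(sets)
  say("segmented: %d segments", nrow(segs))

  parts <- split_segments(segs, train_fraction = config$split$train_fraction,
                          method = config$split$method,
                          n_test_subjects = config$split$n_test_subjects)
  comp <- compress_segments(parts$train,
                            rho_threshold = config$compress$rho_threshold,
                            zeta = config$compress$zeta,
                            force_zeta = config$compress$force_zeta)
  say("compressed training set: %d -> %d segments",
      nrow(parts$train), nrow(comp$segments))

  train <- select_channels(comp$segments, config$select$preset)
  test <- select_channels(parts$test, config$select$preset)

  dcfg <- do.call(dcnn_config, c(config$dcnn, list(seed = config$seed)))
  say("train: %d epochs on %d segments (%s preset)",
      dcfg$epochs, nrow(train), config$select$preset)
  clf <- train_dcnn(train, dcfg)
  report <- evaluate_classifier(clf, test)
  say("test accuracy: %.2f%%", 100 * report$accuracy)

  structure(list(report = report, model = clf, compression = comp$report,
                 train = train, test = test, config = config),
            class = "har_pipeline_result")
}

#' @export
print.har_pipeline_result <- function(x, ...) {
  cat("<har_pipeline_result>\n")
  print(x$report)
  invisible(x)
}
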