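MANIFEST_SCHEMA_VERSION <- 1L

#' Write a dataset to a directory of plain-text tables
#'
#' One CSV per (trial, sensor) with a `time_ms` column followed by the
#' channel values, plus a `manifest.yaml` listing trials, labels, sensors,
#' MVIC references, the generator seed and the schema version.
#'
#' @param dataset An `intent_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- attr(dataset, "design")
  sensors <- attr(dataset, "sensors")
  trials <- dataset |>
    dplyr::distinct(.data$trial_id, .data$participant, .data$activity,
                    .data$category) |>
    arrange(.data$trial_id)
  records <- lapply(seq_len(nrow(trials)), function(i) {
    tid <- trials$trial_id[i]
    sub <- dataset[dataset$trial_id == tid, ]
    files <- setNames(as.list(file.path("trials", tid,
                                        paste0(sub$sensor_id, ".csv"))),
                      sub$sensor_id)
    dir.create(file.path(dir, "trials", tid), recursive = TRUE,
               showWarnings = FALSE)
    for (j in seq_len(nrow(sub))) {
      readr::write_csv(as_tibble(as.data.frame(sub$data[[j]])),
                       file.path(dir, files[[sub$sensor_id[j]]]))
    }
    list(trial_id = tid, participant = trials$participant[i],
         activity = trials$activity[i], category = trials$category[i],
         files = files)
  })
  manifest <- list(
    schema_version = MANIFEST_SCHEMA_VERSION,
    seed = attr(dataset, "seed"),
    conditioned = isTRUE(attr(dataset, "conditioned")),
    design = list(
      n_participants = design$n_participants,
      n_activities = design$n_activities,
      n_trials_per_activity = design$n_trials_per_activity,
      trial_duration = design$trial_duration,
      category_map = as.integer(design$category_map)
    ),
    sensors = lapply(seq_len(nrow(sensors)), function(i) {
      s <- as.list(sensors[i, ])
      s$mvic_reference <- if (is.na(s$mvic_reference)) NULL else
        s$mvic_reference
      s
    }),
    trials = records
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Load a dataset from a manifest directory
#'
#' Validates the manifest (schema version, unique trial ids, existence of
#' every referenced file) before reading anything; integrity problems are
#' reported together rather than one at a time.
#'
#' @param dir Directory containing `manifest.yaml`.
#' @return An `intent_dataset`.
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.yaml")
  if (!file.exists(mpath)) abort(paste0("read_dataset(): no manifest at ",
                                        mpath))
  man <- yaml::read_yaml(mpath)
  if (!identical(as.integer(man$schema_version), MANIFEST_SCHEMA_VERSION)) {
    abort("read_dataset(): unsupported manifest schema version")
  }
  ids <- vapply(man$trials, `[[`, "", "trial_id")
  problems <- character()
  if (anyDuplicated(ids)) {
    problems <- c(problems, paste0("duplicate trial ids: ",
                                   paste(unique(ids[duplicated(ids)]),
                                         collapse = ", ")))
  }
  for (tr in man$trials) {
    for (f in unlist(tr$files)) {
      if (!file.exists(file.path(dir, f))) {
        problems <- c(problems, paste0("missing file: ", f))
      }
    }
  }
  if (length(problems)) {
    abort(paste0("read_dataset(): manifest integrity errors:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  if (!length(man$trials)) warn("read_dataset(): manifest lists no trials")

  design <- trial_design(man$design$n_participants, man$design$n_activities,
                         man$design$n_trials_per_activity,
                         man$design$trial_duration,
                         man$design$category_map)
  sensors <- bind_rows(lapply(man$sensors, function(s) {
    tibble(sensor_id = s$sensor_id, modality = s$modality, fs = s$fs,
           informativeness = s$informativeness,
           mvic_reference = s$mvic_reference %||% NA_real_)
  }))
  class(sensors) <- c("sensor_network", class(sensors))

  rows <- list()
  for (tr in man$trials) {
    for (sid in names(tr$files)) {
      m <- as.matrix(readr::read_csv(file.path(dir, tr$files[[sid]]),
                                     show_col_types = FALSE,
                                     progress = FALSE))
      i <- match(sid, sensors$sensor_id)
      rows[[length(rows) + 1]] <- tibble(
        trial_id = tr$trial_id, participant = as.integer(tr$participant),
        activity = as.integer(tr$activity),
        category = as.integer(tr$category),
        sensor_id = sid, modality = sensors$modality[i], fs = sensors$fs[i],
        data = list(m))
    }
  }
  out <- bind_rows(rows)
  attr(out, "design") <- design
  attr(out, "sensors") <- sensors
  attr(out, "seed") <- man$seed
  attr(out, "conditioned") <- isTRUE(man$conditioned)
  class(out) <- c("intent_dataset", class(out))
  out
}

run_config_schema <- list(
  seed = "integer",
  out = "character",
  design = c("n_participants", "n_activities", "n_trials_per_activity",
             "trial_duration", "category_map"),
  sensors = c("n_semg", "n_imu", "informativeness_semg",
              "informativeness_imu", "mvic_reference"),
  conditioning = c("low_cut", "high_cut", "order"),
  window = c("length", "step"),
  features = c("preset", "ar_order", "ar_method", "imu_mode", "standardise"),
  classifier = c("k", "p"),
  fusion = c("smoothing", "n_repeats"),
  # n_dropped / n_sensors are the canonical sweep-range keys ("N" is a
  # boolean in YAML 1.1); the bare aliases remain accepted from R lists
  experiments = c("which", "horizons", "horizon", "n_sensors", "n_dropped",
                  "R", "N", "n_combos", "n_repetitions")
)

#' Validate a pipeline run configuration
#'
#' Checks the block structure against the published schema before any
#' computation: unknown blocks or keys are rejected, and cross-field
#' constraints (e.g. a dropout count at or above the sensor count) fail
#' here rather than mid-run.
#'
#' @param config A nested list (or path to a YAML file).
#' @return The validated config list, invisibly.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), names(run_config_schema))
  if (length(unknown)) {
    abort(paste0("validate_run_config(): unknown blocks: ",
                 paste(unknown, collapse = ", ")))
  }
  for (blk in setdiff(names(config), c("seed", "out"))) {
    bad <- setdiff(names(config[[blk]]), run_config_schema[[blk]])
    if (length(bad)) {
      abort(paste0("validate_run_config(): unknown keys in `", blk, "`: ",
                   paste(bad, collapse = ", ")))
    }
  }
  if (is.null(config$seed)) abort("validate_run_config(): `seed` required")
  n_sensors <- (config$sensors$n_semg %||% 12) +
    (config$sensors$n_imu %||% 12)
  n_drop <- config$experiments[["n_dropped"]] %||% config$experiments[["N"]]
  if (!is.null(n_drop) && max(n_drop) >= n_sensors) {
    abort("validate_run_config(): dropout N must be below the sensor count")
  }
  n_sens <- config$experiments[["n_sensors"]] %||% config$experiments[["R"]]
  if (!is.null(n_sens) && max(n_sens) > n_sensors) {
    abort("validate_run_config(): sensor count R exceeds the network size")
  }
  invisible(config)
}

config_design <- function(config) {
  d <- config$design %||% list()
  trial_design(d$n_participants %||% 5, d$n_activities %||% 11,
               d$n_trials_per_activity %||% 3, d$trial_duration %||% 1000,
               d$category_map)
}

config_sensors <- function(config) {
  s <- config$sensors %||% list()
  args <- list(n_semg = s$n_semg %||% 12, n_imu = s$n_imu %||% 12)
  if (!is.null(s$informativeness_semg)) {
    args$informativeness_semg <- s$informativeness_semg
  }
  if (!is.null(s$informativeness_imu)) {
    args$informativeness_imu <- s$informativeness_imu
  }
  if (!is.null(s$mvic_reference)) args$mvic_reference <- s$mvic_reference
  do.call(sensor_network, args)
}

#' Run the full simulate-to-experiments pipeline
#'
#' Generates a dataset from the configured design, conditions it, and runs
#' the requested experiments, writing every result as tab-separated text
#' together with the resolved configuration (including the seed) so the run
#' can be reproduced exactly.
#'
#' @param config Nested configuration list or path to a YAML file; see
#'   [validate_run_config()] for the schema.
#' @param out_dir Output directory (overrides `config$out`).
#' @return Named list of `sweep_result` objects, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_run_config(config)
  out_dir <- out_dir %||% config$out %||% abort("run_pipeline(): no output dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  design <- config_design(config)
  sensors <- config_sensors(config)
  dataset <- generate_dataset(design, sensors, seed = derive_seed(seed, "data"))

  fspec <- filter_spec(config$conditioning$low_cut %||% 10,
                       config$conditioning$high_cut %||% 500,
                       config$conditioning$order %||% 4)
  dataset <- condition_dataset(dataset, fspec)
  wspec <- window_spec(config$window$length %||% 200,
                       config$window$step %||% 50,
                       design$trial_duration)
  fcfg <- feature_config(config$features$preset %||% "standard",
                         config$features$ar_order %||% 4,
                         config$features$ar_method %||% "burg",
                         config$features$imu_mode %||% "last")
  smoothing <- config$fusion$smoothing %||% 1
  n_repeats <- config$fusion$n_repeats %||% 5
  ex <- config$experiments %||% list()
  which <- ex$which %||% c("time", "sensors", "dropout")

  results <- list()
  if ("time" %in% which) {
    results$time <- time_sweep(
      dataset, horizons = ex$horizons %||% seq(200, design$trial_duration, 50),
      seed = derive_seed(seed, "time"), n_repeats = n_repeats,
      smoothing = smoothing, window = wspec, config = fcfg)
  }
  if ("sensors" %in% which) {
    results$sensors <- sensor_count_sweep(
      dataset, R = ex[["n_sensors"]] %||% ex[["R"]],
      n_combos = ex$n_combos %||% 50,
      seed = derive_seed(seed, "sensors"), horizon = ex[["horizon"]],
      n_repeats = n_repeats, smoothing = smoothing, window = wspec,
      config = fcfg)
  }
  if ("dropout" %in% which) {
    results$dropout <- dropout_sweep(
      dataset, N = ex[["n_dropped"]] %||% ex[["N"]],
      n_combos = ex$n_combos %||% 50,
      n_repetitions = ex$n_repetitions %||% 20,
      seed = derive_seed(seed, "dropout"), horizon = ex[["horizon"]],
      n_repeats = n_repeats, smoothing = smoothing, window = wspec,
      config = fcfg)
  }

  for (nm in names(results)) {
    readr::write_tsv(tidy(results[[nm]]),
                     file.path(out_dir, paste0(nm, "_sweep.tsv")))
    ratio <- attr(results[[nm]], "ratio")
    if (!is.null(ratio)) {
      readr::write_tsv(ratio$by_value,
                       file.path(out_dir, paste0(nm, "_ratio.tsv")))
    }
    rho <- attr(results[[nm]], "spearman")
    if (!is.null(rho)) {
      readr::write_tsv(tibble(method = names(rho),
                              spearman_rho = unlist(rho)),
                       file.path(out_dir, paste0(nm, "_spearman.tsv")))
    }
  }
  resolved <- config
  resolved$resolved <- list(package_version = as.character(
    utils::packageVersion("intentfuse")), seed = seed)
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
  invisible(results)
}
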