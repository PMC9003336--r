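#' Feature-extraction configuration
#'
#' The sEMG per-window feature set follows the standard time/frequency list:
#' integrated EMG (IEMG), mean absolute value (MAV), mean absolute value
#' slope (MAVS), variance (VAR), root mean square (RMS), waveform length
#' (WL), autoregressive coefficients to order `ar_order` (AR1..AR4), median
#' frequency (FMD) and mean frequency (FMN).
#'
#' Two presets are provided. `"standard"` (default) drops MAVS, giving 11
#' features per sEMG window: MAVS is a cross-window difference rather than a
#' within-window statistic, and 11 is the per-sensor count the fusion network
#' is built around. `"full"` keeps all 12.
#'
#' IMU sensors contribute the raw orientation quaternion (4), accelerometer
#' (3) and magnetometer (3) values: 10 features. `imu_mode` selects whether
#' these are taken from the last sample at or before the horizon (default) or
#' averaged over all samples up to it.
#'
#' @param preset `"standard"` or `"full"`.
#' @param ar_order Autoregressive model order (default 4).
#' @param ar_method `"burg"` (default) or `"ls"` (explicit least squares).
#' @param imu_mode `"last"` or `"mean"`.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(preset = c("standard", "full"), ar_order = 4,
                           ar_method = c("burg", "ls"),
                           imu_mode = c("last", "mean")) {
  preset <- match.arg(preset)
  ar_method <- match.arg(ar_method)
  imu_mode <- match.arg(imu_mode)
  if (ar_order < 1) abort("feature_config(): ar_order >= 1")
  semg <- c("IEMG", "MAV", if (preset == "full") "MAVS", "VAR", "RMS", "WL",
            paste0("AR", seq_len(ar_order)), "FMD", "FMN")
  structure(list(preset = preset, ar_order = as.integer(ar_order),
                 ar_method = ar_method, imu_mode = imu_mode,
                 semg_features = semg, imu_features = imu_channels),
            class = "feature_config")
}

ar_coefficients <- function(x, order, method) {
  if (length(x) < order + 1 || sd(x) == 0) return(rep(0, order))
  if (method == "burg") {
    fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
    co <- fit$ar
  } else {
    xd <- x - mean(x)
    n <- length(xd)
    y <- xd[(order + 1):n]
    X <- vapply(seq_len(order), function(k) xd[(order + 1 - k):(n - k)],
                numeric(n - order))
    co <- tryCatch(solve(crossprod(X), crossprod(X, y))[, 1],
                   error = function(e) rep(0, order))
  }
  out <- rep(0, order)
  out[seq_along(co)] <- co
  out
}

spectral_stats <- function(x, fs) {
  x0 <- x - mean(x)
  n <- length(x0)
  p <- Mod(fft(x0))^2
  k <- seq_len(floor(n / 2))
  p <- p[k + 1]
  f <- k * fs / n
  tot <- sum(p)
  if (tot <= 0) return(c(FMD = 0, FMN = 0))
  fmd <- f[which(cumsum(p) >= tot / 2)[1]]
  c(FMD = fmd, FMN = sum(f * p) / tot)
}

#' Per-window sEMG features
#'
#' Computes the configured feature vector on one window of MVIC-normalised
#' sEMG: `IEMG = sum(|x|)`, `MAV = mean(|x|)`,
#' `MAVS = MAV - prev_window_mav` (0 for the first window of a trial),
#' `VAR = sum(x^2) / (N - 1)`, `RMS = sqrt(mean(x^2))`,
#' `WL = sum(|diff(x)|)`, AR coefficients `a_1..a_p` of
#' `x_t = sum_k a_k x_{t-k} + e_t`, and the periodogram median (FMD) and
#' power-weighted mean (FMN) frequencies in Hz.
#'
#' @param window Numeric window of length `N >= ar_order + 1`.
#' @param fs Sampling rate in Hz (for the spectral features).
#' @param prev_window_mav MAV of the previous window of the same trial, or
#'   `NULL` for the first window.
#' @param config A [feature_config()].
#' @return Named numeric vector matching `config$semg_features`.
#' @examples
#' semg_features(rnorm(200), fs = 1000)
#' @export
semg_features <- function(window, fs, prev_window_mav = NULL,
                          config = feature_config()) {
  n <- length(window)
  if (n < config$ar_order + 1) {
    abort("semg_features(): window shorter than ar_order + 1 samples")
  }
  mav <- mean(abs(window))
  vals <- c(
    IEMG = sum(abs(window)),
    MAV = mav,
    MAVS = mav - (prev_window_mav %||% mav),
    VAR = sum(window^2) / (n - 1),
    RMS = sqrt(mean(window^2)),
    WL = sum(abs(diff(window)))
  )
  ar <- ar_coefficients(window, config$ar_order, config$ar_method)
  names(ar) <- paste0("AR", seq_along(ar))
  out <- c(vals, ar, spectral_stats(window, fs))
  out[config$semg_features]
}

#' Per-trial IMU features at a horizon
#'
#' Returns the raw orientation (4), accelerometer (3) and magnetometer (3)
#' values of the last sample at or before `horizon` (or their mean up to the
#' horizon when `config$imu_mode == "mean"`): 10 values.
#'
#' @param sensor_mat Matrix with a `time_ms` column followed by the 10 IMU
#'   channels.
#' @param horizon Milliseconds; at least one sample must lie at or before it.
#' @param config A [feature_config()].
#' @return Named numeric vector of length 10.
#' @export
imu_features <- function(sensor_mat, horizon, config = feature_config()) {
  keep <- which(sensor_mat[, "time_ms"] <= horizon)
  if (!length(keep)) abort("imu_features(): no sample at or before horizon")
  x <- sensor_mat[keep, -1, drop = FALSE]
  out <- if (config$imu_mode == "last") x[nrow(x), ] else colMeans(x)
  setNames(as.numeric(out), colnames(sensor_mat)[-1])
}

#' Assemble per-sensor feature matrices for a dataset
#'
#' For each sEMG sensor, the trial signal up to `horizon` is segmented with
#' `window` and one feature row per (trial, window) is computed; for each IMU
#' sensor one row per trial is taken at the horizon. Row order is canonical
#' (trials sorted by `trial_id`, windows in time order) and identical across
#' sensors, and category labels are attached at trial granularity.
#'
#' Feature columns are standardised (z-scored) per sensor using dataset-level
#' statistics by default, so that columns with heterogeneous units (MVIC
#' amplitudes, Hz, quaternion components) contribute comparably to distance
#' computations; set `standardise = FALSE` for raw features.
#'
#' Trials missing any sensor stream are excluded with a message.
#'
#' @param dataset A conditioned `intent_dataset`.
#' @param horizon Classification horizon in ms.
#' @param window A [window_spec()] (its `horizon` field is overridden by
#'   `horizon`).
#' @param config A [feature_config()].
#' @param standardise Z-score feature columns?
#' @param scaling Optional `feature_bank` whose per-sensor `center`/`scale`
#'   are reused instead of recomputing them, so that feature scaling can be
#'   frozen (e.g. at the full-horizon statistics) across a horizon sweep.
#' @return A list of class `feature_bank`: `sensors` (a tibble with one row
#'   per sensor holding the feature matrix `X`, its row identity `rows`, the
#'   standardisation `center`/`scale` and the standardised all-zero input
#'   `zero_row`), `trials` (trial labels), plus the horizon and configuration.
#' @export
extract_features <- function(dataset, horizon = NULL,
                             window = window_spec(),
                             config = feature_config(),
                             standardise = TRUE, scaling = NULL) {
  design <- attr(dataset, "design")
  horizon <- horizon %||% design$trial_duration
  sensors <- attr(dataset, "sensors")

  # exclude trials that are missing any sensor stream
  cnt <- table(dataset$trial_id)
  complete <- names(cnt)[cnt == nrow(sensors)]
  dropped <- setdiff(unique(dataset$trial_id), complete)
  if (length(dropped)) {
    inform(paste0("extract_features(): excluding ", length(dropped),
                  " trial(s) with missing sensor streams: ",
                  paste(head(dropped, 5), collapse = ", ")))
  }
  dataset <- dataset[dataset$trial_id %in% complete, ]

  trials <- dataset |>
    dplyr::distinct(.data$trial_id, .data$participant, .data$activity,
                    .data$category) |>
    arrange(.data$trial_id)

  wspec <- window_spec(window$length, window$step, horizon)
  sensor_rows <- lapply(seq_len(nrow(sensors)), function(i) {
    s <- sensors[i, ]
    sub <- dataset[dataset$sensor_id == s$sensor_id, ]
    sub <- sub[match(trials$trial_id, sub$trial_id), ]
    if (s$modality == "semg") {
      per_trial <- lapply(sub$data, function(m) {
        wins <- slide_windows(m[, 2], wspec, fs = s$fs)
        mavs <- vapply(wins, function(w) mean(abs(w)), numeric(1))
        t(vapply(seq_along(wins), function(wi) {
          semg_features(wins[[wi]], fs = s$fs,
                        prev_window_mav = if (wi > 1) mavs[wi - 1],
                        config = config)
        }, numeric(length(config$semg_features))))
      })
      n_win <- vapply(per_trial, nrow, integer(1))
      X <- do.call(rbind, per_trial)
      rows <- tibble(
        trial_id = rep(trials$trial_id, n_win),
        window = unlist(lapply(n_win, seq_len)),
        t_end = (unlist(lapply(n_win, seq_len)) - 1) * wspec$step +
          wspec$length
      )
    } else {
      X <- t(vapply(sub$data, imu_features, numeric(10),
                    horizon = horizon, config = config))
      rows <- tibble(trial_id = trials$trial_id, window = 1L,
                     t_end = horizon)
    }
    if (!all(is.finite(X))) {
      abort(paste0("extract_features(): non-finite features for sensor ",
                   s$sensor_id))
    }
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
    if (!is.null(scaling)) {
      j <- match(s$sensor_id, scaling$sensors$sensor_id)
      if (is.na(j)) abort("extract_features(): sensor missing from `scaling`")
      ctr <- scaling$sensors$center[[j]]
      scl <- scaling$sensors$scale[[j]]
      X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    } else if (standardise) {
      ctr <- colMeans(X)
      scl <- apply(X, 2, sd)
      scl[scl == 0] <- 1
      X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    }
    tibble(sensor_id = s$sensor_id, modality = s$modality,
           n_features = ncol(X),
           features = list(colnames(X)),
           X = list(X), rows = list(rows),
           center = list(ctr), scale = list(scl),
           zero_row = list((0 - ctr) / scl))
  })

  structure(
    list(sensors = bind_rows(sensor_rows), trials = trials,
         horizon = horizon, window = wspec, config = config,
         standardise = standardise),
    class = "feature_bank"
  )
}

#' @export
print.feature_bank <- function(x, ...) {
  cat("<feature_bank> ", nrow(x$trials), " trials, ", nrow(x$sensors),
      " sensors, horizon ", x$horizon, " ms\n", sep = "")
  invisible(x)
}
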