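#' Band-pass filter specification
#'
#' Fourth-order Butterworth band-pass at 10--500 Hz by default, the standard
#' sEMG conditioning band. `order` follows the MATLAB `butter()` convention:
#' it is the order of the low-pass prototype, so the band-pass filter has
#' `2 * order` poles.
#'
#' @param low_cut,high_cut Band edges in Hz, `0 < low_cut < high_cut`.
#' @param order Prototype filter order, `>= 1`.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 10, high_cut = 500, order = 4) {
  if (!(low_cut > 0 && high_cut > low_cut)) {
    abort("filter_spec(): need 0 < low_cut < high_cut")
  }
  if (order < 1) abort("filter_spec(): order >= 1")
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), family = "butterworth"),
            class = "filter_spec")
}

#' Sliding-window specification
#'
#' Defaults to 200 ms windows shifted in 50 ms steps (150 ms overlap) over a
#' 1000 ms classification horizon.
#'
#' @param length,step,horizon Milliseconds, `0 < step <= length <= horizon`.
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(length = 200, step = 50, horizon = 1000) {
  if (!(step > 0 && step <= length && length <= horizon)) {
    abort("window_spec(): need 0 < step <= length <= horizon")
  }
  structure(list(length = length, step = step, horizon = horizon),
            class = "window_spec")
}

#' Apply a causal Butterworth band-pass filter
#'
#' Single-pass (causal) filtering, consistent with eventual real-time use;
#' output length equals input length. If `high_cut` is at or above the
#' Nyquist frequency it is clipped to `0.99 * fs / 2` with a warning, since a
#' digital band edge at Nyquist is undefined.
#'
#' @param x Numeric signal vector.
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz; must exceed `2 * low_cut`.
#' @return Filtered numeric vector, same length as `x`.
#' @examples
#' bandpass(sin(2 * pi * 100 * (1:500) / 1000), filter_spec(), fs = 1000)
#' @export
bandpass <- function(x, spec = filter_spec(), fs) {
  stopifnot(inherits(spec, "filter_spec"))
  if (fs <= 2 * spec$low_cut) {
    abort("bandpass(): fs must exceed 2 * low_cut")
  }
  high <- spec$high_cut
  nyq <- fs / 2
  if (high >= nyq) {
    high <- 0.99 * nyq
    warn(sprintf("bandpass(): high_cut clipped to %.6g Hz (0.99 x Nyquist)",
                 high))
  }
  bf <- signal::butter(spec$order, c(spec$low_cut, high) / nyq, type = "pass")
  as.numeric(signal::filter(bf, x))
}

#' Normalise a signal to its MVIC reference amplitude
#'
#' @param x Numeric signal.
#' @param mvic_reference Positive reference amplitude (peak signal of the
#'   maximal voluntary isometric contraction test for that muscle).
#' @return `x / mvic_reference`, dimensionless MVIC units.
#' @export
mvic_normalise <- function(x, mvic_reference) {
  if (!is.finite(mvic_reference) || mvic_reference <= 0) {
    abort("mvic_normalise(): mvic_reference must be > 0")
  }
  x / mvic_reference
}

#' Truncate every sensor stream of a dataset to a horizon
#'
#' Removes all samples with `time_ms > horizon` from every trial and sensor.
#'
#' @param dataset An `intent_dataset`.
#' @param horizon Milliseconds; must not exceed the trial duration.
#' @return The truncated dataset (trial duration attribute updated).
#' @export
truncate_trials <- function(dataset, horizon) {
  design <- attr(dataset, "design")
  if (!is.null(design) && horizon > design$trial_duration) {
    abort("truncate_trials(): horizon exceeds trial duration")
  }
  out <- dataset
  out$data <- lapply(out$data, function(m) m[m[, "time_ms"] <= horizon, ,
                                             drop = FALSE])
  if (!is.null(design)) {
    design$trial_duration <- as.double(horizon)
    attr(out, "design") <- design
  }
  out
}

#' Segment a signal into overlapping sliding windows
#'
#' Windows of `spec$length` ms shifted by `spec$step` ms, covering
#' `[0, spec$horizon]`: window `i` spans
#' `((i - 1) * step, (i - 1) * step + length]` ms. The number of windows is
#' `floor((horizon - length) / step) + 1`; consecutive windows overlap by
#' `length - step` ms.
#'
#' @param x Numeric signal sampled at `fs` Hz with samples at
#'   `time_ms = (1:n) / fs * 1000`; must cover at least one window length.
#' @param spec A [window_spec()].
#' @param fs Sampling rate in Hz.
#' @return A list of numeric windows, in time order.
#' @examples
#' length(slide_windows(rnorm(1000), window_spec(), fs = 1000)) # 17
#' @export
slide_windows <- function(x, spec = window_spec(), fs) {
  stopifnot(inherits(spec, "window_spec"))
  n_needed <- round(spec$length * fs / 1000)
  if (length(x) < n_needed) {
    abort("slide_windows(): signal shorter than one window length")
  }
  horizon <- min(spec$horizon, length(x) / fs * 1000)
  n_win <- floor((horizon - spec$length) / spec$step) + 1
  lapply(seq_len(n_win), function(i) {
    start_ms <- (i - 1) * spec$step
    i0 <- round(start_ms * fs / 1000) + 1
    x[i0:(i0 + n_needed - 1)]
  })
}

#' Condition a raw dataset
#'
#' Applies the standard conditioning chain: band-pass filtering of the sEMG
#' channels (IMU channels are left unfiltered), MVIC normalisation of the
#' sEMG amplitudes, and truncation to the classification horizon. The applied
#' operations are recorded in the `conditioning` attribute.
#'
#' @param dataset An `intent_dataset` from [generate_dataset()] or
#'   [read_dataset()].
#' @param filter A [filter_spec()] or `NULL` to skip filtering.
#' @param horizon Truncation horizon in ms (default: full trial duration).
#' @param normalise Apply MVIC normalisation to sEMG channels?
#' @return The conditioned dataset.
#' @export
condition_dataset <- function(dataset, filter = filter_spec(),
                              horizon = NULL, normalise = TRUE) {
  sensors <- attr(dataset, "sensors")
  design <- attr(dataset, "design")
  out <- dataset
  mvic <- setNames(sensors$mvic_reference, sensors$sensor_id)
  fsv <- setNames(sensors$fs, sensors$sensor_id)

  is_semg <- out$modality == "semg"
  if (any(is_semg)) {
    seen_warn <- character()
    out$data[is_semg] <- purrr::map2(
      out$data[is_semg], out$sensor_id[is_semg],
      function(m, sid) {
        x <- m[, 2]
        if (!is.null(filter)) {
          # surface each distinct filtering warning (e.g. Nyquist clipping)
          # once per call rather than once per trial
          x <- withCallingHandlers(
            bandpass(x, filter, fs = fsv[[sid]]),
            warning = function(w) {
              if (conditionMessage(w) %in% seen_warn) {
                invokeRestart("muffleWarning")
              }
              seen_warn <<- c(seen_warn, conditionMessage(w))
            }
          )
        }
        if (normalise) x <- mvic_normalise(x, mvic[[sid]])
        m[, 2] <- x
        m
      }
    )
  }
  if (!is.null(horizon)) out <- truncate_trials(out, horizon)
  attr(out, "conditioned") <- TRUE
  attr(out, "conditioning") <- list(filter = filter, horizon = horizon,
                                    normalise = normalise)
  out
}
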