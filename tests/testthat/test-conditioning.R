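test_that("band-pass preserves the passband and attenuates the stopband", {
  fs <- 1000
  t <- seq_len(4000) / fs
  # the default 500 Hz edge sits at Nyquist for fs = 1000, so the clipping
  # warning (tested separately) is expected here
  in_band <- sin(2 * pi * 100 * t)
  out <- suppressWarnings(bandpass(in_band, filter_spec(), fs = fs))
  expect_equal(length(out), length(in_band))
  # steady state after the transient
  expect_lt(abs(max(abs(out[2000:4000])) - 1), 0.1)

  below <- sin(2 * pi * 1 * t)
  out_lo <- suppressWarnings(bandpass(below, filter_spec(), fs = fs))
  expect_lt(max(abs(out_lo[3000:4000])), 0.1)

  expect_identical(suppressWarnings(bandpass(rep(0, 500), filter_spec(),
                                             fs = fs)),
                   rep(0, 500))
})

test_that("filter gain matches the designed transfer function", {
  # oracle: evaluate |H(e^{i w})| directly from the designed polynomials
  fs <- 1000
  spec <- filter_spec(10, 400, 4)
  bf <- signal::butter(spec$order, c(10, 400) / (fs / 2), type = "pass")
  gain_at <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    abs(sum(bf$b * z^(seq_along(bf$b) - 1)) /
          sum(bf$a * z^(seq_along(bf$a) - 1)))
  }
  t <- seq_len(8000) / fs
  for (f in c(50, 100, 200)) {
    out <- bandpass(sin(2 * pi * f * t), spec, fs = fs)
    # steady-state amplitude from the RMS over an integer number of cycles
    amp <- sqrt(2 * mean(out[5001:8000]^2))
    expect_equal(amp, gain_at(f), tolerance = 0.02)
  }
})

test_that("filtering is linear and commutes with normalisation", {
  fs <- 1000
  set.seed(9)
  x <- rnorm(1000); y <- rnorm(1000)
  spec <- filter_spec(10, 450)
  fx <- bandpass(x, spec, fs); fy <- bandpass(y, spec, fs)
  fxy <- bandpass(2 * x + 3 * y, spec, fs)
  expect_equal(fxy, 2 * fx + 3 * fy, tolerance = 1e-9)
  expect_equal(bandpass(mvic_normalise(x, 2.5), spec, fs),
               mvic_normalise(bandpass(x, spec, fs), 2.5),
               tolerance = 1e-9)
})

test_that("a band edge at Nyquist is clipped with a warning", {
  expect_warning(bandpass(rnorm(300), filter_spec(10, 500), fs = 1000),
                 "clipped")
  expect_error(bandpass(rnorm(300), filter_spec(10, 500), fs = 15),
               "fs must exceed")
})

test_that("MVIC normalisation is plain division with a guarded reference", {
  expect_equal(mvic_normalise(rep(3, 10), 3), rep(1, 10))
  expect_equal(mvic_normalise(rep(3, 10), 6), rep(0.5, 10))
  expect_equal(mvic_normalise(rep(0, 10), 2), rep(0, 10))
  expect_error(mvic_normalise(1:5, 0), "must be > 0")
  expect_error(mvic_normalise(1:5, -2), "must be > 0")
})

test_that("truncation keeps exactly the samples inside the horizon", {
  ds <- tiny_dataset()
  tr <- truncate_trials(ds, 200)
  expect_equal(nrow(tr$data[[which(tr$modality == "semg")[1]]]), 200)
  n_imu_full <- nrow(truncate_trials(ds, 1000)$data[[
    which(ds$modality == "imu")[1]]])
  expect_equal(n_imu_full, 60)
  expect_identical(truncate_trials(ds, 1000)$data, ds$data)
  expect_error(truncate_trials(ds, 1500), "exceeds trial duration")
})

test_that("window segmentation follows the stated arithmetic", {
  x <- rnorm(1000)
  expect_length(slide_windows(x, window_spec(200, 50, 1000), 1000), 17)
  expect_length(slide_windows(x[1:200], window_spec(200, 50, 200), 1000), 1)
  w <- slide_windows(x[1:250], window_spec(200, 50, 250), 1000)
  expect_length(w, 2)
  # consecutive windows overlap by 150 ms = 150 samples at 1000 Hz
  expect_identical(w[[1]][51:200], w[[2]][1:150])
  expect_error(slide_windows(x[1:100], window_spec(200, 50, 1000), 1000),
               "shorter than one window")
  expect_error(window_spec(200, 0, 1000))
  expect_error(window_spec(200, 300, 1000))
})

test_that("window counts match a brute-force enumeration oracle", {
  set.seed(31)
  for (i in seq_len(200)) {
    len <- sample(50:400, 1)
    step <- sample(10:len, 1)
    horizon <- len + sample(0:1200, 1)
    n_oracle <- 0
    start <- 0
    while (start + len <= horizon) {
      n_oracle <- n_oracle + 1
      start <- start + step
    }
    x <- rnorm(ceiling(horizon)) # 1000 Hz: 1 sample per ms
    got <- length(slide_windows(x, window_spec(len, step, horizon), 1000))
    expect_equal(got, n_oracle)
  }
})

test_that("conditioning filters and normalises sEMG but leaves IMU raw", {
  ds <- tiny_dataset(seed = 2)
  cd <- condition_quiet(ds)
  imu_rows <- which(ds$modality == "imu")
  expect_identical(cd$data[imu_rows], ds$data[imu_rows])
  semg_rows <- which(ds$modality == "semg")
  expect_false(identical(cd$data[semg_rows], ds$data[semg_rows]))
  expect_true(isTRUE(attr(cd, "conditioned")))
  # filtering + normalisation only touch the value column, not timestamps
  expect_identical(cd$data[[semg_rows[1]]][, "time_ms"],
                   ds$data[[semg_rows[1]]][, "time_ms"])
})
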