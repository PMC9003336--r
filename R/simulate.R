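#' Generate a synthetic multimodal trial dataset
#'
#' Emulates a laboratory reach/grasp intent-sensing collection: each trial is
#' a labelled execution of one activity by one participant, recorded
#' simultaneously by every sensor in the network. sEMG-like sensors produce a
#' broadband Gaussian carrier amplitude-modulated by a smooth, burst-like
#' envelope (sums of logistic ramps); IMU-like sensors produce smooth
#' minimum-jerk orientation/acceleration kinematics with a magnetometer given
#' by a fixed field rotated into the body frame, all with additive noise.
#'
#' Category- and activity-specific envelope/trajectory components are scaled
#' by the sensor's `informativeness` and by a ramp in elapsed time, so
#' class-conditional signal means diverge increasingly with time since
#' activity inception (later classification horizons are easier), and a
#' sensor with informativeness 0 produces class-independent signals.
#' Per-participant random gains and offsets induce participant structure.
#'
#' All randomness derives from `seed` via [derive_seed()] sub-streams, so the
#' same seed always reproduces the dataset exactly.
#'
#' @param design A [trial_design()].
#' @param sensors A [sensor_network()] tibble.
#' @param seed Integer root seed.
#' @return A tibble of class `intent_dataset` with one row per
#'   (trial, sensor): columns `trial_id`, `participant`, `activity`,
#'   `category`, `sensor_id`, `modality`, `fs`, and `data` (a list column of
#'   matrices whose first column is `time_ms`). Attributes `design`,
#'   `sensors` and `seed` carry the provenance.
#' @examples
#' ds <- generate_dataset(trial_design(1, 2, 1), sensor_network(1, 1), seed = 1)
#' dplyr::count(ds, trial_id)
#' @export
generate_dataset <- function(design = trial_design(),
                             sensors = sensor_network(),
                             seed) {
  if (!inherits(design, "trial_design")) {
    abort("generate_dataset(): `design` must be a trial_design()")
  }
  if (nrow(sensors) < 1) abort("generate_dataset(): at least one sensor")
  stopifnot(is.numeric(seed), length(seed) == 1)
  n_cat <- max(design$category_map)

  # class/sensor structure: drawn once per sensor, shared by all trials
  struct <- lapply(seq_len(nrow(sensors)), function(i) {
    s <- sensors[i, ]
    with_seed(derive_seed(seed, "struct", s$sensor_id), {
      if (s$modality == "semg") {
        semg_structure(n_cat, design$n_activities)
      } else {
        imu_structure(n_cat, design$n_activities)
      }
    })
  })
  names(struct) <- sensors$sensor_id

  # per-participant effects per sensor
  pfx <- lapply(sensors$sensor_id, function(sid) {
    lapply(seq_len(design$n_participants), function(p) {
      with_seed(derive_seed(seed, "participant", p, sid), {
        list(gain = exp(rnorm(1, 0, 0.05)),
             offset = rnorm(1, 0, 0.04),
             angle_gain = exp(rnorm(1, 0, 0.04)),
             acc_gain = exp(rnorm(1, 0, 0.10)))
      })
    })
  })
  names(pfx) <- sensors$sensor_id

  grid <- expand.grid(trial = seq_len(design$n_trials_per_activity),
                      activity = seq_len(design$n_activities),
                      participant = seq_len(design$n_participants))
  rows <- vector("list", nrow(grid) * nrow(sensors))
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    p <- grid$participant[g]; a <- grid$activity[g]; r <- grid$trial[g]
    cat_a <- design$category_map[a]
    trial_id <- sprintf("P%02d_A%02d_T%02d", p, a, r)
    # execution variability is a property of the movement, not the sensor:
    # every sensor observes the same expression strength, onset, pace and
    # vigor, which correlates classification errors across sensors
    exec <- with_seed(derive_seed(seed, "execution", trial_id), {
      list(expression = runif(1, 0.35, 1),
           onset = rnorm(1, 0, 25),
           pace = exp(rnorm(1, 0, 0.05)),
           vigor = exp(rnorm(1, 0, 0.08)))
    })
    for (i in seq_len(nrow(sensors))) {
      s <- sensors[i, ]
      tseed <- derive_seed(seed, "trial", trial_id, s$sensor_id)
      dat <- with_seed(tseed, {
        if (s$modality == "semg") {
          gen_semg_trial(struct[[s$sensor_id]], pfx[[s$sensor_id]][[p]],
                         exec, cat_a, a, s$informativeness,
                         s$mvic_reference, s$fs, design$trial_duration)
        } else {
          gen_imu_trial(struct[[s$sensor_id]], pfx[[s$sensor_id]][[p]],
                        exec, cat_a, a, s$informativeness,
                        s$fs, design$trial_duration)
        }
      })
      k <- k + 1L
      rows[[k]] <- tibble(
        trial_id = trial_id, participant = p, activity = a,
        category = cat_a, sensor_id = s$sensor_id, modality = s$modality,
        fs = s$fs, data = list(dat)
      )
    }
  }
  out <- bind_rows(rows)
  attr(out, "design") <- design
  attr(out, "sensors") <- sensors
  attr(out, "seed") <- as.integer(seed)
  attr(out, "conditioned") <- FALSE
  class(out) <- c("intent_dataset", class(out))
  out
}

# logistic ramp centred at tau with width w
ramp <- function(t, tau, w) 1 / (1 + exp(-(t - tau) / w))

semg_structure <- function(n_cat, n_act) {
  list(
    base_amp = runif(1, 0.15, 0.30),
    base_tau = runif(1, 250, 600),
    base_w = runif(1, 80, 150),
    cat = lapply(seq_len(n_cat), function(c) {
      list(a = runif(2, 0.40, 1.00), tau = runif(2, 150, 850),
           w = runif(2, 40, 120))
    }),
    act = lapply(seq_len(n_act), function(a) {
      list(a = runif(1, 0.10, 0.30), tau = runif(1, 150, 850),
           w = runif(1, 40, 120))
    })
  )
}

gen_semg_trial <- function(st, pe, exec, cat, act, inform, mvic, fs,
                           duration) {
  n <- round(fs * duration / 1000)
  t <- (1:n) / fs * 1000
  u <- t / duration
  jit <- exec$onset
  cs <- st$cat[[cat]]
  as_ <- st$act[[act]]
  cat_env <- cs$a[1] * ramp(t, cs$tau[1] + jit, cs$w[1]) +
    cs$a[2] * ramp(t, cs$tau[2] + jit, cs$w[2])
  act_env <- 0.35 * as_$a[1] * ramp(t, as_$tau[1] + jit, as_$w[1])
  # category divergence accumulates over the whole horizon; within-category
  # (activity-level) idiosyncrasies express early and then saturate
  env <- pe$gain * exec$vigor *
    (0.10 + st$base_amp * ramp(t, st$base_tau + jit, st$base_w) +
       inform * exec$expression *
         (u * cat_env + pmin(u / 0.6, 1) * act_env)) + pe$offset
  env <- pmax(env, 0.02)
  x <- mvic * env * rnorm(n)
  cbind(time_ms = t, emg = x)
}

runit3 <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

imu_structure <- function(n_cat, n_act) {
  list(
    axis0 = runit3(),
    theta0 = runif(1, 0.2, 0.6),
    mag_field = runit3(),
    acc_dir = runit3(),
    acc_amp = runif(1, 0.5, 1.5),
    cat = lapply(seq_len(n_cat), function(c) {
      list(axis = runit3(), dtheta = runif(1, 0.5, 1.2))
    }),
    act = lapply(seq_len(n_act), function(a) {
      list(axis = runit3(), dtheta = runif(1, 0.15, 0.40))
    })
  )
}

# rotation matrix of unit quaternion (w, x, y, z)
quat_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

gen_imu_trial <- function(st, pe, exec, cat, act, inform, fs, duration) {
  n <- round(fs * duration / 1000)
  t <- (1:n) / fs * 1000
  u <- pmin(t / duration * exec$pace, 1)
  mj <- 10 * u^3 - 15 * u^4 + 6 * u^5          # minimum-jerk position profile
  mjdd <- 60 * u - 180 * u^2 + 120 * u^3        # its curvature profile

  cs <- st$cat[[cat]]; as_ <- st$act[[act]]
  # endpoint/axis jitter is sensor-frame-specific and stays private
  ax <- st$axis0 + inform * (cs$axis + 0.35 * as_$axis) + rnorm(3, 0, 0.10)
  ax <- ax / sqrt(sum(ax^2))
  # category rotation unfolds over the full horizon; the activity-level
  # deviation is a faster movement that completes early
  mj_fast <- {
    uf <- pmin(u / 0.6, 1)
    10 * uf^3 - 15 * uf^4 + 6 * uf^5
  }
  theta <- pe$angle_gain * exec$vigor *
    ((st$theta0 + inform * exec$expression * cs$dtheta) * mj +
       inform * exec$expression * 0.35 * as_$dtheta * mj_fast)

  qc <- cbind(cos(theta / 2), sin(theta / 2) %o% ax) # noise-free orientation
  q <- qc + matrix(rnorm(n * 4, 0, 0.04), n, 4)
  q <- q / sqrt(rowSums(q^2))

  # gravity read in the rotating body frame carries the class information;
  # the dynamic component is sensor-specific, not class-specific
  gravity <- c(0, 0, 9.81)
  grav_body <- t(vapply(seq_len(n), function(i) {
    crossprod(quat_rotmat(qc[i, ]), gravity)[, 1]
  }, numeric(3)))
  acc <- grav_body +
    (mjdd %o% (pe$acc_gain * exec$vigor * st$acc_amp * st$acc_dir)) +
    matrix(rnorm(n * 3, 0, 0.3), n, 3)

  mag <- t(vapply(seq_len(n), function(i) {
    crossprod(quat_rotmat(q[i, ]), st$mag_field)[, 1]
  }, numeric(3))) + matrix(rnorm(n * 3, 0, 0.05), n, 3)

  out <- cbind(t, q, acc, mag)
  colnames(out) <- c("time_ms", imu_channels)
  out
}

#' @export
print.intent_dataset <- function(x, ...) {
  d <- attr(x, "design")
  cat("<intent_dataset> ", length(unique(x$trial_id)), " trials x ",
      length(unique(x$sensor_id)), " sensors",
      if (isTRUE(attr(x, "conditioned"))) " (conditioned)", "\n", sep = "")
  NextMethod()
}

#' Between-/within-class separability of one sensor's signals
#'
#' Diagnostic for the generator (and for real data): summarises each trial's
#' signal up to `horizon` (for sEMG the rectified-mean/RMS amplitude
#' trajectory over 200 ms segments; for IMU the channel values at 200 ms
#' checkpoints) and accumulates, over the summary dimensions, the
#' between-category to within-category dispersion ratio of each dimension
#' (each normalised by its degrees of freedom) -- a diagonal Mahalanobis
#' separation between the class means. Extending the horizon appends
#' dimensions, so the score accumulates discriminative information over
#' time. Its absolute value grows with the number of dimensions even for
#' noise, so informativeness is judged against the label-permutation
#' distribution ([separability_permutation_test()]), not against zero.
#'
#' @param dataset An `intent_dataset`.
#' @param sensor_id One sensor identifier present in `dataset`.
#' @param horizon Only samples with `time_ms <= horizon` are used.
#' @return A non-negative number (0 when there is no dispersion at all).
#' @examples
#' ds <- generate_dataset(trial_design(2, 2, 2), sensor_network(1, 0), 1)
#' class_separability(ds, "semg01", 1000)
#' @export
class_separability <- function(dataset, sensor_id, horizon) {
  rows <- dataset[dataset$sensor_id == sensor_id, ]
  if (!nrow(rows)) abort(paste0("class_separability(): unknown sensor_id '",
                                sensor_id, "'"))
  dur <- attr(dataset, "design")$trial_duration
  if (!is.null(dur) && horizon > dur) {
    abort("class_separability(): horizon exceeds trial duration")
  }
  # the per-dimension ratio is scale-invariant, so no standardisation needed
  fisher_ratio(trial_summaries(rows, horizon), rows$category)
}

# per-trial summary vectors mirroring what the classifiers consume:
# sEMG -> the amplitude trajectory (rectified mean and RMS of each complete
# 200 ms segment up to the horizon); IMU -> the channel values at each
# 200 ms checkpoint up to the horizon. Later horizons append dimensions
# instead of diluting earlier ones.
trial_summaries <- function(rows, horizon) {
  nseg <- max(1, floor(horizon / 200))
  out <- lapply(rows$data, function(m) {
    tms <- m[, "time_ms"]
    if (ncol(m) == 2) {
      unlist(lapply(seq_len(nseg), function(k) {
        x <- m[tms > (k - 1) * 200 & tms <= k * 200, 2]
        c(mean(abs(x)), sqrt(mean(x^2)))
      }))
    } else {
      unlist(lapply(seq_len(nseg), function(k) {
        i <- max(which(tms <= k * 200))
        as.numeric(m[i, -1])
      }))
    }
  })
  do.call(rbind, out)
}

# sum over dimensions of the df-normalised between/within dispersion ratio
# (per-dimension F statistics); dimensions with no dispersion at all
# contribute 0, perfectly separated dimensions contribute Inf
fisher_ratio <- function(z, cls) {
  groups <- split(seq_len(nrow(z)), cls)
  if (length(groups) < 2) return(0)
  n <- nrow(z); C <- length(groups)
  total <- 0
  for (d in seq_len(ncol(z))) {
    v <- z[, d]
    mu <- mean(v)
    between <- sum(vapply(groups, function(idx) {
      length(idx) * (mean(v[idx]) - mu)^2
    }, numeric(1)))
    within <- sum(vapply(groups, function(idx) {
      sum((v[idx] - mean(v[idx]))^2)
    }, numeric(1)))
    if (within <= .Machine$double.eps) {
      if (between > .Machine$double.eps) return(Inf)
    } else {
      total <- total + (between / (C - 1)) / (within / (n - C))
    }
  }
  total
}

#' Permutation test for class separability
#'
#' Compares [class_separability()] of a sensor against its distribution under
#' random permutations of the category labels. For an uninformative sensor
#' the observed score is exchangeable with the permuted scores and the test
#' does not reject.
#'
#' @inheritParams class_separability
#' @param n_perm Number of label permutations.
#' @param seed Seed for the permutations.
#' @return A list with `statistic`, `p_value` and `n_perm`.
#' @export
separability_permutation_test <- function(dataset, sensor_id, horizon,
                                          n_perm = 99, seed = 1) {
  rows <- dataset[dataset$sensor_id == sensor_id, ]
  if (!nrow(rows)) abort("separability_permutation_test(): unknown sensor_id")
  obs <- class_separability(dataset, sensor_id, horizon)
  cls <- rows$category
  summ <- trial_summaries(rows, horizon)
  perm <- with_seed(derive_seed(seed, "septest"), {
    vapply(seq_len(n_perm), function(i) fisher_ratio(summ, sample(cls)),
           numeric(1))
  })
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}
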