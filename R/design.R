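#' Describe a trial-collection design
#'
#' A design records how many participants performed how many activities, how
#' many repetitions of each, the trial duration, and how activities group into
#' intent categories (the classification target). The default mirrors a
#' laboratory reach/grasp protocol: 5 participants x 11 activities x 3 trials
#' (165 trials), 1000 ms per trial, with the 11 activities grouped into 3
#' categories (reach-to-grasp, reach, gross motor).
#'
#' @param n_participants,n_activities,n_trials_per_activity Positive counts.
#' @param trial_duration Trial duration in milliseconds.
#' @param category_map Integer vector of length `n_activities` giving the
#'   category index of each activity. Defaults to
#'   [default_category_map()]`(n_activities)`.
#' @return A list of class `trial_design`.
#' @examples
#' trial_design() # the 165-trial default
#' trial_design(3, 6, 2)
#' @export
trial_design <- function(n_participants = 5,
                         n_activities = 11,
                         n_trials_per_activity = 3,
                         trial_duration = 1000,
                         category_map = NULL) {
  counts <- c(n_participants = n_participants, n_activities = n_activities,
              n_trials_per_activity = n_trials_per_activity)
  bad <- counts[!is.finite(counts) | counts < 1 | counts != floor(counts)]
  if (length(bad)) {
    abort(paste0("trial_design(): counts must be positive integers; got ",
                 paste(names(bad), "=", bad, collapse = ", ")))
  }
  if (!is.finite(trial_duration) || trial_duration <= 0) {
    abort("trial_design(): trial_duration must be a positive number of ms")
  }
  category_map <- category_map %||% default_category_map(n_activities)
  category_map <- as.integer(category_map)
  if (length(category_map) != n_activities || anyNA(category_map)) {
    abort("trial_design(): category_map must give one category per activity")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_activities = as.integer(n_activities),
         n_trials_per_activity = as.integer(n_trials_per_activity),
         trial_duration = as.double(trial_duration),
         category_map = category_map),
    class = "trial_design"
  )
}

#' Default grouping of activities into intent categories
#'
#' For 11 activities the grouping is the reach/grasp protocol split:
#' activities 1-4 (reach-to-grasp variants) -> category 1, 5-8 (reach
#' variants) -> category 2, 9-11 (gross motor tasks) -> category 3. For other
#' activity counts, activities are divided into `n_categories` contiguous,
#' approximately equal groups.
#'
#' @param n_activities Number of activities.
#' @param n_categories Number of intent categories (default 3, capped at
#'   `n_activities`).
#' @return Integer vector of length `n_activities`.
#' @examples
#' default_category_map(11)
#' default_category_map(6)
#' @export
default_category_map <- function(n_activities, n_categories = 3) {
  n_categories <- min(n_categories, n_activities)
  if (n_activities == 11 && n_categories == 3) {
    return(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L))
  }
  sort(rep_len(seq_len(n_categories), n_activities))
}

#' @export
print.trial_design <- function(x, ...) {
  cat("<trial_design> ", x$n_participants, " participants x ",
      x$n_activities, " activities x ", x$n_trials_per_activity,
      " trials = ", n_trials(x), " trials, ", x$trial_duration, " ms, ",
      length(unique(x$category_map)), " categories\n", sep = "")
  invisible(x)
}

#' Total number of trials implied by a design
#' @param design A [trial_design()].
#' @return Integer trial count.
#' @export
n_trials <- function(design) {
  design$n_participants * design$n_activities * design$n_trials_per_activity
}

imu_channels <- c("q_w", "q_x", "q_y", "q_z",
                  "acc_x", "acc_y", "acc_z",
                  "mag_x", "mag_y", "mag_z")

#' Build a sensor network specification
#'
#' One row per sensor: identifier, modality (`"semg"` at 1000 Hz or `"imu"`
#' at 60 Hz), sampling rate, informativeness in `[0, 1]` (how strongly the
#' sensor's signal separates the intent categories; 0 means the signal is
#' statistically independent of the category), and, for sEMG, the per-channel
#' MVIC reference amplitude used for normalisation.
#'
#' The default network has 12 sEMG + 12 IMU sensors with heterogeneous
#' informativeness per modality, from strongly informative down to
#' near-uninformative, emulating a body-worn network in which some placements
#' barely see the task.
#'
#' @param n_semg,n_imu Number of sensors per modality.
#' @param informativeness_semg,informativeness_imu Numeric vectors recycled to
#'   the modality's sensor count; all values must lie in `[0, 1]`.
#' @param mvic_reference MVIC reference amplitudes for the sEMG sensors
#'   (recycled), in raw signal units.
#' @return A tibble of class `sensor_network` with columns `sensor_id`,
#'   `modality`, `fs`, `informativeness`, `mvic_reference`.
#' @examples
#' sensor_network()
#' sensor_network(n_semg = 2, n_imu = 1, informativeness_semg = c(1, 0))
#' @export
sensor_network <- function(n_semg = 12, n_imu = 12,
                           informativeness_semg = default_informativeness(n_semg),
                           informativeness_imu = default_informativeness(n_imu),
                           mvic_reference = 1) {
  stopifnot(n_semg >= 0, n_imu >= 0, n_semg + n_imu >= 1)
  inf_s <- rep_len(informativeness_semg, n_semg)
  inf_i <- rep_len(informativeness_imu, n_imu)
  if (any(c(inf_s, inf_i) < 0 | c(inf_s, inf_i) > 1)) {
    abort("sensor_network(): informativeness must lie in [0, 1]")
  }
  mvic <- rep_len(mvic_reference, n_semg)
  if (n_semg && any(mvic <= 0)) {
    abort("sensor_network(): mvic_reference must be > 0")
  }
  spec <- bind_rows(
    if (n_semg) tibble(
      sensor_id = sprintf("semg%02d", seq_len(n_semg)),
      modality = "semg", fs = 1000,
      informativeness = inf_s, mvic_reference = mvic
    ),
    if (n_imu) tibble(
      sensor_id = sprintf("imu%02d", seq_len(n_imu)),
      modality = "imu", fs = 60,
      informativeness = inf_i, mvic_reference = NA_real_
    )
  )
  class(spec) <- c("sensor_network", class(spec))
  spec
}

#' Default heterogeneous informativeness profile
#'
#' A fixed, geometrically decaying profile from moderately strong (0.7) to
#' near-uninformative (0.02), so a default network mixes a few sensors that
#' carry much of the signal, many that carry some, and a couple that carry
#' almost none. The levels are calibrated so that individual sensors
#' classify three intent categories well above chance but far from
#' perfectly, while a full 24-sensor network reaches high (but not
#' saturated) accuracy -- the regime in which fusion weighting matters.
#'
#' @param n Number of sensors.
#' @return Numeric vector of length `n`.
#' @export
default_informativeness <- function(n) {
  base <- c(0.60, 0.55, 0.50, 0.45, 0.40, 0.38,
            0.35, 0.30, 0.28, 0.25, 0.06, 0.02)
  rep_len(base, n)
}
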