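# small fixtures shared across test files; everything is generated in code

tiny_network <- function() {
  sensor_network(2, 2,
                 informativeness_semg = c(0.7, 0.2),
                 informativeness_imu = c(0.6, 0.1))
}

tiny_dataset <- function(seed = 1, n_participants = 2, n_activities = 3,
                         n_trials = 2, net = tiny_network()) {
  generate_dataset(
    trial_design(n_participants, n_activities, n_trials, 1000,
                 default_category_map(n_activities, 3)),
    net, seed = seed)
}

# conditioning always clips the 500 Hz band edge at fs = 1000; the warning is
# expected and not what these tests are about
condition_quiet <- function(ds, ...) {
  suppressWarnings(condition_dataset(ds, ...))
}

random_confusion <- function(C, concentration = 1) {
  probs <- matrix(stats::rgamma(C * C, concentration), C, C)
  probs <- probs / rowSums(probs)
  counts <- round(probs * 100)
  structure(list(classes = seq_len(C), counts = counts, probs = probs,
                 smoothing = 0, sensor_id = NA_character_),
            class = "sensor_confusion")
}
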