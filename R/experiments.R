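#' Leave-one-out cross-validation folds
#'
#' One fold per trial: that trial is the testing set and every other trial
#' forms the training pool.
#'
#' @param trials A tibble with a `trial_id` column (e.g. the `trials` element
#'   of a [extract_features()] bank), or an `intent_dataset`.
#' @return A tibble with columns `fold`, `test_trial` and `train`
#'   (list column of training trial ids).
#' @examples
#' loocv_folds(tibble::tibble(trial_id = c("a", "b", "c")))
#' @export
loocv_folds <- function(trials) {
  ids <- sort(unique(trials$trial_id))
  if (length(ids) < 2) abort("loocv_folds(): need at least 2 trials")
  tibble(fold = seq_along(ids), test_trial = ids,
         train = lapply(seq_along(ids), function(i) ids[-i]))
}

#' Split a training pool into Classifier Training and Probability Learning
#' halves
#'
#' Pseudo-randomly halves the pool so that each (participant, activity)
#' stratum splits as evenly as possible (replicate trials of a stratum are
#' assigned at random) while keeping the marginal per-participant and
#' per-activity counts of the two halves within one trial of each other.
#' A greedy randomised assignment of the odd-stratum leftovers enforces the
#' marginal balance; the construction is deterministic given `seed`.
#'
#' @param trials Tibble with columns `trial_id`, `participant`, `activity`
#'   (one row per pool trial).
#' @param seed Integer seed.
#' @return A list with character vectors `classifier_training` and
#'   `probability_learning`.
#' @export
balanced_split <- function(trials, seed) {
  if (!nrow(trials)) abort("balanced_split(): empty training pool")
  for (attempt in seq_len(100)) {
    res <- with_seed(derive_seed(seed, "balsplit", attempt),
                     greedy_split(trials))
    if (split_balanced(res, trials)) return(res)
  }
  warn("balanced_split(): marginal balance not achieved after 100 attempts")
  res
}

greedy_split <- function(trials) {
  participants <- sort(unique(trials$participant))
  activities <- sort(unique(trials$activity))
  dp <- setNames(rep(0, length(participants)), participants)
  da <- setNames(rep(0, length(activities)), activities)
  dt <- 0
  a_ids <- character(); b_ids <- character()
  strata <- split(seq_len(nrow(trials)),
                  paste(trials$participant, trials$activity))
  for (sn in sample(names(strata))) {
    idx <- strata[[sn]]
    idx <- if (length(idx) > 1) sample(idx) else idx
    k <- length(idx) %/% 2
    p <- as.character(trials$participant[idx[1]])
    a <- as.character(trials$activity[idx[1]])
    if (k > 0) {
      a_ids <- c(a_ids, trials$trial_id[idx[seq_len(k)]])
      b_ids <- c(b_ids, trials$trial_id[idx[k + seq_len(k)]])
    }
    if (length(idx) %% 2 == 1) {
      extra <- trials$trial_id[idx[length(idx)]]
      cost_a <- abs(dp[p] + 1) + abs(da[a] + 1) + 0.5 * abs(dt + 1)
      cost_b <- abs(dp[p] - 1) + abs(da[a] - 1) + 0.5 * abs(dt - 1)
      to_a <- if (cost_a != cost_b) cost_a < cost_b else runif(1) < 0.5
      if (to_a) {
        a_ids <- c(a_ids, extra); dp[p] <- dp[p] + 1
        da[a] <- da[a] + 1; dt <- dt + 1
      } else {
        b_ids <- c(b_ids, extra); dp[p] <- dp[p] - 1
        da[a] <- da[a] - 1; dt <- dt - 1
      }
    }
  }
  list(classifier_training = sort(a_ids), probability_learning = sort(b_ids))
}

split_balanced <- function(res, trials) {
  ina <- trials$trial_id %in% res$classifier_training
  ca <- table(trials$participant[ina])
  cb <- table(trials$participant[!ina])
  lv <- union(names(ca), names(cb))
  pa <- ifelse(is.na(ca[lv]), 0, ca[lv]); pb <- ifelse(is.na(cb[lv]), 0, cb[lv])
  ca2 <- table(trials$activity[ina]); cb2 <- table(trials$activity[!ina])
  lv2 <- union(names(ca2), names(cb2))
  aa <- ifelse(is.na(ca2[lv2]), 0, ca2[lv2])
  ab <- ifelse(is.na(cb2[lv2]), 0, cb2[lv2])
  all(abs(pa - pb) <= 1) && all(abs(aa - ab) <= 1) &&
    abs(sum(ina) - sum(!ina)) <= 1
}

# ---------------------------------------------------------------------------
# direct (reference) training path over a feature bank

bank_row_ids <- function(rows) sprintf("%s#%03d", rows$trial_id, rows$window)

sensor_train_rows <- function(bank, i, trial_ids, horizon = NULL) {
  rows <- bank$sensors$rows[[i]]
  keep <- rows$trial_id %in% trial_ids
  if (!is.null(horizon)) keep <- keep & rows$t_end <= horizon
  which(keep)
}

#' Optimise the Classifier-Training / Probability-Learning split
#'
#' Draws `n_repeats` candidate [balanced_split()]s of the training pool;
#' for each, trains one classifier per sensor on the Classifier Training
#' half, estimates every sensor's confusion matrix on the Probability
#' Learning half, and keeps the candidate with the highest mean
#' [sensor_accuracy()] across sensors (ties go to the lowest repeat index).
#'
#' @param bank A [extract_features()] feature bank.
#' @param train_ids Character vector of pool trial ids.
#' @param seed Integer seed (candidate `r` uses
#'   `derive_seed(seed, "rep", r)`).
#' @param n_repeats Number of candidate splits (default 5).
#' @param smoothing Confusion-matrix pseudo-count.
#' @param k,p Classifier hyperparameters (see [knn_fit()]).
#' @return A list with the chosen `split`, per-sensor `models` and `cms`
#'   (named by sensor), `mean_accuracy`, and `repeat_index`.
#' @export
optimise_split <- function(bank, train_ids, seed, n_repeats = 5,
                           smoothing = 1, k = 1, p = 0.5) {
  trials <- bank$trials[bank$trials$trial_id %in% train_ids, ]
  classes <- sort(unique(bank$trials$category))
  best <- NULL
  for (r in seq_len(n_repeats)) {
    sp <- balanced_split(trials, derive_seed(seed, "rep", r))
    models <- list(); cms <- list()
    for (i in seq_len(nrow(bank$sensors))) {
      sid <- bank$sensors$sensor_id[i]
      ct <- sensor_train_rows(bank, i, sp$classifier_training)
      rows <- bank$sensors$rows[[i]]
      X <- bank$sensors$X[[i]]
      lab <- bank$trials$category[match(rows$trial_id, bank$trials$trial_id)]
      m <- windowed_knn_fit(X[ct, , drop = FALSE], lab[ct], rows$window[ct],
                            k = k, p = p, row_id = bank_row_ids(rows[ct, ]))
      preds <- vapply(sp$probability_learning, function(t) {
        q <- which(rows$trial_id == t)
        predict_trial(m, X[q, , drop = FALSE], rows$window[q])
      }, classes[1])
      truth <- bank$trials$category[match(sp$probability_learning,
                                          bank$trials$trial_id)]
      cms[[sid]] <- estimate_confusion(truth, preds, classes, smoothing,
                                       sensor_id = sid)
      models[[sid]] <- m
    }
    macc <- mean(vapply(cms, sensor_accuracy, numeric(1)))
    if (is.null(best) || macc > best$mean_accuracy) {
      best <- list(split = sp, models = models, cms = cms,
                   mean_accuracy = macc, repeat_index = r)
    }
  }
  best
}

#' Run a single leave-one-out fold
#'
#' Trains the requested method on the fold's training pool and classifies
#' the held-out trial. For the modular method (`"mm"`) the per-sensor
#' classifiers and confusion matrices come from [optimise_split()], only
#' `active_sensors` contribute to the fusion, and the decision is the fused
#' posterior argmax. For the non-modular method (`"nmm"`) a single combined
#' classifier is trained on the full pool and inactive sensors' feature
#' columns are zero-filled.
#'
#' @param bank A feature bank (already at the desired horizon).
#' @param fold A list/row with `test_trial` and `train` (see
#'   [loocv_folds()]).
#' @param method `"mm"` or `"nmm"`.
#' @param active_sensors Character vector of active sensor ids (default
#'   all).
#' @param seed Seed for the split optimisation.
#' @param n_repeats,smoothing,prior,k,p Method parameters.
#' @return A list with `correct`, `decision`, `truth` and `method`.
#' @export
run_fold <- function(bank, fold, method = c("mm", "nmm"),
                     active_sensors = NULL, seed = 1, n_repeats = 5,
                     smoothing = 1, prior = NULL, k = 1, p = 0.5) {
  method <- match.arg(method)
  test_id <- fold$test_trial
  train_ids <- unlist(fold$train)
  active_sensors <- active_sensors %||% bank$sensors$sensor_id
  truth <- bank$trials$category[match(test_id, bank$trials$trial_id)]
  classes <- sort(unique(bank$trials$category))

  if (method == "mm") {
    fit <- optimise_split(bank, train_ids,
                          seed = derive_seed(seed, "fold", test_id),
                          n_repeats = n_repeats, smoothing = smoothing,
                          k = k, p = p)
    preds <- lapply(active_sensors, function(sid) {
      i <- match(sid, bank$sensors$sensor_id)
      rows <- bank$sensors$rows[[i]]
      q <- which(rows$trial_id == test_id)
      predict_trial(fit$models[[sid]],
                    bank$sensors$X[[i]][q, , drop = FALSE], rows$window[q])
    })
    names(preds) <- active_sensors
    fr <- fuse(preds, fit$cms,
               prior = prior %||% setNames(rep(1 / length(classes),
                                               length(classes)), classes))
    # with no active sensors the decision comes back as a prior name;
    # map it onto the class vector so the type always matches the labels
    decision <- classes[match(as.character(decide(fr)),
                              as.character(classes))]
  } else {
    cf <- combined_features(bank)
    in_train <- cf$rows$trial_id %in% train_ids
    lab <- bank$trials$category[match(cf$rows$trial_id[in_train],
                                      bank$trials$trial_id)]
    m <- windowed_knn_fit(cf$X[in_train, , drop = FALSE], lab,
                          cf$rows$window[in_train], k = k, p = p,
                          row_id = bank_row_ids(cf$rows[in_train, ]))
    q <- which(cf$rows$trial_id == test_id)
    Xq <- cf$X[q, , drop = FALSE]
    dropped <- which(cf$col_sensor %in%
                       setdiff(bank$sensors$sensor_id, active_sensors))
    if (length(dropped)) {
      Xq[, dropped] <- matrix(cf$zero_row[dropped], nrow(Xq),
                              length(dropped), byrow = TRUE)
    }
    decision <- vote_labels(predict(m, Xq, windows = cf$rows$window[q]))
  }
  list(correct = identical(decision, truth), decision = decision,
       truth = truth, method = method)
}

# ---------------------------------------------------------------------------
# fast sweep engine: exact 1-NN reformulation over per-sensor distance blocks

build_harness <- function(dataset, horizons, window = window_spec(),
                          config = feature_config(), standardise = TRUE,
                          p = 0.5) {
  stopifnot(inherits(dataset, "intent_dataset"))
  if (!isTRUE(attr(dataset, "conditioned"))) {
    dataset <- condition_dataset(dataset)
  }
  hmax <- max(horizons)
  bank <- extract_features(dataset, hmax, window, config, standardise)
  sensors <- bank$sensors
  trials <- bank$trials
  semg <- which(sensors$modality == "semg")
  imu <- which(sensors$modality == "imu")

  G_semg <- lapply(seq_len(nrow(sensors)), function(i) NULL)
  z_semg <- G_semg
  for (i in semg) {
    G_semg[[i]] <- minkowski_cross(sensors$X[[i]], sensors$X[[i]], p)
    z_semg[[i]] <- as.numeric(minkowski_cross(
      matrix(sensors$zero_row[[i]], 1), sensors$X[[i]], p))
  }
  wrows <- if (length(semg)) {
    sensors$rows[[semg[1]]]
  } else {
    tibble(trial_id = trials$trial_id, window = 1L, t_end = hmax)
  }
  rows_of_trial <- split(seq_len(nrow(wrows)), wrows$trial_id)
  rows_of_trial <- rows_of_trial[trials$trial_id]
  # trial x window-position index into the sEMG feature/distance rows
  row_mat <- do.call(rbind, rows_of_trial)

  # per-horizon IMU feature distance blocks (scaling frozen at hmax stats)
  imu_h <- lapply(horizons, function(h) {
    lapply(seq_len(nrow(sensors)), function(i) {
      if (!(i %in% imu)) return(NULL)
      sid <- sensors$sensor_id[i]
      sub <- dataset[dataset$sensor_id == sid, ]
      sub <- sub[match(trials$trial_id, sub$trial_id), ]
      X <- t(vapply(sub$data, imu_features, numeric(10), horizon = h,
                    config = bank$config))
      X <- sweep(sweep(X, 2, sensors$center[[i]]), 2,
                 sensors$scale[[i]], "/")
      list(G = minkowski_cross(X, X, p),
           z = as.numeric(minkowski_cross(matrix(sensors$zero_row[[i]], 1),
                                          X, p)))
    })
  })
  names(imu_h) <- as.character(horizons)

  list(dataset = dataset, bank = bank, sensors = sensors, trials = trials,
       classes = sort(unique(trials$category)),
       semg = semg, imu = imu, G_semg = G_semg, z_semg = z_semg,
       wrows = wrows, rows_of_trial = rows_of_trial, row_mat = row_mat,
       horizons = horizons, imu_h = imu_h, p = p)
}

# number of windows per trial fully inside [0, h]
n_windows_at <- function(harness, h) {
  if (!length(harness$semg)) return(1L)
  sum(harness$wrows$trial_id == harness$trials$trial_id[1] &
        harness$wrows$t_end <= h)
}

# per-fold, per-candidate-split MM statistics at one horizon
mm_cache <- function(harness, h, seed, n_repeats = 5, smoothing = 1) {
  trials <- harness$trials
  sensors <- harness$sensors
  classes <- harness$classes
  C <- length(classes)
  S <- nrow(sensors)
  Fn <- nrow(trials)
  acc <- array(NA_real_, c(Fn, n_repeats, S))
  Lg <- array(NA_real_, c(Fn, n_repeats, S, C))
  imu_blocks <- harness$imu_h[[as.character(h)]]

  for (f in seq_len(Fn)) {
    test_id <- trials$trial_id[f]
    pool <- trials[-f, ]
    fold_seed <- derive_seed(seed, "fold", test_id)
    for (r in seq_len(n_repeats)) {
      sp <- balanced_split(pool, derive_seed(fold_seed, "rep", r))
      ct <- sp$classifier_training
      pl <- sp$probability_learning
      truth_pl <- trials$category[match(pl, trials$trial_id)]
      ct_i <- match(ct, trials$trial_id)
      pl_i <- match(pl, trials$trial_id)
      nw <- n_windows_at(harness, h)
      for (i in seq_len(S)) {
        if (i %in% harness$semg) {
          col_lab <- trials$category[ct_i]
          G <- harness$G_semg[[i]]
          predmat <- matrix(col_lab[1], length(pl_i), nw)
          tpredw <- rep(col_lab[1], nw)
          for (w in seq_len(nw)) {
            ctc <- harness$row_mat[ct_i, w]
            D <- G[harness$row_mat[pl_i, w], ctc, drop = FALSE]
            predmat[, w] <- col_lab[max.col(-D, ties.method = "first")]
            dt <- G[harness$row_mat[f, w], ctc]
            tpredw[w] <- col_lab[which.min(dt)]
          }
          preds <- apply(predmat, 1, vote_labels)
          tpred <- vote_labels(tpredw)
        } else {
          G <- imu_blocks[[i]]$G
          cti <- match(ct, trials$trial_id)
          pli <- match(pl, trials$trial_id)
          D <- G[pli, cti, drop = FALSE]
          col_lab <- trials$category[cti]
          preds <- col_lab[max.col(-D, ties.method = "first")]
          Dt <- G[f, cti, drop = FALSE]
          tpred <- col_lab[max.col(-Dt, ties.method = "first")]
        }
        cm <- estimate_confusion(truth_pl, preds, classes, smoothing)
        acc[f, r, i] <- sensor_accuracy(cm)
        Lg[f, r, i, ] <- log(cm$probs[, match(tpred, classes)])
      }
    }
  }
  list(acc = acc, L = Lg, classes = classes,
       truth = trials$category, n_repeats = n_repeats)
}

# fused MM fold decisions for an active-sensor subset, given a cache and a
# per-fold chosen candidate split
mm_decisions <- function(cache, active_idx, chosen, prior = NULL) {
  Fn <- dim(cache$L)[1]
  C <- length(cache$classes)
  lp <- log(rep_len(prior %||% rep(1 / C, C), C) /
              sum(rep_len(prior %||% rep(1 / C, C), C)))
  scores <- matrix(lp, Fn, C, byrow = TRUE)
  if (length(active_idx)) {
    for (c in seq_len(C)) {
      M <- cache$L[cbind(rep(seq_len(Fn), length(active_idx)),
                         rep(chosen, length(active_idx)),
                         rep(active_idx, each = Fn),
                         c)]
      scores[, c] <- scores[, c] + rowSums(matrix(M, Fn))
    }
  }
  # tolerance-based argmax so floating-point summation order cannot break
  # exact ties differently from fuse(): lowest class index wins
  rowmax <- apply(scores, 1, max)
  cache$classes[max.col((scores >= rowmax - 1e-9) * 1L,
                        ties.method = "first")]
}

# chosen candidate split per fold: argmax over repeats of the mean
# Probability-Learning accuracy across the given sensors
mm_choose_rep <- function(cache, sensor_idx) {
  Fn <- dim(cache$acc)[1]
  vapply(seq_len(Fn), function(f) {
    m <- cache$acc[f, , sensor_idx, drop = FALSE]
    which.max(apply(m, 2, mean)) # ties -> lowest repeat index
  }, integer(1))
}

# NMM fold decisions at horizon h with `active` sensors live and the rest
# zero-filled (set `retrained = TRUE` to restrict to the active columns
# instead, i.e. a model trained on exactly that sensor combination)
nmm_decisions <- function(harness, h, active_idx, retrained = FALSE) {
  trials <- harness$trials
  Fn <- nrow(trials)
  act_semg <- intersect(active_idx, harness$semg)
  act_imu <- intersect(active_idx, harness$imu)
  drop_semg <- setdiff(harness$semg, act_semg)
  drop_imu <- setdiff(harness$imu, act_imu)
  imu_blocks <- harness$imu_h[[as.character(h)]]

  S_semg <- NULL
  if (length(act_semg)) {
    S_semg <- Reduce(`+`, harness$G_semg[act_semg])
  }
  z_semg <- NULL
  if (!retrained && length(drop_semg)) {
    z_semg <- Reduce(`+`, harness$z_semg[drop_semg])
  }
  S_imu <- NULL
  if (length(act_imu)) {
    S_imu <- Reduce(`+`, lapply(imu_blocks[act_imu], `[[`, "G"))
  }
  z_imu <- NULL
  if (!retrained && length(drop_imu)) {
    z_imu <- Reduce(`+`, lapply(imu_blocks[drop_imu], `[[`, "z"))
  }

  nw <- n_windows_at(harness, h)
  vapply(seq_len(Fn), function(f) {
    train_i <- seq_len(Fn)[-f]
    col_lab <- trials$category[train_i]
    # per-training-trial contribution shared by every window position
    base <- numeric(length(train_i))
    if (!is.null(S_imu)) base <- base + S_imu[f, train_i]
    if (!is.null(z_imu)) base <- base + z_imu[train_i]
    predw <- vapply(seq_len(nw), function(w) {
      cols <- harness$row_mat[train_i, w]
      d <- base
      if (!is.null(S_semg)) d <- d + S_semg[harness$row_mat[f, w], cols]
      if (!is.null(z_semg)) d <- d + z_semg[cols]
      col_lab[which.min(d)]
    }, col_lab[1])
    vote_labels(predw)
  }, trials$category[1])
}

# ---------------------------------------------------------------------------
# sweep results container

new_sweep_result <- function(df, variable, spearman = NULL, ratio = NULL,
                             details = NULL, params = list()) {
  attr(df, "variable") <- variable
  attr(df, "spearman") <- spearman
  attr(df, "ratio") <- ratio
  attr(df, "details") <- details
  attr(df, "params") <- params
  class(df) <- c("sweep_result", class(df))
  df
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> over ", attr(x, "variable"), "\n", sep = "")
  NextMethod()
  rho <- attr(x, "spearman")
  if (!is.null(rho)) {
    cat("Spearman rho vs ", attr(x, "variable"), ": ",
        paste(names(rho), round(unlist(rho), 3), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.sweep_result <- function(x, ...) {
  out <- x
  attributes(out)[c("variable", "spearman", "ratio", "details",
                    "params")] <- NULL
  class(out) <- setdiff(class(out), "sweep_result")
  as_tibble(out)
}

#' @export
glance.sweep_result <- function(x, ...) {
  rho <- attr(x, "spearman")
  x |>
    group_by(.data$method) |>
    summarise(mean_accuracy = mean(.data$accuracy),
              min_accuracy = min(.data$accuracy),
              max_accuracy = max(.data$accuracy), .groups = "drop") |>
    mutate(spearman_rho = if (is.null(rho)) NA_real_ else
      unlist(rho)[.data$method])
}

#' Accuracy ratio of the modular to the non-modular method
#'
#' Pointwise ratio of the two methods' mean accuracies at every swept value,
#' summarising the relative benefit of the modular method; the range is
#' reported because the ratio is not expected to be constant.
#'
#' @param x A `sweep_result` containing both methods.
#' @return A list of class `ratio_result`: `by_value` tibble plus `min`,
#'   `max` and `mean` of the ratio.
#' @export
accuracy_ratio <- function(x) {
  wide <- tidy(x) |>
    select("value", "method", "accuracy") |>
    tidyr::pivot_wider(names_from = "method", values_from = "accuracy")
  if (!all(c("mm", "nmm") %in% names(wide))) {
    abort("accuracy_ratio(): sweep must contain both methods")
  }
  by_value <- wide |>
    mutate(ratio = .data$mm / .data$nmm)
  structure(list(by_value = by_value,
                 min = min(by_value$ratio), max = max(by_value$ratio),
                 mean = mean(by_value$ratio)),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat("<ratio_result> MM/NMM accuracy ratio: mean ", round(x$mean, 3),
      ", range [", round(x$min, 3), ", ", round(x$max, 3), "]\n", sep = "")
  invisible(x)
}

#' Two-sided t confidence interval
#'
#' `mean(x) +/- t_{(1+level)/2, n-1} * sd(x) / sqrt(n)`.
#'
#' @param x Numeric vector with at least 2 values.
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
confidence_interval <- function(x, level = 0.95) {
  n <- length(x)
  if (n < 2) abort("confidence_interval(): need at least 2 values")
  half <- qt((1 + level) / 2, n - 1) * sd(x) / sqrt(n)
  c(lower = mean(x) - half, upper = mean(x) + half)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (the usual correction to the
#' classical 6*sum(d^2) formula, which assumes no ties). Returns 0 with a
#' warning when either series is constant (the coefficient is undefined).
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with `rho` and `n`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2 || isTRUE(sd(x) == 0) || isTRUE(sd(y) == 0)) {
    warn("spearman_rho(): constant series; returning 0")
    return(list(rho = 0, n = length(x)))
  }
  list(rho = as.numeric(cor(x, y, method = "spearman")), n = length(x))
}

# ---------------------------------------------------------------------------
# the three sweeps

#' Accuracy versus classification horizon
#'
#' Repeats the full leave-one-out evaluation with only the first `X` ms of
#' every trial available, for `X` over `horizons`, with all sensors active.
#' Feature standardisation is frozen at the full-horizon statistics so that
#' horizons differ only in the data they see. Reports accuracy per horizon
#' per method and the Spearman rank correlation of accuracy with horizon.
#'
#' @param dataset An `intent_dataset` (raw; conditioning is applied
#'   internally).
#' @param horizons Milliseconds (default 200 to 1000 in 50 ms steps).
#' @param methods Subset of `c("mm", "nmm")`.
#' @param seed Root seed for the split optimisation.
#' @param n_repeats Candidate splits per fold for the modular method.
#' @param smoothing Confusion-matrix pseudo-count.
#' @param window,config See [window_spec()], [feature_config()].
#' @param detail Keep per-fold decisions in the `details` attribute?
#' @return A `sweep_result` tibble (`value` = horizon ms) with a `spearman`
#'   attribute.
#' @export
time_sweep <- function(dataset, horizons = seq(200, 1000, by = 50),
                       methods = c("mm", "nmm"), seed = 1, n_repeats = 5,
                       smoothing = 1, window = window_spec(),
                       config = feature_config(), detail = FALSE) {
  design <- attr(dataset, "design")
  if (max(horizons) > design$trial_duration) {
    abort("time_sweep(): horizon exceeds trial duration")
  }
  methods <- match.arg(methods, c("mm", "nmm"), several.ok = TRUE)
  harness <- build_harness(dataset, horizons, window, config)
  S <- nrow(harness$sensors)
  truth <- harness$trials$category
  out <- list(); det <- list()
  for (h in horizons) {
    if ("mm" %in% methods) {
      cache <- mm_cache(harness, h, seed, n_repeats, smoothing)
      chosen <- mm_choose_rep(cache, seq_len(S))
      dec <- mm_decisions(cache, seq_len(S), chosen)
      out[[length(out) + 1]] <- tibble(
        variable = "horizon", value = h, method = "mm",
        accuracy = mean(dec == truth), lower = NA_real_, upper = NA_real_,
        n = length(truth))
      if (detail) det[[length(det) + 1]] <- tibble(
        value = h, method = "mm", test_trial = harness$trials$trial_id,
        decision = dec, correct = dec == truth)
    }
    if ("nmm" %in% methods) {
      dec <- nmm_decisions(harness, h, seq_len(S))
      out[[length(out) + 1]] <- tibble(
        variable = "horizon", value = h, method = "nmm",
        accuracy = mean(dec == truth), lower = NA_real_, upper = NA_real_,
        n = length(truth))
      if (detail) det[[length(det) + 1]] <- tibble(
        value = h, method = "nmm", test_trial = harness$trials$trial_id,
        decision = dec, correct = dec == truth)
    }
  }
  df <- bind_rows(out)
  rho <- lapply(split(df, df$method),
                function(d) spearman_rho(d$accuracy, d$value)$rho)
  new_sweep_result(df, "horizon", spearman = rho,
                   details = if (detail) bind_rows(det),
                   params = list(seed = seed, n_repeats = n_repeats,
                                 smoothing = smoothing))
}

#' Accuracy versus number of sensors (no dropout)
#'
#' For each sensor count `R`, both methods are trained and tested on
#' `n_combos` random combinations of `R` sensors (the methods know exactly
#' which sensors are present: the modular method fuses only those sensors'
#' classifiers and re-selects its split for that subset; the non-modular
#' model is restricted to those sensors' feature columns). Combinations are
#' nested across `R` (each random stream orders the sensors once and takes
#' the first `R`), which keeps every size uniform. Reports mean accuracy and
#' 95% t-intervals over combinations, and the MM/NMM accuracy ratio.
#'
#' @inheritParams time_sweep
#' @param R Sensor counts to test (default `1:n_sensors`).
#' @param n_combos Random sensor combinations per count (default 50).
#' @param horizon Classification horizon in ms (default: trial duration).
#' @param level Confidence level for the intervals.
#' @return A `sweep_result` (`value` = sensor count) with a `ratio`
#'   attribute.
#' @export
sensor_count_sweep <- function(dataset, R = NULL, n_combos = 50, seed = 1,
                               horizon = NULL, n_repeats = 5, smoothing = 1,
                               window = window_spec(),
                               config = feature_config(), level = 0.95) {
  design <- attr(dataset, "design")
  horizon <- horizon %||% design$trial_duration
  stopifnot(length(horizon) == 1)
  harness <- build_harness(dataset, horizon, window, config)
  S <- nrow(harness$sensors)
  R <- R %||% seq_len(S)
  if (max(R) > S) abort("sensor_count_sweep(): R exceeds the sensor count")
  if (n_combos < 1) abort("sensor_count_sweep(): n_combos >= 1")
  truth <- harness$trials$category
  cache <- mm_cache(harness, horizon, seed, n_repeats, smoothing)

  perms <- with_seed(derive_seed(seed, "combo"), {
    lapply(seq_len(n_combos), function(j) sample(S))
  })
  acc <- array(NA_real_, c(length(R), n_combos, 2),
               dimnames = list(NULL, NULL, c("mm", "nmm")))
  for (j in seq_len(n_combos)) {
    for (ri in seq_along(R)) {
      A <- perms[[j]][seq_len(R[ri])]
      chosen <- mm_choose_rep(cache, A)
      acc[ri, j, "mm"] <- mean(mm_decisions(cache, A, chosen) == truth)
      acc[ri, j, "nmm"] <- mean(nmm_decisions(harness, horizon, A,
                                              retrained = TRUE) == truth)
    }
  }
  if (S %in% R && n_combos > 1) {
    inform("sensor_count_sweep(): at R = n_sensors all combinations are the full network")
  }
  df <- bind_rows(lapply(c("mm", "nmm"), function(m) {
    bind_rows(lapply(seq_along(R), function(ri) {
      v <- acc[ri, , m]
      ci <- if (length(v) > 1) confidence_interval(v, level) else
        c(lower = NA_real_, upper = NA_real_)
      tibble(variable = "n_sensors", value = R[ri], method = m,
             accuracy = mean(v), lower = ci[["lower"]],
             upper = ci[["upper"]], n = length(v))
    }))
  }))
  res <- new_sweep_result(df, "n_sensors",
                          params = list(seed = seed, n_combos = n_combos,
                                        horizon = horizon))
  attr(res, "ratio") <- accuracy_ratio(res)
  res
}

#' Accuracy under simulated sensor dropout
#'
#' Both methods are trained once with every sensor active; then `N` randomly
#' chosen sensors "drop out". The modular method simply removes their
#' predictions (and confusion matrices) from the fusion -- no retraining;
#' the non-modular model cannot lose input dimensions, so the dropped
#' sensors' feature columns are fed the value a dead (all-zero) signal
#' produces. Each repetition draws `n_combos` nested random dropout
#' streams; accuracy per `N` is averaged over combinations within a
#' repetition, and the 95% t-interval is taken over repetition means.
#'
#' @inheritParams sensor_count_sweep
#' @param N Dropout counts (default `0:(n_sensors - 1)`).
#' @param n_repetitions Repetitions (default 20).
#' @return A `sweep_result` (`value` = number of dropped sensors) with a
#'   `ratio` attribute.
#' @export
dropout_sweep <- function(dataset, N = NULL, n_combos = 50,
                          n_repetitions = 20, seed = 1, horizon = NULL,
                          n_repeats = 5, smoothing = 1,
                          window = window_spec(),
                          config = feature_config(), level = 0.95) {
  design <- attr(dataset, "design")
  horizon <- horizon %||% design$trial_duration
  stopifnot(length(horizon) == 1)
  harness <- build_harness(dataset, horizon, window, config)
  S <- nrow(harness$sensors)
  N <- N %||% 0:(S - 1)
  if (max(N) >= S) abort("dropout_sweep(): N must be below the sensor count")
  truth <- harness$trials$category
  cache <- mm_cache(harness, horizon, seed, n_repeats, smoothing)
  chosen <- mm_choose_rep(cache, seq_len(S)) # trained on the full network

  acc <- array(NA_real_, c(length(N), n_repetitions, n_combos, 2),
               dimnames = list(NULL, NULL, NULL, c("mm", "nmm")))
  for (k in seq_len(n_repetitions)) {
    perms <- with_seed(derive_seed(seed, "dropout", k), {
      lapply(seq_len(n_combos), function(j) sample(S))
    })
    for (j in seq_len(n_combos)) {
      for (ni in seq_along(N)) {
        dropped <- if (N[ni] > 0) perms[[j]][seq_len(N[ni])] else integer(0)
        A <- setdiff(seq_len(S), dropped)
        acc[ni, k, j, "mm"] <- mean(mm_decisions(cache, A, chosen) == truth)
        acc[ni, k, j, "nmm"] <-
          mean(nmm_decisions(harness, horizon, A) == truth)
      }
    }
  }
  df <- bind_rows(lapply(c("mm", "nmm"), function(m) {
    bind_rows(lapply(seq_along(N), function(ni) {
      rep_means <- vapply(seq_len(n_repetitions),
                          function(k) mean(acc[ni, k, , m]), numeric(1))
      ci <- if (length(rep_means) > 1) confidence_interval(rep_means, level)
      else c(lower = NA_real_, upper = NA_real_)
      tibble(variable = "n_dropped", value = N[ni], method = m,
             accuracy = mean(rep_means), lower = ci[["lower"]],
             upper = ci[["upper"]], n = length(rep_means))
    }))
  }))
  res <- new_sweep_result(df, "n_dropped",
                          params = list(seed = seed, n_combos = n_combos,
                                        n_repetitions = n_repetitions,
                                        horizon = horizon))
  attr(res, "ratio") <- accuracy_ratio(res)
  res
}
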