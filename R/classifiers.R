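#' Fit a k-nearest-neighbour classifier
#'
#' A 1-NN classifier with a fractional Minkowski distance
#' `d(x, y) = sum_k |x_k - y_k|^p` with `p = 0.5` by default (for
#' nearest-neighbour queries only the ordering matters, so the outer
#' `1/p` root is omitted). Training rows are canonicalised by `row_id`
#' so that exact distance ties always resolve to the lowest canonical row,
#' making predictions invariant to the order the training data arrived in.
#'
#' @param x Numeric feature matrix (rows = training examples).
#' @param labels Vector of class labels, one per row.
#' @param k Number of neighbours (default 1).
#' @param p Distance exponent (default 0.5).
#' @param row_id Optional vector of unique row identifiers used to
#'   canonicalise the training order (default: input order).
#' @return An object of class `intent_knn`.
#' @examples
#' m <- knn_fit(matrix(c(0, 0, 1, 1), 2, 2), c("a", "b"))
#' predict(m, matrix(c(0.1, 0.1), 1, 2))
#' @export
knn_fit <- function(x, labels, k = 1, p = 0.5, row_id = NULL) {
  x <- as.matrix(x)
  if (nrow(x) == 0) abort("knn_fit(): empty training set")
  if (nrow(x) != length(labels)) abort("knn_fit(): one label per row")
  if (!all(is.finite(x))) abort("knn_fit(): non-finite features")
  if (k < 1) abort("knn_fit(): k >= 1")
  if (!is.null(row_id)) {
    o <- order(row_id)
    x <- x[o, , drop = FALSE]
    labels <- labels[o]
  }
  structure(list(x = x, labels = labels, k = as.integer(k), p = p),
            class = "intent_knn")
}

# per-element Minkowski distance sums between query rows and training rows
minkowski_cross <- function(q, x, p) {
  q <- as.matrix(q)
  d <- matrix(0, nrow(q), nrow(x))
  for (k in seq_len(ncol(x))) {
    d <- d + abs(outer(q[, k], x[, k], "-"))^p
  }
  d
}

#' @export
predict.intent_knn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x)) {
    abort(sprintf("predict(): query has %d features, model expects %d",
                  ncol(newdata), ncol(object$x)))
  }
  d <- minkowski_cross(newdata, object$x, object$p)
  if (object$k == 1) {
    # ties.method = "first": exact ties go to the lowest canonical row
    object$labels[max.col(-d, ties.method = "first")]
  } else {
    apply(d, 1, function(row) {
      nn <- order(row)[seq_len(min(object$k, length(row)))]
      votes <- table(object$labels[nn])
      winners <- names(votes)[votes == max(votes)]
      # class tie: the tied class whose representative is nearest
      object$labels[nn][match(TRUE, object$labels[nn] %in% winners)]
    })
  }
}

#' @export
print.intent_knn <- function(x, ...) {
  cat("<intent_knn> ", nrow(x$x), " training rows, ", ncol(x$x),
      " features, k = ", x$k, ", p = ", x$p, "\n", sep = "")
  invisible(x)
}

#' Fit a window-position-stratified k-NN classifier
#'
#' Trials are aligned at activity inception and the signal statistics are
#' non-stationary, so the sliding-window index carries alignment
#' information: a segment 800 ms into a trial should be compared against
#' training segments 800 ms into their trials, not against early segments
#' whose amplitude happens to coincide. This fits one [knn_fit()] model per
#' window position; queries are routed to the model of their own position.
#'
#' @inheritParams knn_fit
#' @param windows Integer window position of every training row.
#' @return An object of class `windowed_knn`.
#' @export
windowed_knn_fit <- function(x, labels, windows, k = 1, p = 0.5,
                             row_id = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels), nrow(x) == length(windows))
  idx <- split(seq_len(nrow(x)), windows)
  models <- lapply(idx, function(ix) {
    knn_fit(x[ix, , drop = FALSE], labels[ix], k = k, p = p,
            row_id = if (!is.null(row_id)) row_id[ix])
  })
  structure(list(models = models, k = k, p = p), class = "windowed_knn")
}

#' @export
predict.windowed_knn <- function(object, newdata, windows = NULL, ...) {
  newdata <- as.matrix(newdata)
  windows <- windows %||% rep(1L, nrow(newdata))
  stopifnot(length(windows) == nrow(newdata))
  out <- NULL
  for (w in unique(windows)) {
    m <- object$models[[as.character(w)]]
    if (is.null(m)) {
      abort(paste0("predict(): no training windows at position ", w))
    }
    pr <- predict(m, newdata[windows == w, , drop = FALSE])
    if (is.null(out)) out <- rep(pr[1], nrow(newdata))
    out[windows == w] <- pr
  }
  out
}

#' @export
print.windowed_knn <- function(x, ...) {
  cat("<windowed_knn> ", length(x$models), " window positions, k = ", x$k,
      ", p = ", x$p, "\n", sep = "")
  invisible(x)
}

#' Aggregate per-window labels into one trial decision
#'
#' Modal vote over the window predictions of a trial; ties between classes
#' are broken in favour of the latest window's vote among the tied classes
#' (later windows see more of the activity).
#'
#' @param labels Vector of window-level labels in time order.
#' @return A single label.
#' @examples
#' vote_labels(c("a", "b", "b")) # "b"
#' vote_labels(c("a", "b")) # tie -> "b" (latest window)
#' @export
vote_labels <- function(labels) {
  if (!length(labels)) abort("vote_labels(): need at least one window label")
  ul <- unique(labels)
  counts <- vapply(ul, function(l) sum(labels == l), integer(1))
  winners <- ul[counts == max(counts)]
  if (length(winners) == 1) return(winners)
  # walk windows from latest to earliest; first tied class wins
  rev(labels)[match(TRUE, rev(labels) %in% winners)]
}

#' Classify one trial from its per-window feature rows
#'
#' Each window row is classified by the model, then [vote_labels()]
#' aggregates the window labels into the trial decision.
#'
#' @param model An `intent_knn` or `windowed_knn`.
#' @param windows Feature matrix with one row per window, in time order.
#' @param window_idx Window positions of the query rows (needed for a
#'   `windowed_knn`; defaults to `1:nrow(windows)`).
#' @return A single class label.
#' @export
predict_trial <- function(model, windows, window_idx = NULL) {
  windows <- as.matrix(windows)
  if (inherits(model, "windowed_knn")) {
    vote_labels(predict(model, windows,
                        windows = window_idx %||% seq_len(nrow(windows))))
  } else {
    vote_labels(predict(model, windows))
  }
}

#' Predict with dropped sensors zero-filled (non-modular baseline)
#'
#' The combined (non-modular) classifier cannot remove input dimensions, so
#' a dropped sensor's feature columns are replaced by the value a dead
#' (all-zero) signal would produce -- by default literally 0, or the
#' standardised image of 0 when the feature bank was standardised -- and the
#' prediction proceeds with no other special handling.
#'
#' @param model An `intent_knn` trained on the concatenated feature columns.
#' @param newdata Query feature matrix.
#' @param dropped_cols Integer indices of the dropped sensors' columns.
#' @param fill Replacement value(s) for those columns (scalar or one value
#'   per dropped column).
#' @return Predicted labels.
#' @export
zero_input_predict <- function(model, newdata, dropped_cols = integer(0),
                               fill = 0) {
  newdata <- as.matrix(newdata)
  if (length(dropped_cols)) {
    newdata[, dropped_cols] <- matrix(rep_len(fill, length(dropped_cols)),
                                      nrow(newdata), length(dropped_cols),
                                      byrow = TRUE)
  }
  predict(model, newdata)
}

#' Concatenate a feature bank into combined-classifier inputs
#'
#' Builds the window-level design matrix of the non-modular method: one row
#' per (trial, window) with every sEMG sensor's window features side by side
#' and every IMU sensor's per-trial features repeated across the trial's
#' windows. Column provenance is recorded so sensors can be dropped
#' (zero-filled) later.
#'
#' @param bank A [extract_features()] feature bank.
#' @return A list with `X` (matrix), `rows` (tibble `trial_id`, `window`),
#'   `col_sensor` (sensor id of every column) and `zero_row` (the value an
#'   all-zero raw input maps to in each column).
#' @export
combined_features <- function(bank) {
  semg <- bank$sensors[bank$sensors$modality == "semg", ]
  imu <- bank$sensors[bank$sensors$modality == "imu", ]
  if (nrow(semg)) {
    rows <- semg$rows[[1]][, c("trial_id", "window")]
  } else {
    rows <- tibble(trial_id = bank$trials$trial_id, window = 1L)
  }
  blocks <- list(); col_sensor <- character(); zero <- numeric()
  for (i in seq_len(nrow(semg))) {
    blocks[[length(blocks) + 1]] <- semg$X[[i]]
    col_sensor <- c(col_sensor, rep(semg$sensor_id[i], semg$n_features[i]))
    zero <- c(zero, semg$zero_row[[i]])
  }
  for (i in seq_len(nrow(imu))) {
    idx <- match(rows$trial_id, imu$rows[[i]]$trial_id)
    blocks[[length(blocks) + 1]] <- imu$X[[i]][idx, , drop = FALSE]
    col_sensor <- c(col_sensor, rep(imu$sensor_id[i], imu$n_features[i]))
    zero <- c(zero, imu$zero_row[[i]])
  }
  X <- do.call(cbind, blocks)
  list(X = X, rows = rows, col_sensor = col_sensor, zero_row = zero)
}
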