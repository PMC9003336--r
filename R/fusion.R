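#' Estimate a sensor's confusion matrix from held-out predictions
#'
#' Tallies (true class, predicted class) counts and converts them to
#' row-conditional probabilities `P(prediction = j | true = i)` with additive
#' smoothing: `probs[i, j] = (counts[i, j] + smoothing) /
#' (row_total_i + C * smoothing)`. The default pseudo-count of 1 keeps every
#' entry strictly positive, which matters because an unsmoothed zero entry
#' annihilates the fused posterior of any class the sensor has never been
#' seen to confuse.
#'
#' @param truth Vector of true class labels.
#' @param prediction Vector of predicted class labels, same length.
#' @param classes Ordered vector of all classes (default: sorted union).
#' @param smoothing Non-negative pseudo-count (default 1).
#' @param sensor_id Optional sensor identifier carried in the result.
#' @return An object of class `sensor_confusion`: list with `classes`,
#'   `counts`, `probs`, `smoothing`, `sensor_id`.
#' @examples
#' cm <- estimate_confusion(c("a", "a", "b", "b"), c("a", "b", "b", "b"),
#'                          smoothing = 0)
#' cm$probs
#' @export
estimate_confusion <- function(truth, prediction, classes = NULL,
                               smoothing = 1, sensor_id = NA_character_) {
  if (!length(truth)) abort("estimate_confusion(): empty input")
  if (length(truth) != length(prediction)) {
    abort("estimate_confusion(): truth and prediction lengths differ")
  }
  classes <- classes %||% sort(unique(c(truth, prediction)))
  if (!all(truth %in% classes)) {
    abort("estimate_confusion(): truth label outside `classes`")
  }
  if (!all(prediction %in% classes)) {
    abort("estimate_confusion(): predicted label outside `classes`")
  }
  if (smoothing < 0) abort("estimate_confusion(): smoothing >= 0")
  C <- length(classes)
  counts <- matrix(
    as.numeric(table(factor(truth, levels = classes),
                     factor(prediction, levels = classes))),
    C, C, dimnames = list(true = as.character(classes),
                          predicted = as.character(classes))
  )
  probs <- (counts + smoothing) /
    (rowSums(counts) + C * smoothing)
  structure(list(classes = classes, counts = counts, probs = probs,
                 smoothing = smoothing, sensor_id = sensor_id),
            class = "sensor_confusion")
}

#' @export
print.sensor_confusion <- function(x, ...) {
  cat("<sensor_confusion> ", if (!is.na(x$sensor_id)) x$sensor_id, " ",
      length(x$classes), " classes, smoothing ", x$smoothing,
      ", balanced accuracy ", round(sensor_accuracy(x), 3), "\n", sep = "")
  print(round(x$probs, 3))
  invisible(x)
}

#' @export
tidy.sensor_confusion <- function(x, ...) {
  df <- as.data.frame.table(x$probs, responseName = "probability",
                            stringsAsFactors = FALSE)
  df$count <- as.vector(x$counts) # both tables share column-major layout
  df$sensor_id <- x$sensor_id
  as_tibble(df[, c("sensor_id", "true", "predicted", "probability", "count")])
}

#' Balanced accuracy of a confusion matrix
#'
#' The trace of the row-conditional probability matrix divided by the number
#' of classes: since each row is a conditional distribution given the true
#' class, this is the class-balanced overall accuracy of the sensor.
#'
#' @param cm A `sensor_confusion`.
#' @return A number in `[0, 1]`.
#' @examples
#' sensor_accuracy(estimate_confusion(c(1, 2), c(1, 2), smoothing = 0)) # 1
#' @export
sensor_accuracy <- function(cm) {
  stopifnot(inherits(cm, "sensor_confusion"))
  sum(diag(cm$probs)) / length(cm$classes)
}

#' Fuse per-sensor predictions into a posterior over intent classes
#'
#' Bayesian decision-level fusion: assuming sensors are conditionally
#' independent given the true class, the unnormalised score of class `c` is
#' `prior(c) * prod_s P(prediction_s | true = c)`, where each factor is read
#' from the sensor's confusion matrix. The posterior is the normalised score
#' vector (for two classes this reduces exactly to the familiar
#' `P(E|V) = P(V|E)P(E) / (P(V|E)P(E) + P(V|E')P(E'))`). Products are
#' accumulated in log space so that large sensor networks do not underflow.
#'
#' Dropped sensors are simply absent from `predictions`: their confusion
#' matrices leave the product, and no retraining of the remaining sensors is
#' needed. With zero active sensors the posterior equals the prior.
#'
#' @param predictions Named vector/list mapping active sensor ids to their
#'   predicted class.
#' @param cms Named list of `sensor_confusion` objects covering (at least)
#'   the active sensors; all must share the same class list.
#' @param prior Numeric prior over classes (default uniform); recycled and
#'   normalised.
#' @return An object of class `fusion_result`: `posterior` (named numeric
#'   summing to 1), `decision` (argmax class, ties to the lowest class
#'   index), `active_sensors`, `predictions`.
#' @examples
#' cm <- estimate_confusion(c(1, 1, 2, 2), c(1, 1, 2, 2), smoothing = 1)
#' fuse(c(s1 = 1), list(s1 = cm))
#' @export
fuse <- function(predictions, cms, prior = NULL) {
  sensors <- names(predictions)
  if (length(predictions) && is.null(sensors)) {
    abort("fuse(): `predictions` must be named by sensor id")
  }
  if (!all(sensors %in% names(cms))) {
    abort("fuse(): every active sensor needs a confusion matrix")
  }
  cms <- cms[sensors]
  if (length(cms)) {
    classes <- cms[[1]]$classes
    same <- vapply(cms, function(cm) identical(cm$classes, classes),
                   logical(1))
    if (!all(same)) abort("fuse(): class lists differ across sensors")
  } else if (!is.null(prior) && !is.null(names(prior))) {
    classes <- names(prior)
  } else {
    abort("fuse(): with no active sensors, `prior` must be named by class")
  }
  C <- length(classes)
  prior <- prior %||% rep(1 / C, C)
  prior <- rep_len(prior, C)
  if (any(prior < 0) || sum(prior) <= 0) {
    abort("fuse(): prior must be non-negative with positive sum")
  }
  prior <- prior / sum(prior)

  logscore <- log(prior)
  for (s in sensors) {
    j <- match(predictions[[s]], classes)
    if (is.na(j)) abort("fuse(): prediction outside the class list")
    logscore <- logscore + log(cms[[s]]$probs[, j])
  }
  if (all(logscore == -Inf)) {
    abort(paste0("fuse(): all class scores are zero; use smoothing > 0 ",
                 "when estimating confusion matrices"))
  }
  post <- exp(logscore - max(logscore))
  post <- post / sum(post)
  names(post) <- classes
  # ties (exact or within floating-point noise) go to the lowest class index
  structure(list(posterior = post,
                 decision = classes[which(logscore >= max(logscore) - 1e-9)[1]],
                 active_sensors = sensors,
                 predictions = predictions),
            class = "fusion_result")
}

#' Extract the fused decision
#'
#' @param x A `fusion_result`.
#' @return The argmax class (ties already resolved to the lowest class
#'   index by [fuse()]).
#' @export
decide <- function(x) {
  stopifnot(inherits(x, "fusion_result"))
  x$decision
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("<fusion_result> decision:", format(x$decision), "from",
      length(x$active_sensors), "sensors\n")
  print(round(x$posterior, 4))
  invisible(x)
}

#' @export
tidy.fusion_result <- function(x, ...) {
  tibble(class = names(x$posterior),
         posterior = as.numeric(x$posterior),
         decision = names(x$posterior) == format(x$decision))
}
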