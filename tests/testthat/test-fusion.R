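test_that("confusion estimation tallies and smooths as documented", {
  cm <- estimate_confusion(c("a", "a", "b", "b"), c("a", "b", "b", "b"),
                           smoothing = 0)
  expect_equal(unname(cm$probs["a", ]), c(0.5, 0.5))
  expect_equal(unname(cm$probs["b", ]), c(0, 1))

  perfect <- estimate_confusion(c(1, 2, 3), c(1, 2, 3), smoothing = 0)
  expect_equal(unname(perfect$probs), diag(3))

  sm <- estimate_confusion(c("a", "b"), c("a", "b"), smoothing = 1)
  expect_true(all(sm$probs > 0 & sm$probs < 1))
  expect_equal(unname(rowSums(sm$probs)), c(1, 1))

  expect_error(estimate_confusion(character(0), character(0)), "empty")
  expect_error(estimate_confusion(c("a"), c("a", "b")), "lengths differ")
  expect_error(estimate_confusion("c", "a", classes = c("a", "b")),
               "truth label outside")
})

test_that("sensor accuracy is the balanced diagonal mean", {
  id3 <- estimate_confusion(c(1, 2, 3), c(1, 2, 3), smoothing = 0)
  expect_equal(sensor_accuracy(id3), 1)
  cm <- random_confusion(3)
  cm$probs[] <- 1 / 3
  expect_equal(sensor_accuracy(cm), 1 / 3)
  cm2 <- random_confusion(2)
  cm2$probs <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_equal(sensor_accuracy(cm2), 0.85)
})

test_that("fusion reproduces a hand Bayes computation", {
  cm <- random_confusion(2)
  cm$probs <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  fr <- fuse(c(s = 1), list(s = cm))
  expect_equal(unname(fr$posterior[1]), 0.9 / (0.9 + 0.2), tolerance = 1e-12)
  expect_equal(decide(fr), 1)
})

test_that("uninformative sensors cancel and reliable sensors dominate", {
  unif <- random_confusion(3)
  unif$probs[] <- 1 / 3
  prior <- c(0.5, 0.3, 0.2)
  fr <- fuse(c(s = 2), list(s = unif), prior = prior)
  expect_equal(unname(fr$posterior), prior, tolerance = 1e-12)

  # near-identity confusion: the reliable sensor's prediction wins
  id <- random_confusion(3)
  id$probs <- diag(3) * 0.998 + 0.001
  fr2 <- fuse(c(s = 3), list(s = id), prior = c(0.5, 0.3, 0.2))
  expect_equal(decide(fr2), 3)
  expect_gt(fr2$posterior[3], 0.99)

  # with zero active sensors the posterior is the prior
  fr3 <- fuse(setNames(integer(0), character(0)), list(),
              prior = c(`1` = 0.6, `2` = 0.4))
  expect_equal(unname(fr3$posterior), c(0.6, 0.4))
  expect_equal(decide(fr3), "1")
})

test_that("posteriors normalise and are invariant to sensor order", {
  set.seed(12)
  for (i in seq_len(1000)) {
    C <- sample(2:4, 1)
    S <- sample(1:5, 1)
    cms <- setNames(lapply(seq_len(S), function(s) random_confusion(C)),
                    paste0("s", seq_len(S)))
    preds <- setNames(sample(C, S, replace = TRUE), names(cms))
    fr <- fuse(preds, cms)
    expect_equal(sum(fr$posterior), 1, tolerance = 1e-9)
    if (i <= 50) {
      o <- sample(S)
      fr2 <- fuse(preds[o], cms[o])
      expect_equal(fr$posterior, fr2$posterior, tolerance = 1e-12)
      expect_identical(fr$decision, fr2$decision)
    }
  }
})

test_that("removing sensors from the map equals fusing the survivors", {
  set.seed(33)
  for (i in seq_len(50)) {
    C <- sample(2:3, 1)
    S <- sample(2:6, 1)
    cms <- setNames(lapply(seq_len(S), function(s) random_confusion(C)),
                    paste0("s", seq_len(S)))
    preds <- setNames(sample(C, S, replace = TRUE), names(cms))
    keep <- sample(names(cms), sample(seq_len(S), 1))
    a <- fuse(preds[keep], cms)        # extra matrices present but inactive
    b <- fuse(preds[keep], cms[keep])  # restricted to the survivors
    expect_identical(a$posterior, b$posterior)
    expect_identical(a$decision, b$decision)
  }
})

test_that("tie and degenerate decisions follow the documented rules", {
  cm <- random_confusion(2)
  cm$probs <- matrix(0.5, 2, 2)
  fr <- fuse(c(s = 1), list(s = cm))
  expect_equal(unname(fr$posterior), c(0.5, 0.5))
  expect_equal(decide(fr), 1) # lowest class index

  one <- random_confusion(1)
  one$probs <- matrix(1, 1, 1)
  expect_equal(decide(fuse(c(s = 1), list(s = one))), 1)
})

test_that("all-zero scores are rejected with a smoothing hint", {
  a <- random_confusion(2); b <- random_confusion(2)
  a$probs <- diag(2)           # sensor x is infallible
  b$probs <- 1 - diag(2)       # sensor y always inverts
  # both sensors predicting class 1 is impossible under either truth
  expect_error(fuse(c(x = 1, y = 1), list(x = a, y = b)), "smoothing")
  mismatched <- random_confusion(3)
  expect_error(fuse(c(x = 1, y = 1),
                    list(x = random_confusion(2), y = mismatched)),
               "class lists differ")
})

test_that("estimated confusion matrices recover the generating matrix", {
  gen <- matrix(c(0.7, 0.2, 0.1,
                  0.15, 0.7, 0.15,
                  0.1, 0.3, 0.6), 3, 3, byrow = TRUE)
  set.seed(2024)
  truth <- rep(1:3, each = 2000)
  pred <- unlist(lapply(1:3, function(i) {
    sample(1:3, 2000, replace = TRUE, prob = gen[i, ])
  }))
  est <- estimate_confusion(truth, pred, classes = 1:3, smoothing = 1)
  expect_lt(max(abs(est$probs - gen)), 0.05)
})

test_that("adding a strictly informative sensor cannot reduce expected accuracy", {
  # exhaustive enumeration of the fused decision rule's expected accuracy
  expected_accuracy <- function(cms, prior) {
    C <- nrow(cms[[1]]$probs)
    grids <- do.call(expand.grid, rep(list(seq_len(C)), length(cms)))
    acc <- 0
    for (g in seq_len(nrow(grids))) {
      v <- as.integer(grids[g, ])
      preds <- setNames(v, names(cms))
      dec <- decide(fuse(preds, cms, prior = prior))
      for (tru in seq_len(C)) {
        p_v <- prod(vapply(seq_along(cms), function(s) {
          cms[[s]]$probs[tru, v[s]]
        }, numeric(1)))
        if (dec == tru) acc <- acc + prior[tru] * p_v
      }
    }
    acc
  }
  set.seed(55)
  for (C in 2:3) {
    for (i in seq_len(10)) {
      base <- setNames(lapply(seq_len(sample(1:2, 1)),
                              function(s) random_confusion(C)), NULL)
      names(base) <- paste0("s", seq_along(base))
      prior <- rep(1 / C, C)
      # diagonally dominant extra sensor (delta > 0)
      extra <- random_confusion(C)
      extra$probs <- (extra$probs + 2 * diag(C)) /
        rowSums(extra$probs + 2 * diag(C))
      more <- c(base, list(extra = extra))
      expect_gte(expected_accuracy(more, prior) + 1e-12,
                 expected_accuracy(base, prior))
    }
  }
})
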