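#' Derive a child seed from a root seed and a stream label
#'
#' All randomness in the package flows from one root seed. Sub-streams
#' (per-trial noise, split candidates, sweep combinations, ...) use seeds
#' derived deterministically from the root seed and a human-readable label,
#' so that any stage can be re-run in isolation and still reproduce exactly.
#'
#' The derivation is a small multiplicative string hash folded into the root
#' seed modulo the Mersenne prime 2^31 - 1, which keeps every derived seed a
#' valid 32-bit R integer. It is a stream-splitting convenience, not a
#' cryptographic function.
#'
#' @param seed Integer root seed.
#' @param ... Character or integer labels identifying the sub-stream.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "trial", 17)
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  h <- as.double(seed) %% m
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0(":", paste(format(part), collapse = ",")))) {
      # doubles are exact below 2^53, so (h * 31 + ch) never loses precision
      h <- (h * 31 + ch) %% m
    }
    h <- (h * 48271) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
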