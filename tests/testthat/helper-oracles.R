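# independent brute-force oracles, coded directly from the definitions
oracle_semg <- function(x, fs, ar_order = 4) {
  n <- length(x)
  iemg <- 0; wl <- 0; ss <- 0
  for (i in seq_len(n)) {
    iemg <- iemg + abs(x[i])
    ss <- ss + x[i]^2
    if (i > 1) wl <- wl + abs(x[i] - x[i - 1])
  }
  # AR by explicit least squares on the demeaned series
  xd <- x - mean(x)
  y <- xd[(ar_order + 1):n]
  X <- sapply(seq_len(ar_order),
              function(k) xd[(ar_order + 1 - k):(n - k)])
  ar <- as.numeric(solve(t(X) %*% X, t(X) %*% y))
  # periodogram from a direct DFT double loop
  P <- numeric(floor(n / 2))
  f <- numeric(floor(n / 2))
  for (k in seq_len(floor(n / 2))) {
    re <- sum(xd * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(xd * sin(-2 * pi * k * (0:(n - 1)) / n))
    P[k] <- re^2 + im^2
    f[k] <- k * fs / n
  }
  cum <- cumsum(P)
  fmd <- f[which(cum >= sum(P) / 2)[1]]
  fmn <- sum(f * P) / sum(P)
  c(IEMG = iemg, MAV = iemg / n, VAR = ss / (n - 1), RMS = sqrt(ss / n),
    WL = wl, setNames(ar, paste0("AR", 1:ar_order)), FMD = fmd, FMN = fmn)
}
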