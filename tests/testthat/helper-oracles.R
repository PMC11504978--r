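# Independent brute-force oracles for the spectral front-end. These never
# call the package's own DFT/filterbank/DCT paths: the DFT is an explicit
# basis-matrix product, triangles and DCT are direct sums.

# half-grid DFT by explicit basis product (no FFT)
naiveDftPower <- function(x, n_fft) {
  xp <- c(x, numeric(n_fft - length(x)))
  k <- 0:(n_fft / 2)
  n <- 0:(n_fft - 1)
  basis <- exp(-2i * pi * outer(k, n) / n_fft)
  Mod(as.vector(basis %*% xp))^2
}

# triangle weights evaluated pointwise from the boundary bins
naiveMelEnergy <- function(powerHalf, bins, M, floor_eps = 1e-10) {
  S <- numeric(M)
  for (m in seq_len(M)) {
    lo <- bins[m]; mid <- bins[m + 1]; hi <- bins[m + 2]
    acc <- 0
    for (k in 0:(length(powerHalf) - 1)) {
      w <- 0
      if (k >= lo && k <= mid && mid > lo) w <- (k - lo) / (mid - lo)
      else if (k == mid && mid == lo) w <- 1
      if (k > mid && k <= hi && hi > mid) w <- (hi - k) / (hi - mid)
      acc <- acc + powerHalf[k + 1] * w
    }
    S[m] <- max(acc, floor_eps)
  }
  S
}

# double-loop log + cosine transform
naiveDct <- function(S, n_keep, phase = c("shifted", "standard")) {
  phase <- match.arg(phase)
  M <- length(S)
  off <- if (phase == "shifted") -1 else 1
  out <- numeric(n_keep)
  for (n in seq_len(n_keep)) {
    acc <- 0
    for (m in 0:(M - 1)) {
      acc <- acc + log(S[m + 1]) * cos(pi * n * (2 * m + off) / (2 * M))
    }
    out[n] <- sqrt(2 / M) * acc
  }
  out
}

# direct-sum regression delta with clamped edges
naiveDelta <- function(feat, width = 2L) {
  n <- nrow(feat)
  cl <- function(i) min(max(i, 1L), n)
  denom <- 2 * sum((1:width)^2)
  out <- feat * 0
  for (t in seq_len(n)) {
    for (tau in seq_len(width)) {
      out[t, ] <- out[t, ] + tau * (feat[cl(t + tau), ] - feat[cl(t - tau), ])
    }
  }
  out / denom
}

# full front-end for one windowed frame, by the oracles above
naiveFrameMfcc <- function(frameVec, bank, n_keep = 12L, phase = "shifted") {
  p <- naiveDftPower(frameVec, bank$n_fft)
  S <- naiveMelEnergy(p, bank$bins, bank$M)
  naiveDct(S, n_keep, phase)
}

# linearly separable 36-dim toy set (two well-separated Gaussians)
makeToySet <- function(n = 200L, sep = 1.5, sd = 0.3, seed = 1L) {
  withr::with_seed(seed, {
    X <- rbind(
      matrix(stats::rnorm(n / 2 * 36, sep, sd), ncol = 36),
      matrix(stats::rnorm(n / 2 * 36, -sep, sd), ncol = 36)
    )
    list(X = X, y = rep(c("male", "female"), each = n / 2))
  })
}

# minimal stereo 16-bit WAV writer (fixture for the mono-only contract)
writeStereoWav <- function(path, n = 100L, rate = 44100L) {
  pcm <- as.integer(rep(0L, 2L * n))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 4L * n), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little") # stereo
  writeBin(rate, con, size = 4L, endian = "little")
  writeBin(rate * 4L, con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(4L * n), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  path
}

# write a manifest CSV from a data.frame
writeTestManifest <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
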