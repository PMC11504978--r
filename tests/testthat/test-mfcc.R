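windowedFrames <- function(m, fs = 44100) {
  structure(list(frames = m, L = ncol(m), hop = ncol(m), sample_rate = fs,
                 windowed = TRUE), class = "FrameMatrix")
}

test_that("power spectrum: zero frame, impulse, and Parseval", {
  fr <- windowedFrames(matrix(0, 1, 64))
  expect_true(all(powerSpectrum(fr, 64) == 0))

  imp <- windowedFrames(matrix(c(1, numeric(63)), 1))
  expect_equal(as.vector(powerSpectrum(imp, 64)), rep(1, 33))

  withr::with_seed(5, m <- matrix(stats::rnorm(5 * 64), 5, 64))
  fr2 <- windowedFrames(m)
  E <- powerSpectrum(fr2, 64)
  # Parseval over the full grid: interior bins count twice on the half grid
  full <- E[, 1] + E[, 33] + 2 * rowSums(E[, 2:32, drop = FALSE])
  expect_equal(full, 64 * rowSums(m^2), tolerance = 1e-10)

  expect_error(powerSpectrum(windowedFrames(matrix(0, 1, 100)), 64), "n_fft")
  expect_error(powerSpectrum(windowedFrames(matrix(0, 1, 50)), 96),
               "power of two")
  raw <- structure(list(frames = matrix(0, 1, 64), L = 64, hop = 64,
                        sample_rate = 44100, windowed = FALSE),
                   class = "FrameMatrix")
  expect_error(powerSpectrum(raw, 64), "windowed")
})

test_that("Mel filterbank: unit peaks, compact support, Mel-spaced bounds", {
  bank <- melFilterbank(44100, 2048, M = 26, fmin = 0, fmax = 22050)
  expect_equal(dim(bank$H), c(26, 1025))
  for (m in 1:26) {
    expect_equal(max(bank$H[m, ]), 1)
    expect_equal(which.max(bank$H[m, ]) - 1, bank$bins[m + 1])
    lo <- bank$bins[m]; hi <- bank$bins[m + 2]
    k <- 0:1024
    expect_true(all(bank$H[m, k < lo | k > hi] == 0))
  }
  # boundary points form an arithmetic progression on the Mel scale
  hzPts <- melToHz(seq(hzToMel(0), hzToMel(22050), length.out = 28))
  expect_equal(diff(hzToMel(hzPts)), rep(diff(hzToMel(hzPts))[1], 27),
               tolerance = 1e-10)
  expect_equal(bank$bins, floor(2049 * hzPts / 44100))
  expect_error(melFilterbank(44100, 2048, fmax = 30000), "Nyquist")
  expect_error(melFilterbank(44100, 2048, fmin = -1), "fmin")
})

test_that("filterbank energies: floor, peak-bin selectivity, linearity", {
  bank <- melFilterbank(44100, 2048, M = 26)
  zero <- matrix(0, 3, 1025)
  expect_true(all(filterbankEnergies(zero, bank) == 1e-10))

  # energy only at filter 10's peak bin lands wholly in filter 10
  peakBin <- bank$bins[11]
  spike <- matrix(0, 1, 1025)
  spike[1, peakBin + 1] <- 7
  S <- filterbankEnergies(spike, bank)
  expect_equal(S[1, 10], 7)
  expect_equal(S[1, 9], 1e-10)
  expect_equal(S[1, 11], 1e-10)

  withr::with_seed(8, E <- matrix(stats::runif(2 * 1025), 2))
  expect_equal(filterbankEnergies(2 * E, bank),
               2 * filterbankEnergies(E, bank), tolerance = 1e-12)
  expect_error(filterbankEnergies(matrix(0, 1, 100), bank), "does not match")
})

test_that("cepstral transform agrees with the double-loop oracle", {
  withr::with_seed(9, S <- matrix(stats::runif(6 * 26, 0.1, 10), 6, 26))
  for (phase in c("shifted", "standard")) {
    got <- computeMfcc(S, 12, dctPhase = phase)
    want <- t(apply(S, 1, naiveDct, n_keep = 12, phase = phase))
    expect_equal(got, want, tolerance = 1e-10)
  }
  # constant filterbank energies: compare against the oracle's residual
  Sc <- matrix(2.5, 1, 26)
  expect_equal(as.vector(computeMfcc(Sc, 12)), naiveDct(Sc[1, ], 12),
               tolerance = 1e-12)
  expect_error(computeMfcc(matrix(c(1, -1, rep(1, 24)), 1)), "positive")
  expect_error(computeMfcc(S, 30), "n_keep")
})

test_that("scaling the energies shifts each coefficient by the closed form", {
  withr::with_seed(10, S <- matrix(stats::runif(4 * 26, 0.5, 5), 4, 26))
  c0 <- 3.7
  base <- computeMfcc(S, 12)
  scaled <- computeMfcc(c0 * S, 12)
  m <- 0:25
  shift <- vapply(1:12, function(n)
    log(c0) * sqrt(2 / 26) * sum(cos(pi * n * (2 * m - 1) / 52)), numeric(1))
  expect_equal(scaled, base + rep(shift, each = 4), tolerance = 1e-10)
})

test_that("delta regression: constants, ramps, and the direct-sum oracle", {
  const <- matrix(5, 10, 3)
  expect_true(all(deltaFeatures(const) == 0))

  ramp <- outer(1:20, c(1, -2)) # c_t = a * t per column
  d <- deltaFeatures(ramp, width = 2)
  expect_equal(d[3:18, 1], rep(1, 16))
  expect_equal(d[3:18, 2], rep(-2, 16))

  withr::with_seed(12, f <- matrix(stats::rnorm(15 * 4), 15, 4))
  expect_equal(deltaFeatures(f, 2), naiveDelta(f, 2), tolerance = 1e-12)
  expect_equal(deltaFeatures(f, 3), naiveDelta(f, 3), tolerance = 1e-12)
  expect_warning(deltaFeatures(matrix(1, 2, 2), 2), "fewer frames")
})

test_that("assembled features are 36 wide with stable column order", {
  withr::with_seed(13, m <- matrix(stats::rnorm(8 * 1102, 0, 0.2), 8, 1102))
  fr <- windowedFrames(m)
  fm <- assembleFeatures(fr)
  expect_equal(ncol(fm$values), 36)
  expect_true(all(is.finite(fm$values)))
  expect_equal(colnames(fm$values),
               c(paste0("c", 1:12), paste0("d", 1:12), paste0("dd", 1:12)))
  expect_identical(fm$values, assembleFeatures(fr)$values)
  # single frame: delta blocks are exactly zero under edge replication
  one <- windowedFrames(m[1, , drop = FALSE])
  fm1 <- suppressWarnings(assembleFeatures(one))
  expect_true(all(fm1$values[, 13:36] == 0))
})

test_that("z-scoring uses training statistics only", {
  withr::with_seed(14, {
    tr <- matrix(stats::rnorm(200 * 36, 3, 2), 200, 36)
    te <- matrix(stats::rnorm(50 * 36, -1, 0.5), 50, 36)
  })
  tr[, 5] <- 7 # constant column
  norm <- normalizeFeatures(tr, test = te)
  expect_equal(colMeans(norm$train), rep(0, 36), tolerance = 1e-6)
  expect_equal(apply(norm$train[, -5], 2, sd), rep(1, 35), tolerance = 1e-6)
  expect_true(all(norm$train[, 5] == 0)) # sd floor engaged
  # the test set is transformed with the train mean/sd, not its own
  expect_equal(norm$test, sweep(sweep(te, 2, colMeans(tr)), 2,
                                pmax(apply(tr, 2, sd), 1e-8), `/`))
  expect_false(isTRUE(all.equal(colMeans(norm$test), rep(0, 36),
                                tolerance = 0.5)))
})

test_that("spectrogram localizes tones and floors silence", {
  fs <- 44100
  tone <- audioSignal(sin(2 * pi * 2500 * (0:22049) / fs), fs)
  sp <- spectrogram(tone)
  dom <- dominantFrequency(sp)
  expect_true(all(abs(dom - 2500) <= fs / 2048)) # within one bin
  silence <- audioSignal(numeric(22050), fs)
  sps <- spectrogram(silence)
  expect_true(all(sps$mag == -100)) # uniform dB floor
})

test_that("pipeline MFCCs match the naive front-end within 1e-8 relative", {
  bank <- melFilterbank(44100, 512, M = 20)
  withr::with_seed(15, m <- matrix(stats::rnorm(20 * 400, 0, 0.3), 20, 400))
  fr <- windowedFrames(m)
  E <- powerSpectrum(fr, 512)
  S <- filterbankEnergies(E, bank)
  got <- computeMfcc(S, 12)
  for (i in seq_len(nrow(m))) {
    want <- naiveFrameMfcc(m[i, ], bank)
    expect_equal(as.vector(got[i, ]), want, tolerance = 1e-8)
  }
})

test_that("gain changes shift static coefficients but leave deltas untouched", {
  withr::with_seed(16, m <- matrix(stats::rnorm(10 * 1102, 0, 0.5), 10, 1102))
  f1 <- assembleFeatures(windowedFrames(m))$values
  f2 <- assembleFeatures(windowedFrames(4 * m))$values
  expect_equal(f2[, 13:36], f1[, 13:36], tolerance = 1e-9)
  shifts <- unname(f2[, 1:12] - f1[, 1:12])
  expect_equal(shifts, matrix(shifts[1, ], nrow(shifts), 12, byrow = TRUE),
               tolerance = 1e-9)
})
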