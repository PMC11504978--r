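test_that("female calls hold a stable fundamental with a terminal rise", {
  call <- synthCall(callSpec("female", duration_s = 0.3, f0_base = 2500,
                             glide_hz = 250), 44100)
  traj <- dominantFrequency(spectrogram(call), fmin = 1500, fmax = 4000)
  n <- length(traj)
  early <- traj[seq_len(floor(0.7 * n))]
  binHz <- 44100 / 2048
  expect_lte(max(abs(early - stats::median(early))), 2 * binHz) # flat body
  expect_gt(traj[n], traj[1] + 100) # rising tail
})

test_that("male calls start high and decay onto a lower plateau", {
  call <- synthCall(callSpec("male", duration_s = 0.3, f0_base = 2300,
                             onset_delta_hz = 400), 44100)
  traj <- dominantFrequency(spectrogram(call), fmin = 1500, fmax = 4000)
  plateau <- stats::median(traj[(length(traj) - 5):length(traj)])
  expect_gte(traj[1] - plateau, 200)
  expect_true(all(diff(traj) <= 0)) # monotone decay of the dominant bin
})

test_that("call synthesis is deterministic and respects the amplitude contract", {
  spec <- callSpec("female", duration_s = 0.2)
  a <- synthCall(spec, 44100)
  b <- synthCall(spec, 44100)
  expect_identical(samples(a), samples(b))
  expect_equal(max(abs(samples(a))), 0.8, tolerance = 1e-12)
})

test_that("noise-free recordings are exactly zero outside ground truth", {
  rec <- recordingSpec(n_calls = 4, snr_db = Inf, white_snr_db = Inf)
  out <- synthRecording(rec, "female", seed = 3)
  x <- samples(out$signal)
  inCall <- rep(FALSE, length(x))
  for (i in seq_len(nrow(out$truth)))
    inCall[(out$truth$start_sample[i] + 1):out$truth$end_sample[i]] <- TRUE
  expect_true(all(x[!inCall] == 0))
  expect_gt(max(abs(x[inCall])), 0.7)
  # segments are disjoint, ordered and inside the recording
  expect_true(all(diff(out$truth$start_sample) > 0))
  expect_true(all(out$truth$start_sample[-1] >= out$truth$end_sample[-4]))
  expect_true(all(out$truth$end_sample <= length(x)))
})

test_that("delivered SNR matches the requested level within 1 dB", {
  rec <- recordingSpec(n_calls = 8, snr_db = 20)
  out <- synthRecording(rec, "male", seed = 9)
  x <- samples(out$signal)
  inCall <- rep(FALSE, length(x))
  for (i in seq_len(nrow(out$truth)))
    inCall[(out$truth$start_sample[i] + 1):out$truth$end_sample[i]] <- TRUE
  snrMeasured <- 10 * log10(mean(x[inCall]^2) / mean(x[!inCall]^2))
  # in-call power = signal + noise ~= signal at 20 dB
  expect_equal(snrMeasured, 20, tolerance = 0.05) # within ~1 dB of 20
  # RMS inside segments dominates outside for any snr >= 10
  out10 <- synthRecording(recordingSpec(n_calls = 8, snr_db = 10), "male",
                          seed = 9)
  x10 <- samples(out10$signal)
  in10 <- rep(FALSE, length(x10))
  for (i in seq_len(nrow(out10$truth)))
    in10[(out10$truth$start_sample[i] + 1):out10$truth$end_sample[i]] <- TRUE
  expect_gt(sqrt(mean(x10[in10]^2)), sqrt(mean(x10[!in10]^2)))
})

test_that("zero calls give pure background with empty truth", {
  out <- synthRecording(recordingSpec(n_calls = 0, snr_db = 20), "female",
                        seed = 5)
  expect_equal(nrow(out$truth), 0)
  expect_gt(length(samples(out$signal)), 0)
})

test_that("corpus generation is balanced, labelled and reproducible", {
  c1 <- synthDataset(n_per_sex = 3, calls_per_duck = 2, seed = 17)
  expect_equal(nrow(c1$manifest), 6)
  expect_equal(sum(c1$manifest$sex == "male"), 3)
  expect_equal(sort(names(c1$signals)), sort(c1$manifest$duck_id))
  c2 <- synthDataset(n_per_sex = 3, calls_per_duck = 2, seed = 17)
  for (id in names(c1$signals))
    expect_identical(samples(c1$signals[[id]]), samples(c2$signals[[id]]))

  # on-disk variant: WAVs byte-identical across runs, manifest loadable
  d1 <- tempfile(); d2 <- tempfile()
  synthDataset(n_per_sex = 2, calls_per_duck = 2, seed = 18, out_dir = d1)
  synthDataset(n_per_sex = 2, calls_per_duck = 2, seed = 18, out_dir = d2)
  for (w in list.files(d1, pattern = "\\.wav$")) {
    expect_identical(readBin(file.path(d1, w), "raw", 1e6),
                     readBin(file.path(d2, w), "raw", 1e6))
  }
  mf <- loadManifest(file.path(d1, "manifest.csv"))
  expect_equal(nrow(mf), 4)
})

test_that("the two sexes are separable in static cepstral space", {
  corpus <- synthDataset(n_per_sex = 10, calls_per_duck = 6, seed = 3)
  cf <- corpusFeatures(corpus)
  mu <- sapply(names(cf$features),
               function(id) colMeans(cf$features[[id]]$values[, 1:12]))
  sex <- cf$sexes[colnames(mu)]
  between <- sqrt(sum((rowMeans(mu[, sex == "male"]) -
                         rowMeans(mu[, sex == "female"]))^2))
  withinSe <- mean(c(apply(mu[, sex == "male"], 1, stats::sd),
                     apply(mu[, sex == "female"], 1, stats::sd))) / sqrt(10)
  expect_gt(between, 5 * withinSe)
})
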