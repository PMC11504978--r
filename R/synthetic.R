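# Seeded generator of duck-call-like recordings with ground truth. Calls are
# additive harmonic stacks along a sex-specific fundamental contour:
# females hold a stable fundamental (~2500 Hz) with a small upward glide
# over the final 15% of the call; males start 300-500 Hz above their plateau
# and decay exponentially onto it. Background is band-limited (< 1000 Hz)
# noise — the cage/stepping sounds that dominate real rearing-pen
# recordings — plus an optional faint broadband floor.

#' Specification of one synthetic call
#'
#' @param sex "male" or "female"; selects the contour family.
#' @param duration_s call length in seconds.
#' @param f0_base plateau fundamental in Hz. The defaults (female 2500,
#'   male 2300) are synthetic conventions chosen around the ~2.5 kHz band
#'   where duckling calls concentrate, not measured duck biology.
#' @param glide_hz female terminal rise (Hz over the final 15%); ignored for
#'   males.
#' @param onset_delta_hz male onset excess above the plateau; ignored for
#'   females.
#' @param n_harmonics number of harmonics, amplitude rolloff 1/h.
#' @param attack_s,decay_s amplitude envelope ramp times in seconds.
#' @return list of class \code{"CallSpec"}.
#' @export
callSpec <- function(sex = c("female", "male"), duration_s = 0.25,
                     f0_base = if (match.arg(sex) == "female") 2500 else 2300,
                     glide_hz = 200, onset_delta_hz = 400,
                     n_harmonics = 4L, attack_s = 0.015, decay_s = 0.02) {
  sex <- match.arg(sex)
  if (duration_s <= 0) stop("duration_s must be positive")
  if (f0_base <= 0) stop("f0_base must be positive")
  structure(
    list(sex = sex, duration_s = duration_s, f0_base = f0_base,
         glide_hz = glide_hz, onset_delta_hz = onset_delta_hz,
         n_harmonics = as.integer(n_harmonics),
         attack_s = attack_s, decay_s = decay_s),
    class = "CallSpec"
  )
}

# fundamental-frequency trajectory in Hz, one value per sample
callF0Trajectory <- function(spec, n, sample_rate) {
  t <- (seq_len(n) - 1L) / sample_rate
  dur <- spec$duration_s
  if (spec$sex == "female") {
    f0 <- rep(spec$f0_base, n)
    glideStart <- 0.85 * dur
    late <- t >= glideStart
    f0[late] <- spec$f0_base +
      spec$glide_hz * (t[late] - glideStart) / (dur - glideStart)
  } else {
    tau <- 0.15 * dur # onset decays onto the plateau over ~the first third
    f0 <- spec$f0_base + spec$onset_delta_hz * exp(-t / tau)
  }
  f0
}

#' Synthesise one call
#'
#' Additive synthesis of \code{n_harmonics} phase-continuous harmonics along
#' the sex-specific fundamental trajectory (phase is the cumulative sum of
#' instantaneous frequency), amplitude rolloff 1/h, linear attack/decay
#' envelope, peak normalised to 0.8. Harmonics that would exceed Nyquist are
#' dropped with a message.
#'
#' @param spec a [callSpec()].
#' @param sample_rate sampling rate in Hz.
#' @return an \linkS4class{AudioSignal}.
#' @export
synthCall <- function(spec, sample_rate = 44100) {
  stopifnot(inherits(spec, "CallSpec"))
  n <- max(2L, round(spec$duration_s * sample_rate))
  f0 <- callF0Trajectory(spec, n, sample_rate)
  phase <- 2 * pi * cumsum(f0) / sample_rate
  x <- numeric(n)
  dropped <- 0L
  for (h in seq_len(spec$n_harmonics)) {
    if (h * max(f0) >= sample_rate / 2) {
      dropped <- dropped + 1L
      next
    }
    x <- x + sin(h * phase) / h
  }
  if (dropped > 0L)
    message(dropped, " harmonic(s) above Nyquist dropped")
  # envelope: linear attack, sustain, linear decay
  t <- (seq_len(n) - 1L) / sample_rate
  env <- pmin(1, t / spec$attack_s, (spec$duration_s - t) / spec$decay_s)
  env <- pmax(env, 0)
  x <- x * env
  peak <- max(abs(x))
  if (peak > 0) x <- 0.8 * x / peak
  audioSignal(x, sample_rate)
}

#' Specification of one synthetic recording
#'
#' @param n_calls number of calls to place (0 gives pure background).
#' @param gap_range_s min/max silence before each call and after the last,
#'   seconds (uniformly sampled).
#' @param snr_db in-call signal power over background noise power, dB
#'   (Inf disables noise).
#' @param white_snr_db level of an additional broadband white floor, dB
#'   relative to in-call signal power (default 60: faint; Inf disables).
#' @param lf_noise_max_hz upper edge of the band-limited background (Hz).
#' @param call_type "normal" (sex-specific contour near 2.5 kHz), "alarm"
#'   (2800-2900 Hz band) or "distress" (> 3000 Hz); the latter two exist for
#'   endpoint-detection stress tests, not sex classification.
#' @param duration_range_s min/max call duration, seconds.
#' @param sample_rate sampling rate, Hz.
#' @return list of class \code{"RecordingSpec"}.
#' @export
recordingSpec <- function(n_calls = 10L, gap_range_s = c(0.15, 0.5),
                          snr_db = 20, white_snr_db = 60,
                          lf_noise_max_hz = 1000,
                          call_type = c("normal", "alarm", "distress"),
                          duration_range_s = c(0.15, 0.4),
                          sample_rate = 44100) {
  call_type <- match.arg(call_type)
  structure(
    list(n_calls = as.integer(n_calls), gap_range_s = gap_range_s,
         snr_db = snr_db, white_snr_db = white_snr_db,
         lf_noise_max_hz = lf_noise_max_hz, call_type = call_type,
         duration_range_s = duration_range_s, sample_rate = sample_rate),
    class = "RecordingSpec"
  )
}

sampleCallSpec <- function(rec, sex, f0_offset = 0) {
  dur <- stats::runif(1, rec$duration_range_s[1], rec$duration_range_s[2])
  base <- switch(rec$call_type,
    normal = (if (sex == "female") 2500 else 2300) + f0_offset,
    alarm = stats::runif(1, 2800, 2900) + f0_offset,
    distress = stats::runif(1, 3000, 3300) + f0_offset
  )
  callSpec(
    sex = sex, duration_s = dur, f0_base = base,
    glide_hz = stats::runif(1, 150, 300),
    onset_delta_hz = stats::runif(1, 300, 500)
  )
}

#' Synthesise one recording with ground truth
#'
#' Calls are placed after uniformly sampled silent gaps; band-limited
#' background noise scaled to the requested SNR (measured against mean
#' in-call signal power) is added over the whole recording. Ground truth
#' records the exact sample bounds, sex and call type of every call.
#'
#' @param rec a [recordingSpec()].
#' @param sex sex of the (single) bird in the recording.
#' @param seed RNG seed; the same (spec, sex, seed) reproduces the waveform
#'   exactly.
#' @param f0_offset per-bird fundamental offset in Hz (individual variation).
#' @param sourceId identifier stored on the signal.
#' @return list with \code{signal} (\linkS4class{AudioSignal}) and
#'   \code{truth} (data.frame start_sample, end_sample, sex, call_type;
#'   0-based half-open sample bounds).
#' @export
synthRecording <- function(rec, sex = c("female", "male"), seed = 1L,
                           f0_offset = 0, sourceId = NA_character_) {
  stopifnot(inherits(rec, "RecordingSpec"))
  sex <- match.arg(sex)
  fs <- rec$sample_rate
  withr::with_seed(seed, {
    pieces <- list()
    truth <- list()
    pos <- 0L # samples emitted so far
    for (i in seq_len(rec$n_calls)) {
      gap <- round(stats::runif(1, rec$gap_range_s[1], rec$gap_range_s[2]) * fs)
      call <- synthCall(sampleCallSpec(rec, sex, f0_offset), fs)
      pieces[[length(pieces) + 1L]] <- numeric(gap)
      pieces[[length(pieces) + 1L]] <- samples(call)
      truth[[i]] <- data.frame(
        start_sample = pos + gap,
        end_sample = pos + gap + length(call),
        sex = sex, call_type = rec$call_type
      )
      pos <- pos + gap + length(call)
    }
    tailGap <- round(stats::runif(1, rec$gap_range_s[1], rec$gap_range_s[2]) * fs)
    pieces[[length(pieces) + 1L]] <- numeric(max(tailGap, 2L))
    x <- unlist(pieces, use.names = FALSE)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(start_sample = integer(0), end_sample = integer(0),
                 sex = character(0), call_type = character(0))

    # in-call signal power sets the noise scale
    inCall <- rep(FALSE, length(x))
    for (i in seq_len(nrow(truth)))
      inCall[(truth$start_sample[i] + 1L):truth$end_sample[i]] <- TRUE
    sigPow <- if (any(inCall)) mean(x[inCall]^2) else 1e-4

    if (is.finite(rec$snr_db)) {
      lf <- stats::rnorm(length(x))
      bf <- signal::butter(4, rec$lf_noise_max_hz / (fs / 2), type = "low")
      lf <- as.numeric(signal::filtfilt(bf, lf))
      lf <- lf * sqrt(sigPow / 10^(rec$snr_db / 10) / mean(lf^2))
      x <- x + lf
    }
    if (is.finite(rec$white_snr_db)) {
      w <- stats::rnorm(length(x))
      w <- w * sqrt(sigPow / 10^(rec$white_snr_db / 10) / mean(w^2))
      x <- x + w
    }
    peak <- max(abs(x))
    if (peak > 1) x <- x / peak # headroom guard; noise rarely pushes past 1
    list(signal = audioSignal(x, fs, sourceId = sourceId), truth = truth)
  })
}

#' Synthesise a labelled multi-bird corpus
#'
#' Generates \code{n_per_sex} birds of each sex, each with its own
#' fundamental-frequency offset drawn from N(0, f0_jitter_sd) so individuals
#' differ, and \code{calls_per_duck} calls per bird. With \code{out_dir} the
#' corpus is written to disk (per-bird WAV + ground-truth CSV + manifest
#' CSV); otherwise it is returned in memory.
#'
#' @param n_per_sex birds per sex.
#' @param calls_per_duck calls per bird.
#' @param rec a [recordingSpec()] template (its n_calls is overridden by
#'   \code{calls_per_duck}).
#' @param seed master RNG seed; bird b uses seed + b.
#' @param out_dir optional output directory (created if missing).
#' @param f0_jitter_sd per-bird fundamental offset SD in Hz (default 50).
#' @return list with \code{manifest} (\code{"DatasetManifest"} data.frame),
#'   \code{signals} (named list of AudioSignal, NULL entries when written to
#'   disk), \code{truths} (named list of ground-truth data.frames).
#' @export
synthDataset <- function(n_per_sex = 10L, calls_per_duck = 10L,
                         rec = recordingSpec(), seed = 1L, out_dir = NULL,
                         f0_jitter_sd = 50) {
  rec$n_calls <- as.integer(calls_per_duck)
  toDisk <- !is.null(out_dir)
  if (toDisk && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  offsets <- withr::with_seed(seed, stats::rnorm(2L * n_per_sex, 0, f0_jitter_sd))
  ids <- character(0); sexesv <- character(0); paths <- character(0)
  signals <- list(); truths <- list()
  b <- 0L
  for (sex in c("male", "female")) {
    for (i in seq_len(n_per_sex)) {
      b <- b + 1L
      id <- sprintf("%s_%03d", sex, i)
      out <- synthRecording(rec, sex, seed = seed + b,
                            f0_offset = offsets[b], sourceId = id)
      ids <- c(ids, id); sexesv <- c(sexesv, sex)
      truths[[id]] <- out$truth
      if (toDisk) {
        wav <- file.path(out_dir, paste0(id, ".wav"))
        writeWav(out$signal, wav)
        utils::write.csv(out$truth,
                         file.path(out_dir, paste0(id, "_truth.csv")),
                         row.names = FALSE)
        paths <- c(paths, wav)
        signals[id] <- list(NULL)
      } else {
        paths <- c(paths, NA_character_)
        signals[[id]] <- out$signal
      }
    }
  }
  manifest <- data.frame(wav_path = paths, duck_id = ids, sex = sexesv,
                         split = "unassigned", stringsAsFactors = FALSE)
  class(manifest) <- c("DatasetManifest", "data.frame")
  if (toDisk)
    writeManifest(manifest, file.path(out_dir, "manifest.csv"))
  list(manifest = manifest, signals = signals, truths = truths)
}
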