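# MFCC front-end: power spectrum -> Mel triangular filterbank -> log -> DCT,
# plus first/second-order regression deltas and z-score normalisation.
# Feature layout is fixed at [c1..c12 | d1..d12 | dd1..dd12] = 36 columns.

#' Mel scale
#'
#' mel(f) = 2595 * log10(1 + f / 700); [melToHz()] is its inverse.
#' @param f frequency in Hz.
#' @return Mel value(s).
#' @export
hzToMel <- function(f) 2595 * log10(1 + f / 700)

#' @rdname hzToMel
#' @param m Mel value(s).
#' @export
melToHz <- function(m) 700 * (10^(m / 2595) - 1)

#' Per-frame power spectrum
#'
#' Frames are zero-padded to \code{n_fft} and transformed with the FFT;
#' the spectral line energy is the modulus square E(i,k) = |X(i,k)|^2,
#' returned for the non-redundant half grid k = 0..n_fft/2.
#'
#' @param frames a windowed \code{"FrameMatrix"} (windowing enforced unless
#'   \code{requireWindowed = FALSE}, which exists for diagnostic use).
#' @param n_fft FFT size: a power of two >= the frame length (default 2048,
#'   the next power of two above the 1102-sample 25 ms frame).
#' @param requireWindowed enforce that the Hamming taper was applied.
#' @return num_frames x (n_fft/2 + 1) matrix of spectral line energies.
#' @export
powerSpectrum <- function(frames, n_fft = 2048L, requireWindowed = TRUE) {
  stopifnot(inherits(frames, "FrameMatrix"))
  if (requireWindowed && !frames$windowed)
    stop("frames must be windowed before spectral analysis")
  if (n_fft < frames$L)
    stop("n_fft (", n_fft, ") must be >= frame length (", frames$L, ")")
  if (bitwAnd(n_fft, n_fft - 1L) != 0L)
    stop("n_fft must be a power of two")
  num <- nrow(frames$frames)
  padded <- matrix(0, nrow = n_fft, ncol = num)
  if (num > 0L) padded[seq_len(frames$L), ] <- t(frames$frames)
  X <- stats::mvfft(padded)
  half <- n_fft / 2L + 1L
  t(Mod(X[seq_len(half), , drop = FALSE])^2)
}

#' Build a Mel-scale triangular filterbank
#'
#' M + 2 boundary points are placed at equal Mel spacing between fmin and
#' fmax, converted to FFT bin indices as floor((n_fft + 1) * f / sample_rate),
#' and each filter m is the triangle that rises linearly from bin f(m-1) to a
#' peak of exactly 1 at bin f(m) and falls linearly to zero at bin f(m+1).
#'
#' @param sample_rate sampling rate, Hz.
#' @param n_fft FFT size the bank applies to.
#' @param M number of filters (>= 2).
#' @param fmin,fmax band edges in Hz; fmax must not exceed Nyquist.
#' @return list of class \code{"MelFilterBank"}: weight matrix \code{H}
#'   (M x (n_fft/2 + 1)), boundary bins \code{bins} (length M + 2), and the
#'   construction parameters.
#' @export
melFilterbank <- function(sample_rate = 44100, n_fft = 2048L, M = 26L,
                          fmin = 0, fmax = sample_rate / 2) {
  if (!(fmin >= 0 && fmin < fmax)) stop("require 0 <= fmin < fmax")
  if (fmax > sample_rate / 2)
    stop("fmax (", fmax, ") exceeds Nyquist (", sample_rate / 2, ")")
  if (M < 2L) stop("need at least 2 Mel filters")
  melPts <- seq(hzToMel(fmin), hzToMel(fmax), length.out = M + 2L)
  hzPts <- melToHz(melPts)
  bins <- floor((n_fft + 1) * hzPts / sample_rate)
  half <- n_fft / 2L + 1L
  H <- matrix(0, nrow = M, ncol = half)
  k <- 0:(half - 1L)
  for (m in seq_len(M)) {
    lo <- bins[m]; mid <- bins[m + 1L]; hi <- bins[m + 2L]
    if (mid > lo) {
      rise <- k >= lo & k <= mid
      H[m, rise] <- (k[rise] - lo) / (mid - lo)
    } else {
      H[m, k == mid] <- 1
    }
    if (hi > mid) {
      fall <- k > mid & k <= hi
      H[m, fall] <- (hi - k[fall]) / (hi - mid)
    }
  }
  structure(
    list(H = H, bins = bins, M = M, n_fft = n_fft,
         sample_rate = sample_rate, fmin = fmin, fmax = fmax),
    class = "MelFilterBank"
  )
}

#' @export
print.MelFilterBank <- function(x, ...) {
  cat(sprintf(
    "MelFilterBank: %d triangular filters on %.0f-%.0f Hz (n_fft %d @ %d Hz)\n",
    x$M, x$fmin, x$fmax, x$n_fft, as.integer(x$sample_rate)
  ))
  invisible(x)
}

#' Mel filterbank energies
#'
#' S(i,m) = sum_k E(i,k) * H_m(k), floored at \code{floor_eps} so the
#' subsequent log is finite on silent frames.
#'
#' @param spectralEnergies num_frames x (n_fft/2 + 1) matrix from
#'   [powerSpectrum()].
#' @param bank a \code{"MelFilterBank"} with matching grid.
#' @param floor_eps lower floor applied to the energies (default 1e-10).
#' @return num_frames x M matrix of positive filterbank energies.
#' @export
filterbankEnergies <- function(spectralEnergies, bank, floor_eps = 1e-10) {
  stopifnot(inherits(bank, "MelFilterBank"))
  if (ncol(spectralEnergies) != ncol(bank$H))
    stop("spectral grid (", ncol(spectralEnergies),
         ") does not match filterbank (", ncol(bank$H), ")")
  S <- spectralEnergies %*% t(bank$H)
  pmax(S, floor_eps)
}

#' Cepstral coefficients by log + discrete cosine transform
#'
#' mfcc(i,n) = sqrt(2/M) * sum_{m=0}^{M-1} log(S(i,m)) *
#' cos(pi * n * (2m + phase) / (2M)) for n = 1..n_keep. The 0th coefficient
#' (overall log-energy) is excluded; 12 coefficients are kept by default.
#' \code{dctPhase} selects the cosine argument convention: \code{"shifted"}
#' uses (2m - 1) with m counted from 0 (the convention this pipeline was
#' built around), \code{"standard"} the textbook DCT-II (2m + 1).
#'
#' @param S num_frames x M matrix of positive filterbank energies.
#' @param n_keep number of cepstral coefficients (default 12).
#' @param dctPhase \code{"shifted"} or \code{"standard"}.
#' @return num_frames x n_keep matrix of cepstral coefficients.
#' @export
computeMfcc <- function(S, n_keep = 12L, dctPhase = c("shifted", "standard")) {
  dctPhase <- match.arg(dctPhase)
  M <- ncol(S)
  if (!(n_keep >= 1L && n_keep <= M)) stop("need 1 <= n_keep <= M")
  if (any(S <= 0)) stop("filterbank energies must be positive (apply the floor)")
  logS <- log(S)
  m <- 0:(M - 1L)
  off <- if (dctPhase == "shifted") -1 else 1
  n <- seq_len(n_keep)
  basis <- sqrt(2 / M) *
    cos(pi * outer(2 * m + off, n) / (2 * M)) # M x n_keep
  logS %*% basis
}

#' Temporal regression deltas
#'
#' First-order difference coefficients by the standard regression formula
#' d_t = sum_{tau=1..width} tau * (c_{t+tau} - c_{t-tau}) / (2 * sum tau^2),
#' with edge frames replicated beyond the matrix boundary. Second-order
#' (delta-delta) coefficients are the delta of the delta.
#'
#' @param features num_frames x D matrix (frames in rows, time down rows).
#' @param width regression half-window in frames (default 2).
#' @return matrix of the same shape.
#' @export
deltaFeatures <- function(features, width = 2L) {
  if (!nrow(features)) return(features)
  if (width < 1L) stop("width must be >= 1")
  n <- nrow(features)
  if (n < 2L * width + 1L)
    warning("fewer frames (", n, ") than regression window (",
            2L * width + 1L, "); edge replication dominates")
  idx <- function(i) pmin(pmax(i, 1L), n)
  denom <- 2 * sum((1:width)^2)
  out <- matrix(0, n, ncol(features))
  t0 <- seq_len(n)
  for (tau in seq_len(width)) {
    out <- out + tau * (features[idx(t0 + tau), , drop = FALSE] -
                        features[idx(t0 - tau), , drop = FALSE])
  }
  out / denom
}

#' Assemble the 36-dimensional feature matrix for windowed frames
#'
#' Runs power spectrum -> Mel filterbank -> log-DCT cepstrum -> delta ->
#' delta-delta and column-binds them as
#' \code{[c1..c12 | d1..d12 | dd1..dd12]}.
#'
#' @param frames a windowed \code{"FrameMatrix"} (voiced frames).
#' @param bank a \code{"MelFilterBank"}; default built for the frame's rate.
#' @param n_fft FFT size; must match \code{bank}.
#' @param n_keep cepstral coefficients per block (default 12 -> 36 columns).
#' @param delta_width regression half-window (default 2).
#' @param dctPhase DCT convention, see [computeMfcc()].
#' @param floor_eps filterbank energy floor.
#' @return object of class \code{"FeatureMatrix"}: list with \code{values}
#'   (num_frames x 3*n_keep matrix with named columns), \code{normalized}
#'   (FALSE), and the extraction parameters.
#' @export
assembleFeatures <- function(frames, bank = NULL, n_fft = 2048L,
                             n_keep = 12L, delta_width = 2L,
                             dctPhase = "shifted", floor_eps = 1e-10) {
  stopifnot(inherits(frames, "FrameMatrix"))
  if (is.null(bank))
    bank <- melFilterbank(frames$sample_rate, n_fft = n_fft)
  E <- powerSpectrum(frames, n_fft = bank$n_fft)
  S <- filterbankEnergies(E, bank, floor_eps = floor_eps)
  cep <- computeMfcc(S, n_keep = n_keep, dctPhase = dctPhase)
  d1 <- deltaFeatures(cep, width = delta_width)
  d2 <- deltaFeatures(d1, width = delta_width)
  values <- cbind(cep, d1, d2)
  colnames(values) <- c(
    paste0("c", seq_len(n_keep)),
    paste0("d", seq_len(n_keep)),
    paste0("dd", seq_len(n_keep))
  )
  structure(
    list(values = values, normalized = FALSE, center = NULL, scale = NULL,
         n_keep = n_keep, delta_width = delta_width, dctPhase = dctPhase),
    class = "FeatureMatrix"
  )
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf(
    "FeatureMatrix: %d frames x %d features (%s)\n",
    nrow(x$values), ncol(x$values),
    if (x$normalized) "z-scored" else "raw"
  ))
  invisible(x)
}

#' Z-score features on training statistics
#'
#' Per-column mean/sd are estimated on the training matrix only and the
#' identical affine transform is applied to every other matrix (validation
#' and test sets never contribute statistics — the leakage guard). Standard
#' deviations are floored at 1e-8, so constant columns map to zero.
#'
#' @param train a \code{"FeatureMatrix"} (or plain matrix) of training frames.
#' @param ... further FeatureMatrix/matrix objects to transform with the
#'   training statistics.
#' @return list with \code{train}, one entry per extra matrix (named as
#'   passed), and \code{center}/\code{scale} vectors.
#' @export
normalizeFeatures <- function(train, ...) {
  asMat <- function(x) if (inherits(x, "FeatureMatrix")) x$values else x
  tr <- asMat(train)
  if (!nrow(tr)) stop("training feature matrix is empty")
  center <- colMeans(tr)
  scale <- pmax(apply(tr, 2L, stats::sd), 1e-8)
  apply1 <- function(x) {
    m <- asMat(x)
    v <- sweep(sweep(m, 2L, center, `-`), 2L, scale, `/`)
    if (inherits(x, "FeatureMatrix")) {
      x$values <- v
      x$normalized <- TRUE
      x$center <- center
      x$scale <- scale
      x
    } else v
  }
  extras <- lapply(list(...), apply1)
  c(list(train = apply1(train)), extras,
    list(center = center, scale = scale))
}

#' Log-magnitude spectrogram
#'
#' Diagnostic short-time Fourier magnitude of a signal (no pre-emphasis),
#' using the package's framing and Hamming window.
#'
#' @param signal an \linkS4class{AudioSignal}.
#' @param params [frameParams()] controlling frame/hop.
#' @param n_fft FFT size.
#' @param db if TRUE (default) return 10*log10 power with a -100 dB floor.
#' @return list of class \code{"Spectrogram"}: \code{mag} (num_frames x bins),
#'   \code{freq} Hz per bin, \code{time} seconds per frame centre.
#' @export
spectrogram <- function(signal, params = frameParams(), n_fft = 2048L,
                        db = TRUE) {
  fr <- frameSignal(signal, params)
  if (nrow(fr$frames)) fr <- applyWindow(fr)
  E <- powerSpectrum(fr, n_fft = n_fft, requireWindowed = FALSE)
  mag <- if (db) 10 * log10(pmax(E, 1e-10)) else sqrt(E)
  freq <- (0:(n_fft / 2)) * fr$sample_rate / n_fft
  time <- ((seq_len(nrow(E)) - 1L) * fr$hop + fr$L / 2) / fr$sample_rate
  structure(list(mag = mag, freq = freq, time = time), class = "Spectrogram")
}

#' Dominant-frequency trajectory of a spectrogram
#'
#' The frequency of the strongest bin per frame; used to verify synthetic
#' call contours (flat-then-rising for females, falling onset for males).
#'
#' @param spec a \code{"Spectrogram"}.
#' @param fmin,fmax restrict the search band (Hz).
#' @return numeric vector, Hz per frame.
#' @export
dominantFrequency <- function(spec, fmin = 0, fmax = Inf) {
  keep <- spec$freq >= fmin & spec$freq <= fmax
  f <- spec$freq[keep]
  m <- spec$mag[, keep, drop = FALSE]
  f[max.col(m, ties.method = "first")]
}
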