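# Short-time preprocessing: pre-emphasis, framing, Hamming windowing.
# Pipeline order is pre-emphasis -> framing -> (endpoint detection on raw
# frames) -> windowing -> spectral analysis.

#' Framing parameters
#'
#' Frame length 25 ms places the analysis window inside the 10-30 ms
#' quasi-stationarity range for duckling vocalisations; the 10 ms hop is
#' standard short-time analysis practice. The frame length in samples is
#' \code{L = floor(frame_length_ms * sample_rate / 1000)} (1102 at 44100 Hz).
#'
#' @param frame_length_ms analysis window length in milliseconds.
#' @param hop_length_ms hop (stride) between consecutive frames, ms.
#' @param pre_emphasis_alpha high-pass pre-emphasis coefficient in \[0, 1).
#' @param window_kind taper applied before spectral analysis; only
#'   \code{"hamming"} is supported.
#' @return a list of class \code{"FrameParams"}.
#' @export
frameParams <- function(frame_length_ms = 25, hop_length_ms = 10,
                        pre_emphasis_alpha = 0.95, window_kind = "hamming") {
  if (!(hop_length_ms > 0 && hop_length_ms <= frame_length_ms))
    stop("require 0 < hop_length_ms <= frame_length_ms")
  if (!(pre_emphasis_alpha >= 0 && pre_emphasis_alpha < 1))
    stop("pre_emphasis_alpha must lie in [0, 1)")
  window_kind <- match.arg(window_kind, "hamming")
  structure(
    list(
      frame_length_ms = frame_length_ms,
      hop_length_ms = hop_length_ms,
      pre_emphasis_alpha = pre_emphasis_alpha,
      window_kind = window_kind
    ),
    class = "FrameParams"
  )
}

#' Pre-emphasis filter
#'
#' First-order high-pass filter y(n) = x(n) - alpha * x(n-1), compensating
#' the propagation loss of high-frequency energy before spectral analysis.
#' The first output sample is passed through unchanged (no history is
#' invented): y(0) = x(0).
#'
#' @param signal an \linkS4class{AudioSignal}.
#' @param alpha filter coefficient in \[0, 1); 0 is the identity.
#' @return a filtered \linkS4class{AudioSignal} of the same length.
#' @export
preEmphasize <- function(signal, alpha = 0.95) {
  stopifnot(methods::is(signal, "AudioSignal"))
  if (!(alpha >= 0 && alpha < 1)) stop("alpha must lie in [0, 1)")
  x <- samples(signal)
  y <- x - alpha * c(0, x[-length(x)])
  audioSignal(y, sampleRate(signal), sourceId(signal))
}

#' Slice a signal into overlapping short-time frames
#'
#' Frames of length \code{L = floor(frame_length_ms * fs / 1000)} are taken
#' every \code{hop = floor(hop_length_ms * fs / 1000)} samples. Trailing
#' samples that do not fill a complete frame are dropped, giving
#' \code{1 + floor((n - L) / hop)} frames for a signal of n >= L samples.
#'
#' @param signal an \linkS4class{AudioSignal}.
#' @param params a [frameParams()] list.
#' @return an object of class \code{"FrameMatrix"}: list with \code{frames}
#'   (num_frames x L matrix), \code{L}, \code{hop}, \code{sample_rate},
#'   \code{windowed} (FALSE on creation).
#' @export
frameSignal <- function(signal, params = frameParams()) {
  stopifnot(methods::is(signal, "AudioSignal"))
  fs <- sampleRate(signal)
  L <- floor(params$frame_length_ms * fs / 1000)
  hop <- floor(params$hop_length_ms * fs / 1000)
  x <- samples(signal)
  n <- length(x)
  if (n < L) {
    warning("signal shorter than one frame (", n, " < ", L,
            " samples); returning empty FrameMatrix")
    num <- 0L
    frames <- matrix(numeric(0), nrow = 0L, ncol = L)
  } else {
    num <- 1L + (n - L) %/% hop
    starts <- (seq_len(num) - 1L) * hop
    idx <- outer(starts, seq_len(L), `+`) # num x L sample indices
    frames <- matrix(x[idx], nrow = num, ncol = L)
  }
  structure(
    list(frames = frames, L = L, hop = hop, sample_rate = fs,
         windowed = FALSE),
    class = "FrameMatrix"
  )
}

#' @export
print.FrameMatrix <- function(x, ...) {
  cat(sprintf(
    "FrameMatrix: %d frames x %d samples (hop %d) @ %d Hz, %swindowed\n",
    nrow(x$frames), x$L, x$hop, as.integer(x$sample_rate),
    if (x$windowed) "" else "un"
  ))
  invisible(x)
}

#' Hamming window weights
#'
#' w(n) = 0.54 - 0.46 cos(2 pi n / (N - 1)) for n = 0..N-1; the endpoints
#' equal 0.08 and the centre of an odd-length window equals exactly 1.
#'
#' @param N window length (>= 2).
#' @return numeric vector of N weights.
#' @export
hammingWindow <- function(N) {
  if (N < 2) stop("Hamming window needs N >= 2")
  n <- 0:(N - 1)
  0.54 - 0.46 * cos(2 * pi * n / (N - 1))
}

#' Apply the Hamming taper to every frame
#'
#' Multiplies each frame elementwise by [hammingWindow()] of the frame
#' length, reducing spectral leakage at frame edges. A FrameMatrix can be
#' windowed only once.
#'
#' @param frames an unwindowed \code{"FrameMatrix"}.
#' @return the windowed FrameMatrix (\code{windowed = TRUE}).
#' @export
applyWindow <- function(frames) {
  stopifnot(inherits(frames, "FrameMatrix"))
  if (frames$windowed) stop("FrameMatrix is already windowed")
  w <- hammingWindow(frames$L)
  frames$frames <- sweep(frames$frames, 2L, w, `*`)
  frames$windowed <- TRUE
  frames
}
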