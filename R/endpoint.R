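# Voice-activity endpoint detection by the zero-product method: the per-frame
# product K(i) = E(i) * Z(i) of short-term energy and zero-crossing rate is
# thresholded with hysteresis to locate call start/end points. Detection runs
# on unwindowed pre-emphasized frames: the Hamming taper would attenuate the
# frame-edge sign changes the zero-crossing count relies on.

#' Short-term energy per frame
#'
#' E(i) = sum over the frame of x_i(n)^2.
#'
#' @param frames a \code{"FrameMatrix"}.
#' @return numeric vector, one non-negative value per frame.
#' @export
shortTermEnergy <- function(frames) {
  stopifnot(inherits(frames, "FrameMatrix"))
  rowSums(frames$frames^2)
}

#' Short-term zero-crossing rate per frame
#'
#' Z(i) = 1/2 * sum over n of |sgn(x_i(n)) - sgn(x_i(n-1))| with
#' sgn(x) = 1 for x >= 0 and -1 otherwise. Frames are independent units:
#' the n = 0 term uses the convention x_i(-1) = x_i(0) and contributes zero
#' rather than reaching into the previous frame.
#'
#' @param frames a \code{"FrameMatrix"}.
#' @return numeric vector, one non-negative count per frame.
#' @export
zeroCrossingRate <- function(frames) {
  stopifnot(inherits(frames, "FrameMatrix"))
  s <- ifelse(frames$frames >= 0, 1, -1)
  if (ncol(s) < 2L) return(rep(0, nrow(s)))
  0.5 * rowSums(abs(s[, -1L, drop = FALSE] - s[, -ncol(s), drop = FALSE]))
}

#' Zero-product activity statistic
#'
#' K(i) = Z(i) * E(i), a single per-frame statistic combining loudness and
#' spectral content; duck calls (~2.5 kHz) score high on both, low-frequency
#' background noise scores low on Z even when energetic.
#'
#' @param E per-frame short-term energy.
#' @param Z per-frame zero-crossing rate.
#' @return numeric vector K of the same length.
#' @export
zeroProduct <- function(E, Z) {
  if (length(E) != length(Z))
    stop("E and Z must have equal length (", length(E), " vs ", length(Z), ")")
  E * Z
}

#' Per-frame activity series for a signal
#'
#' Convenience wrapper returning E, Z and K = E*Z for unwindowed frames.
#'
#' @param frames an unwindowed \code{"FrameMatrix"}.
#' @return list of class \code{"ActivitySeries"} with elements E, Z, K.
#' @export
activitySeries <- function(frames) {
  E <- shortTermEnergy(frames)
  Z <- zeroCrossingRate(frames)
  structure(list(E = E, Z = Z, K = zeroProduct(E, Z)),
            class = "ActivitySeries")
}

#' Dual-threshold endpoint detection on the zero-product series
#'
#' Thresholds are set relative to the per-recording maximum:
#' \code{T_high = high_frac * max(K)} seeds a candidate segment wherever
#' K >= T_high; the segment is extended in both directions while
#' K >= \code{T_low = low_frac * max(K)}. Segments separated by at most
#' \code{merge_gap} sub-threshold frames are merged, and segments shorter
#' than \code{min_frames} are discarded (rejects impulsive noise such as
#' birds stepping on the cage mesh while keeping short calls).
#'
#' @param K per-frame zero-product values.
#' @param high_frac seed threshold as a fraction of max(K).
#' @param low_frac extension threshold as a fraction of max(K);
#'   0 < low_frac < high_frac <= 1.
#' @param min_frames minimum segment length in frames.
#' @param merge_gap segments separated by <= this many frames are merged.
#' @param L,hop frame length and hop in samples, used to derive sample
#'   bounds (defaults match 25 ms / 10 ms at 44100 Hz).
#' @param n_samples total signal length, to clip the last segment's sample
#'   end; defaults to the end of the last frame.
#' @return a data.frame of class \code{"SegmentTable"} with columns
#'   start_frame, end_frame (half-open, 0-based), start_sample, end_sample.
#'   Zero rows when no frame reaches T_high (an all-silent recording is not
#'   an error).
#' @export
detectEndpoints <- function(K, high_frac = 0.10, low_frac = 0.02,
                            min_frames = 10L, merge_gap = 5L,
                            L = 1102L, hop = 441L, n_samples = NULL) {
  if (!length(K)) stop("K must be non-empty")
  if (!(low_frac > 0 && low_frac < high_frac && high_frac <= 1))
    stop("require 0 < low_frac < high_frac <= 1")
  kmax <- max(K)
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      start_sample = integer(0), end_sample = integer(0))
  class(empty) <- c("SegmentTable", "data.frame")
  if (kmax <= 0) return(empty)

  tHigh <- high_frac * kmax
  tLow <- low_frac * kmax
  low <- K >= tLow
  # runs of consecutive low-threshold frames
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  seg <- cbind(start = starts[keep], end = ends[keep]) # 1-based inclusive
  # keep only runs containing a seed frame
  hasSeed <- apply(seg, 1L, function(s) any(K[s[1]:s[2]] >= tHigh))
  seg <- seg[hasSeed, , drop = FALSE]
  if (!nrow(seg)) return(empty)
  # merge segments separated by <= merge_gap frames
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1L) {
    for (i in 2:nrow(seg)) {
      gap <- seg[i, "start"] - merged[nrow(merged), "end"] - 1L
      if (gap <= merge_gap) {
        merged[nrow(merged), "end"] <- seg[i, "end"]
      } else {
        merged <- rbind(merged, seg[i, , drop = FALSE])
      }
    }
  }
  len <- merged[, "end"] - merged[, "start"] + 1L
  merged <- merged[len >= min_frames, , drop = FALSE]
  if (!nrow(merged)) return(empty)

  startFrame <- as.integer(merged[, "start"] - 1L) # 0-based
  endFrame <- as.integer(merged[, "end"])          # half-open
  startSample <- startFrame * as.integer(hop)
  endSample <- (endFrame - 1L) * as.integer(hop) + as.integer(L)
  if (!is.null(n_samples)) endSample <- pmin(endSample, as.integer(n_samples))
  out <- data.frame(start_frame = startFrame, end_frame = endFrame,
                    start_sample = startSample, end_sample = endSample)
  class(out) <- c("SegmentTable", "data.frame")
  out
}

#' Extract the voiced portions of a signal
#'
#' Returns one sub-signal per detected segment, sample-accurate (samples
#' \code{start_sample + 1 .. end_sample} in 1-based R indexing).
#'
#' @param signal the \linkS4class{AudioSignal} the segments refer to.
#' @param segments a \code{"SegmentTable"} from [detectEndpoints()].
#' @return list of \linkS4class{AudioSignal} objects (possibly empty).
#' @export
extractVoiced <- function(signal, segments) {
  stopifnot(methods::is(signal, "AudioSignal"))
  n <- length(samples(signal))
  if (!nrow(segments)) return(list())
  if (any(segments$start_sample < 0) || any(segments$end_sample > n))
    stop("segment sample bounds outside signal [0, ", n, "]")
  lapply(seq_len(nrow(segments)), function(i) {
    audioSignal(
      samples(signal)[(segments$start_sample[i] + 1L):segments$end_sample[i]],
      sampleRate(signal),
      sourceId = sourceId(signal)
    )
  })
}

#' Segment report table
#'
#' Formats a SegmentTable as the CSV-ready report with times in seconds.
#'
#' @param segments a \code{"SegmentTable"}.
#' @param duck_id identifier to attach.
#' @param sample_rate sampling rate used for second conversion.
#' @return data.frame with duck_id, segment_index, start_sample, end_sample,
#'   start_sec, end_sec.
#' @export
segmentReport <- function(segments, duck_id, sample_rate = 44100) {
  data.frame(
    duck_id = rep(duck_id, nrow(segments)),
    segment_index = seq_len(nrow(segments)),
    start_sample = segments$start_sample,
    end_sample = segments$end_sample,
    start_sec = segments$start_sample / sample_rate,
    end_sec = segments$end_sample / sample_rate
  )
}
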