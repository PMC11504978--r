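#' AudioSignal: a mono waveform with its sample rate
#'
#' S4 container for a single-channel audio signal. Samples are stored as a
#' numeric vector normalised to \[-1, 1\] (16-bit PCM is divided by 2^15 on
#' read). All processing functions in the package consume and return this
#' class.
#'
#' @slot samples numeric vector of amplitudes in \[-1, 1\].
#' @slot sampleRate positive integer, samples per second (Hz).
#' @slot sourceId optional identifier (e.g. a duck ID or file stem).
#'
#' @examples
#' s <- audioSignal(sin(2 * pi * 440 * (0:999) / 44100), 44100)
#' duration(s)
#' @export
setClass("AudioSignal",
  representation(
    samples = "numeric",
    sampleRate = "numeric",
    sourceId = "character"
  ),
  prototype(sourceId = NA_character_)
)

setValidity("AudioSignal", function(object) {
  msgs <- character()
  if (length(object@samples) < 1L)
    msgs <- c(msgs, "signal must contain at least one sample")
  if (!all(is.finite(object@samples)))
    msgs <- c(msgs, "all samples must be finite")
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0 || object@sampleRate != round(object@sampleRate))
    msgs <- c(msgs, "sampleRate must be a single positive integer")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AudioSignal
#'
#' @param samples numeric vector of amplitudes.
#' @param sampleRate sampling rate in Hz.
#' @param sourceId optional identifier string.
#' @return an \linkS4class{AudioSignal}.
#' @export
audioSignal <- function(samples, sampleRate, sourceId = NA_character_) {
  methods::new("AudioSignal",
    samples = as.numeric(samples),
    sampleRate = as.numeric(sampleRate),
    sourceId = as.character(sourceId)
  )
}

#' @describeIn audioSignal sample vector accessor.
#' @param x an AudioSignal.
#' @export
samples <- function(x) x@samples

#' @describeIn audioSignal sample rate accessor (Hz).
#' @export
sampleRate <- function(x) x@sampleRate

#' @describeIn audioSignal identifier accessor.
#' @export
sourceId <- function(x) x@sourceId

#' @describeIn audioSignal duration in seconds.
#' @export
duration <- function(x) length(x@samples) / x@sampleRate

#' @rdname AudioSignal-class
#' @param object an AudioSignal.
#' @exportMethod show
setMethod("show", "AudioSignal", function(object) {
  cat(sprintf(
    "AudioSignal: %d samples @ %d Hz (%.3f s)%s\n",
    length(object@samples), as.integer(object@sampleRate),
    duration(object),
    if (is.na(object@sourceId)) "" else paste0(" [", object@sourceId, "]")
  ))
  cat(sprintf(
    "  amplitude range [%.4f, %.4f]\n",
    min(object@samples), max(object@samples)
  ))
})

#' @export
length.AudioSignal <- function(x) length(x@samples)
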