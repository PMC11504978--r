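# Minimal RIFF/WAVE codec for 16-bit PCM mono, plus dataset manifests.
# Only the canonical chunks are handled: "fmt " is required before "data";
# unknown chunks are skipped by their declared size.

#' Read a mono 16-bit PCM WAV file
#'
#' Parses a RIFF/WAVE file and returns the waveform scaled to \[-1, 1\]
#' (integer PCM divided by 2^(bits-1)). Only uncompressed 16-bit PCM mono is
#' accepted: stereo files are rejected rather than silently down-mixed, since
#' no down-mix policy preserves the short-term energy statistics downstream
#' stages depend on.
#'
#' @param path path to a .wav file.
#' @param expectedRate required sampling rate in Hz (default 44100). Files at
#'   a different rate are rejected unless \code{resample = TRUE}.
#' @param resample if TRUE, input at another rate is resampled to
#'   \code{expectedRate} with a polyphase linear-phase FIR
#'   (\code{signal::resample}).
#' @return an \linkS4class{AudioSignal}; \code{sourceId} is the file stem.
#' @seealso [writeWav()]
#' @export
readWav <- function(path, expectedRate = 44100L, resample = FALSE) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little") # total size, unused
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L)
      stop("WAV file has no data chunk: ", path)
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audioFormat = readBin(raw[1:2], "integer", 1L, 2L, endian = "little"),
        channels    = readBin(raw[3:4], "integer", 1L, 2L, endian = "little"),
        sampleRate  = readBin(raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits        = readBin(raw[15:16], "integer", 1L, 2L, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$audioFormat != 1L)
        stop("unsupported WAV encoding (format tag ", fmt$audioFormat,
             "); only uncompressed PCM is supported")
      if (fmt$channels != 1L)
        stop("multichannel WAV rejected: file has ", fmt$channels,
             " channels, expected mono")
      if (fmt$bits != 16L)
        stop("unsupported bit depth ", fmt$bits, "; only 16-bit PCM is supported")
      n <- sz %/% 2L
      pcm <- readBin(con, "integer", n, size = 2L, signed = TRUE,
                     endian = "little")
      x <- pcm / 32768
      rate <- fmt$sampleRate
      if (rate != expectedRate) {
        if (!resample)
          stop("sample rate ", rate, " Hz differs from expected ",
               expectedRate, " Hz; pass resample = TRUE to convert")
        x <- as.numeric(signal::resample(x, p = expectedRate, q = rate))
        rate <- expectedRate
      }
      stem <- sub("\\.[Ww][Aa][Vv]$", "", basename(path))
      return(audioSignal(x, rate, sourceId = stem))
    } else {
      # skip unknown chunk (word-aligned)
      seek(con, where = sz + (sz %% 2L), origin = "current")
    }
  }
}

#' Write an AudioSignal as a 16-bit PCM mono WAV file
#'
#' Amplitudes outside \[-1, 1\] are clipped with a warning. Quantisation maps
#' 1.0 to 32767 and -1.0 to -32768.
#'
#' @param signal an \linkS4class{AudioSignal}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeWav <- function(signal, path) {
  stopifnot(methods::is(signal, "AudioSignal"))
  x <- samples(signal)
  if (any(x > 1 | x < -1)) {
    warning("samples outside [-1, 1] clipped before quantisation")
    x <- pmin(1, pmax(-1, x))
  }
  pcm <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
  n <- length(pcm)
  rate <- as.integer(sampleRate(signal))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2L, endian = "little")           # PCM
  writeBin(1L, con, size = 2L, endian = "little")           # mono
  writeBin(rate, con, size = 4L, endian = "little")
  writeBin(rate * 2L, con, size = 4L, endian = "little")    # byte rate
  writeBin(2L, con, size = 2L, endian = "little")           # block align
  writeBin(16L, con, size = 2L, endian = "little")          # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Load and validate a dataset manifest
#'
#' A manifest is a UTF-8 CSV with header columns \code{wav_path, duck_id,
#' sex, split} mapping one recording to one individual. Sex tokens must be
#' exactly "male" or "female" (case-insensitive; normalised to lowercase);
#' anything else — including abbreviations — is a validation error, as label
#' hygiene for a binary task. \code{split} must be one of train, test,
#' unassigned (empty treated as unassigned).
#'
#' @param path manifest CSV path.
#' @param checkPaths if TRUE (default), every referenced WAV must exist
#'   (relative paths resolved against the manifest's directory).
#' @return a data.frame of class \code{"DatasetManifest"} with character
#'   columns wav_path, duck_id, sex, split.
#' @export
loadManifest <- function(path, checkPaths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("wav_path", "duck_id", "sex", "split")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest missing required column(s): ", paste(missing, collapse = ", "))
  df <- df[required]
  df$sex <- tolower(trimws(df$sex))
  df$split <- tolower(trimws(df$split))
  df$split[df$split == ""] <- "unassigned"

  dup <- unique(df$duck_id[duplicated(df$duck_id)])
  if (length(dup))
    stop("duplicate duck_id in manifest: ", paste(dup, collapse = ", "))
  badSex <- unique(df$sex[!df$sex %in% c("male", "female")])
  if (length(badSex))
    stop("unknown sex token(s): ", paste(badSex, collapse = ", "),
         ' (only "male"/"female" accepted)')
  badSplit <- unique(df$split[!df$split %in% c("train", "test", "unassigned")])
  if (length(badSplit))
    stop("unknown split token(s): ", paste(badSplit, collapse = ", "))
  if (checkPaths) {
    paths <- df$wav_path
    rel <- !grepl("^(/|[A-Za-z]:)", paths)
    paths[rel] <- file.path(dirname(path), paths[rel])
    bad <- df$wav_path[!file.exists(paths)]
    if (length(bad))
      stop("manifest references missing file(s): ", paste(bad, collapse = ", "))
    df$wav_path <- paths
  }
  class(df) <- c("DatasetManifest", "data.frame")
  df
}

#' Write a dataset manifest CSV
#'
#' @param manifest a data.frame with columns wav_path, duck_id, sex, split.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(
    as.data.frame(manifest)[c("wav_path", "duck_id", "sex", "split")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
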