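# End-to-end pipeline drivers tying the stages together:
# synth -> features -> train -> evaluate / cross-validate.
# Every run directory receives the resolved configuration (YAML) and seed.

#' Default experiment configuration
#'
#' A plain nested list, YAML-serialisable, collecting every tunable of the
#' pipeline. CLI flags override file values; the resolved configuration is
#' written next to each stage's outputs for provenance.
#'
#' @param seed master seed.
#' @return nested list of class \code{"ExperimentConfig"}.
#' @export
experimentConfig <- function(seed = 1L) {
  structure(
    list(
      seed = as.integer(seed),
      frame = list(frame_length_ms = 25, hop_length_ms = 10,
                   pre_emphasis_alpha = 0.95),
      endpoint = list(high_frac = 0.10, low_frac = 0.02,
                      min_frames = 10L, merge_gap = 5L),
      mfcc = list(n_fft = 2048L, n_mels = 26L, n_keep = 12L,
                  delta_width = 2L, dct_phase = "shifted"),
      model = list(kind = "cnn"),
      train = list(epochs = 100L, batch_size = 256L, lr = 1e-3,
                   validation_split = 0.15),
      data = list(n_train_per_sex = 120L, n_test_per_sex = 30L,
                  n_frames_per_duck = 3000L),
      synth = list(n_per_sex = 10L, calls_per_duck = 10L, snr_db = 20)
    ),
    class = "ExperimentConfig"
  )
}

#' Read / write an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @return [readConfig()]: the configuration list (defaults filled in for
#'   missing keys); [writeConfig()]: the path, invisibly.
#' @export
readConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- experimentConfig()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]]))
      cfg[[k]] <- utils::modifyList(cfg[[k]], user[[k]])
    else cfg[[k]] <- user[[k]]
  }
  cfg
}

#' @rdname readConfig
#' @param config an \code{"ExperimentConfig"}.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Extract voiced-frame features for one signal
#'
#' The full front-end in pipeline order: pre-emphasis -> framing ->
#' endpoint detection on raw (unwindowed) frames -> Hamming windowing of
#' the voiced frames -> MFCC + delta + delta-delta assembly. Deltas are
#' computed per voiced segment, so dynamics never straddle a silence.
#'
#' @param signal an \linkS4class{AudioSignal}.
#' @param config an [experimentConfig()].
#' @return list with \code{features} (a \code{"FeatureMatrix"} stacking all
#'   voiced segments), \code{segments} (the \code{"SegmentTable"}), and
#'   \code{n_voiced_frames}.
#' @export
extractFeatures <- function(signal, config = experimentConfig()) {
  fp <- frameParams(config$frame$frame_length_ms, config$frame$hop_length_ms,
                    config$frame$pre_emphasis_alpha)
  pre <- preEmphasize(signal, fp$pre_emphasis_alpha)
  fr <- frameSignal(pre, fp)
  if (!nrow(fr$frames)) {
    return(list(features = NULL, segments = NULL, n_voiced_frames = 0L))
  }
  act <- activitySeries(fr)
  seg <- detectEndpoints(act$K,
                         high_frac = config$endpoint$high_frac,
                         low_frac = config$endpoint$low_frac,
                         min_frames = config$endpoint$min_frames,
                         merge_gap = config$endpoint$merge_gap,
                         L = fr$L, hop = fr$hop,
                         n_samples = length(samples(signal)))
  if (!nrow(seg))
    return(list(features = NULL, segments = seg, n_voiced_frames = 0L))
  bank <- melFilterbank(fr$sample_rate, n_fft = config$mfcc$n_fft,
                        M = config$mfcc$n_mels)
  perSeg <- lapply(seq_len(nrow(seg)), function(i) {
    sub <- fr
    sub$frames <- fr$frames[(seg$start_frame[i] + 1L):seg$end_frame[i], ,
                            drop = FALSE]
    sub <- applyWindow(sub)
    assembleFeatures(sub, bank = bank,
                     n_keep = config$mfcc$n_keep,
                     delta_width = config$mfcc$delta_width,
                     dctPhase = config$mfcc$dct_phase)$values
  })
  values <- do.call(rbind, perSeg)
  feats <- structure(
    list(values = values, normalized = FALSE, center = NULL, scale = NULL,
         n_keep = config$mfcc$n_keep, delta_width = config$mfcc$delta_width,
         dctPhase = config$mfcc$dct_phase),
    class = "FeatureMatrix"
  )
  list(features = feats, segments = seg, n_voiced_frames = nrow(values))
}

#' Extract features for every duck in a corpus
#'
#' @param corpus either a \code{"DatasetManifest"} data.frame (WAVs read
#'   from disk) or the in-memory list returned by [synthDataset()].
#' @param config an [experimentConfig()].
#' @param verbose log per-duck voiced-frame counts.
#' @return list with \code{features} (named list of \code{"FeatureMatrix"}),
#'   \code{sexes} (named character vector), \code{segments} (named list),
#'   \code{excluded} (ids with zero voiced frames, dropped with a warning).
#' @export
corpusFeatures <- function(corpus, config = experimentConfig(),
                           verbose = FALSE) {
  if (inherits(corpus, "DatasetManifest") || is.data.frame(corpus)) {
    manifest <- corpus
    getSignal <- function(i) readWav(manifest$wav_path[i])
  } else {
    manifest <- corpus$manifest
    getSignal <- function(i) {
      sig <- corpus$signals[[manifest$duck_id[i]]]
      if (is.null(sig)) readWav(manifest$wav_path[i]) else sig
    }
  }
  feats <- list(); segs <- list(); excluded <- character(0)
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$duck_id[i]
    res <- extractFeatures(getSignal(i), config)
    if (res$n_voiced_frames == 0L) {
      excluded <- c(excluded, id)
      next
    }
    feats[[id]] <- res$features
    segs[[id]] <- res$segments
    if (verbose)
      message(sprintf("%s: %d voiced frames in %d segment(s)", id,
                      res$n_voiced_frames, nrow(res$segments)))
  }
  if (length(excluded))
    warning("excluded duck(s) with no voiced segments: ",
            paste(excluded, collapse = ", "))
  sexes <- stats::setNames(manifest$sex, manifest$duck_id)
  list(features = feats, sexes = sexes[names(feats)], segments = segs,
       excluded = excluded)
}

#' Train a sex classifier on a duck-level split
#'
#' Samples a balanced frame set from the training ducks, fits the z-score
#' normalisation on those frames only, and trains the requested
#' architecture.
#'
#' @param features named list of per-duck feature matrices.
#' @param sexes named character vector duck_id -> sex.
#' @param trainIds duck ids forming the training partition.
#' @param config an [experimentConfig()].
#' @param epochs,n_frames_per_duck optional overrides of the config values.
#' @return list with \code{model} (trained \code{"duckNet"}),
#'   \code{center}/\code{scale} normalisation statistics, \code{history}.
#' @export
trainPipeline <- function(features, sexes, trainIds,
                          config = experimentConfig(),
                          epochs = NULL, n_frames_per_duck = NULL) {
  nGet <- if (is.null(n_frames_per_duck)) config$data$n_frames_per_duck
          else n_frames_per_duck
  tr <- sampleFrames(features[trainIds], sexes, n_per_duck = nGet,
                     seed = config$seed)
  norm <- normalizeFeatures(tr$features)
  tc <- trainConfig(
    epochs = if (is.null(epochs)) config$train$epochs else epochs,
    batch_size = config$train$batch_size,
    lr = config$train$lr,
    validation_split = config$train$validation_split,
    seed = config$seed
  )
  model <- buildModel(modelSpec(config$model$kind), input_dim = 36L,
                      seed = config$seed)
  model <- trainModel(model, norm$train, tr$labels, tc)
  list(model = model, center = norm$center, scale = norm$scale,
       history = model$history)
}

#' Evaluate a trained model on held-out ducks
#'
#' Applies the training normalisation, predicts every voiced frame of each
#' test duck, aggregates by majority vote and scores the duck-level calls.
#'
#' @param fit result of [trainPipeline()].
#' @param features named list of per-duck feature matrices.
#' @param sexes named character vector.
#' @param testIds duck ids forming the test partition.
#' @return list with \code{metrics} (\code{"MetricSet"}), \code{perDuck}
#'   (data.frame duck_id, true_sex, vote_fraction, predicted_sex) and
#'   \code{frameMetrics} (frame-level \code{"MetricSet"}).
#' @export
evaluatePipeline <- function(fit, features, sexes, testIds) {
  rows <- vector("list", length(testIds))
  frameTruth <- character(0); framePred <- character(0)
  for (j in seq_along(testIds)) {
    id <- testIds[j]
    m <- features[[id]]
    m <- if (inherits(m, "FeatureMatrix")) m$values else m
    mz <- sweep(sweep(m, 2L, fit$center, `-`), 2L, fit$scale, `/`)
    probs <- predictFrames(fit$model, mz)
    dp <- aggregateDuck(probs, id, sexes[[id]])
    rows[[j]] <- data.frame(duck_id = id, true_sex = sexes[[id]],
                            vote_fraction = dp$frame_vote_fraction,
                            predicted_sex = dp$predicted_sex)
    frameTruth <- c(frameTruth, rep(sexes[[id]], nrow(mz)))
    framePred <- c(framePred, dp$frame_labels)
  }
  perDuck <- do.call(rbind, rows)
  list(
    metrics = classificationMetrics(
      confusionCounts(perDuck$true_sex, perDuck$predicted_sex)),
    perDuck = perDuck,
    frameMetrics = classificationMetrics(
      confusionCounts(frameTruth, framePred))
  )
}

#' Run the full synthetic benchmark
#'
#' Generates a corpus, extracts features, splits at the duck level, trains
#' the configured model and evaluates it on the held-out ducks. This is the
#' package's end-to-end smoke/benchmark path.
#'
#' @param n_train_per_sex,n_test_per_sex ducks per sex in each partition.
#' @param config an [experimentConfig()] (its \code{model$kind}, seeds and
#'   frame/MFCC settings are honoured).
#' @param calls_per_duck calls per synthetic bird.
#' @param n_frames_per_duck frames sampled per training duck.
#' @param epochs training epochs.
#' @return list with \code{evaluation} (see [evaluatePipeline()]),
#'   \code{fit}, \code{corpusInfo}.
#' @export
runBenchmark <- function(n_train_per_sex = 20L, n_test_per_sex = 5L,
                         config = experimentConfig(seed = 42L),
                         calls_per_duck = 6L, n_frames_per_duck = 120L,
                         epochs = 12L) {
  nSex <- n_train_per_sex + n_test_per_sex
  corpus <- synthDataset(
    n_per_sex = nSex, calls_per_duck = calls_per_duck,
    rec = recordingSpec(snr_db = config$synth$snr_db),
    seed = config$seed
  )
  cf <- corpusFeatures(corpus, config)
  manifest <- corpus$manifest[corpus$manifest$duck_id %in% names(cf$features), ]
  split <- splitDataset(manifest, n_train_per_sex, n_test_per_sex,
                        seed = config$seed)
  trainIds <- split$duck_id[split$split == "train"]
  testIds <- split$duck_id[split$split == "test"]
  fit <- trainPipeline(cf$features, cf$sexes, trainIds, config,
                       epochs = epochs,
                       n_frames_per_duck = n_frames_per_duck)
  ev <- evaluatePipeline(fit, cf$features, cf$sexes, testIds)
  list(evaluation = ev, fit = fit,
       corpusInfo = list(n_train = length(trainIds), n_test = length(testIds)))
}
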