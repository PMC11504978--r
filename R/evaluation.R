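# Confusion-matrix evaluation with male as the positive class, per-duck
# majority-vote aggregation of frame decisions, duck-level stratified
# splitting and k-fold cross-validation, and balanced frame sampling.

#' Binary confusion counts (male = positive)
#'
#' @param truth character vector of true labels ("male"/"female").
#' @param predicted character vector of predicted labels, same length.
#' @param positive the positive class (default "male").
#' @return list of class \code{"ConfusionCounts"} with TP, FP, FN, TN.
#' @export
confusionCounts <- function(truth, predicted, positive = "male") {
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length (", length(truth), " vs ",
         length(predicted), ")")
  truth <- as.character(truth); predicted <- as.character(predicted)
  p <- truth == positive
  q <- predicted == positive
  structure(
    list(TP = sum(p & q), FP = sum(!p & q),
         FN = sum(p & !q), TN = sum(!p & !q), positive = positive),
    class = "ConfusionCounts"
  )
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  cat(sprintf("ConfusionCounts (positive = %s): TP %d  FP %d  FN %d  TN %d\n",
              x$positive, x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' accuracy = (TP+TN)/total; recall = TP/(TP+FN) — the recognition accuracy
#' for male ducks; specificity = TN/(FP+TN) — the recognition accuracy for
#' female ducks; precision = TP/(TP+FP); F1 = 2PR/(P+R). A zero denominator
#' yields 0 with a warning. Values are fractions in \[0, 1\]; the print
#' method shows percent to two decimals.
#'
#' @param counts a \code{"ConfusionCounts"}.
#' @return list of class \code{"MetricSet"} with accuracy, recall,
#'   specificity, precision, f1 and the counts.
#' @export
classificationMetrics <- function(counts) {
  stopifnot(inherits(counts, "ConfusionCounts"))
  total <- counts$TP + counts$FP + counts$FN + counts$TN
  if (total == 0L) stop("confusion counts are all zero")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0")
      0
    } else num / den
  }
  accuracy <- (counts$TP + counts$TN) / total
  recall <- safe(counts$TP, counts$TP + counts$FN, "recall")
  specificity <- safe(counts$TN, counts$FP + counts$TN, "specificity")
  precision <- safe(counts$TP, counts$TP + counts$FP, "precision")
  f1 <- if (precision + recall == 0) {
    warning("zero denominator for f1; reporting 0")
    0
  } else 2 * precision * recall / (precision + recall)
  structure(
    list(accuracy = accuracy, recall = recall, specificity = specificity,
         precision = precision, f1 = f1, counts = counts),
    class = "MetricSet"
  )
}

#' @export
print.MetricSet <- function(x, ...) {
  cat(sprintf(
    "MetricSet: accuracy %.2f%%  recall %.2f%%  specificity %.2f%%  precision %.2f%%  F1 %.2f%%\n",
    100 * x$accuracy, 100 * x$recall, 100 * x$specificity,
    100 * x$precision, 100 * x$f1
  ))
  invisible(x)
}

#' Aggregate frame probabilities to a per-duck sex call
#'
#' Each frame votes with its argmax label; the fraction of frames voting
#' male is recorded, and the duck is called male iff that fraction exceeds
#' 0.5. An exact 50/50 tie is called male — a fixed, documented rule so the
#' decision is deterministic. \code{method = "mean_prob"} instead averages
#' the male probability over frames before thresholding.
#'
#' @param frame_probs num_frames x 2 matrix from [predictFrames()].
#' @param duck_id identifier of the bird.
#' @param true_sex "male"/"female" (optional, NA allowed).
#' @param method "vote" (default) or "mean_prob".
#' @return list of class \code{"DuckPrediction"}: duck_id, true_sex,
#'   frame_labels, frame_vote_fraction, predicted_sex.
#' @export
aggregateDuck <- function(frame_probs, duck_id, true_sex = NA_character_,
                          method = c("vote", "mean_prob")) {
  method <- match.arg(method)
  if (!nrow(frame_probs)) stop("no frames to aggregate for duck ", duck_id)
  labels <- frameLabels(frame_probs)
  voteFrac <- mean(labels == "male")
  score <- if (method == "vote") voteFrac else mean(frame_probs[, "male"])
  predicted <- if (score >= 0.5) "male" else "female"
  structure(
    list(duck_id = duck_id, true_sex = true_sex, frame_labels = labels,
         frame_vote_fraction = voteFrac, predicted_sex = predicted,
         method = method),
    class = "DuckPrediction"
  )
}

#' @export
print.DuckPrediction <- function(x, ...) {
  cat(sprintf("DuckPrediction %s: %s (vote fraction %.3f over %d frames%s)\n",
              x$duck_id, x$predicted_sex, x$frame_vote_fraction,
              length(x$frame_labels),
              if (is.na(x$true_sex)) "" else paste0(", truth ", x$true_sex)))
  invisible(x)
}

#' Stratified duck-level train/test split
#'
#' Randomly assigns \code{n_train_per_sex} ducks of each sex to the training
#' partition and \code{n_test_per_sex} to the test partition (disjoint;
#' never a frame-level split, so no bird leaks across partitions).
#'
#' @param manifest a \code{"DatasetManifest"} data.frame.
#' @param n_train_per_sex,n_test_per_sex ducks per sex in each partition
#'   (defaults 120 and 30, i.e. 240 train / 60 test at full roster).
#' @param seed RNG seed.
#' @return the manifest with its \code{split} column filled
#'   (train/test/unassigned).
#' @export
splitDataset <- function(manifest, n_train_per_sex = 120L,
                         n_test_per_sex = 30L, seed = 1L) {
  need <- n_train_per_sex + n_test_per_sex
  for (sx in c("male", "female")) {
    have <- sum(manifest$sex == sx)
    if (have < need)
      stop("not enough ", sx, " ducks: need ", need, ", have ", have)
  }
  manifest$split <- "unassigned"
  withr::with_seed(seed, {
    for (sx in c("male", "female")) {
      ids <- manifest$duck_id[manifest$sex == sx]
      pick <- sample(ids, need)
      manifest$split[manifest$duck_id %in% pick[seq_len(n_train_per_sex)]] <- "train"
      manifest$split[manifest$duck_id %in%
                       pick[n_train_per_sex + seq_len(n_test_per_sex)]] <- "test"
    }
  })
  manifest
}

#' Balanced frame sampling per duck
#'
#' Draws exactly \code{n_per_duck} feature frames from each duck: a uniform
#' subsample without replacement when the duck has at least that many voiced
#' frames, with replacement (and a warning) when it has fewer, so the
#' resulting dataset is balanced across birds.
#'
#' @param features_per_duck named list (by duck_id) of feature matrices or
#'   \code{"FeatureMatrix"} objects.
#' @param sexes named character vector mapping duck_id to "male"/"female".
#' @param n_per_duck frames per duck (default 3000).
#' @param seed RNG seed.
#' @return list with \code{features} (stacked matrix), \code{labels}
#'   (character), \code{duck_id} (character), all of length
#'   n_per_duck * n_ducks.
#' @export
sampleFrames <- function(features_per_duck, sexes, n_per_duck = 3000L,
                         seed = 1L) {
  ids <- names(features_per_duck)
  if (is.null(ids)) stop("features_per_duck must be a named list")
  mats <- lapply(features_per_duck, function(x)
    if (inherits(x, "FeatureMatrix")) x$values else x)
  zero <- ids[vapply(mats, nrow, integer(1)) == 0L]
  if (length(zero))
    stop("duck(s) with zero voiced frames: ", paste(zero, collapse = ", "))
  short <- ids[vapply(mats, nrow, integer(1)) < n_per_duck]
  if (length(short))
    warning(length(short), " duck(s) have fewer than ", n_per_duck,
            " voiced frames; sampling with replacement")
  withr::with_seed(seed, {
    picks <- lapply(mats, function(m) {
      n <- nrow(m)
      if (n >= n_per_duck) sample.int(n, n_per_duck)
      else sample.int(n, n_per_duck, replace = TRUE)
    })
  })
  features <- do.call(rbind, Map(function(m, p) m[p, , drop = FALSE],
                                 mats, picks))
  list(
    features = features,
    labels = rep(as.character(sexes[ids]), each = n_per_duck),
    duck_id = rep(ids, each = n_per_duck)
  )
}

#' Duck-level stratified k-fold cross-validation
#'
#' Ducks (never frames) of each sex are partitioned into k folds whose sizes
#' differ by at most one bird. For each fold a fresh model is trained on the
#' other k-1 folds and evaluated on the held-out ducks by majority vote;
#' the per-fold duck-level metrics and their mean/sd are returned.
#'
#' @param features_per_duck named list of per-duck feature matrices
#'   (raw; normalisation is fitted inside each fold on its training ducks).
#' @param sexes named character vector duck_id -> sex.
#' @param k number of folds (default 5).
#' @param spec a [modelSpec()].
#' @param config a [trainConfig()].
#' @param n_per_duck frames sampled per duck within each fold.
#' @param seed RNG seed for fold assignment (fold f trains with seed
#'   \code{config$seed + f}).
#' @return list of class \code{"CVResult"}: \code{folds} (data.frame of
#'   per-fold metrics), \code{mean}, \code{sd}.
#' @export
kfoldCV <- function(features_per_duck, sexes, k = 5L, spec = modelSpec("bpnn"),
                    config = trainConfig(), n_per_duck = 200L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  ids <- names(features_per_duck)
  sexes <- sexes[ids]
  for (sx in c("male", "female"))
    if (sum(sexes == sx) < k)
      stop("need at least k = ", k, " ducks per sex; have ",
           sum(sexes == sx), " ", sx)
  fold <- integer(length(ids)); names(fold) <- ids
  withr::with_seed(seed, {
    for (sx in c("male", "female")) {
      who <- sample(ids[sexes == sx])
      fold[who] <- rep_len(seq_len(k), length(who))
    }
  })
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    trainIds <- ids[fold != f]
    testIds <- ids[fold == f]
    tr <- sampleFrames(features_per_duck[trainIds], sexes,
                       n_per_duck = n_per_duck, seed = seed + f)
    norm <- normalizeFeatures(tr$features)
    foldCfg <- config
    foldCfg$seed <- config$seed + f
    model <- buildModel(spec, input_dim = ncol(tr$features),
                        seed = config$seed + f)
    model <- trainModel(model, norm$train, tr$labels, foldCfg)
    preds <- vapply(testIds, function(id) {
      m <- features_per_duck[[id]]
      m <- if (inherits(m, "FeatureMatrix")) m$values else m
      mz <- sweep(sweep(m, 2L, norm$center, `-`), 2L, norm$scale, `/`)
      aggregateDuck(predictFrames(model, mz), id, sexes[[id]])$predicted_sex
    }, character(1))
    met <- classificationMetrics(confusionCounts(sexes[testIds], preds))
    rows[[f]] <- data.frame(
      fold = f, accuracy = met$accuracy, recall = met$recall,
      specificity = met$specificity, precision = met$precision, f1 = met$f1
    )
  }
  folds <- do.call(rbind, rows)
  metricCols <- c("accuracy", "recall", "specificity", "precision", "f1")
  structure(
    list(folds = folds,
         mean = colMeans(folds[metricCols]),
         sd = apply(folds[metricCols], 2L, stats::sd)),
    class = "CVResult"
  )
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("CVResult over %d folds: accuracy %.2f%% +/- %.2f%%\n",
              nrow(x$folds), 100 * x$mean["accuracy"], 100 * x$sd["accuracy"]))
  invisible(x)
}
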