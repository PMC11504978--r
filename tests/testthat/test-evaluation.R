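# helper: label vector with a given number of correct predictions per sex
predsWith <- function(nMale = 30, nFemale = 30, okMale, okFemale) {
  truth <- c(rep("male", nMale), rep("female", nFemale))
  pred <- c(rep(c("male", "female"), c(okMale, nMale - okMale)),
            rep(c("female", "male"), c(okFemale, nFemale - okFemale)))
  list(truth = truth, pred = pred)
}

test_that("confusion counts follow the male-positive convention", {
  cc <- confusionCounts(c("male", "male", "female", "female"),
                        c("male", "male", "female", "female"))
  expect_equal(c(cc$TP, cc$FP, cc$FN, cc$TN), c(2, 0, 0, 2))
  cc2 <- confusionCounts(c("male", "female"), c("male", "male"))
  expect_equal(c(cc2$TP, cc2$FP), c(1, 1))
  p <- predsWith(okMale = 28, okFemale = 28)
  cc3 <- confusionCounts(p$truth, p$pred)
  expect_equal(c(cc3$TP, cc3$FN, cc3$TN, cc3$FP), c(28, 2, 28, 2))
  expect_error(confusionCounts(c("male"), c("male", "male")), "length")
})

test_that("metric formulas reproduce the worked per-sex count examples", {
  m1 <- classificationMetrics(confusionCounts(
    predsWith(okMale = 28, okFemale = 28)$truth,
    predsWith(okMale = 28, okFemale = 28)$pred))
  expect_equal(m1$accuracy, 56 / 60)
  expect_equal(round(100 * m1$accuracy, 2), 93.33)
  expect_equal(m1$recall, 28 / 30)
  expect_equal(m1$specificity, 28 / 30)

  m2 <- classificationMetrics(confusionCounts(
    predsWith(okMale = 29, okFemale = 28)$truth,
    predsWith(okMale = 29, okFemale = 28)$pred))
  expect_equal(m2$accuracy, 57 / 60)
  expect_equal(round(100 * m2$accuracy, 2), 95.00)

  perfect <- classificationMetrics(
    confusionCounts(c("male", "female"), c("male", "female")))
  for (k in c("accuracy", "recall", "specificity", "precision", "f1"))
    expect_equal(perfect[[k]], 1)

  # f1 is the harmonic mean of precision and recall
  cc <- confusionCounts(predsWith(okMale = 25, okFemale = 20)$truth,
                        predsWith(okMale = 25, okFemale = 20)$pred)
  m3 <- classificationMetrics(cc)
  expect_equal(m3$f1,
               2 * m3$precision * m3$recall / (m3$precision + m3$recall))
  # zero-denominator policy
  allNeg <- confusionCounts(c("female", "female"), c("female", "female"))
  w <- capture_warnings(mz <- classificationMetrics(allNeg))
  expect_true(all(grepl("zero denominator", w))) # recall, precision, f1
  expect_equal(mz$recall, 0)
})

test_that("identity predictions score all ones; label swap exchanges recall/specificity", {
  withr::with_seed(31, {
    for (i in 1:10) {
      y <- sample(c("male", "female"), 40, replace = TRUE)
      if (length(unique(y)) < 2) next
      m <- classificationMetrics(confusionCounts(y, y))
      expect_equal(unlist(m[c("accuracy", "recall", "specificity",
                              "precision", "f1")]),
                   c(accuracy = 1, recall = 1, specificity = 1,
                     precision = 1, f1 = 1))
      p <- sample(c("male", "female"), 40, replace = TRUE)
      a <- classificationMetrics(confusionCounts(y, p))
      b <- classificationMetrics(confusionCounts(y, p, positive = "female"))
      expect_equal(a$accuracy, b$accuracy)   # accuracy ignores polarity
      expect_equal(a$recall, b$specificity)  # roles swap with the positive class
      expect_equal(a$specificity, b$recall)
    }
  })
})

test_that("duck aggregation: vote arithmetic, tie rule, unanimity", {
  probs <- matrix(0, 3000, 2, dimnames = list(NULL, c("male", "female")))
  probs[1:2400, 1] <- 1; probs[2401:3000, 2] <- 1
  dp <- aggregateDuck(probs, "d1", "male")
  expect_equal(dp$frame_vote_fraction, 0.8)
  expect_equal(dp$predicted_sex, "male")

  tie <- matrix(rep(c(1, 0, 0, 1), each = 5), 10, 2,
                dimnames = list(NULL, c("male", "female")))
  expect_equal(aggregateDuck(tie, "d2")$predicted_sex, "male") # tie -> male

  allF <- matrix(rep(c(0.1, 0.9), each = 1), 20, 2, byrow = FALSE,
                 dimnames = list(NULL, c("male", "female")))
  allF[] <- rep(c(0.1, 0.9), each = 20)
  dpf <- aggregateDuck(allF, "d3")
  expect_equal(dpf$frame_vote_fraction, 0)
  expect_equal(dpf$predicted_sex, "female")
  expect_error(aggregateDuck(allF[0, , drop = FALSE], "d4"), "no frames")
})

test_that("duck-level split is stratified, disjoint and seeded", {
  manifest <- data.frame(
    wav_path = NA_character_, duck_id = sprintf("d%03d", 1:300),
    sex = rep(c("male", "female"), each = 150), split = "unassigned")
  sp <- splitDataset(manifest, 120, 30, seed = 4)
  expect_equal(sum(sp$split == "train"), 240)
  expect_equal(sum(sp$split == "test"), 60)
  for (sx in c("male", "female")) {
    expect_equal(sum(sp$split == "train" & sp$sex == sx), 120)
    expect_equal(sum(sp$split == "test" & sp$sex == sx), 30)
  }
  expect_length(intersect(sp$duck_id[sp$split == "train"],
                          sp$duck_id[sp$split == "test"]), 0)
  expect_identical(sp, splitDataset(manifest, 120, 30, seed = 4))
  expect_false(identical(sp, splitDataset(manifest, 120, 30, seed = 5)))
  expect_error(splitDataset(manifest[1:100, ], 120, 30, seed = 1),
               "not enough")
})

test_that("frame sampling balances ducks and guards degenerate inputs", {
  withr::with_seed(33, {
    feats <- list(
      a = matrix(stats::rnorm(5000 * 4), 5000, 4),
      b = matrix(stats::rnorm(800 * 4), 800, 4)
    )
  })
  sexes <- c(a = "male", b = "female")
  out <- sampleFrames(feats, sexes, n_per_duck = 3000, seed = 2) |>
    suppressWarnings()
  expect_equal(nrow(out$features), 6000)
  expect_equal(table(out$duck_id)[["a"]], 3000)
  expect_equal(out$labels, rep(c("male", "female"), each = 3000))
  # enough frames -> distinct row indices (check via unique row values)
  outA <- sampleFrames(feats["a"], sexes, n_per_duck = 3000, seed = 2)
  expect_equal(nrow(unique(outA$features)), 3000)
  expect_warning(sampleFrames(feats, sexes, n_per_duck = 3000, seed = 2),
                 "replacement")
  feats$c <- feats$a[0, , drop = FALSE]
  sexes <- c(sexes, c = "male")
  expect_error(suppressWarnings(
    sampleFrames(feats, sexes, n_per_duck = 10, seed = 1)), "zero voiced.*c")
})

test_that("cross-validation folds partition ducks evenly without leakage", {
  withr::with_seed(34, {
    nd <- 14
    feats <- lapply(seq_len(nd), function(i) {
      mu <- if (i <= nd / 2) 1.2 else -1.2
      matrix(stats::rnorm(60 * 36, mu, 0.4), 60, 36)
    })
    names(feats) <- sprintf("d%02d", seq_len(nd))
  })
  sexes <- stats::setNames(rep(c("male", "female"), each = 7), names(feats))
  cv <- kfoldCV(feats, sexes, k = 5, spec = modelSpec("bpnn"),
                config = trainConfig(epochs = 12, batch_size = 64, seed = 2),
                n_per_duck = 50, seed = 2)
  expect_equal(nrow(cv$folds), 5)
  expect_true(all(is.finite(cv$mean)))
  expect_gte(cv$mean[["accuracy"]], 0.9) # cleanly separable ducks
  expect_error(kfoldCV(feats, sexes, k = 1), "k must be")
  expect_error(kfoldCV(feats[1:6], sexes[1:6], k = 5), "at least k")
  # fold bookkeeping: recompute assignment as kfoldCV does
  fold <- integer(nd); names(fold) <- names(feats)
  withr::with_seed(2, {
    for (sx in c("male", "female")) {
      who <- sample(names(feats)[sexes == sx])
      fold[who] <- rep_len(seq_len(5), length(who))
    }
  })
  expect_true(all(table(fold) >= 2)) # every duck in exactly one test fold
  for (sx in c("male", "female")) {
    tab <- table(fold[sexes == sx])
    expect_lte(max(tab) - min(tab), 1) # fold sizes differ by <= 1 per sex
  }
})
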