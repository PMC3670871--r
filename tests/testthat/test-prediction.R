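test_that("sex-linked exclusion removes exactly the flagged features", {
  se <- tinySE(seed = 50L)
  expect_message(red <- excludeSexLinked(se), "20 sex-linked")
  expect_identical(nrow(red), nrow(se) - 20L)
  expect_false(any(rowData(red)$sex_linked))
  expect_identical(metadata(red)$removed_sex_linked, 20L)

  none <- nullSE(G = 30L, nA = 4L, nB = 4L, seed = 2L)
  expect_message(same <- excludeSexLinked(none), "0 sex-linked")
  expect_identical(nrow(same), nrow(none))
})

test_that("a perfectly separating feature is selected and classified perfectly", {
  se <- separableSE(nPer = 10L, G = 50L, seed = 2L)
  model <- trainClassifier(se, seed = 5L)
  expect_true("F001" %in% model@features)
  pred <- predictClasses(model, se)
  expect_identical(as.character(pred$label), as.character(se$class))
  expect_identical(crossValidatedAccuracy(se, k = 5L, seed = 6L), 1)
})

test_that("null data yield chance-level nested-CV accuracy (no leakage)", {
  se <- nullSE(G = 500L, nA = 20L, nB = 20L, seed = 31L)
  acc <- crossValidatedAccuracy(se, k = 5L, seed = 17L)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 40))
})

test_that("exclusion holds inside training and is recorded on the model", {
  se <- tinySE(seed = 60L)
  model <- trainClassifier(se, seed = 9L)
  flagged <- rownames(se)[rowData(se)$sex_linked]
  expect_length(intersect(model@features, flagged), 0L)
  expect_identical(model@excludedSexLinked, 20L)
  # without exclusion the strong sex-linked block is available again
  model2 <- trainClassifier(se, exclude = FALSE, seed = 9L)
  expect_identical(model2@excludedSexLinked, 0L)
})

test_that("training and learning curves are deterministic given seeds", {
  se <- tinySE(seed = 70L)
  m1 <- trainClassifier(se, seed = 11L)
  m2 <- trainClassifier(se, seed = 11L)
  expect_identical(m1@features, m2@features)
  expect_identical(m1@coefficients, m2@coefficients)
  expect_identical(m1@lambda, m2@lambda)

  lc1 <- learningCurve(se, sizes = c(10L, 16L), repeats = 2L, seed = 13L,
                       cvFolds = 5L)
  lc2 <- learningCurve(se, sizes = c(10L, 16L), repeats = 2L, seed = 13L,
                       cvFolds = 5L)
  expect_identical(curveTable(lc1), curveTable(lc2))
})

test_that("prediction applies the 0.5 threshold with ties to class A", {
  null_model <- new("ClassifierModel", features = character(0),
                    coefficients = numeric(0), intercept = 0,
                    lambda = 0.1, lambdaRule = "min",
                    classLevels = c("M", "F"), nTrain = 4L, seed = 1L,
                    excludedSexLinked = 0L, standardized = TRUE)
  m <- matrix(rnorm(6), 3, 2, dimnames = list(c("a", "b", "c"),
                                              c("s1", "s2")))
  pred <- predictClasses(null_model, m)
  expect_true(all(pred$probability == 0.5))
  expect_true(all(pred$label == "M"))

  miss <- new("ClassifierModel", features = "absent",
              coefficients = 1.5, intercept = 0, lambda = 0.1,
              lambdaRule = "min", classLevels = c("M", "F"), nTrain = 4L,
              seed = 1L, excludedSexLinked = 0L, standardized = TRUE)
  expect_error(predictClasses(miss, m), "absent", class = "ss_data_error")
})

test_that("external evaluation on the training set itself is perfect for separable data", {
  se <- separableSE(nPer = 10L, G = 40L, seed = 3L)
  lc <- learningCurve(se, sizes = 20L, repeats = 2L, mode = "external",
                      external = se, seed = 21L)
  expect_true(all(curveTable(lc)$accuracy == 1))

  other <- matrix(rnorm(20), 10, 2,
                  dimnames = list(sprintf("zz%d", 1:10), c("x1", "x2")))
  otherPh <- stats::setNames(factor(c("M", "F"), c("M", "F")),
                             colnames(other))
  expect_error(
    learningCurve(se, sizes = 20L, repeats = 1L, mode = "external",
                  external = other, externalPheno = otherPh, seed = 1L),
    "no shared feature", class = "ss_data_error")
})

test_that("accuracy grows with training size on planted data", {
  se <- generateDataset(syntheticConfig(nFeatures = 400L, nClassA = 30L,
                                        nClassB = 30L, nSexLinked = 0L,
                                        nDEAutosomal = 100L, seed = 81L))
  lc <- learningCurve(se, sizes = c(10L, 50L), repeats = 4L, seed = 23L,
                      cvFolds = 5L)
  s <- summary(lc)
  expect_gte(s$mean[s$n == 50] + 0.03, s$mean[s$n == 10])
  expect_gt(s$mean[s$n == 50], 0.7)
})

test_that("an external cohort from the same generative process matches internal accuracy", {
  cfg <- syntheticConfig(nFeatures = 400L, nClassA = 30L, nClassB = 30L,
                         nSexLinked = 10L, nDEAutosomal = 100L, seed = 91L)
  se1 <- generateDataset(cfg)
  se2 <- generateDataset(cfg, cohort = 2L)
  expect_identical(rowData(se1)$delta, rowData(se2)$delta)
  expect_false(identical(assay(se1)[1, 1], assay(se2)[1, 1]))
  internal <- crossValidatedAccuracy(se1, k = 10L, seed = 7L)
  model <- trainClassifier(se1, seed = 7L)
  pred <- predictClasses(model, se2)
  external <- mean(as.character(pred$label) == as.character(se2$class))
  # both estimate the same generalization accuracy; 3 SDs at n = 60
  expect_lt(abs(internal - external), 3 * sqrt(0.25 / 60) * 2)
})

test_that("model serialization carries the fitted parameters", {
  se <- separableSE(nPer = 8L, G = 30L, seed = 4L)
  model <- trainClassifier(se, seed = 3L)
  path <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(model, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(parsed$features, model@features)
  expect_equal(parsed$intercept, model@intercept)
  expect_identical(parsed$class_levels, c("M", "F"))
})
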