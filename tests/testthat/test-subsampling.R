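test_that("balanced draws contain n/2 of each class, without replacement", {
  ph <- makePheno(69, 65)
  ids <- drawBalancedSubsample(ph, 10, seed = 3)
  expect_length(ids, 10L)
  expect_identical(anyDuplicated(ids), 0L)
  expect_identical(as.integer(table(ph[ids])), c(5L, 5L))

  # degenerate population: the draw is the whole set
  ph2 <- makePheno(1, 1)
  expect_setequal(drawBalancedSubsample(ph2, 2, seed = 1), names(ph2))
})

test_that("invalid subsample requests are rejected naming the problem", {
  ph <- makePheno(5, 100)
  expect_error(drawBalancedSubsample(ph, 11, seed = 1), "even",
               class = "ss_config_error")
  expect_error(drawBalancedSubsample(ph, 12, seed = 1), "'M' has 5",
               class = "ss_config_error")
})

test_that("designs are reproducible and cells match direct draws", {
  ph <- makePheno(69, 65)
  d1 <- buildDesign(ph, sizes = c(10L, 20L), repeats = 4L, seed = 99L)
  d2 <- buildDesign(ph, sizes = c(10L, 20L), repeats = 4L, seed = 99L)
  expect_identical(d1@cells, d2@cells)
  expect_identical(dim(d1@cellSeeds), c(2L, 4L))

  # a single cell equals a direct draw with its derived seed
  direct <- drawBalancedSubsample(ph, 20, seed = d1@cellSeeds[2, 3])
  expect_identical(designSubjects(d1, 20L, 3L), direct)

  d3 <- buildDesign(ph, sizes = 10L, repeats = 1L, seed = 7L)
  expect_length(d3@cells[[1L]], 1L)
})

test_that("jaccard obeys its defining identities", {
  expect_identical(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_identical(jaccard(1:3, 4:6), 0)
  expect_identical(jaccard(1:3, 2:4), 0.5)
  expect_identical(jaccard(1:3, 2:4), jaccard(2:4, 1:3))
  expect_error(jaccard(integer(0), character(0)), "undefined",
               class = "ss_config_error")
  # one empty set is legal
  expect_identical(jaccard(integer(0), 1:3), 0)
})

test_that("overlap study matches the hypergeometric intersection mean", {
  nPairs <- 500L
  ph <- makePheno(69, 65)
  interM <- interF <- numeric(nPairs)
  for (k in seq_len(nPairs)) {
    a <- drawBalancedSubsample(ph, 30, seed = 2 * k)
    b <- drawBalancedSubsample(ph, 30, seed = 2 * k + 1)
    common <- intersect(a, b)
    interM[k] <- sum(ph[common] == "M")
    interF[k] <- sum(ph[common] == "F")
  }
  # X ~ Hypergeometric(N, 15, 15): mean 15^2/N, known variance
  hypVar <- function(N) 15 * (15 / N) * ((N - 15) / N) * ((N - 15) / (N - 1))
  expect_lt(abs(mean(interM) - 225 / 69), 3 * sqrt(hypVar(69) / nPairs))
  expect_lt(abs(mean(interF) - 225 / 65), 3 * sqrt(hypVar(65) / nPairs))
})

test_that("median Jaccard is nondecreasing in n and reaches 1 at the full population", {
  meds <- vapply(c(10L, 30L, 60L, 90L, 120L), function(n)
    summary(subsampleOverlapStudy(c(69, 65), n, nPairs = 400L,
                                  seed = n))$median, numeric(1))
  expect_true(all(diff(meds) > -0.011))
  full <- subsampleOverlapStudy(c(65, 65), 130, nPairs = 50L, seed = 1)
  expect_true(all(jaccardValues(full) == 1))
})

test_that("relabeling subjects within classes leaves Jaccard values unchanged", {
  ph <- makePheno(20, 18)
  set.seed(5)
  relabeled <- ph
  names(relabeled)[ph == "M"] <- sample(paste0("mm", 1:20))
  names(relabeled)[ph == "F"] <- sample(paste0("ff", 1:18))
  jOrig <- jRel <- numeric(100)
  for (k in 1:100) {
    jOrig[k] <- jaccard(drawBalancedSubsample(ph, 10, seed = 2 * k),
                        drawBalancedSubsample(ph, 10, seed = 2 * k + 1))
    jRel[k] <- jaccard(drawBalancedSubsample(relabeled, 10, seed = 2 * k),
                       drawBalancedSubsample(relabeled, 10, seed = 2 * k + 1))
  }
  expect_identical(jOrig, jRel)
})

test_that("overlap studies are seeded and serializable", {
  a <- subsampleOverlapStudy(c(69, 65), 30, nPairs = 100L, seed = 4)
  b <- subsampleOverlapStudy(c(69, 65), 30, nPairs = 100L, seed = 4)
  expect_identical(jaccardValues(a), jaccardValues(b))
  path <- withr::local_tempfile(fileext = ".json")
  writeJaccardJSON(a, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$median, summary(a)$median)
  expect_identical(parsed$n, 30L)
})
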