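test_that("pooled t-test reproduces the hand-computed example", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
              dimnames = list("f1", sprintf("s%d", 1:6)))
  ph <- stats::setNames(factor(c("M", "M", "M", "F", "F", "F"),
                               c("M", "F")), colnames(m))
  de <- tTestPerFeature(m, ph, variant = "pooled")
  # t = (2 - 5) / (s_p * sqrt(2/3)) with s_p = 1
  expect_equal(de$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(de$df, 4)
  expect_equal(de$p, 0.02131164, tolerance = 1e-6)
  ref <- stats::t.test(m[1, 1:3], m[1, 4:6], var.equal = TRUE)
  expect_equal(de$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(de$p, ref$p.value, tolerance = 1e-12)
})

test_that("both variants agree with the reference implementation on random instances", {
  set.seed(404)
  for (k in 1:200) {
    na <- sample(3:9, 1); nb <- sample(3:9, 1)
    xa <- rnorm(na, sd = runif(1, 0.2, 3))
    xb <- rnorm(nb, mean = runif(1, -2, 2), sd = runif(1, 0.2, 3))
    m <- matrix(c(xa, xb), nrow = 1,
                dimnames = list("f", sprintf("s%d", seq_len(na + nb))))
    ph <- stats::setNames(factor(rep(c("A", "B"), c(na, nb)), c("A", "B")),
                          colnames(m))
    w <- tTestPerFeature(m, ph, variant = "welch")
    refW <- stats::t.test(xa, xb)
    expect_equal(w$t, unname(refW$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(refW$parameter), tolerance = 1e-10)
    expect_equal(w$p, refW$p.value, tolerance = 1e-10)
    p <- tTestPerFeature(m, ph, variant = "pooled")
    refP <- stats::t.test(xa, xb, var.equal = TRUE)
    expect_equal(p$t, unname(refP$statistic), tolerance = 1e-10)
    expect_equal(p$p, refP$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate features and tiny classes are handled as specified", {
  m <- rbind(flat = rep(2, 6), ok = c(1, 2, 3, 7, 8, 9))
  colnames(m) <- sprintf("s%d", 1:6)
  ph <- stats::setNames(factor(rep(c("A", "B"), each = 3), c("A", "B")),
                        colnames(m))
  de <- tTestPerFeature(m, ph)
  expect_identical(de$t[de$feature_id == "flat"], 0)
  expect_identical(de$p[de$feature_id == "flat"], 1)
  expect_true(all(de$p > 0 & de$p <= 1))

  expect_error(tTestPerFeature(m[, 1:4], ph[1:4]), ">= 2 samples",
               class = "ss_data_error")
})

test_that("t statistics are invariant to location/scale and antisymmetric under label swap", {
  se <- tinySE(seed = 21L)
  de <- tTestPerFeature(se)
  m <- assay(se)
  m2 <- (m + 5) * 3   # shift every feature, rescale all values
  de2 <- tTestPerFeature(m2, stats::setNames(se$class, colnames(se)))
  expect_equal(de2$t, de$t, tolerance = 1e-10)
  expect_equal(de2$p, de$p, tolerance = 1e-10)

  swapped <- stats::setNames(factor(as.character(se$class),
                                    levels = c("F", "M")), colnames(se))
  de3 <- tTestPerFeature(m, swapped)
  expect_equal(de3$t, -de$t, tolerance = 1e-12)
  expect_equal(de3$p, de$p, tolerance = 1e-12)
})

test_that("summary-statistics t-test reproduces the muscularity contrast", {
  res <- summaryStatsTTest(52.9, 7.8, 69, 41.9, 8.3, 65)
  expect_identical(round(res$percentDifference), 26)
  expect_equal(res$t, 7.894315, tolerance = 1e-6)
  expect_lt(res$p, 1e-4)

  eq <- summaryStatsTTest(5, 1, 10, 5, 1, 10)
  expect_identical(eq$t, 0)
  expect_identical(eq$percentDifference, 0)

  expect_error(summaryStatsTTest(1, 0, 10, 2, 1, 10), "positive",
               class = "ss_config_error")
  expect_error(summaryStatsTTest(1, 1, 1, 2, 1, 10), ">= 2",
               class = "ss_config_error")
})

test_that("aggregation averages p-values and ranks with deterministic tie-breaks", {
  mk <- function(p, t) data.frame(feature_id = c("a", "b", "c"), t = t,
                                  df = 4, p = p, p_bh = p)
  # tie on p between a and b: larger |t| wins
  r1 <- mk(c(0.5, 0.5, 0.01), c(1, -2, 5))
  prof1 <- aggregateOverRepeats(list(r1), n = 6L)
  tab1 <- rankTable(prof1)
  expect_identical(tab1$mean_rank, c(3, 2, 1))
  expect_identical(tab1$rank_lo, tab1$mean_rank)  # R = 1: degenerate CI
  expect_identical(tab1$rank_hi, tab1$mean_rank)

  # full tie (same p, same |t|): stable order by feature index
  r2 <- mk(c(0.5, 0.5, 0.01), c(2, -2, 5))
  tab2 <- rankTable(aggregateOverRepeats(list(r2)))
  expect_identical(tab2$mean_rank, c(2, 3, 1))

  prof <- aggregateOverRepeats(list(mk(c(0.2, 0.6, 0.9), c(3, 2, 1)),
                                    mk(c(0.4, 0.6, 0.9), c(3, 2, 1))))
  expect_equal(rankTable(prof)$mean_p, c(0.3, 0.6, 0.9))
  expect_identical(topFeatures(prof), c("a", "b", "c"))

  bad <- mk(c(0.1, 0.2, 0.3), c(1, 2, 3))
  bad$feature_id <- c("a", "b", "ZZZ")
  expect_error(aggregateOverRepeats(list(r1, bad)), "different feature set",
               class = "ss_data_error")
})

test_that("per-repeat ranks form a permutation of 1..G", {
  se <- tinySE(seed = 33L)
  de <- tTestPerFeature(se)
  prof <- aggregateOverRepeats(list(de), n = ncol(se))
  expect_identical(sort(rankTable(prof)$mean_rank),
                   as.numeric(seq_len(nrow(se))))
})

test_that("countSignificant uses a strict threshold and is binomially calibrated under the null", {
  df <- data.frame(feature_id = letters[1:5], t = 0, df = 4,
                   p = c(1, 1, 0.05, 0.049, 0.2), p_bh = 1)
  expect_identical(countSignificant(df, 0.05), 1L)
  expect_identical(countSignificant(data.frame(p = rep(1, 4)), 0.5), 0L)
  expect_error(countSignificant(df, 1.5), class = "ss_config_error")

  de <- tTestPerFeature(nullSE(G = 10000L, nA = 20L, nB = 20L, seed = 15L))
  cnt <- countSignificant(de, 0.05)
  expect_lt(abs(cnt - 500), 3 * sqrt(10000 * 0.05 * 0.95))
})

test_that("mean-p ranking recovers the planted ordering at large n", {
  se <- generateDataset(syntheticConfig(nFeatures = 2000L, nClassA = 55L,
                                        nClassB = 55L, nSexLinked = 50L,
                                        nDEAutosomal = 200L, seed = 13L))
  st <- rankStabilityStudy(se, sizes = 100L, repeats = 10L, seed = 29L)
  tab <- rankTable(st$profiles[["100"]])
  tr <- trueRanking(se)
  meanP <- tab$mean_p[match(tr, tab$feature_id)]
  rho <- stats::cor(seq_along(tr), rank(meanP), method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("rank-profile TSVs carry the documented columns", {
  se <- tinySE(seed = 44L)
  st <- rankStabilityStudy(se, sizes = c(10L, 14L), repeats = 3L, seed = 3L,
                           alphas = c(1e-4, 0.05))
  expect_named(st$profiles, c("10", "14"))
  expect_identical(nrow(st$counts), 2L * 3L * 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRankProfileTSV(st$profiles[["10"]], path, top = 20)
  tsv <- data.table::fread(path)
  expect_identical(colnames(tsv),
                   c("feature_id", "mean_p", "mean_rank", "rank_lo",
                     "rank_hi", "n", "R"))
  expect_identical(nrow(tsv), 20L)
  expect_true(all(tsv$n == 10L & tsv$R == 3L))
})
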