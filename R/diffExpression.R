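# Per-feature two-sample t-tests on log intensities and their aggregation
# across subsample repeats. Raw p-values throughout: ranking is the object of
# interest, so no multiplicity correction is applied (a BH column is provided
# for convenience but never used for ranking).

#' Per-feature two-sample t-tests
#'
#' Computes, for every feature (row), the signed two-sample t statistic
#' (class A minus class B) and the two-sided p-value on the log-scale
#' intensities. The Welch (unequal-variance) variant is the default; the
#' pooled-variance variant is available. A feature with zero variance in
#' both groups and equal means yields t = 0, p = 1; p-values are clamped
#' into (0, 1].
#'
#' @param x `SummarizedExperiment` (first assay used) or numeric matrix,
#'   features x samples.
#' @param pheno named two-level factor; taken from `colData(x)$class` when
#'   `x` is a `SummarizedExperiment`.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return data.frame with columns feature_id, t, df, p, p_bh.
#' @examples
#' m <- rbind(A = c(1, 2, 3, 4, 5, 6))
#' colnames(m) <- paste0("S", 1:6)
#' ph <- setNames(factor(c("M","M","M","F","F","F"), c("M","F")),
#'                colnames(m))
#' tTestPerFeature(m, ph, variant = "pooled")
#' @export
tTestPerFeature <- function(x, pheno = NULL,
                            variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  inp <- resolveInput(x, pheno)
  mat <- inp$exprs; pheno <- inp$pheno
  lv <- levels(pheno)
  ia <- which(pheno == lv[1]); ib <- which(pheno == lv[2])
  na <- length(ia); nb <- length(ib)
  if (na < 2L || nb < 2L)
    dataError("each class needs >= 2 samples (got %d '%s', %d '%s')",
              na, lv[1], nb, lv[2])
  xa <- mat[, ia, drop = FALSE]; xb <- mat[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  dm <- ma - mb
  if (variant == "welch") {
    seTerm <- va / na + vb / nb
    se <- sqrt(seTerm)
    df <- seTerm^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep.int(na + nb - 2, nrow(mat))
  }
  t <- dm / se
  degenerate <- se == 0
  t[degenerate & dm == 0] <- 0
  df[degenerate] <- na + nb - 2
  p <- 2 * stats::pt(-abs(t), df)
  p[degenerate & dm == 0] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- sprintf("feature_%d", seq_len(nrow(mat)))
  data.frame(feature_id = ids, t = unname(t), df = unname(df),
             p = unname(p), p_bh = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Two-sample t-test from summary statistics
#'
#' For worked examples from published group-summary tables (mean +/- SD per
#' group), computes the t statistic, degrees of freedom, two-sided p-value
#' and the percent difference `100 * (meanA - meanB) / meanB`.
#'
#' @param meanA,sdA,nA summary statistics of group A.
#' @param meanB,sdB,nB summary statistics of group B.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return List with elements `t`, `df`, `p`, `percentDifference`.
#' @examples
#' # skeletal muscle index, men (69) vs women (65)
#' summaryStatsTTest(52.9, 7.8, 69, 41.9, 8.3, 65)
#' @export
summaryStatsTTest <- function(meanA, sdA, nA, meanB, sdB, nB,
                              variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (sdA <= 0 || sdB <= 0) configError("group SDs must be positive")
  if (nA < 2L || nB < 2L) configError("group sizes must be >= 2")
  dm <- meanA - meanB
  if (variant == "welch") {
    va <- sdA^2 / nA; vb <- sdB^2 / nB
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (nA - 1) + vb^2 / (nB - 1))
  } else {
    sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- nA + nB - 2
  }
  t <- dm / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       percentDifference = 100 * dm / meanB)
}

#' Aggregate per-feature t-test results over subsample repeats
#'
#' Given one t-test result per repeat (identical feature sets in identical
#' order), computes per feature the arithmetic mean of the raw p-values, the
#' per-repeat rank (ascending p over all features; ties broken by larger
#' absolute t, then by feature index), the mean rank, and the empirical 95%
#' rank interval (2.5th/97.5th percentiles across repeats). The top-`topK`
#' features by mean p-value (ties by mean rank, then index) are recorded.
#'
#' @param results list of data.frames from [tTestPerFeature()], one per
#'   repeat.
#' @param n subsample size the repeats refer to (metadata only).
#' @param topK how many top features to record (default 100).
#' @return A [RankProfile-class].
#' @export
aggregateOverRepeats <- function(results, n = NA_integer_, topK = 100L) {
  if (!length(results)) configError("no repeats to aggregate")
  ids <- results[[1L]]$feature_id
  G <- length(ids)
  R <- length(results)
  P <- matrix(NA_real_, G, R)
  ranks <- matrix(NA_real_, G, R)
  for (j in seq_len(R)) {
    rj <- results[[j]]
    if (!identical(rj$feature_id, ids))
      dataError("repeat %d covers a different feature set", j)
    P[, j] <- rj$p
    ord <- order(rj$p, -abs(rj$t))   # stable: residual ties by index
    ranks[ord, j] <- seq_len(G)
  }
  meanP <- rowMeans(P)
  meanRank <- rowMeans(ranks)
  ci <- rowQuantiles(ranks, c(0.025, 0.975))
  topOrd <- order(meanP, meanRank, seq_len(G))
  top <- ids[topOrd[seq_len(min(topK, G))]]
  new("RankProfile",
      stats = data.frame(feature_id = ids, mean_p = meanP,
                         mean_rank = meanRank, rank_lo = ci[, 1L],
                         rank_hi = ci[, 2L], stringsAsFactors = FALSE),
      n = as.integer(n), repeats = as.integer(R), topFeatures = top)
}

# Row-wise empirical quantiles (type 7) via one global sort; avoids an
# apply() over 41k rows.
rowQuantiles <- function(m, probs) {
  G <- nrow(m); R <- ncol(m)
  if (R == 1L) return(matrix(m[, 1L], G, length(probs)))
  sorted <- matrix(m[order(row(m), m)], nrow = G, byrow = TRUE)
  out <- matrix(NA_real_, G, length(probs))
  for (k in seq_along(probs)) {
    h <- (R - 1) * probs[k] + 1
    lo <- floor(h); hi <- ceiling(h)
    out[, k] <- sorted[, lo] + (h - lo) * (sorted[, hi] - sorted[, lo])
  }
  out
}

#' Count features significant at a raw-p threshold
#'
#' Strict inequality `p < alpha`, matching threshold statements like
#' "p < 0.0001" in published counts.
#'
#' @param result data.frame from [tTestPerFeature()].
#' @param alpha threshold in (0, 1).
#' @return Integer count.
#' @export
countSignificant <- function(result, alpha) {
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    configError("alpha must lie in (0, 1)")
  sum(result$p < alpha)
}

#' Rank-stability study over a sample-size grid
#'
#' The differential-expression arm of the pipeline: for every size in the
#' grid, draws `repeats` balanced subsamples, runs per-feature t-tests on
#' each, aggregates them into a [RankProfile-class], and tallies significant
#' features per repeat at each `alpha`.
#'
#' @param x `SummarizedExperiment` or matrix; see [tTestPerFeature()].
#' @param pheno phenotype factor if `x` is a matrix.
#' @param sizes even subsample sizes (default `seq(10, 120, by = 10)`).
#' @param repeats subsamples per size (default 50).
#' @param seed master seed.
#' @param variant t-test variant.
#' @param alphas significance thresholds to tally (default `1e-4`).
#' @param topK top-feature list length per profile.
#' @return List with elements `profiles` (named list of
#'   [RankProfile-class], one per size), `counts` (data.frame n, rep, alpha,
#'   count) and `design` (the [SubsampleDesign-class] used).
#' @export
rankStabilityStudy <- function(x, pheno = NULL,
                               sizes = seq(10L, 120L, by = 10L),
                               repeats = 50L, seed = 1L,
                               variant = c("welch", "pooled"),
                               alphas = 1e-4, topK = 100L) {
  variant <- match.arg(variant)
  inp <- resolveInput(x, pheno)
  design <- buildDesign(inp$pheno, sizes, repeats, seed)
  profiles <- list()
  counts <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    n <- sizes[i]
    de <- lapply(seq_len(repeats), function(j) {
      ids <- design@cells[[i]][[j]]
      tTestPerFeature(inp$exprs[, ids, drop = FALSE], inp$pheno[ids],
                      variant = variant)
    })
    profiles[[as.character(n)]] <- aggregateOverRepeats(de, n = n,
                                                        topK = topK)
    counts[[i]] <- do.call(rbind, lapply(seq_len(repeats), function(j)
      data.frame(n = n, rep = j, alpha = alphas,
                 count = vapply(alphas, function(a)
                   countSignificant(de[[j]], a), numeric(1)))))
  }
  list(profiles = profiles, counts = do.call(rbind, counts),
       design = design)
}

#' @describeIn RankProfile-class the per-feature summary table.
#' @param x a `RankProfile`.
#' @export
setMethod("rankTable", "RankProfile", function(x) x@stats)

#' @describeIn RankProfile-class IDs of the top features by mean p-value.
#' @export
setMethod("topFeatures", "RankProfile", function(x) x@topFeatures)

setMethod("show", "RankProfile", function(object) {
  cat(sprintf(
    "RankProfile: %d features, n = %s, %d repeats; top feature: %s\n",
    nrow(object@stats),
    ifelse(is.na(object@n), "?", object@n), object@repeats,
    object@topFeatures[1L]))
})

#' Write a rank profile to TSV
#'
#' Columns: feature_id, mean_p, mean_rank, rank_lo, rank_hi, n, R.
#' @param profile a [RankProfile-class].
#' @param path output path.
#' @param top write only the top `top` features by mean p (default all).
#' @return Invisibly, `path`.
#' @export
writeRankProfileTSV <- function(profile, path, top = Inf) {
  st <- profile@stats
  st <- st[order(st$mean_p, st$mean_rank), , drop = FALSE]
  if (is.finite(top)) st <- utils::head(st, top)
  st$n <- profile@n
  st$R <- profile@repeats
  data.table::fwrite(st, path, sep = "\t")
  invisible(path)
}
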