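#' Create a synthetic-dataset configuration
#'
#' Defaults emulate the structure of a 41,000-transcript two-sex human muscle
#' microarray study with 69 + 65 subjects: 1,548 sex-linked transcripts with a
#' large common class shift, 600 autosomal transcripts with graded moderate
#' shifts, the remainder null. Baselines and noise SDs are on the log2 scale;
#' noise is additive Gaussian (log-normal intensities).
#'
#' @param nFeatures,nClassA,nClassB,nSexLinked,nDEAutosomal counts; see
#'   [SyntheticConfig-class].
#' @param sexLinkedEffect absolute log2 shift shared by sex-linked features.
#' @param deEffectRange absolute log2 shift range of the autosomal block,
#'   assigned strictly decreasing over the block.
#' @param baselineMeanSD mean and SD of per-feature baselines.
#' @param featureSDRange bounds of the uniform per-feature noise-SD draw.
#' @param classLevels two class labels; the first is class A.
#' @param seed integer seed (bit-identical regeneration).
#' @return A validated [SyntheticConfig-class] object.
#' @examples
#' cfg <- syntheticConfig(nFeatures = 200, nClassA = 6, nClassB = 6,
#'                        nSexLinked = 10, nDEAutosomal = 20, seed = 1)
#' @export
syntheticConfig <- function(nFeatures = 41000L, nClassA = 69L, nClassB = 65L,
                            nSexLinked = 1548L, sexLinkedEffect = 2.0,
                            nDEAutosomal = 600L, deEffectRange = c(0.2, 1.5),
                            baselineMeanSD = c(7, 2),
                            featureSDRange = c(1.0, 2.5),
                            classLevels = c("M", "F"), seed = 1L) {
  asCount <- function(x, field) {
    if (length(x) != 1L || is.na(x) || !is.finite(as.numeric(x)) ||
        as.numeric(x) < 0 || as.numeric(x) != round(as.numeric(x)))
      configError("field '%s': must be a single non-negative count", field)
    as.integer(x)
  }
  obj <- tryCatch(
    new("SyntheticConfig",
        nFeatures = asCount(nFeatures, "nFeatures"),
        nClassA = asCount(nClassA, "nClassA"),
        nClassB = asCount(nClassB, "nClassB"),
        nSexLinked = asCount(nSexLinked, "nSexLinked"),
        sexLinkedEffect = as.numeric(sexLinkedEffect),
        nDEAutosomal = asCount(nDEAutosomal, "nDEAutosomal"),
        deEffectRange = as.numeric(deEffectRange),
        baselineMeanSD = as.numeric(baselineMeanSD),
        featureSDRange = as.numeric(featureSDRange),
        classLevels = as.character(classLevels),
        seed = asCount(seed, "seed")),
    error = function(e) configError("%s", conditionMessage(e)))
  obj
}

#' Generate a planted two-class expression dataset
#'
#' Draws per-feature baselines mu_g ~ N(baseline mean, baseline SD) and noise
#' SDs sigma_g ~ U(featureSDRange), plants the configured shifts delta_g
#' (sex-linked block first, then the decreasing autosomal grid, each with a
#' random sign so both class directions occur), and emits
#' `value[g, s] = mu_g + delta_g * 1[s in class A] + N(0, sigma_g)`.
#'
#' The result is a [SummarizedExperiment::SummarizedExperiment] with assay
#' `"exprs"` (log2 scale), `colData$class` (two-level factor, class A first),
#' and ground truth in `rowData`: `gene_symbol`, `chromosome` (X/Y for
#' sex-linked, 1–22 otherwise), `sex_linked`, `delta`, `sigma`, and the
#' standardized effect `abs(delta)/sigma`. Identical configurations produce
#' bit-identical output.
#'
#' Cohorts: the per-feature parameters (baselines, SDs, shifts, chromosome
#' assignments) are drawn from the configuration seed alone, while subjects
#' are drawn from a seed derived from `(seed, cohort)`. Datasets generated
#' with different `cohort` values therefore share the planted ground truth
#' but contain independent subjects — an external validation cohort from the
#' same population.
#'
#' @param config a [SyntheticConfig-class], e.g. from [syntheticConfig()].
#' @param cohort cohort index (default 1); change it to draw a new cohort
#'   with identical feature-level truth.
#' @return A `SummarizedExperiment`; the configuration is kept in
#'   `metadata(se)$config`.
#' @examples
#' se <- generateDataset(syntheticConfig(nFeatures = 100, nClassA = 5,
#'                                       nClassB = 5, nSexLinked = 4,
#'                                       nDEAutosomal = 10, seed = 7))
#' dim(se)
#' @export
generateDataset <- function(config = syntheticConfig(), cohort = 1L) {
  if (!is(config, "SyntheticConfig"))
    configError("'config' must be a SyntheticConfig")
  validObject(config)
  G <- config@nFeatures
  nA <- config@nClassA; nB <- config@nClassB; n <- nA + nB
  cohort <- as.integer(cohort)
  feature_ids <- sprintf("F%05d", seq_len(G))
  sample_ids <- if (cohort == 1L) sprintf("S%03d", seq_len(n))
                else sprintf("C%dS%03d", cohort, seq_len(n))
  pheno <- factor(rep(config@classLevels, c(nA, nB)),
                  levels = config@classLevels)

  nSex <- config@nSexLinked; nDE <- config@nDEAutosomal
  withSeed(config@seed, {
    mu <- stats::rnorm(G, config@baselineMeanSD[1], config@baselineMeanSD[2])
    sigma <- stats::runif(G, config@featureSDRange[1], config@featureSDRange[2])
    sgn <- ifelse(stats::runif(G) < 0.5, -1, 1)
    delta <- numeric(G)
    if (nSex > 0L) delta[seq_len(nSex)] <- config@sexLinkedEffect
    if (nDE > 0L)
      delta[nSex + seq_len(nDE)] <-
        seq(max(config@deEffectRange), min(config@deEffectRange),
            length.out = nDE)
    delta <- delta * sgn
    chrom <- character(G)
    if (nSex > 0L)
      chrom[seq_len(nSex)] <- sample(c("X", "Y"), nSex, replace = TRUE)
    if (G > nSex)
      chrom[(nSex + 1L):G] <- sample(as.character(1:22), G - nSex,
                                     replace = TRUE)
  })
  withSeed(deriveSeed(config@seed, 1000003L, cohort), {
    vals <- mu + matrix(stats::rnorm(G * n), G, n) * sigma
    vals[, seq_len(nA)] <- vals[, seq_len(nA)] + delta
  })
  dimnames(vals) <- list(feature_ids, sample_ids)

  rd <- S4Vectors::DataFrame(
    gene_symbol = sprintf("GENE%d", seq_len(G)),
    chromosome = chrom,
    sex_linked = seq_len(G) <= nSex,
    delta = delta,
    sigma = sigma,
    effect = abs(delta) / sigma,
    row.names = feature_ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = vals),
    rowData = rd,
    colData = S4Vectors::DataFrame(class = pheno, row.names = sample_ids))
  S4Vectors::metadata(se)$config <- config
  S4Vectors::metadata(se)$cohort <- cohort
  S4Vectors::metadata(se)$scale <- "log2"
  se
}

#' True ordering of planted features
#'
#' Planted (nonzero-shift) features ordered by decreasing standardized effect
#' `abs(delta)/sigma`, ties broken by feature index. Null features never
#' appear; under a global-null configuration the ranking is empty.
#'
#' @param x a `SummarizedExperiment` from [generateDataset()], or a
#'   data.frame with columns `delta` and `sigma` and feature IDs as row names.
#' @return Character vector of feature IDs.
#' @rdname trueRanking
#' @export
setMethod("trueRanking", "SummarizedExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!all(c("delta", "sigma") %in% colnames(rd)))
    dataError("rowData must carry 'delta' and 'sigma' ground truth")
  .trueRanking(rownames(x), rd$delta, rd$sigma)
})

#' @rdname trueRanking
#' @export
setMethod("trueRanking", "data.frame", function(x) {
  .trueRanking(rownames(x), x$delta, x$sigma)
})

.trueRanking <- function(ids, delta, sigma) {
  planted <- which(delta != 0)
  if (!length(planted)) return(character(0))
  es <- abs(delta[planted]) / sigma[planted]
  ids[planted[order(-es, planted)]]
}

#' Write a synthetic dataset to disk as plain TSV files
#'
#' Emits `expression.tsv` (features x samples), `phenotype.tsv`
#' (sample_id, class), `annotation.tsv` (feature_id, gene_symbol, chromosome,
#' sex_linked) and, when ground truth is present in `rowData`,
#' `ground_truth.tsv` (feature_id, delta, sigma, sex_linked).
#'
#' @param se a `SummarizedExperiment` as produced by [generateDataset()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
writeDataset <- function(se, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rd <- SummarizedExperiment::rowData(se)
  paths <- file.path(dir, c("expression.tsv", "phenotype.tsv",
                            "annotation.tsv"))
  writeExpressionTSV(SummarizedExperiment::assay(se, 1L), paths[1])
  data.table::fwrite(
    data.table::data.table(sample_id = colnames(se),
                           class = as.character(se$class)),
    paths[2], sep = "\t")
  data.table::fwrite(
    data.table::data.table(feature_id = rownames(se),
                           gene_symbol = rd$gene_symbol,
                           chromosome = rd$chromosome,
                           sex_linked = rd$sex_linked),
    paths[3], sep = "\t")
  if (all(c("delta", "sigma") %in% colnames(rd))) {
    gt <- file.path(dir, "ground_truth.tsv")
    data.table::fwrite(
      data.table::data.table(feature_id = rownames(se), delta = rd$delta,
                             sigma = rd$sigma, sex_linked = rd$sex_linked),
      gt, sep = "\t")
    paths <- c(paths, gt)
  }
  invisible(paths)
}
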