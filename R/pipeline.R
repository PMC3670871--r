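# Orchestration: each run*() command validates its configuration, executes
# one pipeline stage, and writes plain-text outputs plus a manifest
# (configuration + seeds + package version) sufficient to reproduce the
# outputs bit-identically.

configAsList <- function(config) {
  list(n_features = config@nFeatures, n_class_a = config@nClassA,
       n_class_b = config@nClassB, n_sex_linked = config@nSexLinked,
       sex_linked_effect = config@sexLinkedEffect,
       n_de_autosomal = config@nDEAutosomal,
       de_effect_range = config@deEffectRange,
       baseline_mean_sd = config@baselineMeanSD,
       feature_sd_range = config@featureSDRange,
       class_levels = config@classLevels, seed = config@seed)
}

writeManifest <- function(outDir, command, params) {
  manifest <- list(command = command,
                   package = "sizeStability",
                   version = as.character(utils::packageVersion("sizeStability")),
                   params = params)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

resolveDataset <- function(input) {
  if (is(input, "SummarizedExperiment")) return(input)
  if (is.character(input) && length(input) == 1L && dir.exists(input))
    return(readDataset(input))
  dataError("input must be a SummarizedExperiment or a dataset directory")
}

#' Simulate a dataset and write it to disk
#'
#' Wraps [generateDataset()] + [writeDataset()]: emits expression.tsv,
#' phenotype.tsv, annotation.tsv, ground_truth.tsv and manifest.json. The
#' output directory is valid input for every other `run*()` command.
#'
#' @param config a [SyntheticConfig-class].
#' @param outDir output directory (created if missing).
#' @return Invisibly, the generated `SummarizedExperiment`.
#' @export
runSimulate <- function(config = syntheticConfig(), outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  se <- generateDataset(config)
  writeDataset(se, outDir)
  writeManifest(outDir, "simulate", configAsList(config))
  invisible(se)
}

#' Run the rank-stability study and write its outputs
#'
#' Per grid size: a rank-profile TSV (feature_id, mean_p, mean_rank,
#' rank_lo, rank_hi, n, R); plus significance_counts.tsv over all sizes,
#' repeats and thresholds, and manifest.json. With `plots = TRUE` (requires
#' ggplot2) a rank_profiles.pdf of the top-100 rank intervals per size.
#'
#' @param input `SummarizedExperiment` or a dataset directory.
#' @param sizes,repeats,seed,variant,alphas,topK see [rankStabilityStudy()].
#' @param outDir output directory.
#' @param plots also write figures (default FALSE).
#' @param top number of top features written per profile TSV (default 100;
#'   `Inf` writes all).
#' @return Invisibly, the [rankStabilityStudy()] result.
#' @export
runDEStability <- function(input, outDir, sizes = seq(10L, 120L, by = 10L),
                           repeats = 50L, seed = 1L, variant = "welch",
                           alphas = 1e-4, topK = 100L, top = 100,
                           plots = FALSE) {
  se <- resolveDataset(input)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  study <- rankStabilityStudy(se, sizes = sizes, repeats = repeats,
                              seed = seed, variant = variant,
                              alphas = alphas, topK = topK)
  for (nm in names(study$profiles))
    writeRankProfileTSV(study$profiles[[nm]],
                        file.path(outDir, sprintf("rank_profile_n%03d.tsv",
                                                  as.integer(nm))),
                        top = top)
  data.table::fwrite(study$counts,
                     file.path(outDir, "significance_counts.tsv"),
                     sep = "\t")
  writeManifest(outDir, "de-stability",
                list(sizes = sizes, repeats = repeats, seed = seed,
                     variant = variant, alphas = alphas, topK = topK))
  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    grDevices::pdf(file.path(outDir, "rank_profiles.pdf"), width = 7,
                   height = 5)
    for (nm in names(study$profiles))
      print(plotRankProfile(study$profiles[[nm]]))
    grDevices::dev.off()
  }
  invisible(study)
}

#' Run the subsample-overlap calibration and write JSON summaries
#'
#' One `jaccard_n*.json` (n, n_pairs, median, quartiles, seed) per size,
#' plus manifest.json.
#'
#' @param classSizes two population class sizes (default `c(69, 65)`).
#' @param sizes even subsample sizes.
#' @param nPairs pairs per size (default 1000).
#' @param seed integer seed.
#' @param outDir output directory.
#' @return Invisibly, a named list of [JaccardSummary-class] objects.
#' @export
runOverlap <- function(classSizes = c(69L, 65L),
                       sizes = seq(10L, 120L, by = 10L), nPairs = 1000L,
                       seed = 1L, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  out <- list()
  for (i in seq_along(sizes)) {
    js <- subsampleOverlapStudy(classSizes, sizes[i], nPairs = nPairs,
                                seed = deriveSeed(seed, i))
    writeJaccardJSON(js, file.path(outDir,
                                   sprintf("jaccard_n%03d.json", sizes[i])))
    out[[as.character(sizes[i])]] <- js
  }
  writeManifest(outDir, "overlap",
                list(class_sizes = classSizes, sizes = sizes,
                     n_pairs = nPairs, seed = seed))
  invisible(out)
}

#' Run a learning-curve study and write its outputs
#'
#' Writes learning_curve.tsv (n, rep, accuracy, mode),
#' learning_curve_summary.json (per-size mean/sd/median) and manifest.json;
#' with `plots = TRUE` (requires ggplot2) a learning_curve.pdf box plot.
#'
#' @param input training dataset (`SummarizedExperiment` or directory).
#' @param externalInput external cohort for `mode = "external"`.
#' @param outDir output directory.
#' @param sizes,repeats,mode,seed,... see [learningCurve()].
#' @param plots also write a figure (default FALSE).
#' @return Invisibly, the [LearningCurve-class].
#' @export
runLearningCurve <- function(input, outDir,
                             sizes = seq(10L, 110L, by = 10L),
                             repeats = 50L, mode = "internal_cv",
                             externalInput = NULL, seed = 1L,
                             plots = FALSE, ...) {
  se <- resolveDataset(input)
  ext <- if (!is.null(externalInput)) resolveDataset(externalInput)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  lc <- learningCurve(se, sizes = sizes, repeats = repeats, mode = mode,
                      external = ext, seed = seed, ...)
  tab <- curveTable(lc)
  tab$mode <- lc@mode
  data.table::fwrite(tab, file.path(outDir, "learning_curve.tsv"),
                     sep = "\t")
  jsonlite::write_json(summary(lc),
                       file.path(outDir, "learning_curve_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeManifest(outDir, "learning-curve",
                list(sizes = sizes, repeats = repeats, mode = mode,
                     seed = seed))
  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    grDevices::pdf(file.path(outDir, "learning_curve.pdf"), width = 7,
                   height = 5)
    print(plotLearningCurve(lc))
    grDevices::dev.off()
  }
  invisible(lc)
}
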