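#' @import methods
NULL

#' Configuration of the synthetic two-class expression generator
#'
#' Describes a planted-effect dataset emulating a two-sex bulk expression
#' study: a block of sex-linked features with a large common log-scale shift,
#' a block of autosomal features with graded moderate shifts (strictly
#' decreasing over the block, so a defined true effect ordering exists), and
#' a null remainder. Per-feature baselines and noise SDs are drawn feature by
#' feature; noise is Gaussian on the log2 scale.
#'
#' @slot nFeatures total number of features (default 41000).
#' @slot nClassA,nClassB samples per class (defaults 69 and 65; class A is the
#'   first label in `classLevels`).
#' @slot nSexLinked number of sex-linked features (default 1548), all given
#'   the shift `sexLinkedEffect`.
#' @slot sexLinkedEffect absolute log2 shift of sex-linked features
#'   (default 2).
#' @slot nDEAutosomal number of autosomal differentially expressed features
#'   (default 600).
#' @slot deEffectRange range of absolute log2 shifts for the autosomal block
#'   (default 0.2–1.5), assigned in decreasing order over the block.
#' @slot baselineMeanSD mean and SD of the per-feature baseline draw
#'   (default 7, 2 on the log2 scale).
#' @slot featureSDRange bounds of the uniform draw of per-feature noise SD
#'   (default 1.0–2.5 log2 units).
#' @slot classLevels the two class labels; the first is class A
#'   (default `c("M", "F")`).
#' @slot seed integer seed; identical configurations generate bit-identical
#'   datasets.
#' @seealso [syntheticConfig()], [generateDataset()]
#' @export
setClass("SyntheticConfig",
  representation(
    nFeatures = "integer", nClassA = "integer", nClassB = "integer",
    nSexLinked = "integer", sexLinkedEffect = "numeric",
    nDEAutosomal = "integer", deEffectRange = "numeric",
    baselineMeanSD = "numeric", featureSDRange = "numeric",
    classLevels = "character", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  bad <- function(field, why) sprintf("field '%s': %s", field, why)
  msgs <- character()
  cnt <- function(x) length(x) == 1L && !is.na(x) && x >= 0L
  if (!cnt(object@nFeatures)) msgs <- c(msgs, bad("nFeatures", "must be a single count >= 0"))
  if (!cnt(object@nClassA) || object@nClassA < 1L) msgs <- c(msgs, bad("nClassA", "must be a positive count"))
  if (!cnt(object@nClassB) || object@nClassB < 1L) msgs <- c(msgs, bad("nClassB", "must be a positive count"))
  if (!cnt(object@nSexLinked)) msgs <- c(msgs, bad("nSexLinked", "must be a count >= 0"))
  if (!cnt(object@nDEAutosomal)) msgs <- c(msgs, bad("nDEAutosomal", "must be a count >= 0"))
  if (cnt(object@nSexLinked) && cnt(object@nDEAutosomal) && cnt(object@nFeatures) &&
      object@nSexLinked + object@nDEAutosomal > object@nFeatures)
    msgs <- c(msgs, bad("nSexLinked/nDEAutosomal", "planted features exceed nFeatures"))
  if (length(object@sexLinkedEffect) != 1L || !is.finite(object@sexLinkedEffect))
    msgs <- c(msgs, bad("sexLinkedEffect", "must be a single finite shift"))
  if (length(object@deEffectRange) != 2L || any(!is.finite(object@deEffectRange)))
    msgs <- c(msgs, bad("deEffectRange", "must be two finite shifts"))
  if (length(object@baselineMeanSD) != 2L || !is.finite(object@baselineMeanSD[2]) ||
      object@baselineMeanSD[2] <= 0)
    msgs <- c(msgs, bad("baselineMeanSD", "must be (mean, sd) with sd > 0"))
  if (length(object@featureSDRange) != 2L || any(!is.finite(object@featureSDRange)) ||
      any(object@featureSDRange <= 0) ||
      object@featureSDRange[1] > object@featureSDRange[2])
    msgs <- c(msgs, bad("featureSDRange", "must be positive increasing bounds"))
  if (length(object@classLevels) != 2L || anyDuplicated(object@classLevels))
    msgs <- c(msgs, bad("classLevels", "must be two distinct labels"))
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, bad("seed", "must be a single integer"))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Balanced subsampling design over a grid of sample sizes
#'
#' Holds, for every (size, repeat) cell, the subject IDs of one balanced
#' class-stratified draw, together with the deterministic per-cell seeds
#' derived from the master seed.
#'
#' @slot sizes even subsample sizes.
#' @slot repeats draws per size.
#' @slot masterSeed the master seed.
#' @slot cellSeeds integer matrix (size x repeat) of derived seeds.
#' @slot cells list (per size) of lists (per repeat) of subject-ID vectors.
#' @slot pheno the two-level phenotype factor the design was drawn from.
#' @seealso [buildDesign()]
#' @export
setClass("SubsampleDesign",
  representation(sizes = "integer", repeats = "integer", masterSeed = "integer",
                 cellSeeds = "matrix", cells = "list", pheno = "factor"))

setValidity("SubsampleDesign", function(object) {
  if (length(object@cells) != length(object@sizes))
    return("one cell list per size required")
  lv <- levels(object@pheno)
  ids <- names(object@pheno)
  for (i in seq_along(object@sizes)) {
    n <- object@sizes[i]
    if (length(object@cells[[i]]) != object@repeats)
      return(sprintf("size %d: expected %d repeats", n, object@repeats))
    for (cell in object@cells[[i]]) {
      if (anyDuplicated(cell)) return("duplicate subject within a cell")
      if (!all(cell %in% ids)) return("cell subject not in phenotype table")
      tab <- table(factor(object@pheno[cell], levels = lv))
      if (any(tab != n / 2)) return(sprintf("size-%d cell is not balanced", n))
    }
  }
  TRUE
})

#' Jaccard overlap calibration of balanced subsamples
#'
#' Distribution of the Jaccard score J(A,B) = |A∩B|/|A∪B| between the subject
#' sets of independently drawn pairs of balanced subsamples of a fixed size.
#'
#' @slot n subsample size (total, both classes).
#' @slot nPairs number of independent pairs drawn.
#' @slot classSizes the two population class sizes.
#' @slot values per-pair Jaccard scores, in \[0, 1\].
#' @slot seed seed used for the draws.
#' @seealso [subsampleOverlapStudy()], [jaccard()]
#' @export
setClass("JaccardSummary",
  representation(n = "integer", nPairs = "integer", classSizes = "integer",
                 values = "numeric", seed = "integer"))

setValidity("JaccardSummary", function(object) {
  if (length(object@values) != object@nPairs)
    return("values must hold one score per pair")
  if (any(object@values < 0 | object@values > 1))
    return("Jaccard values must lie in [0, 1]")
  TRUE
})

#' Per-feature rank-stability profile across subsample repeats
#'
#' For one subsample size, aggregates per-feature two-sample t-test results
#' over repeated balanced subsamples: mean raw p-value, per-repeat rank
#' (ascending p over all features), mean rank, and an empirical 95% rank
#' interval (2.5th/97.5th percentiles across repeats).
#'
#' @slot stats data.frame with columns feature_id, mean_p, mean_rank,
#'   rank_lo, rank_hi.
#' @slot n subsample size the profile refers to (NA if unknown).
#' @slot repeats number of repeats aggregated.
#' @slot topFeatures feature IDs of the top-k features by mean p-value.
#' @seealso [aggregateOverRepeats()], [rankStabilityStudy()]
#' @export
setClass("RankProfile",
  representation(stats = "data.frame", n = "integer", repeats = "integer",
                 topFeatures = "character"))

setValidity("RankProfile", function(object) {
  st <- object@stats
  need <- c("feature_id", "mean_p", "mean_rank", "rank_lo", "rank_hi")
  if (!all(need %in% colnames(st)))
    return(sprintf("stats must have columns %s", paste(need, collapse = ", ")))
  G <- nrow(st)
  if (G < 1L) return("empty profile")
  if (any(st$mean_rank < 1 | st$mean_rank > G))
    return("mean rank outside [1, G]")
  if (any(st$rank_lo > st$mean_rank | st$mean_rank > st$rank_hi))
    return("rank interval must bracket the mean rank")
  TRUE
})

#' Sparse L1-penalized logistic classifier
#'
#' A fitted lasso logistic model predicting the binary class from expression
#' values: the selected features (all with nonzero coefficients), intercept,
#' and the regularization strength chosen by internal cross-validation.
#' Coefficients are on the original expression scale; probabilities refer to
#' class A (the first class level), thresholded at 0.5 with ties going to
#' class A.
#'
#' @slot features selected feature IDs.
#' @slot coefficients their (nonzero) coefficients.
#' @slot intercept model intercept.
#' @slot lambda regularization strength used.
#' @slot lambdaRule "min" (minimum CV deviance) or "1se".
#' @slot classLevels the two class labels; first = class A.
#' @slot nTrain training-set size.
#' @slot seed seed used for fold assignment.
#' @slot excludedSexLinked number of sex-linked features removed before
#'   training.
#' @slot standardized whether features were standardized inside the fit.
#' @seealso [trainClassifier()], [predictClasses()]
#' @export
setClass("ClassifierModel",
  representation(features = "character", coefficients = "numeric",
                 intercept = "numeric", lambda = "numeric",
                 lambdaRule = "character", classLevels = "character",
                 nTrain = "integer", seed = "integer",
                 excludedSexLinked = "integer", standardized = "logical"))

setValidity("ClassifierModel", function(object) {
  if (length(object@features) != length(object@coefficients))
    return("one coefficient per selected feature required")
  if (any(object@coefficients == 0))
    return("selected features must have nonzero coefficients")
  if (length(object@classLevels) != 2L)
    return("exactly two class levels required")
  TRUE
})

#' Classifier learning curve over training-set size
#'
#' Per (training size, repeat) accuracies of lasso classifiers trained on
#' balanced subsamples, evaluated either by internal stratified
#' cross-validation on the subsample or on an external cohort.
#'
#' @slot curve data.frame with columns n, rep, accuracy.
#' @slot mode "internal_cv" or "external".
#' @slot seed master seed of the study.
#' @seealso [learningCurve()]
#' @export
setClass("LearningCurve",
  representation(curve = "data.frame", mode = "character", seed = "integer"))

setValidity("LearningCurve", function(object) {
  if (!all(c("n", "rep", "accuracy") %in% colnames(object@curve)))
    return("curve must have columns n, rep, accuracy")
  if (any(object@curve$accuracy < 0 | object@curve$accuracy > 1))
    return("accuracies must lie in [0, 1]")
  if (!object@mode %in% c("internal_cv", "external"))
    return("mode must be 'internal_cv' or 'external'")
  TRUE
})
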