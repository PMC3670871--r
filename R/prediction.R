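# L1-penalized logistic classification of the binary phenotype: sex-linked
# feature exclusion, lasso fits via glmnet with seeded stratified folds,
# nested cross-validated accuracy, and learning curves over training size.

#' Remove sex-linked features
#'
#' Drops every feature flagged `sex_linked` in `rowData`. Sex-linked
#' transcripts make the sex-prediction problem trivial, so they are excluded
#' before classifier training to pose a physiologically typical problem.
#' Zero flagged features is legal (identity, with a message).
#'
#' @param se `SummarizedExperiment` with a logical `sex_linked` rowData
#'   column.
#' @return The experiment without flagged features;
#'   `metadata(se)$removed_sex_linked` records how many were removed.
#' @export
excludeSexLinked <- function(se) {
  if (!is(se, "SummarizedExperiment"))
    dataError("excludeSexLinked expects a SummarizedExperiment")
  rd <- SummarizedExperiment::rowData(se)
  flag <- if ("sex_linked" %in% colnames(rd)) rd$sex_linked
          else rep(FALSE, nrow(se))
  flag[is.na(flag)] <- FALSE
  out <- se[!flag, ]
  S4Vectors::metadata(out)$removed_sex_linked <- sum(flag)
  message(sprintf("excluded %d sex-linked feature(s)", sum(flag)))
  out
}

# Shared lasso fit: returns a ClassifierModel. `sexLinked` is a logical
# row flag (NULL = none known).
fitLasso <- function(mat, pheno, sexLinked, exclude, lambdaRule, nfolds,
                     nlambda, seed) {
  excluded <- 0L
  if (exclude && !is.null(sexLinked)) {
    keep <- !sexLinked
    excluded <- sum(!keep)
    mat <- mat[keep, , drop = FALSE]
    if (!is.null(sexLinked)) sexLinked <- sexLinked[keep]
  }
  if (nrow(mat) < 1L) dataError("no features left to train on")
  lv <- levels(pheno)
  if (any(table(pheno) < 2L))
    dataError("each class needs >= 2 training samples")
  rng <- range(mat)
  if (rng[1] == rng[2]) dataError("degenerate input: all values constant")
  y <- as.integer(pheno == lv[1])   # 1 = class A
  n <- ncol(mat)
  if (min(table(pheno)) >= 3L) {
    # every CV training part keeps >= 2 samples per class
    k <- max(3L, min(nfolds, n))
    withSeed(seed, foldid <- stratifiedFolds(y, k))
    cv <- quietGlmnet(glmnet::cv.glmnet(t(mat), y, family = "binomial",
                                        alpha = 1, standardize = TRUE,
                                        foldid = foldid, nlambda = nlambda))
    lambda <- if (lambdaRule == "min") cv$lambda.min else cv$lambda.1se
    cf <- as.matrix(stats::coef(cv, s = lambda))
  } else {
    # too few samples per class for internal CV folds: pick lambda on the
    # path by an AIC-style penalized deviance (deterministic)
    fit <- quietGlmnet(glmnet::glmnet(t(mat), y, family = "binomial",
                                      alpha = 1, standardize = TRUE,
                                      nlambda = nlambda))
    aic <- (1 - fit$dev.ratio) * fit$nulldev + 2 * fit$df
    lambda <- fit$lambda[which.min(aic)]
    cf <- as.matrix(stats::coef(fit, s = lambda))
  }
  nz <- which(cf[-1L, 1L] != 0)
  new("ClassifierModel",
      features = rownames(mat)[nz],
      coefficients = unname(cf[-1L, 1L][nz]),
      intercept = cf[1L, 1L],
      lambda = lambda, lambdaRule = lambdaRule, classLevels = lv,
      nTrain = n, seed = as.integer(seed),
      excludedSexLinked = as.integer(excluded), standardized = TRUE)
}

#' Train a lasso logistic classifier
#'
#' L1-penalized logistic regression of the binary class on expression values
#' (features standardized inside the fit). The regularization strength is
#' chosen by internal stratified k-fold cross-validation over a logarithmic
#' lambda grid, by minimum CV binomial deviance (`lambdaRule = "min"`,
#' default) or the one-SE rule. Deterministic given the seed. When a class
#' has fewer than 3 training samples, CV folds are infeasible and lambda is
#' instead chosen on the path by AIC-style penalized deviance.
#'
#' @param x `SummarizedExperiment` or numeric matrix (features x samples).
#' @param pheno named two-level factor if `x` is a matrix.
#' @param exclude drop sex-linked features before training (default TRUE;
#'   requires the `sex_linked` rowData flag, otherwise a no-op).
#' @param lambdaRule `"min"` or `"1se"`.
#' @param nfolds folds of the internal lambda CV (default 10; reduced
#'   automatically when n is smaller).
#' @param nlambda length of the lambda grid (default 60).
#' @param seed integer seed for fold assignment.
#' @return A [ClassifierModel-class].
#' @export
trainClassifier <- function(x, pheno = NULL, exclude = TRUE,
                            lambdaRule = c("min", "1se"), nfolds = 10L,
                            nlambda = 60L, seed = 1L) {
  lambdaRule <- match.arg(lambdaRule)
  inp <- resolveInput(x, pheno)
  fitLasso(inp$exprs, inp$pheno, inp$sexLinked, exclude, lambdaRule,
           nfolds, nlambda, seed)
}

#' Predict class labels and probabilities
#'
#' Logistic probability of class A for each sample; labels thresholded at
#' 0.5 with ties assigned to class A. Every model feature must be present in
#' the new matrix (missing features are an error listing them).
#'
#' @param model a [ClassifierModel-class].
#' @param x `SummarizedExperiment` or numeric matrix (features x samples).
#' @param ... unused.
#' @return data.frame with columns sample_id, probability (of class A),
#'   label.
#' @rdname predictClasses
#' @export
setMethod("predictClasses", "ClassifierModel", function(model, x, ...) {
  mat <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, 1L) else x
  if (!is.matrix(mat)) dataError("prediction input must be a matrix")
  missing <- setdiff(model@features, rownames(mat))
  if (length(missing))
    dataError("matrix lacks %d model feature(s): %s", length(missing),
              paste(utils::head(missing, 10L), collapse = ", "))
  eta <- model@intercept +
    as.numeric(crossprod(mat[model@features, , drop = FALSE],
                         model@coefficients))
  prob <- 1 / (1 + exp(-eta))
  lab <- ifelse(prob >= 0.5, model@classLevels[1L], model@classLevels[2L])
  data.frame(sample_id = colnames(mat), probability = prob,
             label = factor(lab, levels = model@classLevels),
             stringsAsFactors = FALSE)
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf(
    "ClassifierModel: %d feature(s), lambda = %.4g (%s), trained on n = %d (%d sex-linked excluded)\n",
    length(object@features), object@lambda, object@lambdaRule,
    object@nTrain, object@excludedSexLinked))
})

#' Nested cross-validated accuracy
#'
#' Stratified k-fold cross-validation in which the entire training procedure
#' — sex-linked exclusion, lambda selection by internal CV, and the lasso
#' fit — is repeated inside each fold, so no information from held-out
#' samples leaks into training.
#'
#' @param x `SummarizedExperiment` or matrix.
#' @param pheno phenotype factor if `x` is a matrix.
#' @param k outer folds (default 10); must not exceed the sample count.
#' @param seed integer seed.
#' @param exclude drop sex-linked features inside each fold (default TRUE).
#' @param innerNfolds folds of the lambda CV inside each outer fold
#'   (default 3, keeping nested runs affordable).
#' @param lambdaRule,nlambda passed to the inner fit.
#' @param sexLinked optional logical per-row exclusion flags when `x` is a
#'   plain matrix (taken from `rowData` for a `SummarizedExperiment`).
#' @return Fraction of held-out samples classified correctly.
#' @export
crossValidatedAccuracy <- function(x, pheno = NULL, k = 10L, seed = 1L,
                                   exclude = TRUE, innerNfolds = 3L,
                                   lambdaRule = "min", nlambda = 60L,
                                   sexLinked = NULL) {
  inp <- resolveInput(x, pheno)
  if (!is.null(sexLinked)) inp$sexLinked <- sexLinked
  n <- ncol(inp$exprs)
  if (k > n) configError("k = %d folds exceed n = %d samples", k, n)
  if (k < 2L) configError("k must be >= 2")
  y <- as.integer(inp$pheno == levels(inp$pheno)[1L])
  withSeed(seed, foldid <- stratifiedFolds(y, k))
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- foldid != f
    if (!any(!tr)) next
    model <- fitLasso(inp$exprs[, tr, drop = FALSE], inp$pheno[tr],
                      inp$sexLinked, exclude, lambdaRule,
                      innerNfolds, nlambda, deriveSeed(seed, f))
    pred <- predictClasses(model, inp$exprs[, !tr, drop = FALSE])
    correct <- correct + sum(as.character(pred$label) ==
                               as.character(inp$pheno[!tr]))
  }
  correct / n
}

#' Classifier learning curve over training-set size
#'
#' For every size `n` in the grid and every repeat, draws a balanced
#' subsample, trains a lasso classifier on it, and evaluates it either by
#' internal stratified 10-fold cross-validation on the subsample
#' (`mode = "internal_cv"`, nested lambda selection inside each fold) or on
#' an external cohort (`mode = "external"`; feature IDs are intersected with
#' the external matrix before training).
#'
#' @param x `SummarizedExperiment` or matrix (the training population).
#' @param pheno phenotype factor if `x` is a matrix.
#' @param sizes even training sizes (default `seq(10, 110, by = 10)`).
#' @param repeats subsamples per size (default 50).
#' @param mode `"internal_cv"` or `"external"`.
#' @param external external cohort (`SummarizedExperiment` or matrix),
#'   required for `mode = "external"`.
#' @param externalPheno external phenotype factor if `external` is a matrix.
#' @param seed master seed; cell seeds are derived deterministically.
#' @param cvFolds outer folds of the internal evaluation (default 10).
#' @param innerNfolds,lambdaRule,nlambda,exclude passed to the fits.
#' @return A [LearningCurve-class].
#' @export
learningCurve <- function(x, pheno = NULL,
                          sizes = seq(10L, 110L, by = 10L), repeats = 50L,
                          mode = c("internal_cv", "external"),
                          external = NULL, externalPheno = NULL, seed = 1L,
                          cvFolds = 10L, innerNfolds = 3L,
                          lambdaRule = "min", nlambda = 60L,
                          exclude = TRUE) {
  mode <- match.arg(mode)
  inp <- resolveInput(x, pheno)
  ext <- NULL
  if (mode == "external") {
    if (is.null(external))
      configError("mode 'external' requires an external cohort")
    ext <- resolveInput(external, externalPheno)
    common <- intersect(rownames(inp$exprs), rownames(ext$exprs))
    if (!length(common))
      dataError("no shared feature IDs with the external cohort")
    dropped <- nrow(inp$exprs) - length(common)
    if (dropped > 0L)
      message(sprintf("feature intersection with external cohort: %d kept, %d dropped",
                      length(common), dropped))
    keep <- match(common, rownames(inp$exprs))
    inp$exprs <- inp$exprs[keep, , drop = FALSE]
    if (!is.null(inp$sexLinked)) inp$sexLinked <- inp$sexLinked[keep]
    ext$exprs <- ext$exprs[common, , drop = FALSE]
  }
  rows <- vector("list", length(sizes) * repeats)
  idx <- 0L
  for (i in seq_along(sizes)) {
    for (j in seq_len(repeats)) {
      cellSeed <- deriveSeed(seed, i, j)
      ids <- drawBalancedSubsample(inp$pheno, sizes[i], seed = cellSeed)
      subMat <- inp$exprs[, ids, drop = FALSE]
      subPh <- inp$pheno[ids]
      acc <- if (mode == "internal_cv") {
        crossValidatedAccuracy(subMat, subPh,
                               k = min(cvFolds, sizes[i]),
                               seed = deriveSeed(cellSeed, 1L),
                               exclude = exclude,
                               innerNfolds = innerNfolds,
                               lambdaRule = lambdaRule, nlambda = nlambda,
                               sexLinked = inp$sexLinked)
      } else {
        model <- fitLasso(subMat, subPh, inp$sexLinked, exclude,
                          lambdaRule, innerNfolds, nlambda,
                          deriveSeed(cellSeed, 1L))
        pred <- predictClasses(model, ext$exprs)
        mean(as.character(pred$label) == as.character(ext$pheno))
      }
      idx <- idx + 1L
      rows[[idx]] <- data.frame(n = sizes[i], rep = j, accuracy = acc)
    }
  }
  new("LearningCurve", curve = do.call(rbind, rows), mode = mode,
      seed = as.integer(seed))
}

#' Per-repeat accuracies of a learning curve
#' @param x a [LearningCurve-class].
#' @return data.frame with columns n, rep, accuracy.
#' @rdname curveTable
#' @export
setMethod("curveTable", "LearningCurve", function(x) x@curve)

#' @describeIn LearningCurve-class per-size mean, SD and median accuracy.
#' @param object a `LearningCurve`.
#' @export
setMethod("summary", "LearningCurve", function(object, ...) {
  cv <- object@curve
  agg <- do.call(rbind, lapply(split(cv, cv$n), function(d)
    data.frame(n = d$n[1L], mean = mean(d$accuracy),
               sd = stats::sd(d$accuracy),
               median = stats::median(d$accuracy))))
  agg <- agg[order(agg$n), , drop = FALSE]
  rownames(agg) <- NULL
  agg
})

setMethod("show", "LearningCurve", function(object) {
  s <- summary(object)
  cat(sprintf("LearningCurve (%s): %d size(s) x %d repeat(s)\n",
              object@mode, nrow(s), max(object@curve$rep)))
  print(s, digits = 3)
})

#' Serialize a classifier to JSON
#' @param model a [ClassifierModel-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeModelJSON <- function(model, path) {
  jsonlite::write_json(
    list(features = model@features, coefficients = model@coefficients,
         intercept = model@intercept, lambda = model@lambda,
         lambda_rule = model@lambdaRule, class_levels = model@classLevels,
         n_train = model@nTrain, seed = model@seed,
         excluded_sex_linked = model@excludedSexLinked,
         standardized = model@standardized),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
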