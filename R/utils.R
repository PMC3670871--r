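# Internal helpers: classed errors, seed management, fold assignment.

stopf <- function(fmt, ..., class = "ss_error") {
  stop(errorCondition(sprintf(fmt, ...),
                      class = unique(c(class, "ss_error"))))
}

configError <- function(fmt, ...) stopf(fmt, ..., class = "ss_config_error")
dataError   <- function(fmt, ...) stopf(fmt, ..., class = "ss_data_error")

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so that
#' seeded draws inside the package never perturb the user's random stream.
#' @noRd
withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Deterministic per-cell seed
#'
#' Counter-based mix of (master seed, size index, repeat index) so any cell of
#' a subsampling design is reproducible independently of execution order.
#' Arithmetic stays below 2^53 and the result below 2^31.
#' @noRd
deriveSeed <- function(master, i, j = 0L) {
  m <- 2147483647
  s <- abs(as.numeric(master)) %% m
  s <- (s * 48271 + as.numeric(i) * 2971 + 1) %% m
  s <- (s * 48271 + as.numeric(j) * 7919 + 1) %% m
  as.integer(s)
}

# Class-stratified fold labels in 1..k; uses the current RNG stream.
stratifiedFolds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# glmnet is chatty about tiny classes during deliberately small subsample
# fits; muffle only those advisory warnings.
quietGlmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    msg <- conditionMessage(w)
    if (grepl("dangerous ground|grouped=FALSE|fewer than", msg))
      invokeRestart("muffleWarning")
  })
}

# Resolve (expression matrix, phenotype factor, sex-linked flags) from either
# a SummarizedExperiment or an explicit matrix + named factor.
resolveInput <- function(x, pheno = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    mat <- SummarizedExperiment::assay(x, 1L)
    cd <- SummarizedExperiment::colData(x)
    if (is.null(pheno)) {
      if (!"class" %in% colnames(cd))
        dataError("SummarizedExperiment has no 'class' column in colData")
      pheno <- stats::setNames(cd$class, colnames(x))
    }
    rd <- SummarizedExperiment::rowData(x)
    sex <- if ("sex_linked" %in% colnames(rd)) rd$sex_linked else NULL
  } else {
    mat <- x
    sex <- NULL
  }
  if (!is.matrix(mat) || !is.numeric(mat))
    dataError("expression input must be a numeric matrix")
  if (is.null(pheno)) dataError("a phenotype is required")
  pheno <- checkPhenotype(pheno, colnames(mat))
  list(exprs = mat, pheno = pheno, sexLinked = sex)
}

# Validate a two-level phenotype factor against the matrix sample IDs and
# return it aligned to column order.
checkPhenotype <- function(pheno, sample_ids) {
  if (!is.factor(pheno)) pheno <- factor(pheno)
  if (nlevels(pheno) != 2L)
    dataError("phenotype must have exactly two levels, got %d (%s)",
              nlevels(pheno), paste(levels(pheno), collapse = ", "))
  if (!is.null(sample_ids)) {
    if (is.null(names(pheno))) {
      if (length(pheno) != length(sample_ids))
        dataError("phenotype length (%d) does not match sample count (%d)",
                  length(pheno), length(sample_ids))
      names(pheno) <- sample_ids
    } else {
      missing <- setdiff(sample_ids, names(pheno))
      if (length(missing))
        dataError("no phenotype label for sample(s): %s",
                  paste(utils::head(missing, 5L), collapse = ", "))
      pheno <- pheno[sample_ids]
    }
  }
  if (any(is.na(pheno))) dataError("phenotype labels contain NA")
  if (any(table(pheno) == 0L))
    dataError("both phenotype classes must be non-empty")
  droplevels_keep2 <- pheno  # both levels guaranteed non-empty above
  droplevels_keep2
}
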