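#' Draw one balanced class-stratified subsample
#'
#' Uniform without-replacement draw of `n/2` subjects from each of the two
#' classes. Deterministic given the seed.
#'
#' @param pheno named two-level factor (names = subject IDs).
#' @param n even total subsample size; `n/2` must not exceed either class.
#' @param seed integer seed.
#' @return Character vector of `n` subject IDs (class A first).
#' @examples
#' pheno <- setNames(factor(rep(c("M", "F"), c(6, 6))), paste0("S", 1:12))
#' drawBalancedSubsample(pheno, 4, seed = 1)
#' @export
drawBalancedSubsample <- function(pheno, n, seed = 1L) {
  pheno <- checkPhenotype(pheno, NULL)
  if (is.null(names(pheno))) dataError("phenotype must carry subject IDs")
  if (length(n) != 1L || n < 2L || n %% 2L != 0L)
    configError("subsample size n must be a single even count >= 2, got %s",
                paste(n, collapse = ","))
  h <- n / 2L
  lv <- levels(pheno)
  for (cl in lv) {
    avail <- sum(pheno == cl)
    if (h > avail)
      configError("class '%s' has %d subjects, cannot draw %d", cl, avail, h)
  }
  withSeed(seed, {
    picked <- lapply(lv, function(cl) sample(names(pheno)[pheno == cl], h))
  })
  unlist(picked, use.names = FALSE)
}

#' Build a balanced subsampling design over a size grid
#'
#' Draws `repeats` independent balanced subsamples for every size. The seed
#' of cell (size index i, repeat j) is a deterministic counter-based mix of
#' the master seed with (i, j), so identical master seeds give identical
#' designs and any single cell equals a direct [drawBalancedSubsample()]
#' call with its derived seed.
#'
#' @param pheno named two-level factor.
#' @param sizes even subsample sizes (e.g. `seq(10, 120, by = 10)`).
#' @param repeats draws per size (default 50).
#' @param seed master seed.
#' @return A validated [SubsampleDesign-class].
#' @export
buildDesign <- function(pheno, sizes, repeats = 50L, seed = 1L) {
  pheno <- checkPhenotype(pheno, NULL)
  sizes <- as.integer(sizes)
  repeats <- as.integer(repeats)
  if (repeats < 1L) configError("repeats must be >= 1")
  cellSeeds <- outer(seq_along(sizes), seq_len(repeats),
                     function(i, j) mapply(deriveSeed, seed, i, j))
  cellSeeds <- matrix(as.integer(cellSeeds), nrow = length(sizes))
  cells <- lapply(seq_along(sizes), function(i)
    lapply(seq_len(repeats), function(j)
      drawBalancedSubsample(pheno, sizes[i], seed = cellSeeds[i, j])))
  new("SubsampleDesign", sizes = sizes, repeats = repeats,
      masterSeed = as.integer(seed), cellSeeds = cellSeeds, cells = cells,
      pheno = pheno)
}

#' Subjects of one design cell
#'
#' @param design a [SubsampleDesign-class].
#' @param size one of the design's sizes.
#' @param rep repeat index in `1..repeats`.
#' @return Character vector of subject IDs.
#' @rdname designSubjects
#' @export
setMethod("designSubjects", "SubsampleDesign", function(design, size, rep) {
  i <- match(size, design@sizes)
  if (is.na(i)) configError("size %d is not in the design", size)
  if (rep < 1L || rep > design@repeats)
    configError("repeat index %d outside 1..%d", rep, design@repeats)
  design@cells[[i]][[rep]]
})

setMethod("show", "SubsampleDesign", function(object) {
  cat(sprintf(
    "SubsampleDesign: %d size(s) [%s] x %d repeats, master seed %d\n",
    length(object@sizes), paste(object@sizes, collapse = ", "),
    object@repeats, object@masterSeed))
})

#' Write a subsampling design to TSV
#'
#' Long format: one row per (size, repeat, subject_id).
#' @param design a [SubsampleDesign-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeDesignTSV <- function(design, path) {
  rows <- do.call(rbind, lapply(seq_along(design@sizes), function(i)
    do.call(rbind, lapply(seq_len(design@repeats), function(j)
      data.frame(size = design@sizes[i], rep = j,
                 subject_id = design@cells[[i]][[j]])))))
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}

#' Jaccard score of two finite sets
#'
#' `J(A, B) = |A n B| / |A u B|`, always in \[0, 1\]: 0 for disjoint sets,
#' 1 for identical sets. Symmetric; undefined (an error) when both sets are
#' empty. Set-agnostic — applicable to subject-ID sets, gene lists, or any
#' atomic vectors (duplicates are ignored).
#'
#' @param a,b atomic vectors interpreted as sets.
#' @return Numeric scalar in \[0, 1\].
#' @examples
#' jaccard(1:3, 2:4)  # 0.5
#' @export
jaccard <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L)
    configError("Jaccard score is undefined for two empty sets")
  length(intersect(a, b)) / length(union(a, b))
}

#' Jaccard overlap calibration for balanced subsamples
#'
#' How similar are two independently drawn balanced size-`n` subsamples of
#' the same finite population? Draws `nPairs` independent pairs (each taking
#' `n/2` subject indices uniformly without replacement per class) and
#' records the Jaccard score of the two subject-index sets. The closed-form
#' plug-in expectation of the intersection is
#' `(n/2)^2/Na + (n/2)^2/Nb` (hypergeometric means), giving e.g. a median
#' near 0.126 for n = 30 from populations (69, 65).
#'
#' @param classSizes the two population class sizes, e.g. `c(69, 65)`.
#' @param n even subsample size.
#' @param nPairs number of independent pairs (default 1000).
#' @param seed integer seed.
#' @return A [JaccardSummary-class].
#' @examples
#' js <- subsampleOverlapStudy(c(69, 65), n = 30, nPairs = 200, seed = 1)
#' median(jaccardValues(js))
#' @export
subsampleOverlapStudy <- function(classSizes, n, nPairs = 1000L, seed = 1L) {
  if (length(classSizes) != 2L || any(classSizes < 1L))
    configError("classSizes must be two positive population sizes")
  if (length(n) != 1L || n < 2L || n %% 2L != 0L)
    configError("subsample size n must be a single even count >= 2")
  h <- n / 2L
  nA <- as.integer(classSizes[1]); nB <- as.integer(classSizes[2])
  if (h > nA || h > nB)
    configError("class of size %d cannot supply %d subjects",
                min(nA, nB), h)
  draw <- function() c(sample.int(nA, h), nA + sample.int(nB, h))
  withSeed(seed, {
    vals <- vapply(seq_len(nPairs), function(k) jaccard(draw(), draw()),
                   numeric(1))
  })
  new("JaccardSummary", n = as.integer(n), nPairs = as.integer(nPairs),
      classSizes = c(nA, nB), values = vals, seed = as.integer(seed))
}

#' Per-pair Jaccard values of an overlap study
#' @param x a [JaccardSummary-class].
#' @return Numeric vector of length `nPairs`.
#' @rdname jaccardValues
#' @export
setMethod("jaccardValues", "JaccardSummary", function(x) x@values)

#' @describeIn JaccardSummary-class median and quartiles as a list suitable
#'   for JSON serialization.
#' @param object a `JaccardSummary`.
#' @export
setMethod("summary", "JaccardSummary", function(object, ...) {
  q <- stats::quantile(object@values, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = object@n, n_pairs = object@nPairs,
       class_sizes = object@classSizes,
       median = q[2], q1 = q[1], q3 = q[3], seed = object@seed)
})

setMethod("show", "JaccardSummary", function(object) {
  s <- summary(object)
  cat(sprintf(
    "JaccardSummary: n = %d from populations (%d, %d), %d pairs\n  median %.4f [q1 %.4f, q3 %.4f]\n",
    s$n, s$class_sizes[1], s$class_sizes[2], s$n_pairs,
    s$median, s$q1, s$q3))
})

#' Write an overlap summary to JSON
#' @param x a [JaccardSummary-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeJaccardJSON <- function(x, path) {
  jsonlite::write_json(summary(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
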