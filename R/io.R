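# Readers/writers for the tab-delimited formats the pipeline touches and the
# assembly of a validated SummarizedExperiment. Dialect: tab separator, "."
# decimal, UTF-8, no quoting.

# fread that refuses silently repaired tables: ragged rows become errors.
freadStrict <- function(path, ...) {
  withCallingHandlers(
    tryCatch(data.table::fread(path, sep = "\t", header = TRUE,
                               fill = FALSE, ...),
             error = function(e)
               dataError("failed to parse '%s': %s", path,
                         conditionMessage(e))),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("Stopped early|Discarded|fields|fill", msg))
        dataError("'%s': malformed table: %s", path, msg)
      invokeRestart("muffleWarning")
    })
}

#' Read a features x samples expression matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of feature IDs.
#' Duplicate IDs, non-numeric cells and non-finite values are rejected with
#' the offending identifier or line number; ragged rows are a parse error.
#'
#' @param path file path.
#' @return Numeric matrix with feature row names and sample column names.
#' @export
readExpressionTSV <- function(path) {
  dt <- freadStrict(path)
  if (ncol(dt) < 2L) dataError("'%s': no sample columns found", path)
  ids <- as.character(dt[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    dataError("'%s': duplicated feature ID(s): %s", path,
              paste(unique(utils::head(dup, 5L)), collapse = ", "))
  samp <- colnames(dt)[-1L]
  if (anyDuplicated(samp))
    dataError("'%s': duplicated sample ID(s): %s", path,
              paste(unique(samp[duplicated(samp)]), collapse = ", "))
  for (j in seq_along(samp)) {
    col <- dt[[j + 1L]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      dataError("'%s': non-numeric value in column '%s' at line %d", path,
                samp[j], if (length(bad)) bad[1L] + 1L else NA_integer_)
    }
  }
  mat <- as.matrix(dt[, -1L, with = FALSE])
  dimnames(mat) <- list(ids, samp)
  if (!all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    dataError("'%s': non-finite value at feature '%s', sample '%s'", path,
              ids[bad[1L]], samp[bad[2L]])
  }
  mat
}

#' Write an expression matrix to TSV
#'
#' Inverse of [readExpressionTSV()]; a write-then-read round trip reproduces
#' the matrix to at least 12 significant digits.
#'
#' @param mat numeric matrix with feature row names and sample column names.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeExpressionTSV <- function(mat, path) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    dataError("matrix must carry feature row names and sample column names")
  dt <- data.table::data.table(feature_id = rownames(mat))
  dt <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a sample phenotype table from TSV
#'
#' Two columns (sample_id, class); the label set must have exactly two
#' levels. When the labels are exactly M/F the canonical order `c("M", "F")`
#' is used (M = class A); otherwise levels are sorted unless `classLevels`
#' is given.
#'
#' @param path file path.
#' @param classLevels optional explicit two-level order (first = class A).
#' @return Named two-level factor of class labels, names = sample IDs.
#' @export
readPhenotypeTSV <- function(path, classLevels = NULL) {
  dt <- freadStrict(path)
  if (ncol(dt) < 2L) dataError("'%s': expected columns sample_id, class", path)
  ids <- as.character(dt[[1L]]); lab <- as.character(dt[[2L]])
  if (anyDuplicated(ids))
    dataError("'%s': duplicated sample ID(s): %s", path,
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  u <- unique(lab)
  if (length(u) != 2L)
    dataError("'%s': phenotype must have exactly two labels, found %d (%s)",
              path, length(u), paste(utils::head(u, 5L), collapse = ", "))
  lev <- if (!is.null(classLevels)) classLevels
         else if (setequal(u, c("M", "F"))) c("M", "F")
         else sort(u)
  stats::setNames(factor(lab, levels = lev), ids)
}

#' Read a feature annotation table from TSV
#'
#' Columns: feature_id, gene_symbol, chromosome, and optionally sex_linked.
#' When `sex_linked` is absent it is derived as `chromosome %in% c("X", "Y")`;
#' when present it must agree with the chromosome wherever one is given.
#'
#' @param path file path.
#' @return data.frame with columns gene_symbol, chromosome, sex_linked and
#'   feature IDs as row names.
#' @export
readAnnotationTSV <- function(path) {
  dt <- freadStrict(path)
  need <- c("feature_id", "gene_symbol", "chromosome")
  if (!all(need %in% colnames(dt)))
    dataError("'%s': expected columns %s", path, paste(need, collapse = ", "))
  ids <- as.character(dt$feature_id)
  if (anyDuplicated(ids))
    dataError("'%s': duplicated feature ID(s): %s", path,
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chrom <- as.character(dt$chromosome)
  derived <- chrom %in% c("X", "Y")
  if ("sex_linked" %in% colnames(dt)) {
    flag <- as.logical(dt$sex_linked)
    known <- !is.na(chrom) & chrom != ""
    clash <- which(known & flag != derived)
    if (length(clash))
      dataError("'%s': sex_linked flag contradicts chromosome for %s", path,
                paste(utils::head(ids[clash], 5L), collapse = ", "))
  } else flag <- derived
  data.frame(gene_symbol = as.character(dt$gene_symbol), chromosome = chrom,
             sex_linked = flag, row.names = ids,
             stringsAsFactors = FALSE)
}

#' Log-transform an expression matrix
#'
#' Elementwise logarithm (default base 2). All values must be strictly
#' positive; offenders are reported by feature and sample. The operation is
#' not idempotent — track the scale yourself (datasets from
#' [generateDataset()] are already on the log2 scale).
#'
#' @param mat numeric matrix (or `SummarizedExperiment`, transformed in
#'   place on its first assay).
#' @param base logarithm base.
#' @return Object of the same shape with transformed values.
#' @export
logTransform <- function(mat, base = 2) {
  if (is(mat, "SummarizedExperiment")) {
    SummarizedExperiment::assay(mat, 1L) <-
      logTransform(SummarizedExperiment::assay(mat, 1L), base = base)
    return(mat)
  }
  bad <- which(mat <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    show <- utils::head(seq_len(nrow(bad)), 5L)
    where <- paste(sprintf("(%s, %s)",
                           if (is.null(rownames(mat))) bad[show, 1L]
                           else rownames(mat)[bad[show, 1L]],
                           if (is.null(colnames(mat))) bad[show, 2L]
                           else colnames(mat)[bad[show, 2L]]),
                   collapse = ", ")
    dataError("log transform requires positive values; offending cells: %s",
              where)
  }
  log(mat, base = base)
}

#' Assemble a validated SummarizedExperiment
#'
#' Combines an expression matrix, a two-level phenotype and (optionally) a
#' feature annotation into the container every downstream function accepts.
#' Every sample must carry exactly one label; features missing from the
#' annotation are treated as non-sex-linked, with a warning stating how many.
#'
#' @param exprs numeric matrix, features x samples, log scale.
#' @param pheno named two-level factor (names = sample IDs) as returned by
#'   [readPhenotypeTSV()].
#' @param annotation optional data.frame from [readAnnotationTSV()].
#' @return A `SummarizedExperiment` with assay `"exprs"`, `colData$class`,
#'   and annotation columns in `rowData`.
#' @export
assembleExperiment <- function(exprs, pheno, annotation = NULL) {
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    dataError("expression matrix must have feature and sample IDs")
  pheno <- checkPhenotype(pheno, colnames(exprs))
  if (is.null(annotation)) {
    rd <- S4Vectors::DataFrame(gene_symbol = rownames(exprs),
                               chromosome = NA_character_,
                               sex_linked = FALSE,
                               row.names = rownames(exprs))
  } else {
    hit <- match(rownames(exprs), rownames(annotation))
    nMissing <- sum(is.na(hit))
    if (nMissing > 0L)
      warning(sprintf(
        "%d feature(s) missing from annotation; treated as non-sex-linked",
        nMissing))
    rd <- S4Vectors::DataFrame(
      gene_symbol = ifelse(is.na(hit), rownames(exprs),
                           annotation$gene_symbol[hit]),
      chromosome = ifelse(is.na(hit), NA_character_,
                          annotation$chromosome[hit]),
      sex_linked = ifelse(is.na(hit), FALSE, annotation$sex_linked[hit]),
      row.names = rownames(exprs))
    for (col in setdiff(colnames(annotation),
                        c("gene_symbol", "chromosome", "sex_linked"))) {
      v <- annotation[[col]][hit]
      rd[[col]] <- v
    }
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    rowData = rd,
    colData = S4Vectors::DataFrame(class = pheno,
                                   row.names = colnames(exprs)))
}

#' Read a dataset directory written by [writeDataset()] or [runSimulate()]
#'
#' @param dir directory holding expression.tsv, phenotype.tsv and
#'   annotation.tsv (ground_truth.tsv, if present, is merged into rowData).
#' @return A `SummarizedExperiment`.
#' @export
readDataset <- function(dir) {
  exprs <- readExpressionTSV(file.path(dir, "expression.tsv"))
  pheno <- readPhenotypeTSV(file.path(dir, "phenotype.tsv"))
  ann <- readAnnotationTSV(file.path(dir, "annotation.tsv"))
  gtPath <- file.path(dir, "ground_truth.tsv")
  if (file.exists(gtPath)) {
    gt <- data.table::fread(gtPath, sep = "\t", header = TRUE)
    ann$delta <- gt$delta[match(rownames(ann), gt$feature_id)]
    ann$sigma <- gt$sigma[match(rownames(ann), gt$feature_id)]
  }
  assembleExperiment(exprs, pheno, ann)
}

#' Read a GEO series-matrix text file (convenience)
#'
#' Minimal parser for the series-matrix format: sample sex is taken from a
#' `!Sample_characteristics_ch1` line containing `sex:` or `gender:` (values
#' starting with m/f, case-insensitive); the expression table sits between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`. Samples whose
#' sex cannot be parsed are dropped with a warning.
#'
#' @param path file path.
#' @return List with elements `exprs` (numeric matrix) and `pheno` (named
#'   M/F factor over the retained samples).
#' @export
readSeriesMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    dataError("'%s': series-matrix table delimiters missing or empty", path)
  tab <- data.table::fread(text = lines[(beg + 1L):(end - 1L)], sep = "\t",
                           header = TRUE)
  ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, with = FALSE])
  if (!is.numeric(mat)) dataError("'%s': non-numeric expression table", path)
  rownames(mat) <- ids
  samples <- colnames(mat)

  charLines <- lines[grepl("^!Sample_characteristics_ch1", lines)]
  sexLine <- charLines[grepl("sex:|gender:", charLines, ignore.case = TRUE)]
  if (!length(sexLine))
    dataError("'%s': no sex/gender characteristics line found", path)
  fields <- strsplit(sexLine[1L], "\t", fixed = TRUE)[[1L]][-1L]
  fields <- gsub("\"", "", fields)
  sex <- rep(NA_character_, length(fields))
  val <- toupper(trimws(sub(".*[:]", "", fields)))
  sex[startsWith(val, "M")] <- "M"
  sex[startsWith(val, "F")] <- "F"
  if (length(sex) != length(samples))
    dataError("'%s': %d characteristics fields for %d samples", path,
              length(sex), length(samples))
  keep <- !is.na(sex)
  if (any(!keep))
    warning(sprintf("%d sample(s) dropped: unparseable sex", sum(!keep)))
  list(exprs = mat[, keep, drop = FALSE],
       pheno = stats::setNames(factor(sex[keep], levels = c("M", "F")),
                               samples[keep]))
}
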