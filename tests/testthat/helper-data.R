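suppressPackageStartupMessages(library(SummarizedExperiment))

# Small planted dataset: 300 features (20 sex-linked, 40 graded autosomal),
# 12 + 10 samples.
tinySE <- function(seed = 42L, ...) {
  generateDataset(syntheticConfig(nFeatures = 300L, nClassA = 12L,
                                  nClassB = 10L, nSexLinked = 20L,
                                  nDEAutosomal = 40L, seed = seed, ...))
}

# Global-null dataset (no planted effects).
nullSE <- function(G = 2000L, nA = 15L, nB = 15L, seed = 7L) {
  generateDataset(syntheticConfig(nFeatures = G, nClassA = nA, nClassB = nB,
                                  nSexLinked = 0L, nDEAutosomal = 0L,
                                  seed = seed))
}

makePheno <- function(nA, nB, levels = c("M", "F")) {
  stats::setNames(factor(rep(levels, c(nA, nB)), levels = levels),
                  sprintf("S%03d", seq_len(nA + nB)))
}

# One perfectly separating feature (class gap 10 sigma) among pure noise.
separableSE <- function(nPer = 10L, G = 50L, seed = 1L) {
  ph <- makePheno(nPer, nPer)
  set.seed(seed)
  m <- matrix(rnorm(G * 2 * nPer), G, 2 * nPer,
              dimnames = list(sprintf("F%03d", seq_len(G)), names(ph)))
  m["F001", ph == "M"] <- m["F001", ph == "M"] + 10
  assembleExperiment(m, ph)
}

# Synthetic GEO-style series-matrix text (no real data).
writeSeriesFixture <- function(path, sexes = c("male", "female", "male"),
                               truncate = FALSE) {
  n <- length(sexes)
  acc <- sprintf("GSM%04d", seq_len(n))
  lines <- c(
    "!Series_title\t\"synthetic fixture\"",
    paste(c("!Sample_geo_accession", sprintf('"%s"', acc)), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1",
            rep('"tissue: muscle"', n)), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1",
            sprintf('"Sex: %s"', sexes)), collapse = "\t"),
    "!series_matrix_table_begin",
    paste(c("ID_REF", acc), collapse = "\t"),
    paste(c("P1", round(seq_len(n) + 0.5, 2)), collapse = "\t"),
    paste(c("P2", round(seq_len(n) * 2 + 0.25, 2)), collapse = "\t"))
  if (!truncate) lines <- c(lines, "!series_matrix_table_end")
  writeLines(lines, path)
  path
}
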