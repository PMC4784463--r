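# Readers and writers: PLINK ".raw"-style additive text, delimited
# matrix with an embedded phenotype column, VCF (through vcfR), and the
# JSON truth sidecar.  Marker order in the file defines the index
# distance used by LD windows and false-positive-cluster gaps.

#' Read genotypes into a dataset
#'
#' Supported formats: `"matrix"` (delimited samples x markers table with
#' a header; the phenotype is the column named by `phenotype`),
#' `"plink_raw"` (PLINK `--recode A` additive text: FID IID PAT MAT SEX
#' PHENOTYPE then one 0/1/2 column per SNP; 1/2-coded phenotypes are
#' remapped to 0/1), and `"vcf"` (diploid genotypes become ALT-allele
#' dosages; non-biallelic sites are skipped with a count; needs the
#' \pkg{vcfR} package, and `phenotype` must then be a file of one value
#' per sample).  Markers with more than `missing_threshold` missingness
#' are dropped with a message; remaining missing calls are imputed to the
#' marker mode.
#'
#' @param path Input file.
#' @param format `"matrix"`, `"plink_raw"`, or `"vcf"`.
#' @param phenotype Phenotype column name (matrix format) or a path to a
#'   one-column phenotype file (vcf format); ignored for plink_raw.
#' @param missing_threshold Maximum tolerated per-marker missingness.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("matrix", "plink_raw", "vcf"),
                           phenotype = NULL, missing_threshold = 0.05) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         matrix = read_matrix_dataset(path, phenotype, missing_threshold),
         plink_raw = read_plink_raw(path, missing_threshold),
         vcf = read_vcf_dataset(path, phenotype, missing_threshold))
}

read_matrix_dataset <- function(path, phenotype, missing_threshold) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (is.null(phenotype)) phenotype <- "phenotype"
  if (!phenotype %in% names(df))
    stop(sprintf("phenotype column \"%s\" not found in %s", phenotype, path))
  y <- df[[phenotype]]
  g <- as.matrix(df[, setdiff(names(df), phenotype), drop = FALSE])
  finish_dataset(g, y, missing_threshold)
}

read_plink_raw <- function(path, missing_threshold) {
  df <- read.table(path, header = TRUE, check.names = FALSE)
  meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                    names(df))
  if (!"PHENOTYPE" %in% meta)
    stop("plink_raw file lacks a PHENOTYPE column")
  y <- df$PHENOTYPE
  if (all(y %in% c(1, 2))) y <- y - 1  # plink 1/2 disease coding
  g <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  finish_dataset(g, y, missing_threshold)
}

read_vcf_dataset <- function(path, phenotype, missing_threshold) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi))
    message(sprintf("read_genotypes: skipped %d non-biallelic site(s)",
                    sum(multi)))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  dose <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
  })
  g <- t(dose)  # samples x markers
  if (is.null(phenotype))
    stop("vcf format needs a phenotype file (one value per sample)")
  y <- scan(phenotype, quiet = TRUE)
  if (length(y) != nrow(g))
    stop(sprintf("phenotype file has %d values for %d samples",
                 length(y), nrow(g)))
  finish_dataset(g, y, missing_threshold)
}

finish_dataset <- function(g, y, missing_threshold) {
  storage.mode(g) <- "integer"
  miss <- colMeans(is.na(g))
  if (any(miss > missing_threshold)) {
    message(sprintf(
      "read_genotypes: dropped %d marker(s) with > %.0f%% missingness",
      sum(miss > missing_threshold), 100 * missing_threshold))
    g <- g[, miss <= missing_threshold, drop = FALSE]
  }
  for (j in which(colSums(is.na(g)) > 0)) {
    tab <- tabulate(g[, j] + 1L, 3L)
    g[is.na(g[, j]), j] <- which.max(tab) - 1L
  }
  type <- if (all(y %in% 0:1)) "binary" else "quantitative"
  genotype_dataset(g, y, phenotype_type = type)
}

#' Write a dataset to disk
#'
#' `"plink_raw"` writes PLINK-style additive text (FID IID PAT MAT SEX
#' PHENOTYPE + one 0/1/2 column per SNP, phenotype kept as 0/1);
#' `"matrix"` writes a tab-delimited table whose first column is
#' `phenotype`.  A JSON sidecar with the truth indices, marker ids and
#' provenance is written next to the file unless `truth_path = NA`.
#'
#' @param data A [genotype_dataset()].
#' @param path Output file.
#' @param format `"plink_raw"` or `"matrix"`.
#' @param truth_path Sidecar path (default `paste0(path, ".truth.json")`;
#'   `NA` suppresses it).
#' @param provenance Optional list stored verbatim in the sidecar (e.g. a
#'   resolved configuration with its seed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, format = c("plink_raw", "matrix"),
                          truth_path = NULL, provenance = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  format <- match.arg(format)
  n <- nrow(data$genotypes)
  if (format == "plink_raw") {
    df <- data.frame(FID = seq_len(n), IID = seq_len(n),
                     PAT = 0L, MAT = 0L, SEX = 0L,
                     PHENOTYPE = data$phenotype, check.names = FALSE)
    df <- cbind(df, as.data.frame(data$genotypes, check.names = FALSE))
    write.table(df, path, quote = FALSE, row.names = FALSE, sep = " ")
  } else {
    df <- cbind(data.frame(phenotype = data$phenotype, check.names = FALSE),
                as.data.frame(data$genotypes, check.names = FALSE))
    write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  }
  if (is.null(truth_path)) truth_path <- paste0(path, ".truth.json")
  if (!is.na(truth_path)) {
    jsonlite::write_json(
      list(truth = data$truth,
           truth_ids = data$marker_ids[data$truth],
           marker_ids = data$marker_ids,
           phenotype_type = data$phenotype_type,
           provenance = provenance),
      truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a truth sidecar
#'
#' @param path Path to a `.truth.json` sidecar written by
#'   [write_dataset()].
#' @return List with at least `truth` (integer indices).
#' @export
read_truth <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  out$truth <- as.integer(out$truth)
  out
}

#' Export an MBRFS result as a tab-delimited report
#'
#' One row per selected marker: marker index, id, round, admission
#' p-value (worst-case first-order p at admission) and marginal p.
#'
#' @param result An `"mbrfs_result"`.
#' @param data The dataset it was computed on.
#' @param path Output TSV path, or NULL to just return the data frame.
#' @return The report data frame, invisibly when written.
#' @export
export_mbrfs_result <- function(result, data, path = NULL) {
  stopifnot(inherits(result, "mbrfs_result"))
  rows <- do.call(rbind, lapply(seq_along(result$rounds), function(i) {
    log <- result$rounds[[i]]$admission_log
    if (nrow(log) == 0) return(NULL)
    data.frame(marker = log$marker, id = data$marker_ids[log$marker],
               round = i, admission_p = log$worst_p,
               marginal_p = log$marginal_p)
  }))
  if (is.null(rows))
    rows <- data.frame(marker = integer(0), id = character(0),
                       round = integer(0), admission_p = numeric(0),
                       marginal_p = numeric(0))
  if (!is.null(path)) {
    write.table(rows, path, quote = FALSE, row.names = FALSE, sep = "\t")
    return(invisible(rows))
  }
  rows
}
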