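# Conditional-independence and marginal screening tests.
#
# The G-squared (likelihood-ratio chi-square) statistic is the workhorse
# for categorical data: G2 = 2 * sum O * ln(O/E), asymptotically
# chi-square with df = (Cat(A)-1)(Cat(B)-1) * prod Cat(C_i) when the test
# is stratified on conditioning variables C.  Zero observed cells
# contribute 0; rows/columns (and whole strata) with a zero margin are
# dropped and their df subtracted.  Quantitative markers or phenotypes
# use Wald tests from logistic/linear regression instead.

ci_test_result <- function(statistic, df, p_value, conditioning_set,
                           method, reliable = TRUE, note = NULL) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 conditioning_set = conditioning_set, method = method,
                 reliable = reliable, note = note),
            class = "ci_test_result")
}

#' @export
print.ci_test_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, df = %s, p = %.4g%s\n",
              x$method, x$statistic,
              if (is.na(x$df)) "NA" else format(x$df),
              x$p_value,
              if (x$reliable) "" else "  [unreliable]"))
  if (length(x$conditioning_set))
    cat("  conditioned on:", paste(x$conditioning_set, collapse = ", "), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' G-squared statistic of a two-way count table
#'
#' Computes the likelihood-ratio chi-square `2 * sum(O * log(O / E))`
#' with expected counts from the row/column margins.  Cells with `O = 0`
#' contribute zero; rows or columns whose margin is zero are dropped and
#' the degrees of freedom reduced accordingly.
#'
#' @param observed Matrix of non-negative counts, at least 2 x 2 before
#'   margin dropping.
#' @return List with elements `statistic` and `df`, or a no-test signal
#'   (`statistic = NA`, `df = 0`) when fewer than two non-empty rows or
#'   columns remain.
#' @examples
#' g2_from_table(matrix(c(10, 30, 20, 40), 2))
#' @export
g2_from_table <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0) || any(!is.finite(observed)))
    stop("observed must be a matrix of non-negative finite counts")
  if (nrow(observed) < 2 || ncol(observed) < 2)
    stop("observed must be at least 2 x 2")
  rs <- rowSums(observed); cs <- colSums(observed)
  keep_r <- rs > 0; keep_c <- cs > 0
  if (sum(keep_r) < 2 || sum(keep_c) < 2)
    return(list(statistic = NA_real_, df = 0L))
  o <- observed[keep_r, keep_c, drop = FALSE]
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  terms <- o * log(o / e)
  terms[o == 0] <- 0
  list(statistic = 2 * sum(terms),
       df = (nrow(o) - 1L) * (ncol(o) - 1L),
       expected = e)
}

# counts array for y x v within strata of the conditioning columns,
# computed with one pass of tabulate(); levels are the observed levels
# over the whole dataset so stratum tables keep a fixed shape
stratified_counts <- function(y, v, cond) {
  ly <- sort(unique(y)); lv <- sort(unique(v))
  iy <- match(y, ly); iv <- match(v, lv)
  if (is.null(cond) || ncol(cond) == 0) {
    counts <- tabulate(iy + length(ly) * (iv - 1L),
                       nbins = length(ly) * length(lv))
    return(list(counts = array(counts, c(length(ly), length(lv), 1L)),
                n_strata = 1L, cat_cond = integer(0),
                cat_y = length(ly), cat_v = length(lv)))
  }
  cat_cond <- integer(ncol(cond))
  istr <- rep(1L, length(y)); mult <- 1L
  for (j in seq_len(ncol(cond))) {
    lc <- sort(unique(cond[, j]))
    cat_cond[j] <- length(lc)
    istr <- istr + mult * (match(cond[, j], lc) - 1L)
    mult <- mult * length(lc)
  }
  n_strata <- mult
  cell <- iy + length(ly) * (iv - 1L) +
    length(ly) * length(lv) * (istr - 1L)
  counts <- tabulate(cell, nbins = length(ly) * length(lv) * n_strata)
  list(counts = array(counts, c(length(ly), length(lv), n_strata)),
       n_strata = n_strata, cat_cond = cat_cond,
       cat_y = length(ly), cat_v = length(lv))
}

#' Number of cells of a stratified contingency table
#'
#' The G-squared conditional-independence test of A versus B given
#' conditioning variables C stratifies on every category combination of
#' C, giving `Cat(A) * Cat(B) * prod(Cat(C_i))` cells.  This count is the
#' reason full-blanket conditioning collapses: with a binary phenotype, a
#' ternary candidate and 9 ternary blanket members it already reaches
#' 6 * 3^9 = 118098 cells, far beyond what any realistic sample can fill.
#'
#' @param cat_a,cat_b Category counts of the two tested variables.
#' @param cat_conditioning Vector of category counts of the conditioning
#'   variables (may be empty).
#' @return The total cell count as a double.
#' @examples
#' stratified_cell_count(2, 3, rep(3, 9))
#' @export
stratified_cell_count <- function(cat_a, cat_b, cat_conditioning = integer(0)) {
  as.numeric(cat_a) * as.numeric(cat_b) * prod(as.numeric(cat_conditioning))
}

#' Conditional G-squared test
#'
#' Tests independence of a marker and the phenotype within every stratum
#' of the conditioning markers: the statistic is the sum of per-stratum
#' G-squared values and the degrees of freedom the sum of per-stratum df
#' (which equals `(Cat(Y)-1)(Cat(V)-1) * prod(Cat(C_i))` when no stratum
#' or margin is dropped).  If more than 20% of the retained expected cell
#' counts fall below 1 the test is flagged unreliable and callers should
#' treat the pair as independent (the sparse-table regime in which the
#' likelihood-ratio approximation breaks down).
#'
#' @param data A [genotype_dataset()].
#' @param target_marker Index (or id) of the tested marker.
#' @param conditioning_set Indices of conditioning markers (may be empty,
#'   giving the marginal test).
#' @param cell_cap Refuse the test (with an error) when the stratified
#'   table would exceed this many cells.
#' @return A `ci_test_result`.
#' @export
conditional_g2 <- function(data, target_marker, conditioning_set = integer(0),
                           cell_cap = 1e6) {
  stopifnot(inherits(data, "genotype_dataset"))
  target_marker <- resolve_marker(data, target_marker)
  conditioning_set <- resolve_marker(data, conditioning_set)
  if (target_marker %in% conditioning_set)
    stop("conditioning_set must not contain the target marker")
  y <- data$phenotype
  v <- data$genotypes[, target_marker]
  cond <- if (length(conditioning_set))
    data$genotypes[, conditioning_set, drop = FALSE] else NULL
  sc <- stratified_counts(y, v, cond)
  projected <- stratified_cell_count(sc$cat_y, sc$cat_v, sc$cat_cond)
  if (projected > cell_cap)
    stop(sprintf(paste0("refusing stratified G2 test: %d conditioning ",
                        "variables give %.0f cells (cap %.0f)"),
                 length(conditioning_set), projected, cell_cap))
  stat <- 0; df <- 0L
  n_cells <- 0L; n_sparse <- 0L
  for (s in seq_len(sc$n_strata)) {
    tab <- sc$counts[, , s]
    if (sum(tab) == 0) next
    res <- g2_from_table_quiet(tab)
    if (res$df > 0) {
      stat <- stat + res$statistic
      df <- df + res$df
      n_cells <- n_cells + length(res$expected)
      n_sparse <- n_sparse + sum(res$expected < 1)
    }
  }
  if (df == 0L)
    return(ci_test_result(NA_real_, 0L, NA_real_, conditioning_set, "g2",
                          reliable = FALSE, note = "no testable stratum"))
  reliable <- n_sparse <= 0.2 * n_cells
  ci_test_result(stat, df, pchisq(stat, df, lower.tail = FALSE),
                 conditioning_set, "g2", reliable = reliable,
                 note = if (!reliable)
                   sprintf("%d of %d expected cells < 1", n_sparse, n_cells))
}

# as g2_from_table but tolerant of degenerate strata (returns df = 0)
g2_from_table_quiet <- function(observed) {
  rs <- rowSums(observed); cs <- colSums(observed)
  keep_r <- rs > 0; keep_c <- cs > 0
  if (sum(keep_r) < 2 || sum(keep_c) < 2)
    return(list(statistic = 0, df = 0L, expected = numeric(0)))
  o <- observed[keep_r, keep_c, drop = FALSE]
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  terms <- o * log(o / e)
  terms[o == 0] <- 0
  list(statistic = 2 * sum(terms),
       df = (nrow(o) - 1L) * (ncol(o) - 1L),
       expected = e)
}

resolve_marker <- function(data, marker) {
  if (length(marker) == 0) return(integer(0))
  if (is.character(marker)) {
    idx <- match(marker, data$marker_ids)
    if (anyNA(idx)) stop("unknown marker id: ",
                         paste(marker[is.na(idx)], collapse = ", "))
    return(idx)
  }
  marker <- as.integer(marker)
  if (any(marker < 1 | marker > ncol(data$genotypes)))
    stop("marker index out of range")
  marker
}

#' Regression-based conditional-independence test
#'
#' Fits `Y ~ target + conditioners` by logistic (binary Y) or ordinary
#' linear (quantitative Y) regression and returns the Wald test of the
#' target's coefficient: statistic is the squared Wald z, df = 1.
#' Non-convergence, perfect separation or a collinear conditioner yield a
#' no-test signal (`reliable = FALSE`) with a diagnostic note.
#'
#' @param data A [genotype_dataset()].
#' @param target_marker Index (or id) of the tested marker.
#' @param conditioning_set Indices entered as covariates (may be empty).
#' @param family `"logistic"` or `"linear"`; defaults to the phenotype
#'   type.
#' @return A `ci_test_result`.
#' @export
regression_ci_test <- function(data, target_marker,
                               conditioning_set = integer(0),
                               family = c("auto", "logistic", "linear")) {
  stopifnot(inherits(data, "genotype_dataset"))
  family <- match.arg(family)
  if (family == "auto")
    family <- if (data$phenotype_type == "binary") "logistic" else "linear"
  if (family == "logistic" && !all(data$phenotype %in% 0:1))
    stop("logistic family requires a binary 0/1 phenotype")
  target_marker <- resolve_marker(data, target_marker)
  conditioning_set <- resolve_marker(data, conditioning_set)
  if (target_marker %in% conditioning_set)
    stop("conditioning_set must not contain the target marker")
  x <- cbind(target = data$genotypes[, target_marker],
             data$genotypes[, conditioning_set, drop = FALSE])
  df_fit <- data.frame(y = data$phenotype, x)
  fit <- tryCatch({
    if (family == "logistic")
      glm(y ~ ., data = df_fit, family = binomial())
    else
      lm(y ~ ., data = df_fit)
  }, error = function(e) e)
  bad <- function(note) ci_test_result(NA_real_, 1L, NA_real_,
                                       conditioning_set, family,
                                       reliable = FALSE, note = note)
  if (inherits(fit, "error")) return(bad(conditionMessage(fit)))
  if (anyNA(coef(fit)))
    return(bad("collinear covariates: coefficients aliased"))
  sm <- summary(fit)$coefficients
  if (!"target" %in% rownames(sm) || is.na(sm["target", 2]))
    return(bad("target coefficient not estimable (collinear conditioner)"))
  if (family == "logistic" && !fit$converged)
    return(bad("glm did not converge (possible separation)"))
  se <- sm["target", 2]
  if (family == "logistic" && se > 50)
    return(bad("inflated standard error (possible separation)"))
  z <- sm["target", 1] / se
  p <- 2 * pnorm(-abs(z))
  ci_test_result(z^2, 1L, p, conditioning_set, family)
}

# vectorised Cochran-Armitage trend chi-square over genotype count
# matrices (3 columns: dosage 0/1/2); the single code path behind both
# armitage_trend_test() and the marginal screen / baseline corrections
trend_stat_from_counts <- function(case_counts, control_counts,
                                   scores = c(0, 1, 2)) {
  r <- as.matrix(case_counts); n0 <- as.matrix(control_counts)
  tot <- r + n0
  N <- rowSums(tot); R <- rowSums(r)
  sr <- as.numeric(r %*% scores)
  sn <- as.numeric(tot %*% scores)
  s2n <- as.numeric(tot %*% scores^2)
  num <- N * (N * sr - R * sn)^2
  den <- R * (N - R) * (N * s2n - sn^2)
  stat <- unname(ifelse(den > 0, num / den, NA_real_))
  list(statistic = stat,
       p_value = pchisq(stat, 1L, lower.tail = FALSE))
}

#' Cochran-Armitage trend test
#'
#' The 1-df chi-square test for a linear trend in case proportion across
#' genotype dosages 0/1/2 (scores 0, 1, 2), the standard single-marker
#' association test for case-control SNP data.
#'
#' @param case_counts,control_counts Length-3 count vectors over
#'   genotypes 0/1/2.
#' @return A `ci_test_result` with `method = "trend"`.
#' @examples
#' armitage_trend_test(c(10, 20, 30), c(30, 20, 10))
#' @export
armitage_trend_test <- function(case_counts, control_counts) {
  if (length(case_counts) != 3 || length(control_counts) != 3)
    stop("counts must be length-3 vectors over genotypes 0/1/2")
  if (sum(case_counts) + sum(control_counts) == 0)
    stop("zero total count")
  res <- trend_stat_from_counts(rbind(case_counts), rbind(control_counts))
  if (is.na(res$statistic))
    return(ci_test_result(NA_real_, 1L, NA_real_, integer(0), "trend",
                          reliable = FALSE, note = "no genotype variation"))
  ci_test_result(res$statistic, 1L, res$p_value, integer(0), "trend")
}

# trend-test p-values for every marker of a binary-phenotype dataset
trend_pvalues <- function(data) {
  g <- data$genotypes
  y <- data$phenotype
  counts <- function(rows) {
    m <- matrix(0, ncol(g), 3)
    for (k in 0:2) m[, k + 1] <- colSums(g[rows, , drop = FALSE] == k,
                                         na.rm = TRUE)
    m
  }
  res <- trend_stat_from_counts(counts(y == 1), counts(y == 0))
  setNames(res$p_value, data$marker_ids)
}

#' Genotypic chi-square p-values (2 x 3 association test)
#'
#' @param data A binary-phenotype [genotype_dataset()].
#' @return Named vector of p-values (NA for degenerate markers).
#' @export
genotypic_chisq_pvalues <- function(data) {
  g <- data$genotypes; y <- data$phenotype
  vapply(seq_len(ncol(g)), function(j) {
    tab <- table(factor(y, 0:1), factor(g[, j], 0:2))
    res <- g2_from_table_quiet(tab)
    if (res$df == 0) NA_real_ else
      pchisq(res$statistic, res$df, lower.tail = FALSE)
  }, numeric(1)) |> setNames(data$marker_ids)
}

#' Marginal screening of all markers
#'
#' Single-marker association tests at nominal level `alpha`: the
#' Cochran-Armitage trend test for SNP dosages against a binary
#' phenotype (or the genotypic chi-square if `test = "chisq"`), and the
#' regression Wald test otherwise.  Establishes the candidate variable
#' pool that the blanket search fishes from; constant markers are skipped
#' with a message.
#'
#' @param data A [genotype_dataset()].
#' @param alpha Nominal significance level in (0, 1).
#' @param test `"trend"` (default) or `"chisq"` for binary phenotypes.
#' @param p_values Optional precomputed marker p-values (recycled across
#'   methods in benchmarking so all selection rules see identical
#'   evidence).
#' @return Data frame with columns `marker` (index), `id`, `p`, ordered
#'   by ascending p-value; all markers with unadjusted p < alpha.
#' @export
marginal_screen <- function(data, alpha = 0.05,
                            test = c("trend", "chisq"), p_values = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  test <- match.arg(test)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.null(p_values)) p_values <- marginal_pvalues(data, test)
  dropped <- sum(is.na(p_values))
  if (dropped > 0)
    message(sprintf("marginal_screen: skipped %d constant marker(s)", dropped))
  keep <- which(!is.na(p_values) & p_values < alpha)
  out <- data.frame(marker = keep,
                    id = data$marker_ids[keep],
                    p = p_values[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$marker), , drop = FALSE]
}

marginal_pvalues <- function(data, test = "trend") {
  if (data$phenotype_type == "binary" && all(data$genotypes %in% c(0:2, NA))) {
    if (test == "trend") trend_pvalues(data) else
      genotypic_chisq_pvalues(data)
  } else {
    vapply(seq_len(ncol(data$genotypes)), function(j) {
      if (length(unique(data$genotypes[, j])) < 2) return(NA_real_)
      regression_ci_test(data, j)$p_value
    }, numeric(1)) |> setNames(data$marker_ids)
  }
}
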