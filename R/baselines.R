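# Comparison methods: trend test with Bonferroni or Benjamini-Hochberg
# correction, and L1-penalised logistic regression.

selection_result <- function(selected, method, evidence = NULL) {
  structure(list(selected = as.integer(selected), method = method,
                 evidence = evidence),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("%s: %d marker(s) selected\n", x$method, length(x$selected)))
  invisible(x)
}

#' Bonferroni selection
#'
#' Selects every marker with unadjusted p-value below `alpha / m`.
#'
#' @param p_values Vector of per-marker p-values (NAs never selected).
#' @param alpha Family-wise error level.
#' @return A `selection_result`.
#' @export
bonferroni_select <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  if (m < 1) stop("need at least one p-value")
  selection_result(which(!is.na(p_values) & p_values < alpha / m),
                   "bonferroni", evidence = p_values)
}

#' Benjamini-Hochberg selection
#'
#' The standard step-up false-discovery-rate procedure at level `q`,
#' applied through [stats::p.adjust()].
#'
#' @param p_values Vector of per-marker p-values.
#' @param q FDR level in (0, 1).
#' @return A `selection_result`.
#' @export
bh_select <- function(p_values, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  adj <- p.adjust(p_values, method = "BH")
  selection_result(which(!is.na(adj) & adj <= q), "bh", evidence = p_values)
}

#' LASSO selection
#'
#' L1-penalised logistic regression over the full marker set via
#' \pkg{glmnet}; selected markers are those with a nonzero coefficient at
#' the chosen lambda (10-fold cross-validated deviance with the
#' one-standard-error rule by default).
#'
#' @param data A binary-phenotype [genotype_dataset()].
#' @param lambda_rule `"cv_1se"` (default), `"cv_min"`, or `"fixed"`.
#' @param lambda Penalty value when `lambda_rule = "fixed"`.
#' @param nfolds Cross-validation folds.
#' @param rng_seed Optional seed for the fold assignment.
#' @return A `selection_result` with the nonzero coefficients as
#'   evidence.
#' @export
lasso_select <- function(data, lambda_rule = c("cv_1se", "cv_min", "fixed"),
                         lambda = NULL, nfolds = 10, rng_seed = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  lambda_rule <- match.arg(lambda_rule)
  if (data$phenotype_type != "binary")
    stop("lasso_select expects a binary phenotype")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  x <- data$genotypes
  storage.mode(x) <- "double"
  y <- data$phenotype
  if (lambda_rule == "fixed") {
    if (is.null(lambda)) stop("lambda_rule = \"fixed\" needs a lambda")
    fit <- glmnet::glmnet(x, y, family = "binomial", standardize = TRUE)
    cf <- coef(fit, s = lambda)
  } else {
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", standardize = TRUE,
                            nfolds = nfolds)
    s <- if (lambda_rule == "cv_1se") cv$lambda.1se else cv$lambda.min
    cf <- coef(cv, s = s)
  }
  beta <- as.numeric(cf)[-1]  # drop intercept
  selection_result(which(beta != 0), "lasso",
                   evidence = setNames(beta, data$marker_ids))
}
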