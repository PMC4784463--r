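# One fishing round: forward admission under first-order conditioning,
# backward pruning of false positives, and LD pruning of the candidate
# pool around each admitted marker.
#
# The full-blanket conditional test of the original forward phase is
# relaxed to its first-order version: a candidate V is admitted only if
# it is dependent on Y given EACH single blanket member (and marginally,
# when the blanket is empty).  The summary score is the worst-case
# (maximum) p-value over those tests; among dependent candidates the one
# with the smallest worst-case p is admitted, with ties broken by the
# smaller marginal p and then the lower marker index, so the search is
# fully deterministic.

#' Search parameters for the blanket algorithms
#'
#' @param alpha Admission/removal significance level for the
#'   conditional-independence tests (default 0.05).
#' @param r2_threshold Genotype r-squared above which a pool marker near
#'   an admitted marker is LD-pruned (default 0.05).
#' @param ld_window Half-width, in marker index units, of the LD-pruning
#'   window around an admitted marker (default 20; 0 disables pruning).
#' @param ci_backend `"g2"` for stratified likelihood-ratio tests on
#'   categorical data, `"logistic"`/`"linear"` for regression Wald tests.
#' @param cell_cap Maximum stratified-table cell count tolerated by the
#'   G-squared backend (relevant only for full conditioning).
#' @return An object of class `"search_params"`.
#' @export
search_params <- function(alpha = 0.05, r2_threshold = 0.05, ld_window = 20,
                          ci_backend = c("g2", "logistic", "linear"),
                          cell_cap = 1e6) {
  ci_backend <- match.arg(ci_backend)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (r2_threshold < 0 || r2_threshold > 1)
    stop("r2_threshold must lie in [0, 1]")
  if (ld_window < 0) stop("ld_window must be >= 0")
  structure(list(alpha = alpha, r2_threshold = r2_threshold,
                 ld_window = as.integer(ld_window), ci_backend = ci_backend,
                 cell_cap = cell_cap),
            class = "search_params")
}

new_blanket <- function() {
  structure(list(members = integer(0),
                 admission_log = data.frame(marker = integer(0),
                                            worst_p = numeric(0),
                                            marginal_p = numeric(0)),
                 removed_by_ld = list()),
            class = "blanket")
}

#' @export
print.blanket <- function(x, ...) {
  cat(sprintf("blanket with %d member(s)\n", length(x$members)))
  if (nrow(x$admission_log)) print(x$admission_log)
  invisible(x)
}

run_ci_test <- function(data, target, conditioning, params) {
  if (params$ci_backend == "g2")
    conditional_g2(data, target, conditioning, cell_cap = params$cell_cap)
  else
    regression_ci_test(data, target, conditioning,
                       family = params$ci_backend)
}

# p-value actually used for decisions: an unreliable test is treated,
# conservatively, as evidence of independence
effective_p <- function(res) {
  if (!isTRUE(res$reliable) || is.na(res$p_value)) 1 else res$p_value
}

ci_cache_key <- function(target, conditioning)
  paste0(target, "|", paste(sort(conditioning), collapse = ","))

cached_ci_p <- function(data, target, conditioning, params, cache) {
  if (is.null(cache))
    return(effective_p(run_ci_test(data, target, conditioning, params)))
  key <- ci_cache_key(target, conditioning)
  p <- cache[[key]]
  if (is.null(p)) {
    p <- effective_p(run_ci_test(data, target, conditioning, params))
    cache[[key]] <- p
  }
  p
}

#' First-order dependence check of a candidate against a blanket
#'
#' Runs one conditional-independence test of the candidate against the
#' phenotype per single blanket member (the marginal test when the
#' blanket is empty) and summarises them by the worst-case (maximum)
#' p-value.  The candidate is declared dependent when every test rejects
#' at `params$alpha`, i.e. when `worst_p < alpha`; unreliable tests count
#' as non-rejections.
#'
#' @param data A [genotype_dataset()].
#' @param candidate Marker index, not among `members`.
#' @param members Current blanket member indices.
#' @param params A [search_params()].
#' @param cache Optional environment memoising (candidate, conditioner)
#'   test p-values across the search.
#' @return List with `is_dependent` and `worst_p`.
#' @export
first_order_dependent <- function(data, candidate, members, params,
                                  cache = NULL) {
  if (candidate %in% members) stop("candidate is already a blanket member")
  conds <- if (length(members) == 0) list(integer(0)) else
    lapply(members, identity)
  worst <- 0
  for (cond in conds) {
    p <- cached_ci_p(data, candidate, cond, params, cache)
    if (p > worst) worst <- p
    if (worst >= params$alpha) break  # cannot be admitted; stop early
  }
  list(is_dependent = worst < params$alpha, worst_p = worst)
}

#' One forward admission step
#'
#' Evaluates every pool candidate with [first_order_dependent()] and
#' admits the dependent candidate with the smallest worst-case p-value
#' (ties: smaller marginal p, then lower marker index).
#'
#' @param data A [genotype_dataset()].
#' @param pool Data frame with columns `marker` and `p` (marginal
#'   p-values), as produced by [marginal_screen()].
#' @param blanket A blanket object.
#' @param params A [search_params()].
#' @param cache Optional memoisation environment.
#' @return The admitted marker index, or `NULL` when no candidate is
#'   dependent (or the pool is empty).
#' @export
forward_step <- function(data, pool, blanket, params, cache = NULL) {
  if (nrow(pool) == 0) return(NULL)
  if (any(pool$marker %in% blanket$members))
    stop("pool must be disjoint from the blanket")
  worst <- rep(NA_real_, nrow(pool))
  for (i in seq_len(nrow(pool))) {
    res <- first_order_dependent(data, pool$marker[i], blanket$members,
                                 params, cache)
    if (res$is_dependent) worst[i] <- res$worst_p
  }
  if (all(is.na(worst))) return(NULL)
  ord <- order(worst, pool$p, pool$marker, na.last = TRUE)
  pool$marker[ord[1]]
}

#' Backward pruning of a blanket
#'
#' Repeatedly removes, most-recently-admitted first, any member whose
#' worst-case first-order p-value against the other members (marginal
#' when it is the only member) is at or above `params$alpha`, until the
#' blanket is stable.  Idempotent by construction.
#'
#' @inheritParams forward_step
#' @return The pruned blanket.
#' @export
backward_prune <- function(data, blanket, params, cache = NULL) {
  repeat {
    removed <- FALSE
    for (m in rev(blanket$members)) {
      others <- setdiff(blanket$members, m)
      res <- first_order_dependent(data, m, others, params, cache)
      if (!res$is_dependent) {
        blanket$members <- setdiff(blanket$members, m)
        blanket$admission_log <-
          blanket$admission_log[blanket$admission_log$marker != m, ,
                                drop = FALSE]
        removed <- TRUE
        break
      }
    }
    if (!removed) return(blanket)
  }
}

#' LD-prune the candidate pool around an admitted marker
#'
#' Removes from the pool every marker lying within `ld_window` index
#' positions of the admitted marker AND having genotype r-squared above
#' `r2_threshold` with it; both conditions are required.  Mirrors the
#' practice of collapsing an LD block once one of its SNPs has been
#' captured.
#'
#' @param pool Candidate pool data frame (columns `marker`, `p`).
#' @param admitted Index of the just-admitted marker.
#' @param genotypes Sample x marker dosage matrix.
#' @param params A [search_params()].
#' @return List with the reduced `pool` and the `removed` marker indices.
#' @export
ld_prune <- function(pool, admitted, genotypes, params) {
  if (admitted %in% pool$marker) stop("admitted marker must not be in pool")
  if (params$ld_window == 0 || nrow(pool) == 0)
    return(list(pool = pool, removed = integer(0)))
  near <- abs(pool$marker - admitted) <= params$ld_window
  if (!any(near)) return(list(pool = pool, removed = integer(0)))
  ga <- genotypes[, admitted]
  r2 <- rep(0, nrow(pool))
  r2[near] <- suppressWarnings(
    cor(ga, genotypes[, pool$marker[near], drop = FALSE]))^2
  r2[is.na(r2)] <- 0
  drop <- near & r2 > params$r2_threshold
  list(pool = pool[!drop, , drop = FALSE],
       removed = pool$marker[drop])
}

#' Run one fishing round
#'
#' Alternates forward admission, LD pruning of the pool, and backward
#' pruning of the blanket until no further candidate is dependent.
#' Markers admitted and later removed by the backward phase are judged
#' false positives and do not return to the pool.
#'
#' @inheritParams forward_step
#' @return List with the `blanket` and the surviving `pool` (input pool
#'   minus members, LD casualties and backward-pruned markers).
#' @export
run_mb_round <- function(data, pool, params, cache = NULL) {
  blanket <- new_blanket()
  repeat {
    admitted <- forward_step(data, pool, blanket, params, cache)
    if (is.null(admitted)) break
    row <- pool[pool$marker == admitted, , drop = FALSE]
    res <- first_order_dependent(data, admitted, blanket$members, params,
                                 cache)
    blanket$members <- c(blanket$members, admitted)
    blanket$admission_log <- rbind(
      blanket$admission_log,
      data.frame(marker = admitted, worst_p = res$worst_p,
                 marginal_p = row$p))
    pool <- pool[pool$marker != admitted, , drop = FALSE]
    pruned <- ld_prune(pool, admitted, data$genotypes, params)
    pool <- pruned$pool
    blanket$removed_by_ld[[as.character(admitted)]] <- pruned$removed
    blanket <- backward_prune(data, blanket, params, cache)
  }
  list(blanket = blanket, pool = pool)
}
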