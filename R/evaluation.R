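# Scoring a selection against simulation truth: TDR, FDR, MCC, flat and
# cluster-based, plus per-marker discovery rates across replicates.

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; any zero
#' factor in the denominator gives 0 by convention.
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @return A value in \[-1, 1\].
#' @examples
#' mcc(6, 1, 2, 1091)
#' @export
mcc <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be non-negative")
  num <- as.numeric(tp) * tn - as.numeric(fp) * fn
  fac <- as.numeric(c(tp + fp, tp + fn, tn + fp, tn + fn))
  if (any(fac == 0)) return(0)
  num / sqrt(prod(fac))
}

#' SNP-level (flat) evaluation of a selection
#'
#' Counts exact hits: `TP = |selected n truth|`, `TDR = TP / |truth|`,
#' `FDR = FP / (TP + FP)` with the 0/0 convention giving 0.
#'
#' @param selected Integer indices of selected markers.
#' @param truth Integer indices of the causal markers.
#' @param n_markers Total number of markers.
#' @return List with `tp`, `fp`, `fn`, `tn`, `tdr`, `fdr`, `mcc`, and
#'   `hit` (logical per truth marker, in truth order).
#' @export
evaluate_flat <- function(selected, truth, n_markers) {
  selected <- unique(as.integer(selected))
  truth <- as.integer(truth)
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  fn <- length(truth) - tp
  tn <- n_markers - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       tdr = if (length(truth)) tp / length(truth) else NA_real_,
       fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       mcc = mcc(tp, fp, fn, tn),
       hit = truth %in% selected)
}

#' Cluster-based evaluation for markers embedded in LD blocks
#'
#' A captured marker within `window` index positions of a true causal
#' marker and with genotype r-squared above `r2_threshold` with it counts
#' toward that causal marker; all captured markers qualifying for the
#' same causal marker form a single true-positive cluster (TPC).  The
#' remaining captured markers are false positives; runs of them no more
#' than `fp_gap` indices apart merge into one false-positive cluster
#' (FPC).  TDR, FDR and MCC are computed on clusters, with
#' `TN = n_markers - (markers participating in any cluster)` as an
#' index-unit approximation.
#'
#' @param selected Indices of captured markers.
#' @param truth Indices of the causal markers.
#' @param genotypes Dosage matrix used for the r-squared checks.
#' @param window Index window around a causal marker (default 20).
#' @param r2_threshold Minimum r-squared with the causal marker
#'   (default 0.05).
#' @param fp_gap Maximum index gap merging false positives (default 10).
#' @return List with `tpc`, `fpc`, `fn`, `tn`, `tdr`, `fdr`, `mcc`,
#'   `hit` (per truth marker).
#' @export
evaluate_clustered <- function(selected, truth, genotypes, window = 20,
                               r2_threshold = 0.05, fp_gap = 10) {
  selected <- sort(unique(as.integer(selected)))
  truth <- as.integer(truth)
  n_markers <- ncol(genotypes)
  claimed <- logical(length(selected))
  hit <- logical(length(truth))
  for (i in seq_along(truth)) {
    t <- truth[i]
    near <- abs(selected - t) <= window
    if (!any(near)) next
    qual <- near
    for (k in which(near)) {
      s <- selected[k]
      qual[k] <- s == t ||
        isTRUE(suppressWarnings(cor(genotypes[, s], genotypes[, t]))^2 >
                 r2_threshold)
    }
    if (any(qual)) {
      hit[i] <- TRUE
      claimed <- claimed | qual
    }
  }
  tpc <- sum(hit)
  fps <- selected[!claimed]
  fpc <- if (length(fps) == 0) 0L else {
    if (fp_gap > 0) sum(diff(fps) > fp_gap) + 1L else length(fps)
  }
  fn <- length(truth) - tpc
  involved <- sum(claimed) + length(fps)
  tn <- max(0L, n_markers - involved - fn)
  list(tpc = tpc, fpc = fpc, fn = fn, tn = tn,
       tdr = if (length(truth)) tpc / length(truth) else NA_real_,
       fdr = if (tpc + fpc > 0) fpc / (tpc + fpc) else 0,
       mcc = mcc(tpc, fpc, fn, tn),
       hit = hit)
}

#' Per-marker discovery rate across replicates
#'
#' `100 * (number of replicates in which the marker was selected) /
#' n_reps`, for every marker.
#'
#' @param per_replicate_selections List of integer selection vectors, one
#'   per replicate.
#' @param n_markers Total number of markers.
#' @param n_reps Number of replicates (defaults to the list length).
#' @return Numeric vector of percentages, length `n_markers`.
#' @export
discovery_rate <- function(per_replicate_selections, n_markers,
                           n_reps = length(per_replicate_selections)) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  counts <- tabulate(unlist(lapply(per_replicate_selections,
                                   function(s) unique(as.integer(s)))),
                     nbins = n_markers)
  100 * counts / n_reps
}
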