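# Scoring predictions against simulator truth: segment accuracy under the
# 75%-coverage + exact copy-number rule, rank-matched cellularity metrics,
# purity error, and cluster-assignment concordance.

# overlap length of [s1,e1] and [s2,e2] (1-based inclusive)
.overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

#' Segment identification accuracy
#'
#' A truth segment counts as accurately identified iff some single predicted
#' segment overlaps at least `min_coverage` of its length AND matches its
#' total and major copy numbers exactly. Accuracy is the identified fraction
#' of all truth segments.
#'
#' @param truth_segments Data frame `chrom start end total_cn major_cn`.
#' @param predicted_segments Data frame with the same columns.
#' @param min_coverage Required overlap fraction (default 0.75).
#' @param include_neutral Count copy-neutral (2,1) truth segments in the
#'   denominator (default TRUE).
#' @return Accuracy fraction in \[0, 1\].
#' @export
segment_accuracy <- function(truth_segments, predicted_segments,
                             min_coverage = 0.75, include_neutral = TRUE) {
  if (is.null(truth_segments) || nrow(truth_segments) == 0) {
    stop("empty truth segment set")
  }
  tr <- truth_segments
  if (!include_neutral) {
    tr <- tr[!(tr$total_cn == 2 & tr$major_cn == 1), , drop = FALSE]
    if (nrow(tr) == 0) stop("no non-neutral truth segments")
  }
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    ps <- predicted_segments[
      predicted_segments$chrom == tr$chrom[i] &
        predicted_segments$total_cn == tr$total_cn[i] &
        predicted_segments$major_cn == tr$major_cn[i], , drop = FALSE]
    if (nrow(ps) == 0) return(FALSE)
    ov <- .overlap_len(ps$start, ps$end, tr$start[i], tr$end[i])
    any(ov >= min_coverage * (tr$end[i] - tr$start[i] + 1))
  }, logical(1))
  mean(hit)
}

# rank-match two ascending cellularity vectors: largest to largest, down to
# the shorter length
.rank_match <- function(truth, estimate) {
  truth <- sort(truth)
  estimate <- sort(estimate)
  m <- min(length(truth), length(estimate))
  if (m == 0) return(NULL)
  data.frame(truth = utils::tail(truth, m),
             estimate = utils::tail(estimate, m),
             flagged = length(truth) != length(estimate))
}

#' Pooled cellularity metrics
#'
#' Rank-matches each sample's estimated cluster cellularities to the truth
#' (largest down, to the shorter count; mismatching counts are flagged),
#' pools the pairs over samples, and returns the Pearson correlation and the
#' mean absolute error.
#'
#' @param truth_clusters List (one element per sample) of ascending truth
#'   cellularities, or a single numeric vector.
#' @param estimated_clusters Matching list (or vector) of estimates.
#' @return List with `pearson_r` (NA when fewer than 2 pooled pairs or zero
#'   variance), `mae`, `pairs` (the pooled matched pairs), `n_flagged`.
#' @export
cellularity_metrics <- function(truth_clusters, estimated_clusters) {
  if (!is.list(truth_clusters)) truth_clusters <- list(truth_clusters)
  if (!is.list(estimated_clusters)) {
    estimated_clusters <- list(estimated_clusters)
  }
  stopifnot(length(truth_clusters) == length(estimated_clusters))
  pairs <- do.call(rbind, Map(.rank_match, truth_clusters,
                              estimated_clusters))
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(list(pearson_r = NA_real_, mae = NA_real_, pairs = NULL,
                n_flagged = 0L))
  }
  r <- if (nrow(pairs) >= 2 && stats::sd(pairs$truth) > 0 &&
           stats::sd(pairs$estimate) > 0) {
    stats::cor(pairs$truth, pairs$estimate)
  } else NA_real_
  list(pearson_r = r,
       mae = mean(abs(pairs$truth - pairs$estimate)),
       pairs = pairs,
       n_flagged = sum(pairs$flagged))
}

#' Absolute tumor-purity error
#'
#' @param truth_purity True purity in (0, 1].
#' @param estimated_purity Estimated top-cluster cellularity `beta_K`.
#' @return `|estimate - truth|`; vectorized.
#' @export
purity_error <- function(truth_purity, estimated_purity) {
  abs(estimated_purity - truth_purity)
}

#' Cluster-assignment concordance
#'
#' Fraction of aberrant truth segments whose best-overlap predicted segment
#' carries the rank-matched cluster label. Truth and estimated clusters are
#' matched by rank (largest cellularity to largest).
#'
#' @param truth_segments Truth segments with a `cellularity` column (NA on
#'   neutral segments, which are excluded).
#' @param predicted_segments Predicted segments with `cluster` and
#'   `cellularity` columns.
#' @param truth_clusters Ascending truth cluster cellularities.
#' @param estimated_clusters Ascending estimated cluster cellularities.
#' @return Concordant fraction in \[0, 1\] (NA if no aberrant truth
#'   segments).
#' @export
cluster_concordance <- function(truth_segments, predicted_segments,
                                truth_clusters, estimated_clusters) {
  tr <- truth_segments[!is.na(truth_segments$cellularity), , drop = FALSE]
  if (nrow(tr) == 0) return(NA_real_)
  match_tab <- .rank_match(truth_clusters, estimated_clusters)
  if (is.null(match_tab)) return(NA_real_)
  ok <- vapply(seq_len(nrow(tr)), function(i) {
    ps <- predicted_segments[predicted_segments$chrom == tr$chrom[i], ,
                             drop = FALSE]
    if (nrow(ps) == 0) return(FALSE)
    ov <- .overlap_len(ps$start, ps$end, tr$start[i], tr$end[i])
    best <- ps[which.max(ov), ]
    # expected estimate cellularity for this truth segment's cluster
    j <- which(abs(match_tab$truth - tr$cellularity[i]) < 1e-9)
    if (!length(j)) return(FALSE)
    isTRUE(abs(best$cellularity - match_tab$estimate[j[1]]) < 1e-9)
  }, logical(1))
  mean(ok)
}

#' Evaluate one sample's predictions against truth
#'
#' @param truth List with `truth_segments`, `truth_clusters`, `purity` (as
#'   produced by [simulate_sample()]).
#' @param result Pipeline result ([call_subclones()] output).
#' @return One-row data frame of metrics.
#' @export
evaluate_sample <- function(truth, result) {
  acc <- segment_accuracy(truth$truth_segments, result$segments)
  cm <- cellularity_metrics(list(truth$truth_clusters),
                            list(result$clusters$cellularity))
  conc <- cluster_concordance(truth$truth_segments, result$segments,
                              truth$truth_clusters,
                              result$clusters$cellularity)
  data.frame(
    K_true = length(truth$truth_clusters),
    K_est = nrow(result$clusters),
    accuracy = acc,
    cellularity_mae = cm$mae,
    purity_truth = truth$purity,
    purity_est = max(result$clusters$cellularity),
    purity_error = purity_error(truth$purity,
                                max(result$clusters$cellularity)),
    cluster_concordance = conc
  )
}
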