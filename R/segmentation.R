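# Max-posterior decoding of the joint chain, merging into segments, and
# per-segment reliability scores.

#' Decode per-SNP joint states
#'
#' Assigns each SNP the joint state `(c, k)` with the maximum posterior
#' probability; exact ties break toward the lower state index, then the
#' lower cluster index.
#'
#' @param posterior Output of [forward_backward()].
#' @return Data frame with 1-based columns `c` (state row) and `k`
#'   (cluster), plus `posterior` (the winning probability).
#' @export
decode <- function(posterior) {
  C <- posterior$C
  K <- posterior$K
  # reorder columns to (c, k)-lexicographic so "first" implements the tie rule
  perm <- as.vector(t(matrix(seq_len(C * K), C, K)))
  g <- posterior$gamma[, perm, drop = FALSE]
  j <- max.col(g, ties.method = "first")
  data.frame(
    c = (j - 1L) %/% K + 1L,
    k = (j - 1L) %% K + 1L,
    posterior = g[cbind(seq_len(nrow(g)), j)]
  )
}

#' Merge per-SNP assignments into segments
#'
#' Maximal runs of identical `(c, k)` within a chromosome become segments.
#' Runs shorter than `min_snps` are absorbed into the flanking segment with
#' the higher mean posterior over the run's SNPs (the longer flank when no
#' posterior is supplied).
#'
#' @param assignments Output of [decode()].
#' @param records The SNP records the assignments refer to.
#' @param min_snps Minimum run length kept as its own segment (default 10).
#' @param posterior Optional [forward_backward()] output used for the
#'   absorption rule.
#' @return Data frame with `chrom, start, end, n_snps, c, k, i_start, i_end`
#'   (record-index range).
#' @export
merge_segments <- function(assignments, records, min_snps = 10L,
                           posterior = NULL) {
  n <- nrow(records)
  stopifnot(nrow(assignments) == n)
  key <- paste(records$chrom, assignments$c, assignments$k)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(i_start = starts, i_end = ends,
                     len = r$lengths,
                     c = assignments$c[starts], k = assignments$k[starts],
                     chrom = records$chrom[starts],
                     stringsAsFactors = FALSE)

  mean_post <- function(i0, i1, cc, kk) {
    if (is.null(posterior)) return(NA_real_)
    j <- (kk - 1L) * posterior$C + cc
    mean(posterior$gamma[i0:i1, j])
  }
  repeat {
    short <- which(runs$len < min_snps)
    if (!length(short)) break
    # absorb the shortest run first
    i <- short[which.min(runs$len[short])]
    left <- if (i > 1 && runs$chrom[i - 1] == runs$chrom[i]) i - 1L else NA
    right <- if (i < nrow(runs) && runs$chrom[i + 1] == runs$chrom[i])
      i + 1L else NA
    if (is.na(left) && is.na(right)) {
      runs$len[i] <- min_snps  # lone short chromosome: keep as-is
      next
    }
    target <- if (is.na(left)) right else if (is.na(right)) left else {
      pl <- mean_post(runs$i_start[i], runs$i_end[i], runs$c[left],
                      runs$k[left])
      pr <- mean_post(runs$i_start[i], runs$i_end[i], runs$c[right],
                      runs$k[right])
      if (is.na(pl)) {
        if (runs$len[left] >= runs$len[right]) left else right
      } else if (pl >= pr) left else right
    }
    runs$i_start[target] <- min(runs$i_start[target], runs$i_start[i])
    runs$i_end[target] <- max(runs$i_end[target], runs$i_end[i])
    runs$len[target] <- runs$i_end[target] - runs$i_start[target] + 1L
    runs <- runs[-i, , drop = FALSE]
    # merging may create adjacent runs with identical labels; collapse them
    j <- 1L
    while (j < nrow(runs)) {
      if (runs$chrom[j] == runs$chrom[j + 1] && runs$c[j] == runs$c[j + 1] &&
          runs$k[j] == runs$k[j + 1]) {
        runs$i_end[j] <- runs$i_end[j + 1]
        runs$len[j] <- runs$i_end[j] - runs$i_start[j] + 1L
        runs <- runs[-(j + 1L), , drop = FALSE]
      } else j <- j + 1L
    }
  }
  data.frame(chrom = runs$chrom,
             start = records$pos[runs$i_start],
             end = records$pos[runs$i_end],
             n_snps = runs$i_end - runs$i_start + 1L,
             c = runs$c, k = runs$k,
             i_start = runs$i_start, i_end = runs$i_end,
             stringsAsFactors = FALSE)
}

#' Reliability score of a segment
#'
#' The mean, over the segment's heterozygous SNPs, of the likelihood ratio
#' between the observed and the expected depths:
#' `[pmf(b|T,c,k)/pmf(b_bar|T,c,k)] * [pmf(d|.)/pmf(d_bar|.)]` with
#' `b_bar = round(T * z/y)` and `d_bar = round(lambda_{c,k})`; segments
#' without heterozygous SNPs use the read-count ratio over all their SNPs.
#' The score is `100 * clamp(mean, 0, 1)`.
#'
#' @param segment One row of [merge_segments()] output (needs `i_start`,
#'   `i_end`, `c`, `k`).
#' @param records SNP records.
#' @param params Fitted `hmm_params`.
#' @return Score in \[0, 100\].
#' @export
reliability_score <- function(segment, records, params) {
  state <- params$states[segment$c, ]
  beta_k <- params$beta[segment$k]
  p_c <- params$p[segment$c]
  idx <- segment$i_start:segment$i_end
  rec <- records[idx, , drop = FALSE]
  m <- rc_mean(state, beta_k, params$lam)
  d_bar <- round(m)
  rc_ratio <- function(dd) {
    rc_loglik(dd, state, beta_k, params$lam, p_c) -
      rc_loglik(d_bar, state, beta_k, params$lam, p_c)
  }
  het <- which(rec$is_het %in% TRUE)
  if (length(het)) {
    q <- .baf_q(state, beta_k)
    Tj <- rec$T[het]
    b_bar <- round(Tj * q)
    lr <- baf_loglik(rec$b[het], Tj, state, beta_k,
                     mirror = isTRUE(params$mirror)) -
      baf_loglik(b_bar, Tj, state, beta_k, mirror = isTRUE(params$mirror)) +
      rc_ratio(rec$d[het])
    s <- mean(exp(lr))
  } else {
    s <- mean(exp(rc_ratio(rec$d)))
  }
  100 * min(max(s, 0), 1)
}

#' Annotate segments with copy numbers, cellularity and scores
#'
#' @param segments Output of [merge_segments()].
#' @param records SNP records.
#' @param params Fitted `hmm_params`.
#' @return Segment table with `chrom start end n_snps total_cn major_cn
#'   class cluster cellularity score`.
#' @export
annotate_segments <- function(segments, records, params) {
  states <- params$states
  score <- vapply(seq_len(nrow(segments)), function(i) {
    reliability_score(segments[i, ], records, params)
  }, numeric(1))
  data.frame(
    chrom = segments$chrom,
    start = segments$start,
    end = segments$end,
    n_snps = segments$n_snps,
    total_cn = states$n_total[segments$c],
    major_cn = states$n_major[segments$c],
    class = states$class[segments$c],
    cluster = segments$k,
    cellularity = params$beta[segments$k],
    score = score,
    stringsAsFactors = FALSE
  )
}

.file_header <- function(params = NULL) {
  ver <- as.character(utils::packageVersion("subcloneCN"))
  extra <- if (!is.null(params)) {
    sprintf(" K=%d beta=%s lam=%.4g", params$K,
            paste(sprintf("%.4f", params$beta), collapse = ","), params$lam)
  } else ""
  sprintf("# subcloneCN v%s%s", ver, extra)
}

#' Write the segment table
#'
#' Tab-delimited with a `#` header line carrying the tool version and fitted
#' parameters.
#'
#' @param segments Annotated segment table ([annotate_segments()]).
#' @param path Output path.
#' @param params Optional fitted `hmm_params` for the header.
#' @return Invisibly, `path`.
#' @export
write_segments <- function(segments, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.file_header(params), con)
  utils::write.table(segments, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a segment table written by [write_segments()]
#' @param path File path.
#' @return Segment data frame.
#' @export
read_segments <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write per-SNP calls
#'
#' Columns `chrom pos d b T state cluster posterior` (`state` is the 0-based
#' state index of the state table).
#'
#' @param assignments Output of [decode()].
#' @param records SNP records.
#' @param path Output path.
#' @param params Optional fitted `hmm_params` for the header.
#' @return Invisibly, `path`.
#' @export
write_snp_calls <- function(assignments, records, path, params = NULL) {
  out <- data.frame(
    chrom = records$chrom, pos = records$pos, d = records$d,
    b = records$b, T = records$T,
    state = assignments$c - 1L,
    cluster = assignments$k,
    posterior = signif(assignments$posterior, 6)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.file_header(params), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export segments as BED (0-based half-open)
#'
#' @param segments Annotated segment table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(
    chrom = segments$chrom,
    start = segments$start - 1L,
    end = segments$end,
    name = segments$class,
    score = round(segments$score)
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
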