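# Input handling for per-SNP tables extracted from a tumor BAM:
# chrom, pos (1-based), d (window read count), b (B-allele read depth),
# T (total allelic read depth), optional gc and mappability of the window.

.REQUIRED_COLS <- c("chrom", "pos", "d", "b", "T")

#' Load a per-SNP input table
#'
#' Reads a tab-delimited table with header columns `chrom pos d b T` and
#' optional `gc` and `mappability` columns; lines starting with `#` are
#' ignored. Records are validated (`0 <= b <= T`, `d >= 0`, no duplicate
#' positions within a chromosome) and returned sorted by `(chrom, pos)`;
#' unsorted input is sorted with a warning.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of validated SNP records with an `is_het` column
#'   initialised to `NA` (set later by [classify_heterozygous()]).
#' @export
load_snp_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(.REQUIRED_COLS, names(tab))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("pos", "d", "b", "T", intersect(c("gc", "mappability"),
                                                names(tab)))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad)) {
      stop("malformed value in column '", col, "' at data line ", bad[1])
    }
    if (anyNA(v) && col %in% .REQUIRED_COLS) {
      stop("missing value in column '", col, "' at data line ",
           which(is.na(v))[1])
    }
    tab[[col]] <- v
  }
  validate_snp_records(tab)
}

#' Validate and order SNP records
#'
#' Enforces the record invariants (`0 <= b <= T`, `d >= 0`, strictly
#' increasing positions within each chromosome) and sorts by `(chrom, pos)`.
#'
#' @param records A data frame with at least the columns
#'   `chrom, pos, d, b, T`.
#' @return The validated, position-sorted records.
#' @export
validate_snp_records <- function(records) {
  if (any(records$b < 0 | records$b > records$T)) {
    i <- which(records$b < 0 | records$b > records$T)[1]
    stop("invalid record at data line ", i, ": b must satisfy 0 <= b <= T")
  }
  if (any(records$d < 0)) {
    stop("invalid record at data line ", which(records$d < 0)[1],
         ": d must be non-negative")
  }
  ord <- order(records$chrom, records$pos)
  if (is.unsorted(ord)) {
    warning("input records not sorted by (chrom, pos); sorting")
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
  }
  dup <- duplicated(records[, c("chrom", "pos")])
  if (any(dup)) {
    stop("duplicate position within a chromosome at data line ",
         which(dup)[1])
  }
  if (is.null(records$is_het)) records$is_het <- NA
  records
}

#' Write a per-SNP table
#'
#' Inverse of [load_snp_table()]; writes the standard tab-delimited format
#' (optionally with `gc`/`mappability` columns if present).
#'
#' @param records SNP records.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_snp_table <- function(records, path) {
  cols <- intersect(c("chrom", "pos", "d", "b", "T", "gc", "mappability"),
                    names(records))
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# median-ratio correction of d within the bins of one covariate
.bin_correct <- function(d, covariate, n_bins) {
  rng <- range(covariate)
  if (diff(rng) == 0) return(d)
  bins <- cut(covariate, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
              include.lowest = TRUE)
  global_med <- stats::median(d)
  bin_med <- as.vector(tapply(d, bins, stats::median))
  factor <- ifelse(is.na(bin_med) | bin_med <= 0, 1, global_med / bin_med)
  # bin medians within 2% of the global median are sampling noise (and
  # below the integer-rounding resolution of the counts), not bias;
  # snapping them to 1 makes the correction idempotent
  factor[abs(log(factor)) < 0.02] <- 1
  as.numeric(d * factor[as.integer(bins)])
}

#' Correct GC-content and mappability bias in read counts
#'
#' Median-ratio bin correction: each record's `d` is scaled by
#' (global median of d) / (median of d within the record's GC bin), then by
#' the analogous mappability-bin factor, and rounded to the nearest
#' non-negative integer. Empty bins get a factor of 1. If the `gc` or
#' `mappability` column is absent (or contains missing values) the
#' corresponding correction is skipped with a warning.
#'
#' @param records SNP records.
#' @param n_gc_bins Number of equal-width GC bins (default 25).
#' @param n_map_bins Number of equal-width mappability bins (default 10).
#' @return Records with bias-corrected `d`.
#' @export
correct_read_counts <- function(records, n_gc_bins = 25L, n_map_bins = 10L) {
  d <- records$d
  if (is.null(records$gc) || anyNA(records$gc)) {
    warning("gc column absent or incomplete; GC correction skipped")
  } else {
    d <- .bin_correct(d, records$gc, n_gc_bins)
  }
  if (is.null(records$mappability) || anyNA(records$mappability)) {
    warning("mappability column absent or incomplete; ",
            "mappability correction skipped")
  } else {
    d <- .bin_correct(d, records$mappability, n_map_bins)
  }
  records$d <- pmax(round(d), 0)
  records
}

#' Normalize allelic read depths
#'
#' Removes a global allelic bias from the B-allele depths. Over a grid of
#' candidate heterozygous-calling thresholds `t` (on `min(b, T-b)/T`), the
#' threshold whose putative-heterozygous set (sites with `T >= min_depth`)
#' has median `b/T` closest to 1/2 is selected (ties to the smallest
#' threshold); `b` is then rescaled multiplicatively on that set so its
#' median `b/T` is 1/2, rounded and clamped to `[0, T]`. The selected
#' threshold is stored in `attr(, "het_threshold")` and the scale factor in
#' `attr(, "baf_scale")`.
#'
#' @param records SNP records.
#' @param threshold_grid Candidate thresholds (default `seq(0.10, 0.30,
#'   by = 0.02)`).
#' @param min_depth Minimum `T` for a site to enter the putative-het set
#'   (default 10).
#' @return Records with rescaled `b` and the attributes above.
#' @export
normalize_allelic_depths <- function(records,
                                     threshold_grid = seq(0.10, 0.30,
                                                          by = 0.02),
                                     min_depth = 10L) {
  ratio <- ifelse(records$T > 0, pmin(records$b, records$T - records$b) /
                    records$T, 0)
  baf <- ifelse(records$T > 0, records$b / records$T, 0.5)
  deep <- records$T >= min_depth
  med <- vapply(threshold_grid, function(t) {
    sel <- deep & ratio >= t
    if (!any(sel)) return(NA_real_)
    stats::median(baf[sel])
  }, numeric(1))
  if (all(is.na(med))) {
    warning("no putative heterozygous sites at any threshold; ",
            "allelic normalization skipped")
    attr(records, "het_threshold") <- threshold_grid[1]
    attr(records, "baf_scale") <- 1
    return(records)
  }
  best <- which.min(abs(med - 0.5))  # ties resolve to the smallest threshold
  t_sel <- threshold_grid[best]
  sel <- deep & ratio >= t_sel
  scale <- 0.5 / med[best]
  records$b[sel] <- pmin(pmax(round(records$b[sel] * scale), 0),
                         records$T[sel])
  attr(records, "het_threshold") <- t_sel
  attr(records, "baf_scale") <- scale
  records
}

#' Flag sites heterozygous in the normal genome
#'
#' `is_het` is set to `TRUE` iff `T >= min_depth` and
#' `min(b, T-b)/T >= threshold`. Homozygous sites keep their read counts and
#' contribute only the read-count likelihood downstream.
#'
#' @param records SNP records (ideally after [normalize_allelic_depths()]).
#' @param threshold Allelic-ratio threshold; defaults to the grid-selected
#'   threshold stored by [normalize_allelic_depths()], else 0.2.
#' @param min_depth Minimum total allelic depth (default 10).
#' @return Records with the `is_het` flag set.
#' @export
classify_heterozygous <- function(records,
                                  threshold = attr(records, "het_threshold"),
                                  min_depth = 10L) {
  if (is.null(threshold)) threshold <- 0.2
  ratio <- ifelse(records$T > 0, pmin(records$b, records$T - records$b) /
                    records$T, 0)
  records$is_het <- records$T >= min_depth & ratio >= threshold
  # remember the selection rule so the model can condition the B-allele
  # likelihood on a site having passed it
  attr(records, "het_sel") <- list(threshold = threshold,
                                   min_depth = min_depth)
  records
}

#' Standard preprocessing pipeline
#'
#' Convenience wrapper: bias correction (if covariates are present), allelic
#' normalization, and heterozygosity flagging.
#'
#' @param records SNP records from [load_snp_table()].
#' @param correct_bias Apply [correct_read_counts()] when `gc`/`mappability`
#'   are available (default TRUE).
#' @return Preprocessed records ready for model fitting.
#' @export
preprocess_snp_table <- function(records, correct_bias = TRUE) {
  if (correct_bias && !is.null(records$gc) && !anyNA(records$gc) &&
      !is.null(records$mappability) && !anyNA(records$mappability)) {
    records <- correct_read_counts(records)
  }
  records <- normalize_allelic_depths(records)
  classify_heterozygous(records)
}
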