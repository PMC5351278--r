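#' Enumerate tumor aberration states
#'
#' Builds the table of tumor genotype states used as the aberration chain of
#' the factorial HMM. A state is a pair (total copy number `n_total`,
#' major-allele copy number `n_major`) with `0 <= n_total <= max_copy` and
#' `ceiling(n_total/2) <= n_major <= n_total`. Each state carries the
#' expected tumor B-allele frequency at a site heterozygous in the normal
#' genome, `mu = n_major / n_total` (with the convention `mu = 1/2` for the
#' homozygous-deletion state, a placeholder that the emission model never
#' uses on its own), and an aberration class label (see
#' [classify_aberration()]).
#'
#' @param max_copy Integer copy-number ceiling, between 1 and 10. The default
#'   of 7 follows common practice among copy-number callers.
#' @return A `data.frame` with one row per state, ordered by
#'   `(n_total, n_major)`, and columns `index` (0-based state id), `n_total`,
#'   `n_major`, `mu`, `class`.
#' @examples
#' enumerate_states(2)
#' nrow(enumerate_states(7))  # 20 states
#' @export
enumerate_states <- function(max_copy = 7L) {
  max_copy <- as.integer(max_copy)
  if (length(max_copy) != 1L || is.na(max_copy) || max_copy < 1L ||
      max_copy > 10L) {
    stop("max_copy must be a single integer in [1, 10]")
  }
  n_total <- integer(0)
  n_major <- integer(0)
  for (n in 0:max_copy) {
    majors <- seq.int(ceiling(n / 2), n)
    if (n == 0L) majors <- 0L
    n_total <- c(n_total, rep.int(n, length(majors)))
    n_major <- c(n_major, majors)
  }
  mu <- ifelse(n_total == 0L, 0.5, n_major / pmax(n_total, 1L))
  cls <- vapply(seq_along(n_total), function(i) {
    classify_aberration(n_total[i], n_major[i])
  }, character(1))
  data.frame(
    index = seq_along(n_total) - 1L,
    n_total = n_total,
    n_major = n_major,
    mu = mu,
    class = cls,
    stringsAsFactors = FALSE
  )
}

#' Classify an aberration state
#'
#' Maps a (total, major) copy-number pair to one of the aberration classes
#' used in copy-number/LOH calling:
#' \describe{
#'   \item{HOMD}{homozygous deletion, total = 0}
#'   \item{HEMD}{hemizygous deletion, total = 1}
#'   \item{HET}{copy-neutral heterozygous (2,1) -- the normal state}
#'   \item{NLOH}{copy-neutral LOH (2,2)}
#'   \item{ALOH}{amplified LOH, total >= 3 with major = total}
#'   \item{BAMP}{balanced amplification, even total >= 4 with major = total/2}
#'   \item{GAIN}{unbalanced gain at total 3 or 4}
#'   \item{AMP}{unbalanced amplification at total >= 5}
#' }
#'
#' @param n_total Total copy number (integer >= 0).
#' @param n_major Major-allele copy number.
#' @return A single character class label.
#' @examples
#' classify_aberration(2, 2)  # "NLOH"
#' classify_aberration(4, 2)  # "BAMP"
#' @export
classify_aberration <- function(n_total, n_major) {
  n_total <- as.integer(n_total)
  n_major <- as.integer(n_major)
  if (length(n_total) != 1L || length(n_major) != 1L ||
      is.na(n_total) || is.na(n_major) || n_total < 0L ||
      n_major < ceiling(n_total / 2) || n_major > max(n_total, 0L)) {
    stop("invalid (n_total, n_major) pair")
  }
  if (n_total == 0L) return("HOMD")
  if (n_total == 1L) return("HEMD")
  if (n_total == 2L) return(if (n_major == 2L) "NLOH" else "HET")
  if (n_major == n_total) return("ALOH")
  if (n_total %% 2L == 0L && n_major == n_total %/% 2L) return("BAMP")
  if (n_total <= 4L) "GAIN" else "AMP"
}

#' Write the state table to a TSV file
#'
#' @param states State table from [enumerate_states()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_states <- function(states, path) {
  out <- data.frame(
    index = states$index,
    n_total = states$n_total,
    n_major = states$n_major,
    mu = states$mu,
    class = states$class
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
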