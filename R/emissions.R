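# Emission models: binomial B-allele depth and negative-binomial read counts,
# conditional on an aberration state c and a clonal cluster k. The observed
# signal at a locus is a mixture of normal cells (copy number 2, BAF 1/2) at
# fraction 1 - beta_k and aberrant cells (n_c copies, major count n_major) at
# cellularity beta_k.

# numerical floors: keep every log-likelihood finite
.Q_EPS <- 1e-4     # clamp on the binomial success probability
.MEAN_FLOOR <- 1e-3 # floor on lambda_{c,k} as a fraction of lambda

#' Mixture mean of the B-allele copy number
#'
#' `z = n_s * mu_s * (1 - beta_k) + n_major * beta_k`, with normal-cell
#' constants `n_s = 2`, `mu_s = 1/2` (so the normal contribution is
#' `1 - beta_k`).
#'
#' @param state One row of the state table ([enumerate_states()]), or any
#'   list with `n_total` and `n_major`.
#' @param beta_k Cellularity of the cluster, in (0, 1].
#' @return Mixture B-allele copy number (non-negative real).
#' @export
mixed_b_copy <- function(state, beta_k) {
  (1 - beta_k) + state$n_major * beta_k
}

#' Mixture mean of the total copy number
#'
#' `y = n_s * (1 - beta_k) + n_total * beta_k` with `n_s = 2`.
#'
#' @inheritParams mixed_b_copy
#' @return Mixture total copy number (non-negative real).
#' @export
mixed_total_copy <- function(state, beta_k) {
  2 * (1 - beta_k) + state$n_total * beta_k
}

# success probability of the BAF binomial for one (state, cluster) pair
.baf_q <- function(state, beta_k) {
  y <- mixed_total_copy(state, beta_k)
  if (y < .Q_EPS) return(0.5)
  min(max(mixed_b_copy(state, beta_k) / y, .Q_EPS), 1 - .Q_EPS)
}

#' B-allele depth log-likelihood
#'
#' Log-probability of observing `b` B-allele reads out of `T` at a site
#' heterozygous in the normal genome, given an aberration state and a
#' cluster cellularity. Because the B allele may sit on either the major or
#' the minor haplotype, the default likelihood is an equal-weight mixture of
#' `Binomial(T, q)` and `Binomial(T, 1 - q)` with `q = z / y` (clamped away
#' from 0 and 1); `mirror = FALSE` gives the single-binomial form.
#'
#' @inheritParams mixed_b_copy
#' @param b B-allele read depth (0 <= b <= T).
#' @param T_depth Total allelic read depth (>= 1).
#' @param mirror Use the phase-symmetric two-component mixture (default).
#' @return Log-likelihood (finite for all valid inputs).
#' @export
baf_loglik <- function(b, T_depth, state, beta_k, mirror = TRUE) {
  q <- .baf_q(state, beta_k)
  l1 <- stats::dbinom(b, T_depth, q, log = TRUE)
  if (!mirror) return(l1)
  l2 <- stats::dbinom(b, T_depth, 1 - q, log = TRUE)
  pmax(l1, l2) + log1p(exp(-abs(l1 - l2))) - log(2)
}

#' Read-count mean for a (state, cluster) pair
#'
#' `lambda_{c,k} = (y_{c,k} / 2) * lam`, floored at `1e-3 * lam` so the
#' negative binomial never degenerates at a zero mean.
#'
#' @inheritParams mixed_b_copy
#' @param lam Mean read count of a normal two-copy region (> 0).
#' @return Positive mean read count.
#' @export
rc_mean <- function(state, beta_k, lam) {
  max(mixed_total_copy(state, beta_k) / 2, .MEAN_FLOOR) * lam
}

#' Read-count log-likelihood
#'
#' Negative-binomial log pmf with per-state success probability `p_c` and
#' size `r = lambda_{c,k} * (1 - p_c) / p_c`, so that the mean equals
#' `lambda_{c,k}` and the variance `lambda_{c,k} / (1 - p_c)`.
#'
#' @inheritParams rc_mean
#' @param d Window read count (integer >= 0).
#' @param p_c Success probability of the negative binomial, in (0, 1).
#' @return Log-likelihood.
#' @export
rc_loglik <- function(d, state, beta_k, lam, p_c) {
  m <- rc_mean(state, beta_k, lam)
  r <- m * (1 - p_c) / p_c
  lgamma(d + r) - lgamma(d + 1) - lgamma(r) + r * log1p(-p_c) + d * log(p_c)
}

#' Per-site emission log-likelihood
#'
#' The per-SNP emission of the factorial HMM: the read-count term always
#' contributes; the B-allele term contributes only at sites flagged
#' heterozygous in the normal genome.
#'
#' @param record A one-row data frame (or list) with fields `d`, `b`, `T`,
#'   `is_het`.
#' @param state One row of the state table.
#' @param k Cluster index (1-based).
#' @param params Emission parameter list with `beta` (length K), `lam`, `p`
#'   (length C, indexed by `state$index + 1`).
#' @return Log-likelihood of the site's observations.
#' @export
site_loglik <- function(record, state, k, params) {
  beta_k <- params$beta[k]
  ll <- rc_loglik(record$d, state, beta_k, params$lam,
                  params$p[state$index + 1L])
  if (isTRUE(record$is_het)) {
    ll <- ll + baf_loglik(record$b, record$T, state, beta_k)
  }
  ll
}

# ---- vectorized internals -------------------------------------------------
# Joint states are laid out state-fastest: column j holds (c, k) with
# c = (j - 1) %% C + 1, k = (j - 1) %/% C + 1.

# per-column emission constants for all C*K joint states
.emission_pars <- function(states, beta, lam, p) {
  C <- nrow(states)
  K <- length(beta)
  bk <- rep(beta, each = C)
  nt <- rep(states$n_total, K)
  nm <- rep(states$n_major, K)
  y <- 2 * (1 - bk) + nt * bk
  z <- (1 - bk) + nm * bk
  q <- ifelse(y < .Q_EPS, 0.5, pmin(pmax(z / y, .Q_EPS), 1 - .Q_EPS))
  m <- pmax(y / 2, .MEAN_FLOOR) * lam
  pc <- rep(p, K)
  list(C = C, K = K, cidx = rep(seq_len(C), K), kidx = rep(seq_len(K), each = C),
       beta = bk, n_total = nt, n_major = nm, y = y, z = z, q = q, m = m,
       p = pc, r = m * (1 - pc) / pc)
}

# N x (C*K) negative-binomial log-pmf matrix (compiled kernel)
.nb_loglik_matrix <- function(d, ep) {
  cpp_nb_loglik(as.integer(d), ep$r, ep$p)
}

# log of the binomial mass inside the heterozygous-calling band
# [ceil(t*T), floor((1-t)*T)], per unique depth (rows) and per state q
# (columns). Because the band is symmetric in b <-> T-b, the same mass
# normalizes both components of the mirrored mixture.
.logpkeep_mat <- function(uT, q, threshold) {
  blo <- ceiling(threshold * uT)
  bhi <- floor((1 - threshold) * uT)
  nT <- length(uT)
  M <- length(q)
  qq <- rep(q, each = nT)
  pk <- stats::pbinom(rep(bhi, M), rep(uT, M), qq) -
    stats::pbinom(rep(blo, M) - 1, rep(uT, M), qq)
  matrix(log(pmax(pk, 1e-12)), nT, M)
}

# derivative of .logpkeep_mat with respect to q, via
# d/dq pbinom(k, n, q) = -n * dbinom(k, n - 1, q)
.dlogpkeep_mat <- function(uT, q, threshold) {
  blo <- ceiling(threshold * uT)
  bhi <- floor((1 - threshold) * uT)
  nT <- length(uT)
  M <- length(q)
  qq <- rep(q, each = nT)
  pk <- stats::pbinom(rep(bhi, M), rep(uT, M), qq) -
    stats::pbinom(rep(blo, M) - 1, rep(uT, M), qq)
  dpk <- -rep(uT, M) * (stats::dbinom(rep(bhi, M), rep(uT, M) - 1, qq) -
                          stats::dbinom(rep(blo, M) - 1, rep(uT, M) - 1,
                                        qq))
  matrix(dpk / pmax(pk, 1e-12), nT, M)
}

# n_het x (C*K) B-allele log-likelihood matrix (phase-symmetric mixture).
# When `het_sel` (list with `threshold`) is given, the likelihood is
# conditioned on the site having passed the heterozygous-calling band --
# without this, strongly skewed LOH states are systematically penalized at
# the surviving sites and cellularity is biased downward.
.baf_loglik_matrix <- function(b, T_depth, ep, mirror = TRUE,
                               het_sel = NULL) {
  out <- cpp_baf_loglik(as.integer(b), as.integer(T_depth), ep$q,
                        isTRUE(mirror))
  if (!is.null(het_sel)) {
    uT <- sort(unique(T_depth))
    lpk <- .logpkeep_mat(uT, ep$q, het_sel$threshold)
    out <- out - lpk[match(T_depth, uT), , drop = FALSE]
  }
  out
}

# full emission log-likelihood matrix for the joint chain
.emission_loglik <- function(records, ep, mirror = TRUE, het_sel = NULL) {
  E <- .nb_loglik_matrix(records$d, ep)
  het <- which(records$is_het)
  if (length(het)) {
    E[het, ] <- E[het, , drop = FALSE] +
      .baf_loglik_matrix(records$b[het], records$T[het], ep,
                         mirror = mirror, het_sel = het_sel)
  }
  E
}
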