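# Shared fixtures and independent oracles for the test suite.

# small hand-built record table
tiny_records <- function() {
  data.frame(
    chrom = "chr1",
    pos = c(100, 2100, 4100),
    d = c(30, 28, 33),
    b = c(15, 0, 20),
    T = c(30, 30, 40),
    is_het = c(TRUE, FALSE, TRUE)
  )
}

# simulate a mixture and preprocess it, at reduced size for unit tests
small_sim <- function(mix = "a_050n_050", n_snps = 4000, seed = 7,
                      preprocess = TRUE) {
  genomes <- default_genomes(seed)
  sim <- simulate_sample(list(proportions = parse_mixture_name(mix),
                              n_snps = n_snps, seed = seed), genomes)
  if (preprocess) sim$records <- preprocess_snp_table(sim$records)
  sim
}

# independent emission oracle: dbinom/dnbinom straight from the model
# definitions, no shared code with the package internals
oracle_emission <- function(records, params) {
  states <- params$states
  C <- nrow(states)
  K <- params$K
  E <- matrix(0, nrow(records), C * K)
  for (k in seq_len(K)) {
    for (c in seq_len(C)) {
      bk <- params$beta[k]
      nt <- states$n_total[c]
      nm <- states$n_major[c]
      y <- 2 * (1 - bk) + nt * bk
      z <- (1 - bk) + nm * bk
      q <- if (y < 1e-4) 0.5 else min(max(z / y, 1e-4), 1 - 1e-4)
      m <- max(y / 2, 1e-3) * params$lam
      pc <- params$p[c]
      r <- m * (1 - pc) / pc
      ll <- dnbinom(records$d, size = r, prob = 1 - pc, log = TRUE)
      het <- which(records$is_het %in% TRUE)
      if (length(het)) {
        mix <- 0.5 * dbinom(records$b[het], records$T[het], q) +
          0.5 * dbinom(records$b[het], records$T[het], 1 - q)
        ll[het] <- ll[het] + log(mix)
      }
      E[, (k - 1) * C + c] <- ll
    }
  }
  E
}

# exhaustive-path forward-backward oracle for tiny chains
brute_force_fb <- function(records, params) {
  E <- oracle_emission(records, params)
  N <- nrow(records)
  M <- ncol(E)
  stopifnot(M^N <= 2e5)
  paths <- as.matrix(expand.grid(rep(list(seq_len(M)), N)))
  logp <- log(params$pi[paths[, 1]]) + E[cbind(1, paths[, 1])]
  if (N >= 2) {
    for (t in 2:N) {
      A <- transition_prob(records$pos[t] - records$pos[t - 1], params)
      logp <- logp + log(A[cbind(paths[, t - 1], paths[, t])]) +
        E[cbind(t, paths[, t])]
    }
  }
  mx <- max(logp)
  w <- exp(logp - mx)
  loglik <- mx + log(sum(w))
  gamma <- matrix(0, N, M)
  for (t in seq_len(N)) {
    for (j in seq_len(M)) {
      gamma[t, j] <- sum(w[paths[, t] == j]) / sum(w)
    }
  }
  list(gamma = gamma, loglik = loglik)
}

# one-hot posterior matrix from a truth (state, cluster) assignment
one_hot_gamma <- function(c_idx, k_idx, C, K) {
  G <- matrix(0, length(c_idx), C * K)
  G[cbind(seq_along(c_idx), (k_idx - 1L) * C + c_idx)] <- 1
  G
}

# map simulator truth segments to state-table rows for each SNP
truth_state_index <- function(records, truth_segments, states) {
  out <- integer(nrow(records))
  for (i in seq_len(nrow(truth_segments))) {
    hit <- records$chrom == truth_segments$chrom[i] &
      records$pos >= truth_segments$start[i] &
      records$pos <= truth_segments$end[i]
    j <- which(states$n_total == truth_segments$total_cn[i] &
                 states$n_major == truth_segments$major_cn[i])
    out[hit] <- j
  }
  out
}
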