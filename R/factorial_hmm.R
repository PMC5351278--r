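# Factorial HMM over C aberration states x K clonal clusters. The joint
# transition kernel factorizes as (cluster chain) x (state chain); each
# factor is a distance-dependent sticky chain ("stay with probability
# rho(dist), else uniform over the other levels") with
# rho(dist) = 1 - (1 - exp(-dist/L)) * (1 - rho_min), L = 1e5 bp.
# Joint states are laid out state-fastest: j = (k-1)*C + c.

.PI_FLOOR <- 1e-6
# cellularity floor: clones below ~5% of cells are unresolvable at 30x
# coverage, and a cluster pinned here acts as a pure noise sink
.BETA_MIN <- 0.05

#' Construct factorial-HMM parameters
#'
#' @param states State table from [enumerate_states()].
#' @param beta Strictly increasing cluster cellularities, each in (0, 1].
#' @param lam Mean read count of a normal two-copy region.
#' @param p Per-state negative-binomial success probabilities (length
#'   `nrow(states)`); a scalar is recycled.
#' @param pi Initial distribution over the C*K joint states (default
#'   uniform).
#' @param rho_state,rho_cluster Asymptotic stay probabilities of the two
#'   chains (defaults 0.999).
#' @param L Distance scale of the transition decay in bp (default 1e5).
#' @param mirror Use the phase-symmetric BAF mixture (default TRUE).
#' @param het_sel Optional list with `threshold` (and `min_depth`)
#'   describing the heterozygous-calling rule applied to the input; when
#'   given, the B-allele likelihood is conditioned on a site passing that
#'   rule (see [classify_heterozygous()]).
#' @return An `hmm_params` list.
#' @export
make_hmm_params <- function(states, beta, lam, p = 0.5, pi = NULL,
                            rho_state = 0.999, rho_cluster = 0.999,
                            L = 1e5, mirror = TRUE, het_sel = NULL) {
  C <- nrow(states)
  K <- length(beta)
  if (K >= 2 && any(diff(beta) <= 0)) stop("beta must be strictly increasing")
  if (any(beta <= 0 | beta > 1)) stop("beta must lie in (0, 1]")
  if (lam <= 0) stop("lam must be positive")
  if (length(p) == 1L) p <- rep(p, C)
  if (length(p) != C) stop("p must have one entry per state")
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  if (is.null(pi)) pi <- rep(1 / (C * K), C * K)
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  structure(list(states = states, K = K, beta = beta, lam = lam, p = p,
                 pi = pi, rho_state = rho_state, rho_cluster = rho_cluster,
                 L = L, mirror = mirror, het_sel = het_sel),
            class = "hmm_params")
}

.rho_dist <- function(dist, rho_min, L) {
  1 - (1 - exp(-dist / L)) * (1 - rho_min)
}

# v %*% A for the structured joint kernel (A is symmetric, so this also
# serves as A %*% v in the backward pass)
.Amult <- function(v, rho_s, rho_c, C, K) {
  Vm <- matrix(v, C, K)
  if (C > 1L) {
    us <- (1 - rho_s) / (C - 1)
    Vm <- (rho_s - us) * Vm + matrix(colSums(Vm) * us, C, K, byrow = TRUE)
  }
  if (K > 1L) {
    uc <- (1 - rho_c) / (K - 1)
    Vm <- (rho_c - uc) * Vm + matrix(rowSums(Vm) * uc, C, K)
  }
  dim(Vm) <- NULL
  Vm
}

#' Joint transition matrix at a given genomic distance
#'
#' Returns the dense `C*K x C*K` row-stochastic transition matrix, the
#' Kronecker product of the cluster-chain and state-chain factors evaluated
#' at `dist_bp`.
#'
#' @param dist_bp Distance between adjacent SNPs in bp (>= 1).
#' @param params `hmm_params` object.
#' @return A row-stochastic matrix.
#' @export
transition_prob <- function(dist_bp, params) {
  C <- nrow(params$states)
  K <- params$K
  one_factor <- function(m, rho_min) {
    if (m == 1L) return(matrix(1, 1, 1))
    rho <- .rho_dist(dist_bp, rho_min, params$L)
    A <- matrix((1 - rho) / (m - 1), m, m)
    diag(A) <- rho
    A
  }
  one_factor(K, params$rho_cluster) %x% one_factor(C, params$rho_state)
}

#' Forward-backward inference on the joint chain
#'
#' Runs scaled forward-backward independently on each chromosome (chains
#' share one parameter set) and returns the per-SNP joint posteriors
#' `gamma`, the total observed-data log-likelihood, and the expected
#' stay/switch statistics of both chains used by the M-step.
#'
#' @param records Preprocessed SNP records (with `is_het` set).
#' @param params `hmm_params` object.
#' @return A posterior list with elements `gamma` (N x C*K matrix), `loglik`,
#'   `C`, `K`, `chain_starts`, `stay_state`, `stay_cluster`, `w`
#'   (per-transition distance weights `1 - exp(-dist/L)`).
#' @export
forward_backward <- function(records, params) {
  states <- params$states
  C <- nrow(states)
  K <- params$K
  M <- C * K
  ep <- .emission_pars(states, params$beta, params$lam, params$p)
  E <- .emission_loglik(records, ep, mirror = isTRUE(params$mirror),
                        het_sel = params$het_sel)
  N <- nrow(records)
  gamma <- matrix(0, N, M)
  chain_ids <- split(seq_len(N), records$chrom)
  loglik <- 0
  chain_starts <- integer(0)
  stay_state <- stay_cluster <- w_all <- numeric(0)

  for (idx in chain_ids) {
    n <- length(idx)
    chain_starts <- c(chain_starts, idx[1])
    if (n >= 2) {
      dist <- diff(records$pos[idx])
      rs <- .rho_dist(dist, params$rho_state, params$L)
      rc <- .rho_dist(dist, params$rho_cluster, params$L)
      wts <- 1 - exp(-dist / params$L)
    } else {
      rs <- rc <- wts <- numeric(0)
    }
    res <- tryCatch(
      cpp_fb(E[idx, , drop = FALSE], rs, rc, params$pi, C, K),
      error = function(e) {
        stop("forward-backward failed on chain starting at record ", idx[1],
             ": ", conditionMessage(e), " (missing numerical floor?)")
      })
    gamma[idx, ] <- res$gamma
    loglik <- loglik + res$loglik
    if (n >= 2) {
      stay_state <- c(stay_state, res$stay_state)
      stay_cluster <- c(stay_cluster, res$stay_cluster)
      w_all <- c(w_all, wts)
    }
  }
  list(gamma = gamma, loglik = loglik, C = C, K = K,
       chain_starts = chain_starts, stay_state = stay_state,
       stay_cluster = stay_cluster, w = w_all)
}

#' Expected partial log-likelihoods
#'
#' The posterior-weighted read-count and B-allele log-likelihood sums,
#' returned separately for diagnostics.
#'
#' @param gamma N x C*K posterior matrix.
#' @param records SNP records.
#' @param params `hmm_params` object.
#' @return Named numeric vector `c(d = E(LL_d), b = E(LL_b))`.
#' @export
expected_loglik_parts <- function(gamma, records, params) {
  ep <- .emission_pars(params$states, params$beta, params$lam, params$p)
  ll_d <- sum(gamma * .nb_loglik_matrix(records$d, ep))
  het <- which(records$is_het %in% TRUE)
  ll_b <- if (length(het)) {
    sum(gamma[het, , drop = FALSE] *
          .baf_loglik_matrix(records$b[het], records$T[het], ep,
                             mirror = isTRUE(params$mirror),
                             het_sel = params$het_sel))
  } else 0
  c(d = ll_d, b = ll_b)
}

# ---- M-step ----------------------------------------------------------------

# MLE of the asymptotic stay probability of one chain, from expected stay
# indicators s_hat and distance weights w (stay prob at step t is
# 1 - w_t * (1 - rho_min)); concave 1-D problem
.update_rho <- function(s_hat, w) {
  n_off <- sum(1 - s_hat)
  f <- function(x) sum(s_hat * log1p(-w * x)) + n_off * log(x)
  opt <- stats::optimize(f, c(1e-9, 1), maximum = TRUE)
  min(max(1 - opt$maximum, 0), 1 - 1e-9)
}

# digamma/trigamma analogues of the NB log-pmf matrix (compiled kernel)
.nb_psi_matrices <- function(d, ep) {
  cpp_nb_psi(as.integer(d), ep$r, ep$p)
}

#' EM maximization step
#'
#' Closed-form updates for the initial distribution and the stay parameters
#' of both transition chains, followed by damped Newton-Raphson updates of
#' `(lam, p, beta)` on the expected complete-data log-likelihood, with box
#' constraints (`beta` in \[0.05, 1\], `p` in \[1e-4, 1 - 1e-4\], `lam > 0`)
#' and step halving so the objective never decreases. A non-finite or
#' non-concave Newton step falls back to a bounded line search
#' ([stats::optimize()]). `beta` is re-sorted ascending afterwards (with a
#' consistent relabeling of `pi`).
#'
#' @param posterior Output of [forward_backward()] (or a bare `gamma`
#'   matrix, in which case only the emission parameters are updated).
#' @param records SNP records.
#' @param params Current `hmm_params`.
#' @param control Optional list: `newton_sweeps` (default 1).
#' @return Updated `hmm_params`.
#' @export
m_step <- function(posterior, records, params, control = list()) {
  if (is.matrix(posterior)) posterior <- list(gamma = posterior)
  G <- posterior$gamma
  C <- nrow(params$states)
  K <- params$K

  if (!is.null(posterior$chain_starts)) {
    pi <- colMeans(G[posterior$chain_starts, , drop = FALSE])
    pi <- pmax(pi, .PI_FLOOR)
    params$pi <- pi / sum(pi)
  }
  if (length(posterior$stay_state)) {
    if (C > 1) {
      params$rho_state <- .update_rho(posterior$stay_state, posterior$w)
    }
    if (K > 1) {
      params$rho_cluster <- .update_rho(posterior$stay_cluster, posterior$w)
    }
  }
  # inner Newton loop: iterate sweeps until (lam, p, beta) stabilize, so the
  # M-step performs a (near-)full conditional maximization; once lam and p
  # have settled, later sweeps refine only beta (the structurally coupled
  # block)
  sweeps <- control$newton_sweeps %||% 4L
  lam_p_settled <- FALSE
  for (s in seq_len(sweeps)) {
    old <- c(params$beta, params$lam, params$p)
    old_lp <- c(params$lam, params$p)
    params <- .update_emission_newton(G, records, params,
                                      beta_only = lam_p_settled)
    if (!lam_p_settled) {
      lam_p_settled <- max(abs(c(params$lam, params$p) - old_lp) /
                             pmax(abs(old_lp), 1e-3)) < 1e-3
    }
    if (max(abs(c(params$beta, params$lam, params$p) - old) /
              pmax(abs(old), 1e-3)) < 5e-4) break
  }
  # enforce the cellularity ordering beta_1 < ... < beta_K
  ord <- order(params$beta)
  if (any(ord != seq_len(K))) {
    params$beta <- params$beta[ord]
    pim <- matrix(params$pi, C, K)[, ord, drop = FALSE]
    params$pi <- as.vector(pim)
  }
  params
}

# one damped-Newton sweep over lam, p (per state) and beta (per cluster)
.update_emission_newton <- function(G, records, params, beta_only = FALSE) {
  states <- params$states
  C <- nrow(states)
  K <- params$K
  d <- as.integer(records$d)
  het <- which(records$is_het %in% TRUE)
  Gh <- G[het, , drop = FALSE]
  bh <- as.integer(records$b[het])
  Th <- as.integer(records$T[het])
  mirror <- isTRUE(params$mirror)
  cidx <- rep(seq_len(C), K)

  q_nb_cols <- function(beta, lam, p, jset = NULL) {
    ep <- .emission_pars(states, beta, lam, p)
    if (is.null(jset)) return(cpp_nb_qcols(d, ep$r, ep$p, G))
    cpp_nb_qcols(d, ep$r[jset], ep$p[jset], G[, jset, drop = FALSE])
  }
  het_sel <- params$het_sel
  uT <- sort(unique(Th))
  # posterior mass aggregated by unique total depth, for the truncation term
  GhT <- if (length(het) && !is.null(het_sel)) {
    rowsum(Gh, match(Th, uT))
  } else NULL
  q_baf_cols <- function(beta, lam, p, jset = NULL) {
    if (!length(het)) return(rep(0, if (is.null(jset)) C * K else
      length(jset)))
    ep <- .emission_pars(states, beta, lam, p)
    qs <- if (is.null(jset)) ep$q else ep$q[jset]
    Gs <- if (is.null(jset)) Gh else Gh[, jset, drop = FALSE]
    out <- cpp_baf_qcols(bh, Th, qs, Gs, mirror)
    if (!is.null(het_sel)) {
      GT <- if (is.null(jset)) GhT else GhT[, jset, drop = FALSE]
      out <- out - colSums(GT * .logpkeep_mat(uT, qs, het_sel$threshold))
    }
    out
  }

  beta <- params$beta
  lam <- params$lam
  p <- params$p

  if (!beta_only) {
    # ---- lam ----
    ep <- .emission_pars(states, beta, lam, p)
    gr <- cpp_nb_gradcols(d, ep$r, ep$p, G)
    fac <- (1 - ep$p) / ep$p
    mfl <- pmax(ep$y / 2, .MEAN_FLOOR)
    g <- sum(gr$cA * fac * mfl)
    h <- sum(gr$cB * fac^2 * mfl^2)
    lam <- .newton_scalar(
      lam, g, h, lower = 1e-6, upper = Inf,
      objective = function(x) sum(q_nb_cols(beta, x, p)))

    # ---- p (independent across states given lam, beta) ----
    ep <- .emission_pars(states, beta, lam, p)
    gr <- cpp_nb_gradcols(d, ep$r, ep$p, G)
    cA <- gr$cA
    cB <- gr$cB
    cG <- colSums(G)
    cd <- as.vector(crossprod(G, records$d))
    rp <- -ep$m / ep$p^2
    rpp <- 2 * ep$m / ep$p^3
    g_col <- cA * rp - cG * ep$r / (1 - ep$p) + cd / ep$p
    h_col <- cB * rp^2 + cA * rpp - cG * (2 * rp / (1 - ep$p) +
                                            ep$r / (1 - ep$p)^2) -
      cd / ep$p^2
    g_c <- as.vector(rowsum(g_col, cidx))
    h_c <- as.vector(rowsum(h_col, cidx))
    step <- ifelse(is.finite(g_c / h_c) & h_c < 0, -g_c / h_c, NA_real_)
    if (anyNA(step)) {
      # bounded line search on the affected coordinates
      for (cc in which(is.na(step))) {
        obj <- function(x) {
          p2 <- p
          p2[cc] <- x
          sum(rowsum(q_nb_cols(beta, lam, p2), cidx)[cc, ])
        }
        opt <- stats::optimize(obj, c(1e-4, 1 - 1e-4), maximum = TRUE)
        step[cc] <- opt$maximum - p[cc]
      }
    }
    if (max(abs(g_c * step)) < 1e-3) {
      p <- pmin(pmax(p + step, 1e-4), 1 - 1e-4)
    } else {
      q_old <- as.vector(rowsum(q_nb_cols(beta, lam, p), cidx))
      for (half in 1:8) {
        p_new <- pmin(pmax(p + step, 1e-4), 1 - 1e-4)
        q_new <- as.vector(rowsum(q_nb_cols(beta, lam, p_new), cidx))
        bad <- q_new < q_old - 1e-9
        if (!any(bad)) {
          p <- p_new
          break
        }
        step[bad] <- step[bad] / 2
        if (half == 8L) {
          p_new[bad] <- p[bad]
          p <- p_new
        }
      }
    }
  }

  # ---- beta (per cluster) ----
  ep <- .emission_pars(states, beta, lam, p)
  fac <- (1 - ep$p) / ep$p
  for (k in seq_len(K)) {
    jset <- (k - 1L) * C + seq_len(C)
    Gk <- G[, jset, drop = FALSE]
    dmdb <- ifelse(ep$y[jset] / 2 > .MEAN_FLOOR,
                   lam * (states$n_total - 2) / 2, 0)
    grk <- cpp_nb_gradcols(d, ep$r[jset], ep$p[jset], Gk)
    g <- sum(grk$cA * fac[jset] * dmdb)
    h <- sum(grk$cB * fac[jset]^2 * dmdb^2)
    if (length(het)) {
      q <- ep$q[jset]
      y <- ep$y[jset]
      z <- ep$z[jset]
      interior <- q > .Q_EPS & q < 1 - .Q_EPS & y >= .Q_EPS
      qp <- ifelse(interior,
                   ((states$n_major - 1) * y - z * (states$n_total - 2)) /
                     y^2, 0)
      qpp <- ifelse(interior, -2 * (states$n_total - 2) * qp / y, 0)
      bg <- cpp_baf_gradcols(bh, Th, q, Gh[, jset, drop = FALSE], mirror)
      c1 <- bg$c1
      c2 <- bg$c2
      if (!is.null(het_sel)) {
        # truncation term: subtract d/dq log Pkeep (and its q-derivative,
        # obtained by central differences on the analytic first derivative)
        t0 <- het_sel$threshold
        dq <- 1e-4
        W0 <- .dlogpkeep_mat(uT, q, t0)
        Wp <- .dlogpkeep_mat(uT, pmin(q + dq, 1 - 1e-6), t0)
        Wm <- .dlogpkeep_mat(uT, pmax(q - dq, 1e-6), t0)
        GT <- GhT[, jset, drop = FALSE]
        c1 <- c1 - colSums(GT * W0)
        c2 <- c2 - colSums(GT * (Wp - Wm)) / (2 * dq)
      }
      g <- g + sum(c1 * qp)
      h <- h + sum(c2 * qp^2) + sum(c1 * qpp)
    }
    if (abs(g) < 1e-12 && abs(h) < 1e-12) next  # non-identifiable (all-neutral)
    obj_k <- function(x) {
      b2 <- beta
      b2[k] <- x
      sum(q_nb_cols(b2, lam, p, jset)) + sum(q_baf_cols(b2, lam, p, jset))
    }
    beta[k] <- .newton_scalar(beta[k], g, h, lower = .BETA_MIN, upper = 1,
                              objective = obj_k)
  }

  params$beta <- beta
  params$lam <- lam
  params$p <- p
  params
}

# damped Newton step for a scalar coordinate, with bounded line-search
# fallback when the step is non-finite or the curvature is not negative.
# When the predicted objective gain is negligible the (expensive) ascent
# check is skipped: the step is a contraction toward a local maximum.
.newton_scalar <- function(x, g, h, lower, upper, objective) {
  if (abs(g) < 1e-12 && abs(h) < 1e-12) return(x)
  delta <- if (is.finite(g) && is.finite(h) && h < 0) -g / h else NA_real_
  if (!is.finite(delta)) {
    hi <- if (is.finite(upper)) upper else x * 8
    opt <- stats::optimize(objective, c(lower, hi), maximum = TRUE)
    return(opt$maximum)
  }
  if (abs(g * delta) < 1e-3) {
    return(min(max(x + delta, lower), upper))
  }
  q_old <- objective(x)
  for (half in 1:10) {
    x_new <- min(max(x + delta, lower), upper)
    if (objective(x_new) >= q_old - 1e-9) return(x_new)
    delta <- delta / 2
  }
  x
}

#' Fit the factorial HMM by EM
#'
#' Alternates [forward_backward()] and [m_step()] until the relative
#' log-likelihood increment `Inc = 2|LL_n - LL_{n-1}| / (|LL_n| + |LL_{n-1}|)`
#' drops below `tol` or `max_iter` is reached.
#'
#' @param records Preprocessed SNP records.
#' @param init Initial `hmm_params`.
#' @param max_iter Maximum EM iterations (default 100); `0` returns the
#'   initial parameters with their log-likelihood.
#' @param tol Convergence threshold on `Inc` (default 1e-4).
#' @param control Passed to [m_step()].
#' @return List with `params`, `posterior` (matching `params`), and
#'   `ll_trace`.
#' @export
run_em <- function(records, init, max_iter = 100L, tol = 1e-4,
                   control = list()) {
  params <- init
  post <- forward_backward(records, params)
  trace <- post$loglik
  if (max_iter >= 1L) {
    for (it in seq_len(max_iter)) {
      params <- m_step(post, records, params, control = control)
      post_new <- forward_backward(records, params)
      ll_prev <- post$loglik
      ll_new <- post_new$loglik
      if (ll_new < ll_prev - 1e-6 * abs(ll_prev)) {
        warning(sprintf(
          "log-likelihood decreased at EM iteration %d (%.6g -> %.6g)",
          it, ll_prev, ll_new))
      }
      trace <- c(trace, ll_new)
      post <- post_new
      inc <- 2 * abs(ll_new - ll_prev) / (abs(ll_new) + abs(ll_prev))
      if (inc < tol) break
    }
  }
  list(params = params, posterior = post, ll_trace = trace)
}

#' Default initial parameters for a given cluster count
#'
#' @param records SNP records.
#' @param states State table.
#' @param K Number of clusters.
#' @param beta_K0 Initial top-cluster cellularity; lower clusters start at
#'   evenly spaced fractions of it.
#' @return `hmm_params` object.
#' @export
init_params <- function(records, states, K, beta_K0) {
  make_hmm_params(states,
                  beta = beta_K0 * seq_len(K) / K,
                  lam = stats::median(records$d),
                  p = 0.5,
                  het_sel = attr(records, "het_sel"))
}

#' Grid-searched EM initialization
#'
#' Runs a few EM iterations from every point of the initialization grid
#' (top-cluster cellularity `beta_K0` in `beta_grid`, lower clusters at
#' evenly spaced fractions of it), optionally augmented with warm-start
#' candidates derived from a previously fitted `(K-1)`-cluster model, then
#' runs the best short fit to convergence. Deterministic given the grid and
#' the record order; failing starts are skipped with a message.
#'
#' @param records Preprocessed SNP records.
#' @param K Number of clonal clusters.
#' @param states State table (default [enumerate_states()]).
#' @param control List: `beta_grid` (default `c(0.2, 0.35, 0.5, 0.65, 0.8,
#'   0.95)`), `short_iter` (default 3), `max_iter` (default 100), `tol`
#'   (default 1e-4), `warm` (optional `hmm_params` of a smaller model whose
#'   split variants join the start list).
#' @return The best fit, as returned by [run_em()], plus `init_beta` (the
#'   initial top-cluster cellularity of the winning start, NA for a warm
#'   start).
#' @export
grid_search_init <- function(records, K, states = enumerate_states(),
                             control = list()) {
  grid <- control$beta_grid %||% c(0.2, 0.35, 0.5, 0.65, 0.8, 0.95)
  short_iter <- control$short_iter %||% 3L
  max_iter <- control$max_iter %||% 100L
  tol <- control$tol %||% 1e-4

  warm <- control$warm
  if (!is.null(warm) && warm$K == K - 1L) {
    # warm split candidates carry most of the signal; keep a small cold grid
    grid <- control$cold_grid %||% c(0.5, 0.9)
  }
  inits <- lapply(grid, function(b0) init_params(records, states, K, b0))
  init_beta <- grid
  if (!is.null(warm) && warm$K == K - 1L) {
    inits <- c(inits, .warm_splits(warm, states))
    init_beta <- c(init_beta, rep(NA_real_, length(inits) - length(grid)))
  }
  shorts <- lapply(inits, function(ip) {
    tryCatch(run_em(records, ip, max_iter = short_iter, tol = tol),
             error = function(e) {
               message("EM start failed: ", conditionMessage(e))
               NULL
             })
  })
  ok <- !vapply(shorts, is.null, logical(1))
  if (!any(ok)) stop("all EM starts failed")
  lls <- rep(-Inf, length(shorts))
  lls[ok] <- vapply(shorts[ok], function(f) f$posterior$loglik, numeric(1))
  best_i <- which.max(lls)
  best <- shorts[[best_i]]
  fit <- run_em(records, best$params, max_iter = max_iter, tol = tol)
  fit$ll_trace <- c(best$ll_trace, fit$ll_trace[-1])
  fit$init_beta <- init_beta[best_i]
  fit
}

# warm-start candidates for K clusters from a fitted (K-1)-cluster model:
# a new cellularity below the lowest, in the largest gap, or above the top,
# keeping the fitted lam and p
.warm_splits <- function(warm, states) {
  b <- warm$beta
  cand <- list(c(b[1] / 2, b))
  gaps <- diff(c(0, b))
  j <- which.max(gaps)
  lo <- if (j == 1) max(0.05, b[1] / 4) else b[j - 1]
  cand[[length(cand) + 1L]] <- sort(c(b, (lo + b[j]) / 2))
  cand[[length(cand) + 1L]] <- sort(c(b, min(1, max(b) * 1.3)))
  cand <- unique(lapply(cand, function(x) {
    x <- pmin(pmax(x, .BETA_MIN), 1)
    # enforce strict ordering with a minimal gap
    for (i in seq_along(x)[-1]) {
      if (x[i] <= x[i - 1]) x[i] <- min(1, x[i - 1] + 0.01)
    }
    round(x, 6)
  }))
  cand <- Filter(function(x) !any(duplicated(x)), cand)
  lapply(cand, function(x) {
    make_hmm_params(states, beta = x, lam = warm$lam, p = warm$p,
                    rho_state = warm$rho_state,
                    rho_cluster = warm$rho_cluster,
                    mirror = warm$mirror, het_sel = warm$het_sel)
  })
}
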