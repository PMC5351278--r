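states7 <- enumerate_states(7)
state_of <- function(nt, nm) {
  states7[states7$n_total == nt & states7$n_major == nm, ]
}

test_that("mixture copy numbers follow the two-population algebra", {
  # copy-neutral het: z = 1 and y = 2 at any cellularity
  for (b in c(0.1, 0.5, 1)) {
    expect_equal(mixed_b_copy(state_of(2, 1), b), 1)
    expect_equal(mixed_total_copy(state_of(2, 1), b), 2)
  }
  expect_equal(mixed_b_copy(state_of(3, 2), 1), 2)
  expect_equal(mixed_b_copy(state_of(0, 0), 0.5), 0.5)  # 2*0.5*0.5 + 0
  expect_equal(mixed_total_copy(state_of(4, 2), 0.5), 3)
  expect_equal(mixed_total_copy(state_of(0, 0), 1), 0)
  # rc_mean is affine in beta with slope lam * (n_c - 2) / 2
  lam <- 30
  for (nt in c(0, 1, 3, 5)) {
    st <- state_of(nt, max(nt, ceiling(nt / 2)))
    slope <- (rc_mean(st, 0.8, lam) - rc_mean(st, 0.3, lam)) / 0.5
    expect_equal(slope, lam * (nt - 2) / 2, tolerance = 1e-10)
  }
})

test_that("baf_loglik matches direct binomial-mixture evaluation", {
  # copy-neutral state: q = 1/2 closed form, symmetric in b <-> T-b
  st <- state_of(2, 1)
  for (b in c(0, 7, 15)) {
    expect_equal(baf_loglik(b, 30, st, 0.7),
                 lchoose(30, b) + 30 * log(0.5), tolerance = 1e-12)
    expect_equal(baf_loglik(b, 30, st, 0.7),
                 baf_loglik(30 - b, 30, st, 0.7))
  }
  # NLOH at beta 0.5: q = 0.75, mixture of Binom(10,.75) and Binom(10,.25)
  st <- state_of(2, 2)
  expect_equal(baf_loglik(3, 10, st, 0.5),
               log(0.5 * dbinom(3, 10, 0.75) + 0.5 * dbinom(3, 10, 0.25)),
               tolerance = 1e-12)
  # normalization over the full support
  for (nt in c(0, 2, 3, 5)) {
    st <- state_of(nt, max(nt, ceiling(nt / 2)))
    for (T_depth in c(10, 50)) {
      total <- sum(exp(vapply(0:T_depth, baf_loglik, numeric(1),
                              T_depth = T_depth, state = st,
                              beta_k = 0.6)))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  }
  # more tumor -> higher likelihood of skewed data under an LOH state,
  # for data at least as skewed as the largest modeled BAF
  skew <- vapply(seq(0.05, 0.95, by = 0.1), function(bk) {
    baf_loglik(30, 30, state_of(2, 2), bk)
  }, numeric(1))
  expect_true(all(diff(skew) >= -1e-12))
})

test_that("rc_loglik is the mean-lambda negative binomial", {
  st <- state_of(2, 1)
  # agrees with dnbinom under the size/prob mapping
  r <- 30 * (1 - 0.2) / 0.2
  for (d in c(0, 10, 30, 100)) {
    expect_equal(rc_loglik(d, st, 0.5, 30, 0.2),
                 dnbinom(d, size = r, prob = 1 - 0.2, log = TRUE),
                 tolerance = 1e-12)
  }
  # moment identity: the distribution's mean equals lambda_{c,k}
  d <- 0:500
  pmf <- exp(rc_loglik(d, st, 0.5, 30, 0.2))
  expect_equal(sum(d * pmf), 30, tolerance = 1e-6)
  expect_equal(sum(pmf), 1, tolerance = 1e-8)
  # guarded mean at the degenerate state
  expect_equal(rc_mean(state_of(0, 0), 1, 30), 0.03)
  # small-p limit approaches Poisson
  d <- 0:200
  nb <- exp(rc_loglik(d, st, 0.5, 30, 1e-3))
  expect_lt(max(abs(nb - dpois(d, 30))), 1e-3)
})

test_that("site_loglik composes the two emission terms", {
  params <- list(beta = c(0.3, 0.7), lam = 30, p = rep(0.25, nrow(states7)))
  set.seed(42)
  for (i in 1:100) {
    st <- states7[sample(nrow(states7), 1), ]
    k <- sample(2, 1)
    rec <- list(d = rpois(1, 35), b = rbinom(1, 30, 0.5), T = 30,
                is_het = runif(1) < 0.5)
    expected <- rc_loglik(rec$d, st, params$beta[k], params$lam,
                          params$p[st$index + 1]) +
      if (rec$is_het) baf_loglik(rec$b, rec$T, st, params$beta[k]) else 0
    expect_equal(site_loglik(rec, st, k, params), expected,
                 tolerance = 1e-12)
  }
  # copy-neutral het sites are cellularity-free
  rec <- list(d = 28, b = 14, T = 31, is_het = TRUE)
  expect_equal(site_loglik(rec, state_of(2, 1), 1, params),
               site_loglik(rec, state_of(2, 1), 2, params))
})

test_that("vectorized emission matrix matches the independent oracle", {
  sim <- small_sim(n_snps = 300, seed = 2)
  params <- make_hmm_params(states7, beta = c(0.35, 0.6), lam = 29,
                            p = 0.3)
  ep <- subcloneCN:::.emission_pars(states7, params$beta, params$lam,
                                    params$p)
  E <- subcloneCN:::.emission_loglik(sim$records, ep)
  expect_equal(E, oracle_emission(sim$records, params), tolerance = 1e-10)
})
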