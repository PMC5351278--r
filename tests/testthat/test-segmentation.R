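st7 <- enumerate_states(7)

# minimal posterior object with a given gamma
fake_post <- function(gamma, C, K) list(gamma = gamma, C = C, K = K)

test_that("decode takes the max-posterior joint state with the tie rule", {
  C <- 4; K <- 2
  g <- matrix(0.01, 3, C * K)
  g[1, (1 - 1) * C + 3] <- 0.9   # (c=3, k=1)
  g[2, (2 - 1) * C + 1] <- 0.9   # (c=1, k=2)
  # exact tie between (c=1,k=2) and (c=2,k=1): lower c wins
  g[3, ] <- 0
  g[3, (2 - 1) * C + 1] <- 0.5
  g[3, (1 - 1) * C + 2] <- 0.5
  a <- decode(fake_post(g, C, K))
  expect_equal(a$c, c(3, 1, 1))
  expect_equal(a$k, c(1, 2, 2))
  expect_equal(a$posterior[1], 0.9)
})

test_that("merge_segments produces maximal runs and absorbs islands", {
  n <- 9
  rec <- data.frame(chrom = "chr1", pos = (1:n) * 1000, d = 30,
                    b = 15, T = 30, is_het = TRUE)
  asg <- data.frame(c = c(1, 1, 1, 2, 2, 2, 1, 1, 1), k = 1,
                    posterior = 1)
  segs <- merge_segments(asg, rec, min_snps = 1)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$n_snps, c(3, 3, 3))
  expect_equal(segs$start, c(1000, 4000, 7000))
  expect_equal(segs$end, c(3000, 6000, 9000))

  # a 3-SNP island below min_snps = 5 is absorbed -> one segment
  segs2 <- merge_segments(asg, rec, min_snps = 5)
  expect_equal(nrow(segs2), 1)
  expect_equal(segs2$n_snps, n)

  # uniform assignment: one segment per chromosome
  rec$chrom <- rep(c("chr1", "chr2"), c(5, 4))
  asg1 <- data.frame(c = 2, k = 1, posterior = 1)[rep(1, n), ]
  segs3 <- merge_segments(asg1, rec, min_snps = 1)
  expect_equal(nrow(segs3), 2)

  # segments tile the SNP index space exactly
  covered <- unlist(Map(seq, segs$i_start, segs$i_end))
  expect_identical(sort(covered), 1:n)
})

test_that("reliability_score is 100 at the mode and decays in the tails", {
  params <- make_hmm_params(st7, beta = 0.6, lam = 30, p = 0.3)
  c_idx <- which(st7$n_total == 2 & st7$n_major == 1)
  n <- 20
  rec <- data.frame(chrom = "chr1", pos = (1:n) * 1000, d = 30,
                    b = 15, T = 30, is_het = TRUE)
  seg <- data.frame(i_start = 1, i_end = n, c = c_idx, k = 1)
  expect_equal(reliability_score(seg, rec, params), 100)

  # observations far in the tails push the score toward 0
  rec_bad <- rec
  rec_bad$d <- 150
  rec_bad$b <- 29
  expect_lt(reliability_score(seg, rec_bad, params), 1)

  # score under the true state beats the score under a wrong state
  set.seed(77)
  wins <- 0
  c_nloh <- which(st7$n_total == 2 & st7$n_major == 2)
  for (rep in 1:20) {
    m <- 30
    q <- (1 - 0.6) + 2 * 0.6  # z of NLOH at beta 0.6 over y = 2
    rr <- data.frame(chrom = "chr1", pos = (1:m) * 1000,
                     d = rnbinom(m, mu = 30, size = 70),
                     T = rpois(m, 30) + 1)
    rr$b <- rbinom(m, rr$T, q / 2)
    rr$is_het <- TRUE
    sg_true <- data.frame(i_start = 1, i_end = m, c = c_nloh, k = 1)
    sg_wrong <- data.frame(i_start = 1, i_end = m, c = c_idx, k = 1)
    if (reliability_score(sg_true, rr, params) >
          reliability_score(sg_wrong, rr, params)) wins <- wins + 1
  }
  expect_gte(wins, 18)

  # homozygous-only segment falls back to the read-count ratio
  rec_hom <- rec
  rec_hom$is_het <- FALSE
  s_hom <- reliability_score(seg, rec_hom, params)
  expect_true(s_hom >= 0 && s_hom <= 100)
})

test_that("segment and SNP tables round-trip and the BED is 0-based", {
  sim <- small_sim(n_snps = 1200, seed = 41)
  params <- make_hmm_params(st7, beta = 0.5, lam = 30, p = 0.3)
  post <- forward_backward(sim$records, params)
  asg <- decode(post)
  segs <- merge_segments(asg, sim$records, min_snps = 10, posterior = post)
  ann <- annotate_segments(segs, sim$records, params)
  expect_true(all(ann$score >= 0 & ann$score <= 100))
  expect_true(all(ann$start <= ann$end))
  # adjacent segments differ in (state, cluster)
  for (ch in unique(segs$chrom)) {
    s <- segs[segs$chrom == ch, ]
    if (nrow(s) > 1) {
      expect_true(all(s$c[-1] != s$c[-nrow(s)] |
                        s$k[-1] != s$k[-nrow(s)]))
    }
  }
  path <- tempfile(fileext = ".tsv")
  write_segments(ann, path, params)
  back <- read_segments(path)
  expect_equal(back$start, ann$start)
  expect_equal(back$total_cn, ann$total_cn)
  expect_equal(back$cellularity, ann$cellularity, tolerance = 1e-9)
  expect_equal(nrow(back), nrow(ann))

  bed <- tempfile(fileext = ".bed")
  write_segments_bed(ann, bed)
  bed_tab <- read.delim(bed, header = FALSE)
  expect_equal(bed_tab$V2, ann$start - 1)
  expect_equal(bed_tab$V3, ann$end)

  snp_path <- tempfile(fileext = ".tsv")
  write_snp_calls(asg, sim$records, snp_path, params)
  snp_back <- read.delim(snp_path, comment.char = "#")
  expect_equal(nrow(snp_back), nrow(sim$records))
  expect_equal(snp_back$state, asg$c - 1)
})
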