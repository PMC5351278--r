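# End-to-end pipeline: preprocess -> select K by incremental BIC ->
# decode/segment/score.

#' Call clonal and subclonal CNA/LOH segments
#'
#' Runs the full analysis on a preprocessed SNP table: cluster-number
#' selection by the incremental BIC rule, max-posterior decoding,
#' segmentation with reliability scores.
#'
#' @param records SNP records; if `is_het` is not yet set the standard
#'   preprocessing ([preprocess_snp_table()]) is applied first.
#' @param alpha BIC regularization weight. The default 0.002 is calibrated
#'   to the desk-scale reference of 20,000 SNPs (see the methods vignette);
#'   the selected K is monotone non-increasing in `alpha`.
#' @param K_max Maximum cluster count (default 5).
#' @param max_copy Copy-number ceiling of the state space (default 7).
#' @param min_snps Minimum segment length in SNPs (default 10).
#' @param control EM control list (see [grid_search_init()]).
#' @return List with `records` (preprocessed), `fit` (selected model),
#'   `model_table` (per-K log-likelihood and dBIC), `assignments` (per-SNP
#'   calls), `segments` (annotated segment table), `clusters`
#'   (`cluster cellularity`), `purity`.
#' @export
call_subclones <- function(records, alpha = 0.002, K_max = 5L, max_copy = 7L,
                           min_snps = 10L, control = list()) {
  if (all(is.na(records$is_het))) {
    records <- preprocess_snp_table(records)
  }
  states <- enumerate_states(max_copy)
  sel <- select_num_clusters(records, K_max = K_max, alpha = alpha,
                             states = states, control = control)
  fit <- sel$best
  assignments <- decode(fit$posterior)
  segs <- merge_segments(assignments, records, min_snps = min_snps,
                         posterior = fit$posterior)
  segments <- annotate_segments(segs, records, fit$params)
  clusters <- data.frame(cluster = seq_len(fit$params$K),
                         cellularity = fit$params$beta)
  list(records = records, fit = fit, model_table = sel$table,
       assignments = assignments, segments = segments,
       clusters = clusters, purity = max(fit$params$beta))
}

#' Default simulated-mixture battery
#'
#' Twelve mixtures spanning one, two and three clonal populations, including
#' the worked compositions of the simulation study design (e.g.
#' `a_010b_030n_060` with clusters \{0.3, 0.4\}).
#'
#' @return Data frame with `name` and `n_clones`.
#' @export
default_battery <- function() {
  data.frame(
    name = c(
      "a_020n_080", "a_040n_060", "a_060n_040", "a_080n_020",
      "a_010b_030n_060", "a_020b_030n_050", "a_030b_040n_030",
      "a_040b_020n_040",
      "a_020b_035c_025n_020", "a_010b_010d_025n_055",
      "a_035b_015d_025n_025", "a_030b_025c_015n_030"
    ),
    n_clones = c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3)
  )
}

#' Simulate and analyze a battery of tumor mixtures
#'
#' For each mixture: build the clone lineage, simulate a sample, run the
#' full pipeline, and score against the truth. Seeds are derived
#' deterministically from `seed`.
#'
#' @param seed Master integer seed.
#' @param n_snps SNPs per sample (default 20000).
#' @param battery Battery table ([default_battery()]).
#' @param coverage Mean normal-copy read count (default 30).
#' @param control EM control list.
#' @param verbose Print per-sample progress (default FALSE).
#' @return List with `per_sample` (one metrics row per mixture, including
#'   the mixture name), `cellularity_pairs` (pooled rank-matched truth /
#'   estimate pairs), `truth_clusters` and `estimated_clusters` (lists).
#' @export
run_mixture_battery <- function(seed, n_snps = 20000L,
                                battery = default_battery(),
                                coverage = 30, control = list(),
                                verbose = FALSE) {
  truth_list <- list()
  est_list <- list()
  rows <- list()
  for (i in seq_len(nrow(battery))) {
    name <- battery$name[i]
    sample_seed <- (seed * 1000L + i) %% .Machine$integer.max
    genomes <- default_genomes(sample_seed)
    spec <- list(proportions = parse_mixture_name(name),
                 coverage = coverage, n_snps = n_snps, seed = sample_seed)
    sim <- simulate_sample(spec, genomes)
    t0 <- Sys.time()
    res <- call_subclones(sim$records, control = control)
    if (verbose) {
      message(sprintf("%s: K_true=%d K_est=%d purity %.2f->%.2f (%.1fs)",
                      name, length(sim$truth_clusters),
                      nrow(res$clusters), sim$purity, res$purity,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
    ev <- evaluate_sample(sim, res)
    ev <- cbind(data.frame(name = name, n_clones = battery$n_clones[i]), ev)
    rows[[i]] <- ev
    truth_list[[i]] <- sim$truth_clusters
    est_list[[i]] <- res$clusters$cellularity
  }
  per_sample <- do.call(rbind, rows)
  cm <- cellularity_metrics(truth_list, est_list)
  list(per_sample = per_sample, cellularity_pairs = cm$pairs,
       pooled_pearson_r = cm$pearson_r, pooled_mae = cm$mae,
       truth_clusters = truth_list, estimated_clusters = est_list)
}
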