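# Synthetic heterogeneous tumor mixtures. A normal genome (n) and up to four
# phylogenetically related tumor clone genomes (a, b, c, d; b and c derive
# from a, d derives from b) are mixed at chosen proportions; per-SNP window
# read counts and allelic depths are then drawn at the distribution level
# (negative binomial / Poisson / binomial) so the first moments match the
# mixture copy numbers. This replaces read-level BAM resampling and yields
# exact truth segments and cluster cellularities.

.LINEAGE <- c(a = "root", b = "a", c = "a", d = "b")

# clones that carry an event introduced by `clone`: itself plus descendants
.carriers <- function(clone) {
  kids <- names(.LINEAGE)[.LINEAGE == clone]
  out <- clone
  for (k in kids) out <- c(out, .carriers(k))
  out
}

# run RNG-dependent code under a local, restorable seed
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Parse a mixture name into clone proportions
#'
#' Mixture names follow the convention `"a_010b_030n_060"`: clone letter,
#' underscore, three-digit percentage. Proportions must sum to 1.
#'
#' @param name Mixture name string.
#' @return Named numeric vector of proportions (names among `a,b,c,d,n`).
#' @examples
#' parse_mixture_name("a_010b_030n_060")
#' @export
parse_mixture_name <- function(name) {
  m <- gregexpr("([abcdn])_([0-9]{3})", name)[[1]]
  if (m[1] == -1) stop("malformed mixture name: ", name)
  toks <- regmatches(name, gregexpr("([abcdn])_([0-9]{3})", name))[[1]]
  if (sum(attr(m, "match.length")) != nchar(name)) {
    stop("malformed mixture name: ", name)
  }
  props <- as.numeric(substr(toks, 3, 5)) / 100
  names(props) <- substr(toks, 1, 1)
  if (anyDuplicated(names(props))) stop("duplicate clone in mixture name")
  if (abs(sum(props) - 1) > 1e-9) {
    stop("mixture proportions must sum to 1 (got ", sum(props), ")")
  }
  props
}

#' Build a default lineage of clone genomes
#'
#' Genome `a` (the main clone) receives `n_segments_per_clone` aberrant
#' segments over two synthetic chromosomes, with copy-number states drawn
#' from \{(1,1),(2,2),(3,2),(4,2),(4,3),(5,3)\} and copy-neutral (2,1) gaps
#' between them. Genomes `b`, `c` and `d` each introduce 4-6 new events on
#' intervals that are copy-neutral in every other clone, so each locus
#' carries at most one aberrant genotype (the model's single-aberration
#' assumption). The layout is deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param n_segments_per_clone Number of aberrant segments of clone `a`
#'   (default 12).
#' @param chrom_lengths Named lengths (bp) of the synthetic chromosomes.
#' @return Named list of clone genomes; each genome is a list with `name`,
#'   `parent` and an `events` data frame
#'   (`chrom start end total_cn major_cn`). The normal genome `n` has no
#'   events.
#' @export
default_genomes <- function(seed, n_segments_per_clone = 12L,
                            chrom_lengths = c(chr1 = 1e7, chr2 = 1e7)) {
  .with_seed(seed, {
    n_sub <- stats::setNames(sample(4:6, 3, replace = TRUE), c("b", "c", "d"))
    n_events <- n_segments_per_clone + sum(n_sub)
    # carve alternating gap/event slots along the chromosomes
    slots <- list()
    for (chrom in names(chrom_lengths)) {
      pos <- 1
      len <- chrom_lengths[[chrom]]
      repeat {
        pos <- pos + round(stats::runif(1, 1e5, 4e5))  # neutral gap
        ev_len <- round(stats::runif(1, 1.5e5, 5e5))
        if (pos + ev_len > len) break
        slots[[length(slots) + 1L]] <- c(pos, pos + ev_len - 1)
        names(slots)[length(slots)] <- chrom
        pos <- pos + ev_len
      }
    }
    if (length(slots) < n_events) {
      stop("chromosomes too short for the requested number of events")
    }
    use <- sample(seq_along(slots), n_events)
    owners <- rep(c("a", "b", "c", "d"),
                  times = c(n_segments_per_clone, n_sub))
    a_states <- rbind(c(1, 1), c(2, 2), c(3, 2), c(4, 2), c(4, 3), c(5, 3))
    genomes <- list()
    for (clone in c("a", "b", "c", "d")) {
      idx <- use[owners == clone]
      st <- a_states[sample(nrow(a_states), length(idx), replace = TRUE), ,
                     drop = FALSE]
      ev <- data.frame(
        chrom = names(slots)[idx],
        start = vapply(slots[idx], `[`, numeric(1), 1),
        end = vapply(slots[idx], `[`, numeric(1), 2),
        total_cn = st[, 1],
        major_cn = st[, 2]
      )
      ev <- ev[order(ev$chrom, ev$start), , drop = FALSE]
      rownames(ev) <- NULL
      genomes[[clone]] <- list(
        name = clone,
        parent = if (clone == "a") NA_character_ else .LINEAGE[[clone]],
        events = ev
      )
    }
    genomes$n <- list(name = "n", parent = NA_character_,
                      events = genomes$a$events[0, ])
    attr(genomes, "chrom_lengths") <- chrom_lengths
    genomes
  })
}

#' Truth cellularities of a mixture
#'
#' An event introduced by clone `g` is carried by `g` and all of its
#' descendants; its cellularity is the summed mixture proportion of those
#' carriers. The distinct event cellularities (sorted ascending) are the
#' clonal-cluster cellularities, and tumor purity is `1 - p_n`.
#'
#' @param proportions Named proportions (see [parse_mixture_name()]), must
#'   sum to 1.
#' @param genomes Clone genomes from [default_genomes()] (used to know which
#'   clones actually carry events).
#' @return List with `clusters` (ascending cellularities), `event_cellularity`
#'   (named by introducing clone), and `purity`.
#' @export
truth_cellularities <- function(proportions, genomes = NULL) {
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1")
  }
  clones <- intersect(c("a", "b", "c", "d"), names(.LINEAGE))
  cell <- vapply(clones, function(g) {
    sum(proportions[intersect(.carriers(g), names(proportions))])
  }, numeric(1))
  # clones with no events in the genome set introduce no cluster
  if (!is.null(genomes)) {
    has_events <- vapply(clones, function(g) {
      !is.null(genomes[[g]]) && nrow(genomes[[g]]$events) > 0
    }, logical(1))
    cell <- cell[has_events]
  }
  cell <- cell[cell > 0]
  purity <- 1 - ifelse(is.na(proportions["n"]), 0, proportions["n"])
  list(clusters = sort(unique(unname(cell))),
       event_cellularity = cell,
       purity = unname(purity))
}

# per-locus (total, major) copy numbers of one genome, given the disjoint
# event layout: a clone's genotype at a locus is its own or an inherited event
.genome_events <- function(genomes, clone) {
  if (clone == "n") return(genomes$n$events)
  chain <- clone
  while (!is.na(genomes[[chain[1]]]$parent)) {
    chain <- c(genomes[[chain[1]]]$parent, chain)
  }
  do.call(rbind, lapply(chain, function(g) genomes[[g]]$events))
}

#' Simulate one tumor-mixture sample
#'
#' Places `n_snps` SNPs on a regular grid (`snp_spacing` bp) across the
#' synthetic chromosomes and draws, per SNP: window read count
#' `d ~ NB(mean = coverage * y*/2, prob = nb_p)`, total allelic depth
#' `T ~ Poisson(coverage * y*/2)` floored at 1, and B-allele depth
#' `b ~ Binomial(T, z*/y*)`, where `y*` and `z*` are the mixture total and
#' B-allele copy numbers. A fraction `het_rate` of SNPs is heterozygous in
#' the germline (B allele on the major or minor haplotype with equal
#' probability); the rest are homozygous (BAF 0 or 1).
#'
#' @param spec List with `proportions` (named, summing to 1), and optionally
#'   `coverage` (default 30), `n_snps` (default 20000), `snp_spacing` (bp;
#'   by default chosen per chromosome so the grid spans the whole genome --
#'   1000 bp at the default 20000 SNPs over two 10-Mb chromosomes), `seed`
#'   (default 1), `nb_p` (NB success probability, default 0.3), `het_rate`
#'   (default 1/3), `allelic_bias` (multiplier on the B-allele success
#'   probability at heterozygous sites, default 1; used to exercise the
#'   allelic-depth normalizer).
#' @param genomes Clone genomes from [default_genomes()].
#' @return List with `records` (SNP table, including `gc` and `mappability`
#'   columns), `truth_segments`
#'   (`chrom start end total_cn major_cn cellularity`, `cellularity = NA` on
#'   copy-neutral segments), `truth_clusters` (ascending cellularities) and
#'   `purity`.
#' @export
simulate_sample <- function(spec, genomes) {
  props <- spec$proportions
  if (abs(sum(props) - 1) > 1e-9) stop("proportions must sum to 1")
  coverage <- spec$coverage %||% 30
  n_snps <- spec$n_snps %||% 20000L
  seed <- spec$seed %||% 1L
  nb_p <- spec$nb_p %||% 0.3
  het_rate <- spec$het_rate %||% (1 / 3)
  bias <- spec$allelic_bias %||% 1

  chrom_lengths <- attr(genomes, "chrom_lengths")
  n_chrom <- length(chrom_lengths)
  per_chrom <- rep(n_snps %/% n_chrom, n_chrom)
  per_chrom[1] <- per_chrom[1] + n_snps %% n_chrom
  chrom <- rep(names(chrom_lengths), per_chrom)
  # unless a spacing is forced, spread the SNP grid over the whole genome so
  # a reduced n_snps means lower marker density, not a truncated genome
  pos <- unlist(lapply(seq_len(n_chrom), function(i) {
    m <- per_chrom[i]
    spacing <- spec$snp_spacing %||% max(floor(chrom_lengths[[i]] / m), 1)
    spacing %/% 2 + (seq_len(m) - 1) * spacing
  }), use.names = FALSE)

  present <- names(props)[props > 0]
  # per-genome copy numbers at every SNP
  total_g <- matrix(2, nrow = n_snps, ncol = length(present),
                    dimnames = list(NULL, present))
  major_g <- matrix(1, nrow = n_snps, ncol = length(present),
                    dimnames = list(NULL, present))
  for (g in present) {
    ev <- .genome_events(genomes, g)
    if (is.null(ev) || nrow(ev) == 0) next
    for (j in seq_len(nrow(ev))) {
      hit <- chrom == ev$chrom[j] & pos >= ev$start[j] & pos <= ev$end[j]
      total_g[hit, g] <- ev$total_cn[j]
      major_g[hit, g] <- ev$major_cn[j]
    }
  }
  w <- props[present]
  y_star <- as.vector(total_g %*% w)
  z_major <- as.vector(major_g %*% w)
  z_minor <- y_star - z_major

  .with_seed(seed, {
    is_het <- stats::runif(n_snps) < het_rate
    b_on_major <- stats::runif(n_snps) < 0.5
    hom_alt <- stats::runif(n_snps) < 0.5
    z_star <- ifelse(is_het, ifelse(b_on_major, z_major, z_minor),
                     ifelse(hom_alt, y_star, 0))
    mu_d <- coverage * y_star / 2
    d <- stats::rnbinom(n_snps, mu = pmax(mu_d, 1e-6),
                        size = pmax(mu_d, 1e-6) * (1 - nb_p) / nb_p)
    T_depth <- pmax(stats::rpois(n_snps, pmax(mu_d, 1e-6)), 1)
    q <- pmin(pmax(z_star / pmax(y_star, 1e-9), 0.005), 0.995)
    q <- ifelse(is_het, pmin(pmax(q * bias, 0.005), 0.995), q)
    b <- stats::rbinom(n_snps, T_depth, q)
    records <- data.frame(
      chrom = chrom, pos = pos, d = d, b = b, T = T_depth,
      gc = round(stats::runif(n_snps, 0.3, 0.6), 4),
      mappability = round(stats::runif(n_snps, 0.8, 1.0), 4),
      is_het = NA
    )
    attr(records, "truth_is_het") <- is_het

    tc <- truth_cellularities(props, genomes)
    truth <- .truth_segments(genomes, present, tc$event_cellularity,
                             chrom, pos)
    list(records = records, truth_segments = truth,
         truth_clusters = tc$clusters, purity = tc$purity)
  })
}

# maximal constant-(total, major, cellularity) intervals of the mixture,
# clipped to the simulated SNP grid; neutral stretches get cellularity NA
.truth_segments <- function(genomes, present, event_cell, chrom, pos) {
  segs <- list()
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    lo <- min(p); hi <- max(p)
    evs <- list()
    for (g in intersect(c("a", "b", "c", "d"), present)) {
      ev <- genomes[[g]]$events
      ev <- ev[ev$chrom == ch & ev$end >= lo & ev$start <= hi, , drop = FALSE]
      if (nrow(ev)) {
        ev$cellularity <- unname(event_cell[g])
        evs[[g]] <- ev
      }
    }
    evs <- do.call(rbind, evs)
    if (is.null(evs) || nrow(evs) == 0) {
      segs[[ch]] <- data.frame(chrom = ch, start = lo, end = hi,
                               total_cn = 2, major_cn = 1,
                               cellularity = NA_real_)
      next
    }
    evs <- evs[order(evs$start), , drop = FALSE]
    rows <- list()
    cur <- lo
    for (j in seq_len(nrow(evs))) {
      if (evs$start[j] > cur) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = cur, end = evs$start[j] - 1,
          total_cn = 2, major_cn = 1, cellularity = NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = max(evs$start[j], lo),
        end = min(evs$end[j], hi),
        total_cn = evs$total_cn[j], major_cn = evs$major_cn[j],
        cellularity = evs$cellularity[j])
      cur <- evs$end[j] + 1
    }
    if (cur <= hi) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = cur, end = hi, total_cn = 2, major_cn = 1,
        cellularity = NA_real_)
    }
    segs[[ch]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Write simulator truth files
#'
#' Writes `truth_segments.tsv`
#' (`chrom start end total_cn major_cn cellularity`) and
#' `truth_clusters.tsv` (`cellularity purity`) next to the sample table.
#'
#' @param sim Output of [simulate_sample()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default "sim").
#' @return Invisibly, the paths written.
#' @export
write_truth_files <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg_path <- file.path(dir, paste0(prefix, "_truth_segments.tsv"))
  clu_path <- file.path(dir, paste0(prefix, "_truth_clusters.tsv"))
  utils::write.table(sim$truth_segments, seg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(cellularity = sim$truth_clusters, purity = sim$purity),
    clu_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(segments = seg_path, clusters = clu_path))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
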