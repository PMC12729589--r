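# independent oracles used across test files; these never call the
# implementation paths they check

# exon-level transcript rows from a list of (start, end) pairs
make_tx <- function(id, exons, strand = "+", chrom = "chr1",
                    gene = paste0(id, "_g"), biotype = "novel") {
  tibble::tibble(
    transcript_id = id, gene_id = gene, chrom = chrom, strand = strand,
    start = vapply(exons, `[`, numeric(1), 1),
    end = vapply(exons, `[`, numeric(1), 2),
    biotype = biotype
  )
}

# P(X >= k) by exhaustive enumeration of all C(N, n) draws; elements
# 1..K are the successes
oracle_hyper_enum <- function(k, K, n, N) {
  if (n == 0) {
    return(as.numeric(k <= 0))
  }
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# conditional pmf of the group-A sum given the total, from the
# negative-hypergeometric closed form (independent of the dnbinom route)
oracle_nb_exact <- function(ya, yb, phi) {
  na <- length(ya)
  nb <- length(yb)
  ra <- na / phi
  rb <- nb / phi
  total <- sum(ya) + sum(yb)
  if (total == 0) {
    return(1)
  }
  s <- 0:total
  lp <- lgamma(s + ra) - lgamma(s + 1) - lgamma(ra) +
    lgamma(total - s + rb) - lgamma(total - s + 1) - lgamma(rb) -
    (lgamma(total + ra + rb) - lgamma(total + 1) - lgamma(ra + rb))
  pmf <- exp(lp)
  pmf <- pmf / sum(pmf)
  obs <- pmf[sum(ya) + 1]
  max(sum(pmf[pmf <= obs * (1 + 1e-8)]), obs)
}

# brute-force BH from the min-over-tail definition:
# adjusted_i = min over j with p_(j) >= p_i of p_(j) * m / rank(j), capped
oracle_bh <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    j <- which(sp >= pi - 1e-15)
    min(1, min(sp[j] * m / j))
  }, numeric(1))
}

# count tibble -> plain matrix (tests only)
counts_to_mat <- function(tbl) {
  m <- as.matrix(tbl[setdiff(names(tbl), "feature_id")])
  rownames(m) <- tbl$feature_id
  m
}

# tiny default simulation config shared by several files
small_sim_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(
      seed = seed, n_coding_genes = 30, n_novel_transcripts = 60,
      n_lncrna = 40, n_mrna = 60, n_mirna = 30,
      n_planted_triplets = 5, n_decoy_pairs = 10
    ),
    list(...)
  )
  do.call(simulation_config, args)
}
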