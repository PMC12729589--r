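#' Run the full three-step ceRNA screen on expression matrices
#'
#' Convenience driver that chains the ceRNA screen end to end: target
#' filtering ([filter_targets()]), per-matrix size factors, optional
#' differential-expression gating (only features significant in at least
#' one stage comparison enter the screen), Spearman edge filtering
#' ([spearman_edges()]), pair screening ([screen_pairs()]) and network
#' assembly ([build_network()]). Expression profiles used for the
#' correlations are size-factor-normalized counts.
#'
#' @param lnc,mrna,mirna count tibbles (`feature_id` + sample columns).
#' @param samples sample sheet tibble.
#' @param targets raw target record tibble.
#' @param score_min,energy_max target-prediction thresholds
#'   (defaults 50 and -10).
#' @param rho_max Spearman threshold (default -0.7).
#' @param r_min Pearson threshold (default 0.9).
#' @param p_max hypergeometric p threshold (default 0.05).
#' @param alpha,lfc DE significance thresholds (defaults 0.05 and 1).
#' @param phi NB dispersion for the lncRNA and mRNA tests (default 0.01).
#' @param phi_mirna dispersion for the miRNA test (defaults to `phi`).
#' @param de_gate gate the screen on DE features (default `TRUE`).
#' @param universe_mode,pair_types,all_shared,pair_fdr passed to
#'   [screen_pairs()].
#' @return A list: `targets` (filtered records), `de` (named list of tidy
#'   DE tables for lnc/mrna/mirna), `edges`, `pairs`, `network`.
#' @export
cerna_screen <- function(lnc, mrna, mirna, samples, targets,
                         score_min = 50, energy_max = -10,
                         rho_max = -0.7, r_min = 0.9, p_max = 0.05,
                         alpha = 0.05, lfc = 1,
                         phi = 0.01, phi_mirna = phi,
                         de_gate = TRUE,
                         universe_mode = "filtered",
                         pair_types = "lncRNA-mRNA",
                         all_shared = FALSE, pair_fdr = FALSE) {
  validate_counts_samples(lnc, samples)
  validate_counts_samples(mrna, samples)
  validate_counts_samples(mirna, samples)
  filt <- filter_targets(targets, score_min = score_min, energy_max = energy_max)

  norm_tbl <- function(counts) {
    sf <- tryCatch(size_factors(counts), error = function(e) {
      size_factors(counts, pseudo_reference = TRUE)
    })
    m <- counts_to_matrix(counts)
    fac <- sf$size_factor[match(colnames(m), sf$sample_id)]
    list(norm = matrix_to_counts(sweep(m, 2, fac, "/")), sf = sf)
  }
  nl <- norm_tbl(lnc)
  nm <- norm_tbl(mrna)
  ni <- norm_tbl(mirna)

  de <- list(
    lnc = call_de(lnc, samples, phi = phi, alpha = alpha, lfc = lfc, sf = nl$sf),
    mrna = call_de(mrna, samples, phi = phi, alpha = alpha, lfc = lfc, sf = nm$sf),
    mirna = call_de(mirna, samples, phi = phi_mirna, alpha = alpha, lfc = lfc, sf = ni$sf)
  )

  sig_ids <- function(tbl) unique(tbl$feature_id[tbl$status != "ns"])
  keep_lnc <- if (de_gate) sig_ids(de$lnc) else lnc$feature_id
  keep_mrna <- if (de_gate) sig_ids(de$mrna) else mrna$feature_id
  keep_mirna <- if (de_gate) sig_ids(de$mirna) else mirna$feature_id

  cerna_expr <- bind_rows(
    nl$norm |> filter(.data$feature_id %in% keep_lnc),
    nm$norm |> filter(.data$feature_id %in% keep_mrna)
  )
  mirna_expr <- ni$norm |> filter(.data$feature_id %in% keep_mirna)
  types <- c(
    stats::setNames(rep("lncRNA", nrow(lnc)), lnc$feature_id),
    stats::setNames(rep("mRNA", nrow(mrna)), mrna$feature_id)
  )

  if (nrow(mirna_expr) == 0 || nrow(cerna_expr) == 0) {
    edges <- tibble(mirna_id = character(), cerna_id = character(), rho = numeric())
  } else {
    edges <- spearman_edges(mirna_expr, cerna_expr, filt, rho_max = rho_max)
  }
  pairs <- screen_pairs(
    edges, cerna_expr,
    types = types, r_min = r_min, p_max = p_max,
    universe_mode = universe_mode, mirna_expr = mirna_expr, targets = filt,
    pair_types = pair_types, all_shared = all_shared, pair_fdr = pair_fdr
  )
  network <- build_network(pairs, edges)
  list(targets = filt, de = de, edges = edges, pairs = pairs, network = network)
}

#' Compare screened pairs with a planted ground truth
#'
#' @param pairs screened pairs from [screen_pairs()] or [cerna_screen()].
#' @param truth the `truth` element of [simulate_expression()].
#' @return A one-row tibble: `n_planted`, `n_recovered`, `recovery`,
#'   `n_decoy`, `n_decoy_passed`, `decoy_rate`.
#' @export
evaluate_screen <- function(pairs, truth) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  got <- key(pairs$rna_a, pairs$rna_b)
  planted <- key(truth$planted_pairs$lncrna_id, truth$planted_pairs$mrna_id)
  decoy <- key(truth$decoy_pairs$lncrna_id, truth$decoy_pairs$mrna_id)
  tibble(
    n_planted = length(planted),
    n_recovered = sum(planted %in% got),
    recovery = sum(planted %in% got) / length(planted),
    n_decoy = length(decoy),
    n_decoy_passed = sum(decoy %in% got),
    decoy_rate = if (length(decoy)) sum(decoy %in% got) / length(decoy) else 0
  )
}

#' Independently permute the sample columns of a count tibble
#'
#' Used for label-shuffle null checks: permuting each matrix's columns with
#' its own permutation destroys cross-matrix correlation structure while
#' preserving each feature's marginal distribution.
#'
#' @param counts count tibble.
#' @param seed integer seed for the permutation.
#' @return The permuted tibble (same columns, values shuffled across
#'   samples within the matrix).
#' @export
permute_samples <- function(counts, seed) {
  cols <- setdiff(names(counts), "feature_id")
  perm <- with_seed(seed, sample(cols))
  out <- counts[c("feature_id", perm)]
  names(out) <- c("feature_id", cols)
  out
}
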