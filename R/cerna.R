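#' Filter predicted miRNA-target records
#'
#' Keeps a (miRNA, target) interaction iff it appears in both predictors'
#' outputs (`source == "both"`) and passes both thresholds: TargetScan-style
#' score at least `score_min` and miRanda-style binding energy at most
#' `energy_max`. Records with a missing score automatically fail the
#' corresponding threshold.
#'
#' @param records target record tibble (`mirna_id`, `target_id`,
#'   `targetscan_score`, `miranda_energy`, `source`).
#' @param score_min TargetScan-style score threshold (default 50).
#' @param energy_max miRanda-style energy threshold in kcal/mol
#'   (default -10).
#' @return The retained records, one row per (miRNA, target) pair.
#' @export
filter_targets <- function(records, score_min = 50, energy_max = -10) {
  validate_targets(records)
  records |>
    filter(
      .data$source == "both",
      !is.na(.data$targetscan_score), .data$targetscan_score >= score_min,
      !is.na(.data$miranda_energy), .data$miranda_energy <= energy_max
    ) |>
    distinct(.data$mirna_id, .data$target_id, .keep_all = TRUE)
}

#' Spearman anti-correlation edges between miRNAs and candidate ceRNAs
#'
#' For every filtered (miRNA, target) prediction whose members are present
#' in the expression matrices, computes the Spearman rank correlation
#' (Pearson on mid-ranks, average ranks for ties) of the two expression
#' profiles across the matched samples and keeps the edge iff
#' `rho <= rho_max`. Pairs involving a constant profile have undefined
#' rank correlation and are skipped with a warning.
#'
#' @param mirna_expr miRNA expression tibble (`feature_id` + samples).
#' @param cerna_expr candidate ceRNA expression tibble (lncRNA and/or mRNA
#'   rows) with the same sample columns.
#' @param targets filtered target records from [filter_targets()].
#' @param rho_max Spearman threshold (default -0.7).
#' @return A tibble (`mirna_id`, `cerna_id`, `rho`) of retained edges.
#' @export
spearman_edges <- function(mirna_expr, cerna_expr, targets, rho_max = -0.7) {
  m_mir <- counts_to_matrix(mirna_expr)
  m_cer <- counts_to_matrix(cerna_expr)
  common <- intersect(colnames(m_mir), colnames(m_cer))
  if (length(common) < 3 ||
      length(common) != ncol(m_mir) || length(common) != ncol(m_cer)) {
    abort("miRNA and ceRNA matrices must share the same sample columns (>= 3)")
  }
  m_cer <- m_cer[, colnames(m_mir), drop = FALSE]
  cand <- targets |>
    filter(
      .data$mirna_id %in% rownames(m_mir),
      .data$target_id %in% rownames(m_cer)
    ) |>
    distinct(.data$mirna_id, .data$target_id)
  if (nrow(cand) == 0) {
    return(tibble(mirna_id = character(), cerna_id = character(), rho = numeric()))
  }
  rank_rows <- function(m) t(apply(m, 1, rank, ties.method = "average"))
  r_mir <- rank_rows(m_mir)
  r_cer <- rank_rows(m_cer)
  rho <- row_pearson(
    r_mir[cand$mirna_id, , drop = FALSE],
    r_cer[cand$target_id, , drop = FALSE]
  )
  n_const <- sum(is.na(rho))
  if (n_const > 0) {
    warn(sprintf(
      "%d miRNA-target pair(s) skipped: constant expression, rank correlation undefined",
      n_const
    ))
  }
  tibble(mirna_id = cand$mirna_id, cerna_id = cand$target_id, rho = rho) |>
    filter(!is.na(.data$rho), .data$rho <= rho_max)
}

# rowwise Pearson correlation of two conformable matrices
row_pearson <- function(a, b) {
  a <- sweep(a, 1, rowMeans(a))
  b <- sweep(b, 1, rowMeans(b))
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  unname(ifelse(den > 0, num / den, NA_real_))
}

#' Screen candidate ceRNA pairs
#'
#' From the retained miRNA-ceRNA edges, forms every unordered pair of
#' ceRNAs sharing at least one retained miRNA and applies the two remaining
#' filters of the three-step ceRNA screen: the Pearson correlation of the
#' two expression profiles must be at least `r_min`, and the hypergeometric
#' shared-miRNA test (`k` shared regulators out of retained target-set
#' sizes `K` and `n` in a universe of `N` miRNAs) must give `p < p_max`.
#'
#' @param edges retained edges from [spearman_edges()].
#' @param cerna_expr expression tibble covering all ceRNAs in `edges`.
#' @param types optional named character vector mapping RNA ids to
#'   `"lncRNA"` or `"mRNA"`; required when `pair_types = "lncRNA-mRNA"`.
#' @param r_min Pearson threshold (default 0.9).
#' @param p_max hypergeometric p-value threshold (default 0.05).
#' @param universe_mode how to set `N`: `"filtered"` (default, distinct
#'   miRNAs with at least one retained edge), `"all_expressed"` (every
#'   miRNA in `mirna_expr`), or `"all_predicted"` (every miRNA in
#'   `targets`).
#' @param mirna_expr,targets required only for the corresponding
#'   `universe_mode`.
#' @param pair_types `"lncRNA-mRNA"` (default) reports only mixed pairs,
#'   with the lncRNA as `rna_a`; `"all"` also reports lncRNA-lncRNA and
#'   mRNA-mRNA pairs.
#' @param all_shared if `TRUE`, additionally require that every miRNA
#'   predicted to target both members has retained edges to both
#'   (`targets` must be supplied).
#' @param pair_fdr apply BH across surviving pairs and filter on the
#'   adjusted value instead of the raw p (default `FALSE`, matching a raw
#'   `p < 0.05` screen).
#' @return A tibble of surviving pairs: `rna_a`, `rna_b`, `type_a`,
#'   `type_b`, `shared_mirnas` (list column), `k`, `K`, `n`, `N`,
#'   `pearson_r`, `hyper_p` (and `hyper_fdr` when `pair_fdr`).
#' @export
screen_pairs <- function(edges, cerna_expr, types = NULL,
                         r_min = 0.9, p_max = 0.05,
                         universe_mode = c("filtered", "all_expressed", "all_predicted"),
                         mirna_expr = NULL, targets = NULL,
                         pair_types = c("lncRNA-mRNA", "all"),
                         all_shared = FALSE, pair_fdr = FALSE) {
  universe_mode <- match.arg(universe_mode)
  pair_types <- match.arg(pair_types)
  empty <- tibble(
    rna_a = character(), rna_b = character(),
    type_a = character(), type_b = character(),
    shared_mirnas = list(), k = integer(), K = integer(), n = integer(),
    N = integer(), pearson_r = numeric(), hyper_p = numeric()
  )
  if (nrow(edges) == 0) {
    return(empty)
  }
  N <- switch(universe_mode,
    filtered = dplyr::n_distinct(edges$mirna_id),
    all_expressed = {
      if (is.null(mirna_expr)) abort("universe_mode='all_expressed' needs mirna_expr")
      nrow(mirna_expr)
    },
    all_predicted = {
      if (is.null(targets)) abort("universe_mode='all_predicted' needs targets")
      dplyr::n_distinct(targets$mirna_id)
    }
  )
  if (all_shared && is.null(targets)) {
    abort("all_shared = TRUE needs the filtered target records")
  }

  sets <- split(edges$mirna_id, edges$cerna_id)
  pairs <- edges |>
    inner_join(edges, by = "mirna_id", relationship = "many-to-many") |>
    filter(.data$cerna_id.x < .data$cerna_id.y) |>
    distinct(rna_a = .data$cerna_id.x, rna_b = .data$cerna_id.y)
  if (nrow(pairs) == 0) {
    return(empty)
  }

  m_cer <- counts_to_matrix(cerna_expr)
  miss <- setdiff(unique(c(pairs$rna_a, pairs$rna_b)), rownames(m_cer))
  if (length(miss) > 0) {
    abort(sprintf(
      "ceRNA(s) missing from expression matrix: %s",
      paste(head(miss, 5), collapse = ", ")
    ))
  }
  pairs$pearson_r <- row_pearson(
    m_cer[pairs$rna_a, , drop = FALSE],
    m_cer[pairs$rna_b, , drop = FALSE]
  )
  pairs <- pairs |> filter(!is.na(.data$pearson_r), .data$pearson_r >= r_min)
  if (nrow(pairs) == 0) {
    return(empty)
  }

  pairs <- pairs |>
    mutate(
      shared_mirnas = purrr::map2(
        .data$rna_a, .data$rna_b,
        function(a, b) sort(intersect(sets[[a]], sets[[b]]))
      ),
      k = unname(lengths(.data$shared_mirnas)),
      K = unname(lengths(sets[.data$rna_a])),
      n = unname(lengths(sets[.data$rna_b])),
      N = N,
      hyper_p = hypergeom_shared(.data$k, .data$K, .data$n, .data$N)
    )

  if (all_shared) {
    pred_sets <- split(targets$mirna_id, targets$target_id)
    pred_shared <- purrr::map2_int(
      pairs$rna_a, pairs$rna_b,
      function(a, b) length(intersect(pred_sets[[a]] %||% character(0),
        pred_sets[[b]] %||% character(0)))
    )
    pairs <- pairs |> filter(.data$k == pred_shared)
  }

  if (pair_fdr) {
    pairs <- pairs |>
      mutate(hyper_fdr = bh_fdr(.data$hyper_p)) |>
      filter(.data$hyper_fdr < p_max, .data$k >= 1)
  } else {
    pairs <- pairs |> filter(.data$hyper_p < p_max, .data$k >= 1)
  }

  if (is.null(types)) {
    if (pair_types == "lncRNA-mRNA") {
      abort("pair_types = 'lncRNA-mRNA' needs the `types` id->type mapping")
    }
    pairs$type_a <- NA_character_
    pairs$type_b <- NA_character_
  } else {
    pairs$type_a <- unname(types[pairs$rna_a])
    pairs$type_b <- unname(types[pairs$rna_b])
    if (pair_types == "lncRNA-mRNA") {
      pairs <- pairs |> filter(.data$type_a != .data$type_b)
      flip <- pairs$type_a != "lncRNA"
      tmp <- pairs[flip, ]
      pairs[flip, c("rna_a", "rna_b", "type_a", "type_b", "K", "n")] <-
        tmp[, c("rna_b", "rna_a", "type_b", "type_a", "n", "K")]
    }
  }
  pairs |>
    select(
      "rna_a", "rna_b", "type_a", "type_b", "shared_mirnas",
      "k", "K", "n", "N", "pearson_r", "hyper_p",
      dplyr::any_of("hyper_fdr")
    ) |>
    arrange(.data$rna_a, .data$rna_b)
}
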