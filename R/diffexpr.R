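#' Negative-binomial exact test with fixed dispersion
#'
#' Two-sided exact test for a difference in mean between two groups of
#' replicate counts, assuming each count is NB with common mean within a
#' group and fixed dispersion `phi` (`Var = mu + phi mu^2`). Counts are
#' first scaled to a common effective library size via the supplied (or
#' internally computed) size factors and rounded. Conditional on the
#' gene's total sum `T`, the group-A sum follows the distribution induced
#' by the two group sums (each NB with dispersion `phi / n_group`); the
#' two-sided p-value is the total probability of all outcomes `s in [0, T]`
#' whose conditional probability does not exceed that of the observed sum
#' (small-probability-mass rule), and is never below the observed outcome's
#' own mass.
#'
#' An all-zero gene returns `p = 1` by convention.
#'
#' @param counts_a,counts_b integer replicate counts for the two groups.
#' @param phi NB dispersion (> 0), default 0.01.
#' @param sf_a,sf_b optional per-replicate size factors used to equalize
#'   library sizes before testing (default: no scaling).
#' @return A single p-value in (0, 1].
#' @export
#' @examples
#' nb_exact_test(c(10, 12, 9), c(50, 55, 60), phi = 0.01)
nb_exact_test <- function(counts_a, counts_b, phi = 0.01,
                          sf_a = NULL, sf_b = NULL) {
  if (phi <= 0) abort("phi must be > 0")
  if (length(counts_a) < 1 || length(counts_b) < 1) {
    abort("each group needs at least one replicate")
  }
  if (any(c(counts_a, counts_b) < 0)) abort("counts must be non-negative")
  sf <- c(
    sf_a %||% rep(1, length(counts_a)),
    sf_b %||% rep(1, length(counts_b))
  )
  sf <- sf / exp(mean(log(sf)))
  y <- round(c(counts_a, counts_b) / sf)
  nb_exact_pvalue(
    y[seq_along(counts_a)], y[length(counts_a) + seq_along(counts_b)], phi
  )
}

# core conditional test on (already equalized) integer counts
nb_exact_pvalue <- function(ya, yb, phi) {
  na <- length(ya)
  nb <- length(yb)
  sa <- sum(ya)
  total <- sa + sum(yb)
  if (total == 0) {
    return(1)
  }
  mu <- total / (na + nb)
  s <- 0:total
  lp <- dnbinom(s, size = na / phi, mu = na * mu, log = TRUE) +
    dnbinom(total - s, size = nb / phi, mu = nb * mu, log = TRUE)
  lp <- lp - logsumexp(lp)
  lp_obs <- lp[sa + 1]
  p <- exp(logsumexp(lp[lp <= lp_obs + 1e-8]))
  min(max(p, exp(lp_obs)), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validates the inputs and applies the BH step-up adjustment
#' (`adjusted_(i) = min over j >= i of p_(j) m / j`, capped at 1), which is
#' monotone in p and equivariant under permutation of the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the original order.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(pvalues, method = "BH")
}

#' Differential expression across all pairwise stage comparisons
#'
#' Runs the fixed-dispersion NB exact test for every feature in every
#' unordered pair of stages (six comparisons for a four-stage design).
#' Log2 fold changes are `log2((mean_B + 1) / (mean_A + 1))` on
#' size-factor-normalized counts (B relative to A, stages in sample-sheet
#' order); FDR is BH within each comparison; a feature is `up` iff
#' `fdr < alpha` and `log2fc > lfc`, `down` iff `fdr < alpha` and
#' `log2fc < -lfc`, otherwise `ns`.
#'
#' @param counts count tibble (`feature_id` + sample columns).
#' @param samples sample sheet tibble (`sample_id`, `stage`, `replicate`).
#' @param phi NB dispersion, default 0.01.
#' @param alpha FDR threshold, default 0.05.
#' @param lfc absolute log2 fold-change threshold, default 1.
#' @param sf optional tibble (`sample_id`, `size_factor`); computed by
#'   [size_factors()] when `NULL` (falling back to the pseudo-reference if
#'   no feature is expressed in all samples).
#' @return One tidy tibble over all comparisons: `comparison`,
#'   `feature_id`, `mean_a`, `mean_b`, `log2fc`, `pvalue`, `fdr`, `status`.
#' @export
call_de <- function(counts, samples, phi = 0.01, alpha = 0.05, lfc = 1,
                    sf = NULL) {
  validate_counts(counts)
  validate_samplesheet(samples)
  validate_counts_samples(counts, samples)
  m <- counts_to_matrix(counts)[, samples$sample_id, drop = FALSE]
  if (nrow(m) == 0) {
    return(tibble(
      comparison = character(), feature_id = character(),
      mean_a = numeric(), mean_b = numeric(), log2fc = numeric(),
      pvalue = numeric(), fdr = numeric(), status = character()
    ))
  }
  if (is.null(sf)) {
    sf <- tryCatch(size_factors(counts), error = function(e) {
      warn("falling back to pseudo-reference size factors")
      size_factors(counts, pseudo_reference = TRUE)
    })
  }
  fac <- sf$size_factor[match(colnames(m), sf$sample_id)]
  fac <- fac / exp(mean(log(fac)))
  norm <- sweep(m, 2, fac, "/")
  pseudo <- round(norm)

  stages <- unique(samples$stage)
  shallow <- table(samples$stage)
  if (any(shallow < 2)) {
    warn("stage(s) with < 2 replicates; exact test still defined")
  }
  pairs <- combn(stages, 2, simplify = FALSE)

  purrr::map_dfr(pairs, function(pr) {
    a_cols <- samples$sample_id[samples$stage == pr[1]]
    b_cols <- samples$sample_id[samples$stage == pr[2]]
    pa <- pseudo[, a_cols, drop = FALSE]
    pb <- pseudo[, b_cols, drop = FALSE]
    pv <- vapply(
      seq_len(nrow(m)),
      function(i) nb_exact_pvalue(pa[i, ], pb[i, ], phi),
      numeric(1)
    )
    mean_a <- rowMeans(norm[, a_cols, drop = FALSE])
    mean_b <- rowMeans(norm[, b_cols, drop = FALSE])
    l2fc <- log2((mean_b + 1) / (mean_a + 1))
    fdr <- bh_fdr(pv)
    tibble(
      comparison = paste0(pr[1], "_vs_", pr[2]),
      feature_id = rownames(m),
      mean_a = mean_a, mean_b = mean_b, log2fc = l2fc,
      pvalue = pv, fdr = fdr,
      status = dplyr::case_when(
        fdr < alpha & l2fc > lfc ~ "up",
        fdr < alpha & l2fc < -lfc ~ "down",
        TRUE ~ "ns"
      )
    )
  })
}

#' Set logic over multi-comparison DE results
#'
#' Builds the per-comparison membership matrix of features significant
#' (`status != "ns"`) in at least one comparison, plus union, intersection
#' and Venn region counts derived from it.
#'
#' @param de a tidy DE table from [call_de()].
#' @return A list: `membership` (tibble `feature_id` + one logical column
#'   per comparison), `union` and `intersection` (character vectors of
#'   feature ids), and `region_counts` (tibble `pattern`, `n`, where
#'   `pattern` concatenates comparison membership as 0/1 in column order).
#' @export
de_set_ops <- function(de) {
  comparisons <- unique(de$comparison)
  sig <- de |> filter(.data$status != "ns")
  membership <- sig |>
    distinct(.data$feature_id, .data$comparison) |>
    mutate(hit = TRUE) |>
    tidyr::pivot_wider(
      names_from = "comparison", values_from = "hit", values_fill = FALSE
    )
  for (cmp in setdiff(comparisons, names(membership))) {
    membership[[cmp]] <- FALSE
  }
  membership <- membership |> select("feature_id", dplyr::all_of(comparisons))
  mm <- as.matrix(membership[comparisons])
  patterns <- if (nrow(mm) == 0) {
    character(0)
  } else {
    apply(mm, 1, function(r) paste(as.integer(r), collapse = ""))
  }
  region_counts <- tibble(pattern = patterns) |>
    dplyr::count(.data$pattern, name = "n")
  list(
    membership = membership,
    union = membership$feature_id,
    intersection = membership$feature_id[rowSums(mm) == length(comparisons)],
    region_counts = region_counts
  )
}
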