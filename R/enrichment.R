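#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for over-representation of a query gene list
#' against a universe, using the one-sided hypergeometric survivor function
#' `P(X >= k)` with BH correction across tested terms. The universe
#' defaults to all genes appearing in the annotation table; the query list
#' is intersected with the universe before testing, and terms with no
#' member in the universe are dropped.
#'
#' @param gene_list character vector of query gene ids.
#' @param annotations tibble (`term_id`, `term_name`, `gene_id`).
#' @param universe optional character vector of background gene ids.
#' @return A tibble sorted by p-value: `term_id`, `term_name`, `k` (list
#'   hits), `K` (term size in universe), `n` (list size in universe), `N`
#'   (universe size), `pvalue`, `fdr`. Empty list gives an empty result.
#' @export
#' @examples
#' anno <- tibble::tibble(
#'   term_id = rep(c("T1", "T2"), c(4, 6)), term_name = term_id,
#'   gene_id = c(paste0("g", 1:4), paste0("g", 5:10))
#' )
#' ora(c("g1", "g2", "g3", "g5"), anno)
ora <- function(gene_list, annotations, universe = NULL) {
  need <- c("term_id", "term_name", "gene_id")
  miss <- setdiff(need, names(annotations))
  if (length(miss) > 0) {
    abort(sprintf("annotation table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  annotations <- annotations |>
    distinct(.data$term_id, .data$term_name, .data$gene_id)
  if (is.null(universe)) universe <- unique(annotations$gene_id)
  universe <- unique(universe)
  if (length(universe) == 0) abort("universe is empty")
  gene_list <- intersect(unique(gene_list), universe)
  empty <- tibble(
    term_id = character(), term_name = character(),
    k = integer(), K = integer(), n = integer(), N = integer(),
    pvalue = numeric(), fdr = numeric()
  )
  if (length(gene_list) == 0) {
    return(empty)
  }
  anno <- annotations |> filter(.data$gene_id %in% universe)
  res <- anno |>
    group_by(.data$term_id, .data$term_name) |>
    summarise(
      K = dplyr::n_distinct(.data$gene_id),
      k = sum(unique(.data$gene_id) %in% gene_list),
      .groups = "drop"
    ) |>
    filter(.data$K > 0) |>
    mutate(
      n = length(gene_list), N = length(universe),
      pvalue = hypergeom_shared(.data$k, .data$K, .data$n, .data$N),
      fdr = bh_fdr(.data$pvalue)
    ) |>
    arrange(.data$pvalue) |>
    select("term_id", "term_name", "k", "K", "n", "N", "pvalue", "fdr")
  if (nrow(res) == 0) empty else res
}
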