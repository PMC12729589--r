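#' FPKM expression summarization
#'
#' Computes fragments per kilobase of transcript per million mapped
#' fragments: `FPKM = count * 1e9 / (length_bp * library_size)`. Library
#' sizes default to the column sums of the count matrix.
#'
#' @param counts count tibble (`feature_id` + sample columns).
#' @param lengths tibble (`feature_id`, `length`) of transcript lengths in
#'   bp; every feature in `counts` must be present with length > 0.
#' @param library_sizes optional tibble (`sample_id`, `library_size`);
#'   defaults to per-sample total counts.
#' @return A tibble shaped like `counts` with FPKM values; the lengths and
#'   library sizes used are attached as attributes `lengths` and
#'   `library_sizes`.
#' @export
#' @examples
#' counts <- tibble::tibble(feature_id = "f", s1 = 100L)
#' fpkm(counts, tibble::tibble(feature_id = "f", length = 1000),
#'   library_sizes = tibble::tibble(sample_id = "s1", library_size = 1e6)
#' )
fpkm <- function(counts, lengths, library_sizes = NULL) {
  validate_counts(counts)
  m <- counts_to_matrix(counts)
  miss <- setdiff(rownames(m), lengths$feature_id)
  if (length(miss) > 0) {
    abort(sprintf(
      "missing length for feature(s): %s",
      paste(head(miss, 5), collapse = ", ")
    ))
  }
  len <- lengths$length[match(rownames(m), lengths$feature_id)]
  if (any(len <= 0)) abort("all transcript lengths must be > 0")
  if (is.null(library_sizes)) {
    library_sizes <- tibble(
      sample_id = colnames(m),
      library_size = colSums(m)
    )
  }
  miss <- setdiff(colnames(m), library_sizes$sample_id)
  if (length(miss) > 0) {
    abort(sprintf(
      "missing library size for sample(s): %s",
      paste(miss, collapse = ", ")
    ))
  }
  libs <- library_sizes$library_size[match(colnames(m), library_sizes$sample_id)]
  if (any(libs <= 0)) abort("all library sizes must be > 0")
  out <- sweep(sweep(m * 1e9, 1, len, "/"), 2, libs, "/")
  res <- matrix_to_counts(out)
  attr(res, "lengths") <- len
  attr(res, "library_sizes") <- libs
  res
}

#' Median-of-ratios size factors
#'
#' The normalization scheme popularized by DESeq: per-feature geometric
#' means across samples form a pseudo-reference (features with any zero
#' count are excluded), and each sample's size factor is the median of its
#' count-to-reference ratios. With `pseudo_reference = TRUE`, features with
#' zeros are kept by computing the geometric mean over positive counts
#' only — a fallback for sparse matrices where no feature is expressed
#' everywhere.
#'
#' @param counts count tibble.
#' @param pseudo_reference keep features containing zeros by using the
#'   geometric mean of their positive counts (default `FALSE`).
#' @return A tibble (`sample_id`, `size_factor`), size factors all finite
#'   and positive.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  validate_counts(counts)
  m <- counts_to_matrix(counts)
  if (ncol(m) < 1 || nrow(m) < 1) abort("count matrix must be non-empty")
  if (pseudo_reference) {
    logref <- apply(m, 1, function(x) mean(log(x[x > 0])))
    use <- rowSums(m > 0) > 0
  } else {
    use <- rowSums(m == 0) == 0
    if (!any(use)) {
      abort(paste(
        "no feature has nonzero counts in every sample;",
        "rerun with pseudo_reference = TRUE"
      ))
    }
    logref <- rowMeans(log(m))
  }
  sf <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[use, j]
    lr <- logref[use]
    if (pseudo_reference) {
      lr <- lr[v > 0]
      v <- v[v > 0]
    }
    exp(median(log(v) - lr))
  }, numeric(1))
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    abort("size factors are not all finite and positive; try pseudo_reference = TRUE")
  }
  tibble(sample_id = colnames(m), size_factor = sf)
}

#' Principal-component coordinates of samples
#'
#' Runs PCA on the samples of an expression matrix, by default after a
#' `log2(x + 1)` transform, centering features.
#'
#' @param counts expression tibble (`feature_id` + sample columns).
#' @param n_components number of components to return.
#' @param log_transform apply `log2(x + 1)` first (default `TRUE`).
#' @return An object of class `sample_pca`: list with `scores` (tibble
#'   `sample_id`, `PC1`, ...) and `variance_explained` (fractions,
#'   non-increasing, summing to at most 1).
#' @export
pca_coordinates <- function(counts, n_components = 2, log_transform = TRUE) {
  m <- counts_to_matrix(counts)
  if (n_components > min(dim(m))) {
    abort(sprintf(
      "n_components (%d) exceeds min(features, samples) = %d",
      n_components, min(dim(m))
    ))
  }
  x <- if (log_transform) log2(m + 1) else m
  p <- prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  k <- seq_len(n_components)
  scores <- as_tibble(p$x[, k, drop = FALSE]) |>
    mutate(sample_id = colnames(m), .before = 1)
  structure(
    list(scores = scores, variance_explained = ve[k]),
    class = "sample_pca"
  )
}

#' @export
print.sample_pca <- function(x, ...) {
  cat("<sample_pca> variance explained:",
    paste0(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "), "\n")
  print(x$scores)
  invisible(x)
}

#' All-pairs Pearson correlation between samples
#'
#' @param counts expression tibble (`feature_id` + sample columns).
#' @param log_transform apply `log2(x + 1)` first (default `TRUE`).
#' @return A symmetric sample-by-sample correlation matrix with unit
#'   diagonal. Samples with zero variance get `NA` rows/columns and a
#'   warning (never a silent 0).
#' @export
sample_correlation <- function(counts, log_transform = TRUE) {
  m <- counts_to_matrix(counts)
  x <- if (log_transform) log2(m + 1) else m
  sds <- apply(x, 2, stats::sd)
  r <- suppressWarnings(cor(x))
  if (any(sds == 0)) {
    warn(sprintf(
      "zero-variance sample(s), correlation undefined: %s",
      paste(colnames(x)[sds == 0], collapse = ", ")
    ))
    r[sds == 0, ] <- NA_real_
    r[, sds == 0] <- NA_real_
  }
  diag(r) <- 1
  r
}
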