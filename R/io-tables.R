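#' Read and write the pipeline's tabular artifacts
#'
#' Strict TSV readers/writers for count matrices, sample sheets and miRNA
#' target tables. All readers validate rather than coerce: duplicated ids,
#' negative or non-integer counts, and missing columns are errors, never
#' silent fixes. Feature ids must match `[A-Za-z0-9._-]+`.
#'
#' @param path file path.
#' @param counts count tibble (`feature_id` + one integer column per sample).
#' @param samples sample sheet tibble (`sample_id`, `stage`, `replicate`).
#' @param targets target record tibble (`mirna_id`, `target_id`,
#'   `targetscan_score`, `miranda_energy`, `source`).
#' @return The validated tibble (readers) or `path` invisibly (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  names(x)[1] <- "feature_id"
  validate_counts(x)
}

#' @rdname table_io
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  readr::write_tsv(counts, path)
  invisible(path)
}

validate_counts <- function(counts, what = "count matrix") {
  if (!"feature_id" %in% names(counts)) {
    abort(sprintf("%s must have a feature_id column", what))
  }
  assert_valid_ids(as.character(counts$feature_id), "feature")
  sample_cols <- setdiff(names(counts), "feature_id")
  assert_valid_ids(sample_cols, "sample")
  for (s in sample_cols) {
    v <- counts[[s]]
    if (!is.numeric(v) || anyNA(v)) {
      abort(sprintf("%s: column %s has missing or non-numeric values", what, s))
    }
    if (any(v < 0)) abort(sprintf("%s: column %s has negative counts", what, s))
    if (any(v != floor(v))) {
      abort(sprintf("%s: column %s has non-integer counts", what, s))
    }
  }
  as_tibble(counts)
}

#' @rdname table_io
#' @export
read_samplesheet <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  validate_samplesheet(x)
}

#' @rdname table_io
#' @export
write_samplesheet <- function(samples, path) {
  validate_samplesheet(samples)
  readr::write_tsv(samples, path)
  invisible(path)
}

validate_samplesheet <- function(samples) {
  need <- c("sample_id", "stage", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    abort(sprintf("sample sheet missing column(s): %s", paste(miss, collapse = ", ")))
  }
  assert_valid_ids(as.character(samples$sample_id), "sample")
  tally <- table(samples$stage)
  if (any(tally < 2)) {
    abort(sprintf(
      "stage(s) with fewer than 2 replicates: %s",
      paste(names(tally)[tally < 2], collapse = ", ")
    ))
  }
  as_tibble(samples)
}

#' Cross-validate a count matrix against a sample sheet
#'
#' Checks that the matrix sample columns and the sheet's `sample_id` values
#' match exactly, naming any offenders.
#'
#' @inheritParams table_io
#' @return `counts`, invisibly, if consistent.
#' @export
validate_counts_samples <- function(counts, samples) {
  cols <- setdiff(names(counts), "feature_id")
  extra <- setdiff(cols, samples$sample_id)
  missing <- setdiff(samples$sample_id, cols)
  if (length(extra) > 0 || length(missing) > 0) {
    abort(sprintf(
      "count matrix / sample sheet mismatch: columns not in sheet [%s]; sheet samples not in matrix [%s]",
      paste(extra, collapse = ", "), paste(missing, collapse = ", ")
    ))
  }
  invisible(counts)
}

#' @rdname table_io
#' @export
read_targets <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  validate_targets(x)
}

#' @rdname table_io
#' @export
write_targets <- function(targets, path) {
  validate_targets(targets)
  readr::write_tsv(targets, path)
  invisible(path)
}

validate_targets <- function(targets) {
  need <- c("mirna_id", "target_id", "targetscan_score", "miranda_energy", "source")
  miss <- setdiff(need, names(targets))
  if (length(miss) > 0) {
    abort(sprintf("target table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!all(targets$source %in% c("both", "targetscan", "miranda"))) {
    abort("target source must be one of both/targetscan/miranda")
  }
  as_tibble(targets)
}
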