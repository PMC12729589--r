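# shared internal helpers

ID_REGEX <- "^[A-Za-z0-9._-]+$"

assert_valid_ids <- function(ids, what = "feature") {
  bad <- ids[!grepl(ID_REGEX, ids)]
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid %s id(s): %s (must match [A-Za-z0-9._-]+)",
      what, paste(head(bad, 5), collapse = ", ")
    ))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf(
      "duplicated %s id(s): %s", what, paste(head(dup, 5), collapse = ", ")
    ))
  }
  invisible(ids)
}

logsumexp <- function(x) {
  x <- x[!is.infinite(x) | x > -Inf]
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (is.infinite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# counts tibble (feature_id + one numeric column per sample) -> integer matrix
counts_to_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "feature_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
  rownames(m) <- counts$feature_id
  storage.mode(m) <- "double"
  m
}

matrix_to_counts <- function(m) {
  out <- as_tibble(m, rownames = "feature_id")
  out
}

# deterministic apportionment of n among classes with fractional weights:
# floor(n * w) plus one extra to the largest remainders
largest_remainder <- function(n, weights) {
  stopifnot(abs(sum(weights) - 1) < 1e-9)
  raw <- n * weights
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

# derive a per-entity sub-seed from a master seed so adding entities does not
# reshuffle existing ones; keeps results below 2^31
sub_seed <- function(seed, stream, index = 0L) {
  h <- (as.double(seed) * 48271 + stream * 9973 + index * 7919) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

star_label <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "ns",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
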