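#' Read and write transcript models as GTF
#'
#' `read_gtf()` parses the exon lines of a GTF 2.2 file into the exon-level
#' transcript tibble used throughout the package; `write_gtf()` is its
#' inverse, so `read_gtf(write_gtf(x, f))` reproduces `x`. GTF coordinates
#' are 1-based inclusive; internally every interval is 0-based half-open
#' (start is decremented on read, incremented on write), which keeps the
#' positional classifier's interval arithmetic free of off-by-one cases.
#' Malformed lines (wrong column count, non-numeric or inverted
#' coordinates, unknown strand, missing `gene_id`/`transcript_id`
#' attributes) raise an error naming the offending line; nothing is
#' silently coerced.
#'
#' @param path file path.
#' @param transcripts exon-level transcript tibble (`transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, optional `biotype`).
#' @return `read_gtf()` returns the transcript tibble with exons sorted by
#'   start within each transcript; `write_gtf()` returns `path` invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".gtf")
#' tx <- tibble::tibble(
#'   transcript_id = "t1", gene_id = "g1", chrom = "chr1",
#'   strand = "+", start = c(100, 300), end = c(200, 450), biotype = "novel"
#' )
#' write_gtf(tx, f)
#' read_gtf(f)
read_gtf <- function(path) {
  if (!file.exists(path)) abort(sprintf("GTF file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(),
      start = integer(), end = integer(), biotype = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    abort(sprintf(
      "GTF parse error at line %d: expected 9 tab-separated fields, got %d",
      lineno[which(nf != 9)[1]], nf[which(nf != 9)[1]]
    ))
  }
  m <- do.call(rbind, fields)
  feature <- m[, 3]
  exon <- feature == "exon"
  if (!any(exon)) {
    abort("GTF file contains no exon features")
  }
  m <- m[exon, , drop = FALSE]
  lineno <- lineno[exon]

  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(sprintf("GTF parse error at line %d: non-numeric coordinates", lineno[bad[1]]))
  }
  bad <- which(end < start)
  if (length(bad) > 0) {
    abort(sprintf("GTF parse error at line %d: end < start", lineno[bad[1]]))
  }
  strand <- m[, 7]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0) {
    abort(sprintf(
      "GTF parse error at line %d: unknown strand '%s'",
      lineno[bad[1]], strand[bad[1]]
    ))
  }

  attr_field <- m[, 9]
  get_attr <- function(key, required = TRUE) {
    vals <- rep(NA_character_, length(attr_field))
    found <- regexpr(sprintf('(^|; ?)%s "([^"]*)"', key), attr_field, perl = TRUE)
    ok <- found > 0
    vals[ok] <- sub(
      sprintf('.*?%s "([^"]*)".*', key), "\\1",
      attr_field[ok],
      perl = TRUE
    )
    if (required && any(!ok)) {
      abort(sprintf(
        "GTF parse error at line %d: missing %s attribute",
        lineno[which(!ok)[1]], key
      ))
    }
    vals
  }
  gene_id <- get_attr("gene_id")
  transcript_id <- get_attr("transcript_id")
  biotype <- get_attr("transcript_biotype", required = FALSE)
  biotype[is.na(biotype)] <- "novel"

  tibble(
    transcript_id = transcript_id, gene_id = gene_id,
    chrom = m[, 1], strand = strand,
    start = start - 1L, end = end, # 1-based inclusive -> 0-based half-open
    biotype = biotype
  ) |>
    arrange(match(.data$transcript_id, unique(.data$transcript_id)), .data$start) |>
    validate_transcripts()
}

#' @rdname read_gtf
#' @export
write_gtf <- function(transcripts, path) {
  tx <- validate_transcripts(transcripts)
  biotype <- if ("biotype" %in% names(tx)) tx$biotype else "novel"
  lines <- sprintf(
    '%s\tcernascreen\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
    tx$chrom, tx$start + 1L, tx$end, tx$strand,
    tx$gene_id, tx$transcript_id, biotype
  )
  readr::write_lines(lines, path)
  invisible(path)
}

# structural validation of the exon-level transcript tibble
validate_transcripts <- function(tx) {
  need <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(tx))
  if (length(miss) > 0) {
    abort(sprintf("transcript table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(tx$end < tx$start)) abort("transcript table has exon with end < start")
  if (any(!tx$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  split_idx <- split(seq_len(nrow(tx)), tx$transcript_id)
  for (idx in split_idx) {
    s <- tx$start[idx]
    e <- tx$end[idx]
    o <- order(s)
    if (any(e[o][-length(o)] > s[o][-1])) {
      abort(sprintf(
        "overlapping exons in transcript %s", tx$transcript_id[idx[1]]
      ))
    }
  }
  as_tibble(tx)
}

# per-transcript summaries used by the filter and classifier
transcript_summary <- function(tx) {
  tx |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = .data$gene_id[1], chrom = .data$chrom[1],
      strand = .data$strand[1],
      tx_start = min(.data$start), tx_end = max(.data$end),
      n_exons = dplyr::n(), length = sum(.data$end - .data$start),
      .groups = "drop"
    )
}
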