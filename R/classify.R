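#' Retention filter for candidate novel lncRNAs
#'
#' Applies the standard novelty filter: a candidate transcript is retained
#' iff its summed exon length is at least `min_length` (default 200 bp), it
#' has at least `min_exons` exons (default 2), and all three
#' coding-potential predictors (CPC, CNCI, FEELnc style) call it
#' non-coding — the intersection rule. Input order is preserved.
#'
#' @param candidates exon-level transcript tibble of candidates.
#' @param verdicts tibble (`transcript_id`, `cpc_noncoding`,
#'   `cnci_noncoding`, `feelnc_noncoding`); every candidate must have a row.
#' @param min_length minimum transcript length in bp.
#' @param min_exons minimum exon count.
#' @return The retained subset of `candidates` (exon-level tibble).
#' @export
filter_novel_lncrnas <- function(candidates, verdicts,
                                 min_length = 200L, min_exons = 2L) {
  candidates <- validate_transcripts(candidates)
  need <- c("transcript_id", "cpc_noncoding", "cnci_noncoding", "feelnc_noncoding")
  miss <- setdiff(need, names(verdicts))
  if (length(miss) > 0) {
    abort(sprintf("verdict table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  smry <- transcript_summary(candidates)
  no_verdict <- setdiff(smry$transcript_id, verdicts$transcript_id)
  if (length(no_verdict) > 0) {
    abort(sprintf(
      "candidate(s) missing a coding-potential verdict: %s",
      paste(head(no_verdict, 5), collapse = ", ")
    ))
  }
  keep <- smry |>
    left_join(verdicts, by = "transcript_id") |>
    filter(
      .data$length >= min_length,
      .data$n_exons >= min_exons,
      .data$cpc_noncoding, .data$cnci_noncoding, .data$feelnc_noncoding
    )
  candidates |> filter(.data$transcript_id %in% keep$transcript_id)
}

#' Classify novel lncRNAs by genomic position relative to coding transcripts
#'
#' Assigns each lncRNA exactly one of five positional classes against the
#' coding transcripts on its chromosome, in this precedence order:
#'
#' 1. `intronic`: the lncRNA span lies fully inside one intron of a coding
#'    transcript (either strand);
#' 2. `antisense`: at least `min_overlap` bp of exon-to-exon overlap with a
#'    coding transcript on the opposite strand;
#' 3. `sense_overlapping`: at least `min_overlap` bp of span overlap with a
#'    coding transcript on the same strand;
#' 4. `bidirectional`: no span overlap, opposite strand, divergent
#'    orientation (the two transcripts point away from each other) with
#'    transcription start sites within `bidirectional_window` bp;
#' 5. `lincRNA` (intergenic) otherwise.
#'
#' Containment-first precedence makes the five categories a partition; the
#' result is deterministic in the inputs and invariant under coordinate
#' translation and global strand flip.
#'
#' @param lncrnas exon-level transcript tibble of lncRNAs.
#' @param coding exon-level transcript tibble of coding transcripts (may
#'   have zero rows, in which case everything is `lincRNA`).
#' @param bidirectional_window promoter window in bp (default 1000).
#' @param min_overlap minimum overlap in bp (default 1).
#' @return A tibble (`transcript_id`, `class`) with one row per lncRNA.
#' @export
#' @examples
#' lnc <- tibble::tibble(
#'   transcript_id = "l1", gene_id = "l1g", chrom = "chr1", strand = "-",
#'   start = 1000, end = 1500
#' )
#' classify_lncrnas(lnc, lnc[0, ])
classify_lncrnas <- function(lncrnas, coding,
                             bidirectional_window = 1000L, min_overlap = 1L) {
  lncrnas <- validate_transcripts(lncrnas)
  coding <- validate_transcripts(coding)
  lnc_tx <- transcript_summary(lncrnas)
  clash <- intersect(lnc_tx$transcript_id, unique(coding$transcript_id))
  if (length(clash) > 0) {
    abort(sprintf(
      "lncRNA id(s) collide with coding ids: %s",
      paste(head(clash, 5), collapse = ", ")
    ))
  }
  fallback <- tibble(transcript_id = lnc_tx$transcript_id, class = "lincRNA")
  if (nrow(coding) == 0) {
    return(fallback)
  }
  cod_tx <- transcript_summary(coding)

  # introns of each coding transcript
  introns <- coding |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    summarise(
      chrom = .data$chrom[1],
      i_start = list(.data$end[-dplyr::n()]),
      i_end = list(.data$start[-1]),
      .groups = "drop"
    ) |>
    tidyr::unnest(c("i_start", "i_end"))

  intronic_ids <- lnc_tx |>
    inner_join(introns, by = "chrom", relationship = "many-to-many") |>
    filter(.data$tx_start >= .data$i_start, .data$tx_end <= .data$i_end) |>
    dplyr::pull(.data$transcript_id.x) |>
    unique()

  # exon-level overlap on the opposite strand
  antisense_ids <- lncrnas |>
    select(lnc_id = "transcript_id", "chrom",
      lnc_strand = "strand", ls = "start", le = "end"
    ) |>
    inner_join(
      coding |>
        select(cod_id = "transcript_id", "chrom",
          cod_strand = "strand", cs = "start", ce = "end"
        ),
      by = "chrom", relationship = "many-to-many"
    ) |>
    filter(.data$lnc_strand != .data$cod_strand) |>
    mutate(ov = pmin(.data$le, .data$ce) - pmax(.data$ls, .data$cs)) |>
    filter(.data$ov > 0) |>
    group_by(.data$lnc_id, .data$cod_id) |>
    summarise(ov = sum(.data$ov), .groups = "drop") |>
    filter(.data$ov >= min_overlap) |>
    dplyr::pull(.data$lnc_id) |>
    unique()

  # span-level overlap on the same strand
  span_pairs <- lnc_tx |>
    select(lnc_id = "transcript_id", "chrom",
      lnc_strand = "strand", ls = "tx_start", le = "tx_end"
    ) |>
    inner_join(
      cod_tx |>
        select(cod_id = "transcript_id", "chrom",
          cod_strand = "strand", cs = "tx_start", ce = "tx_end"
        ),
      by = "chrom", relationship = "many-to-many"
    )
  sense_ids <- span_pairs |>
    filter(
      .data$lnc_strand == .data$cod_strand,
      pmin(.data$le, .data$ce) - pmax(.data$ls, .data$cs) >= min_overlap
    ) |>
    dplyr::pull(.data$lnc_id) |>
    unique()

  # divergent promoters: opposite strand, no overlap, TSSs within window,
  # transcription pointing away on both sides
  bidir_ids <- span_pairs |>
    filter(
      .data$lnc_strand != .data$cod_strand,
      pmin(.data$le, .data$ce) <= pmax(.data$ls, .data$cs) # no span overlap
    ) |>
    mutate(
      lnc_tss = ifelse(.data$lnc_strand == "+", .data$ls, .data$le),
      cod_tss = ifelse(.data$cod_strand == "+", .data$cs, .data$ce),
      divergent = ifelse(.data$lnc_strand == "+",
        .data$cod_tss <= .data$lnc_tss, # coding leftward, lnc rightward
        .data$lnc_tss <= .data$cod_tss
      )
    ) |>
    filter(.data$divergent, abs(.data$lnc_tss - .data$cod_tss) <= bidirectional_window) |>
    dplyr::pull(.data$lnc_id) |>
    unique()

  fallback |>
    mutate(class = dplyr::case_when(
      .data$transcript_id %in% intronic_ids ~ "intronic",
      .data$transcript_id %in% antisense_ids ~ "antisense",
      .data$transcript_id %in% sense_ids ~ "sense_overlapping",
      .data$transcript_id %in% bidir_ids ~ "bidirectional",
      TRUE ~ "lincRNA"
    ))
}
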