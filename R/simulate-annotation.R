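#' Simulate a coding annotation plus novel lncRNA candidates with known classes
#'
#' Lays out `n_coding_genes` three-exon protein-coding genes on the + strand
#' of a single synthetic chromosome, one gene per disjoint 50 kb slot, then
#' places `n_novel_transcripts` two-exon novel transcripts whose geometry
#' relative to the nearest coding gene realizes an assigned positional class
#' (intergenic, antisense, sense-overlapping, intronic, bidirectional).
#' Class counts are apportioned deterministically from
#' `config$class_proportions` by largest-remainder rounding, so a fixed
#' `n_novel_transcripts` always yields the same class tally. Coding-potential
#' verdicts mark every novel transcript non-coding by all three predictors
#' unless `config$contamination_fraction > 0`.
#'
#' All coordinates are 0-based half-open; [write_gtf()] converts on output.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `coding` and `novel` (exon-level transcript
#'   tibbles: `transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `biotype`), `true_class` (tibble `transcript_id`, `class`) and
#'   `verdicts` (tibble of the three non-coding flags).
#' @export
#' @examples
#' ann <- simulate_annotation(simulation_config(seed = 1, n_novel_transcripts = 20))
#' table(ann$true_class$class)
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)

  slot <- 50000L
  n_cod <- config$n_coding_genes
  window <- config$bidirectional_window
  if (window > 10000L) {
    abort("bidirectional_window above 10000 bp would collide with the intergenic placement zone")
  }

  # coding genes: exons at +10000..10300, +11300..11600, +12600..12900
  cod_idx <- seq_len(n_cod)
  slot_start <- (cod_idx - 1L) * slot
  coding <- tibble(
    gene = rep(cod_idx, each = 3L),
    exon = rep(1:3, times = n_cod)
  ) |>
    mutate(
      transcript_id = sprintf("ENSCHIT%05d", .data$gene),
      gene_id = sprintf("ENSCHIG%05d", .data$gene),
      chrom = "chr1",
      strand = "+",
      start = slot_start[.data$gene] +
        c(10000L, 11300L, 12600L)[.data$exon],
      end = slot_start[.data$gene] +
        c(10300L, 11600L, 12900L)[.data$exon],
      biotype = "coding"
    ) |>
    select("transcript_id", "gene_id", "chrom", "strand", "start", "end", "biotype")

  counts <- largest_remainder(
    config$n_novel_transcripts,
    config$class_proportions[lnc_classes()]
  )
  non_ig <- counts[setdiff(lnc_classes(), "lincRNA")]
  if (any(non_ig > n_cod)) {
    abort(sprintf(
      "class count %d exceeds n_coding_genes (%d); increase n_coding_genes",
      max(non_ig), n_cod
    ))
  }
  if (counts[["lincRNA"]] > 15L * n_cod) {
    abort("too many intergenic transcripts for the slot layout; increase n_coding_genes")
  }

  gap <- as.integer(max(50L, ceiling(window * 0.3)))

  class_vec <- rep(lnc_classes(), times = counts[lnc_classes()])
  n_novel <- length(class_vec)
  within <- stats::ave(seq_len(n_novel), class_vec, FUN = seq_along)
  host <- ((within - 1L) %% n_cod) + 1L       # host coding gene index
  kth <- (within - 1L) %/% n_cod              # within-slot index (intergenic)
  s0 <- slot_start[host]

  # two-exon geometry per class, relative to the host slot (host gene is '+')
  geom <- function(cls, s0, kth) {
    switch(cls,
      intronic = list(strand = "+", e1 = c(10400L, 10550L), e2 = c(10650L, 10800L)),
      antisense = list(strand = "-", e1 = c(10100L, 10400L), e2 = c(10500L, 10700L)),
      sense_overlapping = list(strand = "+", e1 = c(12700L, 13100L), e2 = c(13200L, 13500L)),
      bidirectional = list(
        strand = "-",
        e1 = c(10000L - gap - 500L, 10000L - gap - 300L),
        e2 = c(10000L - gap - 200L, 10000L - gap)
      ),
      lincRNA = list(
        strand = "+",
        e1 = c(25000L + kth * 1500L, 25000L + kth * 1500L + 500L),
        e2 = c(25000L + kth * 1500L + 600L, 25000L + kth * 1500L + 1100L)
      )
    )
  }

  novel <- purrr::pmap_dfr(
    list(seq_len(n_novel), class_vec, s0, kth),
    function(i, cls, s0, kth) {
      g <- geom(cls, s0, kth)
      tibble(
        transcript_id = sprintf("MSTRG.%d.1", i),
        gene_id = sprintf("MSTRG.%d", i),
        chrom = "chr1",
        strand = g$strand,
        start = s0 + c(g$e1[1], g$e2[1]),
        end = s0 + c(g$e1[2], g$e2[2]),
        biotype = "novel"
      )
    }
  )

  true_class <- tibble(
    transcript_id = sprintf("MSTRG.%d.1", seq_len(n_novel)),
    class = class_vec
  )

  verdicts <- tibble(
    transcript_id = true_class$transcript_id,
    cpc_noncoding = TRUE,
    cnci_noncoding = TRUE,
    feelnc_noncoding = TRUE
  )
  n_contam <- floor(config$contamination_fraction * n_novel)
  if (n_contam > 0) {
    with_seed(sub_seed(config$seed, 11L), {
      idx <- sample.int(n_novel, n_contam)
      which_tool <- sample(c("cpc_noncoding", "cnci_noncoding", "feelnc_noncoding"),
        n_contam,
        replace = TRUE
      )
      for (j in seq_along(idx)) {
        verdicts[[which_tool[j]]][idx[j]] <- FALSE
      }
    })
  }

  structure(
    list(
      coding = coding, novel = novel,
      true_class = true_class, verdicts = verdicts
    ),
    class = "annotation_sim"
  )
}
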