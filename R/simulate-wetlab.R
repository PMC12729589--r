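#' Simulate qPCR Ct tables with planted fold changes
#'
#' Generates technical-triplicate Ct values for a set of target genes and
#' one reference gene over the configured stage x replicate design. For each
#' gene the planted fold change of stage s relative to the first
#' (calibrator) stage enters as `Ct = baseline - log2(fold) + noise`, while
#' the reference gene tracks only the per-sample baseline shift, so the
#' 2^-ddCt analysis of [ddct()] recovers the planted folds exactly when
#' `ct_noise_sd = 0`.
#'
#' @param config a [simulation_config()].
#' @param genes character vector of target gene names.
#' @param folds optional tibble (`gene`, `stage`, `fold`) of planted folds
#'   relative to the first stage; defaults to random 2^U(-2, 2) folds with
#'   fold 1 in the calibrator stage.
#' @param reference_gene name of the reference gene (default "beta-actin").
#' @param ct_noise_sd technical noise sd on Ct units (default 0.05).
#' @return A list: `ct` (tibble `sample_id`, `group`, `gene`, `replicate`,
#'   `ct`) and `folds` (the planted fold table).
#' @export
simulate_qpcr <- function(config, genes = paste0("target-", 1:4), folds = NULL,
                          reference_gene = "beta-actin", ct_noise_sd = 0.05) {
  stopifnot(inherits(config, "simulation_config"))
  stages <- config$stages
  if (is.null(folds)) {
    folds <- with_seed(sub_seed(config$seed, 51L), {
      tidyr::expand_grid(gene = genes, stage = stages) |>
        mutate(fold = ifelse(.data$stage == stages[1], 1,
          2^runif(dplyr::n(), -2, 2)
        ))
    })
  }
  stopifnot(all(c("gene", "stage", "fold") %in% names(folds)))

  reps <- config$replicates_per_stage
  design <- tidyr::expand_grid(
    stage = stages, replicate = seq_len(reps),
    gene = c(genes, reference_gene), tech_rep = 1:3
  ) |>
    mutate(sample_id = paste0(.data$stage, "-", .data$replicate))

  with_seed(sub_seed(config$seed, 52L), {
    base_gene <- stats::setNames(
      c(runif(length(genes), 22, 28), 18),
      c(genes, reference_gene)
    )
    sample_shift <- stats::setNames(
      rnorm(length(unique(design$sample_id)), 0, 0.2),
      unique(design$sample_id)
    )
    ct <- design |>
      left_join(folds, by = c("gene", "stage")) |>
      mutate(
        fold = ifelse(.data$gene == reference_gene, 1, .data$fold),
        ct = base_gene[.data$gene] - log2(.data$fold) +
          sample_shift[.data$sample_id] +
          rnorm(dplyr::n(), 0, ct_noise_sd)
      ) |>
      select(
        "sample_id",
        group = "stage", "gene", replicate = "tech_rep", "ct"
      )
  })
  list(ct = ct, folds = folds)
}

#' Simulate a dual-luciferase reporter experiment
#'
#' Produces two-channel readings (reporter, normalizer) for the WT and MUT
#' constructs under miRNA mimic and negative-control (NC) treatment. The
#' mimic suppresses the reporter channel of the WT construct by
#' `suppression_wt` (default 0.5) and leaves the mutated construct
#' untouched (`suppression_mut = 1`), the pattern expected when mutation of
#' the binding site abolishes miRNA binding.
#'
#' @param config a [simulation_config()].
#' @param suppression_wt,suppression_mut multiplicative effect of the mimic
#'   on the reporter channel for each construct.
#' @param n_replicates transfection replicates per condition.
#' @param noise_sd log-normal noise sd on both channels (default 0.05).
#' @return A tibble (`construct`, `treatment`, `replicate`, `reporter`,
#'   `normalizer`).
#' @export
simulate_luciferase <- function(config, suppression_wt = 0.5,
                                suppression_mut = 1, n_replicates = 3,
                                noise_sd = 0.05) {
  stopifnot(inherits(config, "simulation_config"))
  design <- tidyr::expand_grid(
    construct = c("WT", "MUT"), treatment = c("mimic", "NC"),
    replicate = seq_len(n_replicates)
  )
  with_seed(sub_seed(config$seed, 53L), {
    supp <- ifelse(design$construct == "WT" & design$treatment == "mimic",
      suppression_wt,
      ifelse(design$construct == "MUT" & design$treatment == "mimic",
        suppression_mut, 1
      )
    )
    design |>
      mutate(
        normalizer = 1000 * exp(rnorm(dplyr::n(), 0, noise_sd)),
        reporter = .data$normalizer * 0.8 * supp *
          exp(rnorm(dplyr::n(), 0, noise_sd))
      )
  })
}
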