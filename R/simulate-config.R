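#' Configuration for the synthetic ceRNA study generator
#'
#' Builds and validates the single configuration object consumed by all
#' `simulate_*()` generators. Defaults describe a 4-stage x 3-replicate
#' longissimus dorsi style design with 20 planted ceRNA triplets; the five
#' positional class proportions default to published lncRNA survey values
#' (intergenic 52.4%, antisense 13.4%, sense-overlapping 7.2%, intronic
#' 11.6%, bidirectional 10.22%) renormalized to sum to one.
#'
#' @param seed integer master seed; every generator derives its own
#'   deterministic sub-streams from it.
#' @param n_coding_genes number of protein-coding genes in the synthetic
#'   annotation; each gene occupies its own genomic slot.
#' @param n_novel_transcripts number of candidate novel lncRNA transcripts.
#' @param class_proportions named numeric over the five positional classes
#'   (`lincRNA`, `antisense`, `sense_overlapping`, `intronic`,
#'   `bidirectional`); must sum to 1 within 1e-9.
#' @param n_lncrna,n_mrna,n_mirna numbers of expressed features per matrix.
#' @param n_planted_triplets number of planted lncRNA/miRNA/mRNA triplets.
#' @param mirnas_per_triplet shared miRNAs planted per triplet (>= 1).
#' @param n_decoy_pairs lncRNA-mRNA decoy pairs that share a miRNA in the
#'   target tables but carry no expression structure.
#' @param decoy_fail_fraction fraction of extra decoy target records built to
#'   fail exactly one prediction threshold or appear in only one predictor.
#' @param stages ordered character vector of the four stage labels.
#' @param replicates_per_stage biological replicates per stage (>= 2).
#' @param dispersion negative-binomial dispersion phi, Var = mu + phi mu^2.
#' @param baseline_mean_log_range range (natural log) for per-feature
#'   baseline means, drawn log-uniformly.
#' @param fold_span ratio between the largest and smallest stage mean of a
#'   planted trajectory (> 1).
#' @param noise_sd sd of multiplicative log-normal sample-level noise on the
#'   stage means (0 = none).
#' @param contamination_fraction fraction of novel transcripts whose
#'   coding-potential verdicts mark them coding by one predictor, to
#'   exercise the intersection rule.
#' @param bidirectional_window promoter window (bp) within which the
#'   generator places bidirectional lncRNA TSSs (and beyond which it places
#'   intergenic ones).
#'
#' @return A validated list of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1, n_novel_transcripts = 50)
#' cfg$class_proportions
simulation_config <- function(seed = 1L,
                              n_coding_genes = 200L,
                              n_novel_transcripts = 500L,
                              class_proportions = default_class_proportions(),
                              n_lncrna = 300L,
                              n_mrna = 500L,
                              n_mirna = 100L,
                              n_planted_triplets = 20L,
                              mirnas_per_triplet = 2L,
                              n_decoy_pairs = 40L,
                              decoy_fail_fraction = 0.5,
                              stages = c("120dPG", "1mo", "3mo", "10mo"),
                              replicates_per_stage = 3L,
                              dispersion = 0.01,
                              baseline_mean_log_range = c(log(50), log(500)),
                              fold_span = 8,
                              noise_sd = 0.05,
                              contamination_fraction = 0,
                              bidirectional_window = 1000L) {
  cfg <- list(
    seed = as.integer(seed),
    n_coding_genes = as.integer(n_coding_genes),
    n_novel_transcripts = as.integer(n_novel_transcripts),
    class_proportions = class_proportions,
    n_lncrna = as.integer(n_lncrna),
    n_mrna = as.integer(n_mrna),
    n_mirna = as.integer(n_mirna),
    n_planted_triplets = as.integer(n_planted_triplets),
    mirnas_per_triplet = as.integer(mirnas_per_triplet),
    n_decoy_pairs = as.integer(n_decoy_pairs),
    decoy_fail_fraction = decoy_fail_fraction,
    stages = as.character(stages),
    replicates_per_stage = as.integer(replicates_per_stage),
    dispersion = dispersion,
    baseline_mean_log_range = baseline_mean_log_range,
    fold_span = fold_span,
    noise_sd = noise_sd,
    contamination_fraction = contamination_fraction,
    bidirectional_window = as.integer(bidirectional_window)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

#' @rdname simulation_config
#' @export
default_class_proportions <- function() {
  p <- c(
    lincRNA = 52.4, antisense = 13.4, sense_overlapping = 7.2,
    intronic = 11.6, bidirectional = 10.22
  )
  p / sum(p)
}

lnc_classes <- function() {
  c("lincRNA", "antisense", "sense_overlapping", "intronic", "bidirectional")
}

validate_simulation_config <- function(cfg) {
  p <- cfg$class_proportions
  if (!is.numeric(p) || is.null(names(p)) ||
      !setequal(names(p), lnc_classes())) {
    abort("class_proportions must be a named numeric over the five positional classes")
  }
  if (any(p < 0)) abort("class_proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("class_proportions must sum to 1 (got %.10f)", sum(p)))
  }
  ints <- c(
    "n_coding_genes", "n_novel_transcripts", "n_lncrna", "n_mrna", "n_mirna",
    "n_planted_triplets", "mirnas_per_triplet"
  )
  for (f in ints) {
    if (cfg[[f]] < 1L) abort(sprintf("%s must be >= 1", f))
  }
  if (cfg$n_decoy_pairs < 0L) abort("n_decoy_pairs must be >= 0")
  if (cfg$replicates_per_stage < 2L) abort("replicates_per_stage must be >= 2")
  if (length(cfg$stages) != 4L || anyDuplicated(cfg$stages)) {
    abort("stages must be 4 distinct labels")
  }
  if (cfg$dispersion <= 0) abort("dispersion must be > 0")
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0")
  if (cfg$fold_span <= 1) abort("fold_span must be > 1")
  if (length(cfg$baseline_mean_log_range) != 2 ||
      diff(cfg$baseline_mean_log_range) < 0) {
    abort("baseline_mean_log_range must be an increasing pair")
  }
  if (cfg$decoy_fail_fraction < 0 || cfg$decoy_fail_fraction > 1) {
    abort("decoy_fail_fraction must be in [0, 1]")
  }
  if (cfg$contamination_fraction < 0 || cfg$contamination_fraction > 1) {
    abort("contamination_fraction must be in [0, 1]")
  }
  if (cfg$n_planted_triplets > min(cfg$n_lncrna, cfg$n_mrna)) {
    abort("n_planted_triplets exceeds available lncRNA or mRNA features")
  }
  if (cfg$n_planted_triplets * cfg$mirnas_per_triplet > cfg$n_mirna) {
    abort("not enough miRNAs for the requested planted triplets")
  }
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf(
    "  %d coding genes, %d novel transcripts; %d lncRNA x %d mRNA x %d miRNA\n",
    x$n_coding_genes, x$n_novel_transcripts, x$n_lncrna, x$n_mrna, x$n_mirna
  ))
  cat(sprintf(
    "  stages: %s (x%d replicates); %d planted triplets; phi = %g; seed = %d\n",
    paste(x$stages, collapse = ", "), x$replicates_per_stage,
    x$n_planted_triplets, x$dispersion, x$seed
  ))
  invisible(x)
}
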