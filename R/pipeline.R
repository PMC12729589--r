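#' Configuration for a full pipeline run
#'
#' Bundles the simulation settings and every screening threshold. Defaults
#' are the printed thresholds of the reference screen (TargetScan-style
#' score >= 50, miRanda-style energy <= -10, Spearman <= -0.7, Pearson
#' >= 0.9, hypergeometric p < 0.05, DE at FDR < 0.05 and |log2FC| > 1, NB
#' dispersion 0.01), so a bare run is "the screen at its published
#' thresholds on synthetic data".
#'
#' @param seed master seed for the run.
#' @param sim a [simulation_config()]; defaults to one built from `seed`.
#' @param score_min,energy_max,rho_max,r_min,p_max,alpha,lfc,phi,phi_mirna
#'   screen thresholds, see [cerna_screen()].
#' @param bidirectional_window,min_overlap classifier parameters, see
#'   [classify_lncrnas()].
#' @param top_lnc,top_mrna connectivity-ranking depth, see
#'   [connectivity_ranking()].
#' @param de_gate,universe_mode,pair_types screen options.
#' @return A validated list of class `cerna_config`.
#' @export
cerna_config <- function(seed = 1L, sim = simulation_config(seed = seed),
                         score_min = 50, energy_max = -10,
                         rho_max = -0.7, r_min = 0.9, p_max = 0.05,
                         alpha = 0.05, lfc = 1, phi = 0.01, phi_mirna = phi,
                         bidirectional_window = 1000L, min_overlap = 1L,
                         top_lnc = 3L, top_mrna = 6L,
                         de_gate = TRUE, universe_mode = "filtered",
                         pair_types = "lncRNA-mRNA") {
  stopifnot(inherits(sim, "simulation_config"))
  if (rho_max < -1 || rho_max > 1) abort("rho_max must lie in [-1, 1]")
  if (r_min < -1 || r_min > 1) abort("r_min must lie in [-1, 1]")
  if (p_max <= 0 || p_max > 1) abort("p_max must lie in (0, 1]")
  if (alpha <= 0 || alpha > 1) abort("alpha must lie in (0, 1]")
  if (phi <= 0 || phi_mirna <= 0) abort("dispersions must be > 0")
  if (lfc < 0) abort("lfc must be >= 0")
  if (sim$n_lncrna > sim$n_novel_transcripts) {
    abort("n_lncrna must not exceed n_novel_transcripts (lncRNA ids are drawn from the novel annotation)")
  }
  structure(
    list(
      seed = as.integer(seed), sim = sim,
      score_min = score_min, energy_max = energy_max, rho_max = rho_max,
      r_min = r_min, p_max = p_max, alpha = alpha, lfc = lfc,
      phi = phi, phi_mirna = phi_mirna,
      bidirectional_window = as.integer(bidirectional_window),
      min_overlap = as.integer(min_overlap),
      top_lnc = as.integer(top_lnc), top_mrna = as.integer(top_mrna),
      de_gate = de_gate, universe_mode = universe_mode,
      pair_types = pair_types
    ),
    class = "cerna_config"
  )
}

#' Run the whole synthetic ceRNA pipeline into a directory
#'
#' Executes simulate -> classify -> QC -> differential expression -> ceRNA
#' screen -> wet-lab statistics in dependency order, writing every
#' intermediate artifact as plain text plus a machine-readable
#' `run_report.json` whose record counts equal the on-disk row counts.
#' Rerunning with the same config into a clean directory reproduces
#' identical tables.
#'
#' @param config a [cerna_config()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages (default `TRUE`).
#' @return The run report, invisibly: a nested list with per-stage counts,
#'   thresholds used, seed and package version.
#' @export
run_cerna_pipeline <- function(config = cerna_config(), outdir, quiet = TRUE) {
  stopifnot(inherits(config, "cerna_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  pth <- function(...) file.path(outdir, ...)

  # -- annotation ------------------------------------------------------
  say("simulating annotation")
  ann <- simulate_annotation(config$sim)
  write_gtf(ann$coding, pth("coding.gtf"))
  write_gtf(ann$novel, pth("novel_candidates.gtf"))
  readr::write_tsv(ann$verdicts, pth("coding_potential_verdicts.tsv"))
  readr::write_tsv(ann$true_class, pth("truth_classes.tsv"))

  say("filtering and classifying novel lncRNAs")
  retained <- filter_novel_lncrnas(ann$novel, ann$verdicts)
  classes <- classify_lncrnas(
    retained, ann$coding,
    bidirectional_window = config$bidirectional_window,
    min_overlap = config$min_overlap
  )
  readr::write_tsv(classes, pth("lncrna_classes.tsv"))
  agreement <- classes |>
    inner_join(ann$true_class, by = "transcript_id") |>
    summarise(agreement = mean(.data$class.x == .data$class.y)) |>
    dplyr::pull(.data$agreement)

  # -- expression ------------------------------------------------------
  say("simulating expression")
  sim <- simulate_expression(config$sim)
  write_counts(sim$lnc, pth("lncrna_counts.tsv"))
  write_counts(sim$mrna, pth("mrna_counts.tsv"))
  write_counts(sim$mirna, pth("mirna_counts.tsv"))
  write_samplesheet(sim$samples, pth("samples.tsv"))
  readr::write_tsv(sim$truth$planted_triplets, pth("truth_triplets.tsv"))
  readr::write_tsv(sim$truth$decoy_pairs, pth("truth_decoys.tsv"))
  targets <- simulate_targets(config$sim, sim$truth)
  write_targets(targets, pth("targets.tsv"))

  say("expression QC")
  lnc_lengths <- transcript_summary(ann$novel) |>
    select(feature_id = "transcript_id", "length")
  fpkm_lnc <- fpkm(sim$lnc, lnc_lengths)
  readr::write_tsv(fpkm_lnc, pth("lncrna_fpkm.tsv"))
  sf_lnc <- size_factors(sim$lnc)
  readr::write_tsv(sf_lnc, pth("lncrna_size_factors.tsv"))
  pca <- pca_coordinates(sim$lnc)
  readr::write_tsv(pca$scores, pth("lncrna_pca.tsv"))
  corr <- sample_correlation(sim$lnc)
  readr::write_tsv(as_tibble(corr, rownames = "sample_id"), pth("sample_correlation.tsv"))

  # -- DE + ceRNA screen ----------------------------------------------
  say("differential expression and ceRNA screen")
  screen <- cerna_screen(
    sim$lnc, sim$mrna, sim$mirna, sim$samples, targets,
    score_min = config$score_min, energy_max = config$energy_max,
    rho_max = config$rho_max, r_min = config$r_min, p_max = config$p_max,
    alpha = config$alpha, lfc = config$lfc,
    phi = config$phi, phi_mirna = config$phi_mirna,
    de_gate = config$de_gate, universe_mode = config$universe_mode,
    pair_types = config$pair_types
  )
  readr::write_tsv(screen$de$lnc, pth("de_lncrna.tsv"))
  readr::write_tsv(screen$de$mrna, pth("de_mrna.tsv"))
  readr::write_tsv(screen$de$mirna, pth("de_mirna.tsv"))
  membership <- de_set_ops(screen$de$lnc)$membership
  readr::write_tsv(membership, pth("de_lncrna_membership.tsv"))
  readr::write_tsv(screen$edges, pth("cerna_edges.tsv"))
  pairs_flat <- screen$pairs |>
    mutate(shared_mirnas = purrr::map_chr(
      .data$shared_mirnas,
      paste,
      collapse = ";"
    ))
  readr::write_tsv(pairs_flat, pth("cerna_pairs.tsv"))
  write_network(screen$network, pth("cerna_network"), format = "tsv")
  write_network(screen$network, pth("cerna_network.json"), format = "json")
  write_network(screen$network, pth("cerna_network.graphml"), format = "graphml")
  ranking <- connectivity_ranking(
    screen$network,
    top_lnc = config$top_lnc, top_mrna = config$top_mrna
  )
  readr::write_tsv(ranking$sankey, pth("sankey_triples.tsv"))
  recovery <- evaluate_screen(screen$pairs, sim$truth)

  # -- wet-lab statistics ---------------------------------------------
  say("wet-lab validation statistics")
  qp <- simulate_qpcr(config$sim)
  readr::write_tsv(qp$ct, pth("qpcr_ct.tsv"))
  folds <- ddct(qp$ct, "beta-actin", config$sim$stages[1])
  readr::write_tsv(folds, pth("qpcr_folds.tsv"))
  anova_tbl <- folds |>
    group_by(.data$gene) |>
    dplyr::group_modify(~ one_way_anova(.x, value = "fold", group = "group")) |>
    ungroup()
  readr::write_tsv(anova_tbl, pth("qpcr_anova.tsv"))
  luc <- simulate_luciferase(config$sim)
  readr::write_tsv(luc, pth("luciferase_readings.tsv"))
  rel <- luciferase_relative(luc)
  readr::write_tsv(rel$relative, pth("luciferase_relative.tsv"))

  report <- list(
    seed = config$seed,
    version = as.character(utils::packageVersion("cernascreen")),
    thresholds = config[c(
      "score_min", "energy_max", "rho_max", "r_min", "p_max",
      "alpha", "lfc", "phi", "phi_mirna"
    )],
    stages = list(
      annotation = list(
        n_coding = dplyr::n_distinct(ann$coding$transcript_id),
        n_novel = dplyr::n_distinct(ann$novel$transcript_id),
        n_retained = dplyr::n_distinct(retained$transcript_id),
        classifier_agreement = agreement
      ),
      expression = list(
        n_lncrna = nrow(sim$lnc), n_mrna = nrow(sim$mrna),
        n_mirna = nrow(sim$mirna), n_samples = nrow(sim$samples),
        n_target_records = nrow(targets)
      ),
      de = list(
        comparisons = unique(screen$de$lnc$comparison),
        n_sig_lncrna = dplyr::n_distinct(
          screen$de$lnc$feature_id[screen$de$lnc$status != "ns"]
        ),
        n_sig_mrna = dplyr::n_distinct(
          screen$de$mrna$feature_id[screen$de$mrna$status != "ns"]
        ),
        n_sig_mirna = dplyr::n_distinct(
          screen$de$mirna$feature_id[screen$de$mirna$status != "ns"]
        )
      ),
      cerna = list(
        n_filtered_targets = nrow(screen$targets),
        n_edges = nrow(screen$edges),
        n_pairs = nrow(screen$pairs),
        n_nodes = nrow(screen$network$nodes),
        n_sankey = nrow(ranking$sankey),
        recovery = as.list(recovery)
      ),
      wetlab = list(
        n_qpcr_rows = nrow(qp$ct), n_fold_rows = nrow(folds),
        n_luciferase_rows = nrow(luc)
      )
    )
  )
  jsonlite::write_json(report, pth("run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  say("done: %d ceRNA pairs", nrow(screen$pairs))
  invisible(report)
}
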