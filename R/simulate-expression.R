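#' Simulate stage-structured count matrices with planted ceRNA triplets
#'
#' Draws negative-binomial counts (`Var = mu + phi mu^2`) for three feature
#' classes over a 4-stage x `replicates_per_stage` design. The first
#' `n_planted_triplets` lncRNAs/mRNAs and the first
#' `n_planted_triplets * mirnas_per_triplet` miRNAs form planted ceRNA
#' triplets: each planted miRNA follows a strictly monotone geometric ramp
#' across the four stages (total span `fold_span`), and its partner lncRNA
#' and mRNA follow the reversed ramp, so that on noise-free stage means
#' Spearman(miRNA, lncRNA) = -1 and Pearson(lncRNA, mRNA) = +1 exactly. All
#' other features have stage-constant means drawn log-uniformly from
#' `baseline_mean_log_range`. Sample-level multiplicative log-normal noise
#' with sd `noise_sd` perturbs the stage means before counts are drawn.
#'
#' @param config a [simulation_config()].
#' @param noise_model `"nb"` (default) draws negative-binomial counts;
#'   `"poisson"` draws Poisson counts; `"means"` returns the (real-valued)
#'   per-sample means themselves — the noise-free limit used to verify the
#'   planted correlation structure in closed form.
#' @return A list with count tibbles `lnc`, `mrna`, `mirna` (column
#'   `feature_id` + one column per sample), `samples` (sample sheet:
#'   `sample_id`, `stage`, `replicate`) and `truth`, itself a list with
#'   `planted_triplets` (one row per lncRNA/miRNA/mRNA combination),
#'   `planted_pairs`, and `decoy_pairs`.
#' @export
#' @examples
#' sim <- simulate_expression(simulation_config(
#'   seed = 7, n_lncrna = 30, n_mrna = 40,
#'   n_mirna = 20, n_planted_triplets = 3
#' ))
#' dim(as.matrix(sim$lnc[-1]))
simulate_expression <- function(config, noise_model = c("nb", "poisson", "means")) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  noise_model <- match.arg(noise_model)

  n_stage <- length(config$stages)
  reps <- config$replicates_per_stage
  samples <- tibble(
    sample_id = paste0(
      rep(config$stages, each = reps), "-",
      rep(seq_len(reps), times = n_stage)
    ),
    stage = rep(config$stages, each = reps),
    replicate = rep(seq_len(reps), times = n_stage)
  )

  lnc_ids <- sprintf("MSTRG.%d.1", seq_len(config$n_lncrna))
  mrna_ids <- sprintf("gene-%04d", seq_len(config$n_mrna))
  mirna_ids <- sprintf("chi-miR-%03d-5p", seq_len(config$n_mirna))

  n_tr <- config$n_planted_triplets
  mpt <- config$mirnas_per_triplet
  planted_lnc <- lnc_ids[seq_len(n_tr)]
  planted_mrna <- mrna_ids[seq_len(n_tr)]
  planted_mirna <- matrix(mirna_ids[seq_len(n_tr * mpt)], nrow = n_tr, byrow = TRUE)

  # geometric ramp with total span fold_span and geometric mean 1
  ramp <- config$fold_span^(seq(0, 1, length.out = n_stage) - 0.5)

  # planted trajectory direction per triplet (miRNA up or down over stages)
  dir <- with_seed(
    sub_seed(config$seed, 21L),
    sample(c(-1, 1), n_tr, replace = TRUE)
  )

  stage_means <- function(ids, stream, planted_rows, planted_dir) {
    nf <- length(ids)
    base <- with_seed(
      sub_seed(config$seed, stream),
      exp(runif(
        nf, config$baseline_mean_log_range[1],
        config$baseline_mean_log_range[2]
      ))
    )
    mu <- matrix(base, nrow = nf, ncol = n_stage)
    for (j in seq_along(planted_rows)) {
      mu[planted_rows[j], ] <- base[planted_rows[j]] * ramp^planted_dir[j]
    }
    rownames(mu) <- ids
    mu
  }

  mu_mirna <- stage_means(
    mirna_ids, 22L,
    planted_rows = seq_len(n_tr * mpt),
    planted_dir = rep(dir, each = mpt)
  )
  # lncRNA / mRNA follow the reversed miRNA trajectory
  mu_lnc <- stage_means(lnc_ids, 23L, seq_len(n_tr), -dir)
  mu_mrna <- stage_means(mrna_ids, 24L, seq_len(n_tr), -dir)

  draw <- function(mu, stream) {
    nf <- nrow(mu)
    ns <- nrow(samples)
    m <- mu[, match(samples$stage, config$stages), drop = FALSE]
    colnames(m) <- samples$sample_id
    with_seed(sub_seed(config$seed, stream), {
      if (config$noise_sd > 0 && noise_model != "means") {
        m <- m * matrix(exp(rnorm(nf * ns, 0, config$noise_sd)), nf, ns)
      }
      out <- switch(noise_model,
        means = m,
        poisson = matrix(stats::rpois(nf * ns, lambda = m), nf, ns),
        nb = matrix(
          rnbinom(nf * ns, mu = m, size = 1 / config$dispersion), nf, ns
        )
      )
    })
    dimnames(out) <- dimnames(m)
    matrix_to_counts(out)
  }

  lnc <- draw(mu_lnc, 31L)
  mrna <- draw(mu_mrna, 32L)
  mirna <- draw(mu_mirna, 33L)

  planted_triplets <- tibble(
    lncrna_id = rep(planted_lnc, each = mpt),
    mirna_id = as.vector(t(planted_mirna)),
    mrna_id = rep(planted_mrna, each = mpt)
  )
  planted_pairs <- tibble(lncrna_id = planted_lnc, mrna_id = planted_mrna)

  # decoy pairs: non-planted lncRNA/mRNA pairs that will share a miRNA in the
  # target tables but have stage-constant, independent expression
  nd <- min(
    config$n_decoy_pairs,
    config$n_lncrna - n_tr, config$n_mrna - n_tr,
    config$n_mirna - n_tr * mpt
  )
  decoy_pairs <- tibble(
    lncrna_id = lnc_ids[n_tr + seq_len(nd)],
    mrna_id = mrna_ids[n_tr + seq_len(nd)],
    mirna_id = mirna_ids[n_tr * mpt + seq_len(nd)]
  )

  list(
    lnc = lnc, mrna = mrna, mirna = mirna, samples = samples,
    truth = list(
      planted_triplets = planted_triplets,
      planted_pairs = planted_pairs,
      decoy_pairs = decoy_pairs
    )
  )
}

#' Simulate miRNA target-prediction tables for a planted ground truth
#'
#' Emits one record per (miRNA, target RNA) interaction with a
#' TargetScan-style score (higher = more likely) and a miRanda-style binding
#' energy (more negative = stronger). Planted interactions always pass both
#' thresholds (score >= 50, energy <= -10) and appear in both predictors
#' (`source = "both"`). Decoy-pair interactions also pass, so that only the
#' expression screen can remove them. A further `decoy_fail_fraction`
#' proportion of random records is built to fail exactly one threshold or to
#' appear in only one predictor's output, exercising the intersection rule.
#'
#' @param config a [simulation_config()].
#' @param truth the `truth` element returned by [simulate_expression()].
#' @return A tibble with columns `mirna_id`, `target_id`,
#'   `targetscan_score`, `miranda_energy`, `source`
#'   (one of `"both"`, `"targetscan"`, `"miranda"`).
#' @export
simulate_targets <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  tr <- truth$planted_triplets
  passing <- function(n, stream) {
    with_seed(sub_seed(config$seed, stream), tibble(
      targetscan_score = runif(n, 60, 95),
      miranda_energy = runif(n, -30, -15)
    ))
  }

  planted <- bind_rows(
    tibble(mirna_id = tr$mirna_id, target_id = tr$lncrna_id),
    tibble(mirna_id = tr$mirna_id, target_id = tr$mrna_id)
  ) |>
    distinct()
  planted <- dplyr::bind_cols(planted, passing(nrow(planted), 41L)) |>
    mutate(source = "both")

  dp <- truth$decoy_pairs
  decoy <- bind_rows(
    tibble(mirna_id = dp$mirna_id, target_id = dp$lncrna_id),
    tibble(mirna_id = dp$mirna_id, target_id = dp$mrna_id)
  ) |>
    distinct()
  decoy <- dplyr::bind_cols(decoy, passing(nrow(decoy), 42L)) |>
    mutate(source = "both")

  # threshold / intersection failures over random non-planted combinations
  n_fail <- ceiling(config$decoy_fail_fraction * nrow(decoy))
  failing <- NULL
  if (n_fail > 0) {
    failing <- with_seed(sub_seed(config$seed, 43L), {
      mir_pool <- sprintf("chi-miR-%03d-5p", seq_len(config$n_mirna))
      tgt_pool <- c(
        sprintf("MSTRG.%d.1", seq_len(config$n_lncrna)),
        sprintf("gene-%04d", seq_len(config$n_mrna))
      )
      mode <- sample(c("low_score", "weak_energy", "single_source"),
        n_fail,
        replace = TRUE
      )
      tibble(
        mirna_id = sample(mir_pool, n_fail, replace = TRUE),
        target_id = sample(tgt_pool, n_fail, replace = TRUE),
        targetscan_score = ifelse(mode == "low_score",
          runif(n_fail, 20, 49), runif(n_fail, 60, 95)
        ),
        miranda_energy = ifelse(mode == "weak_energy",
          runif(n_fail, -9, -1), runif(n_fail, -30, -15)
        ),
        source = ifelse(mode == "single_source",
          sample(c("targetscan", "miranda"), n_fail, replace = TRUE), "both"
        )
      )
    })
    # a failing record must not duplicate (and thereby mask) a planted one
    failing <- anti_join(failing, planted, by = c("mirna_id", "target_id")) |>
      anti_join(decoy, by = c("mirna_id", "target_id"))
    failing$miranda_energy[failing$source == "targetscan"] <- NA_real_
    failing$targetscan_score[failing$source == "miranda"] <- NA_real_
  }

  bind_rows(planted, decoy, failing) |>
    distinct(.data$mirna_id, .data$target_id, .keep_all = TRUE)
}
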