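test_that("class counts follow the configured proportions deterministically", {
  cfg <- simulation_config(seed = 1, n_coding_genes = 200, n_novel_transcripts = 1000)
  ann <- simulate_annotation(cfg)
  got <- table(ann$true_class$class)
  # largest-remainder apportionment of the normalized default proportions
  p <- default_class_proportions()
  expected <- floor(1000 * p)
  short <- 1000 - sum(expected)
  ord <- order(1000 * p - expected, decreasing = TRUE)
  expected[ord[seq_len(short)]] <- expected[ord[seq_len(short)]] + 1
  for (cls in names(expected)) {
    expect_equal(unname(got[[cls]]), unname(expected[[cls]]))
  }
  expect_equal(sum(got), 1000)
})

test_that("degenerate proportions put every transcript in one class", {
  cfg <- simulation_config(
    seed = 2, n_coding_genes = 20, n_novel_transcripts = 10,
    class_proportions = c(
      lincRNA = 0, antisense = 0, sense_overlapping = 0,
      intronic = 1, bidirectional = 0
    )
  )
  ann <- simulate_annotation(cfg)
  expect_true(all(ann$true_class$class == "intronic"))
  # and the geometry realizes it
  cl <- classify_lncrnas(ann$novel, ann$coding)
  expect_true(all(cl$class == "intronic"))
})

test_that("config validation rejects bad proportions and degenerate designs", {
  expect_error(
    simulation_config(class_proportions = c(
      lincRNA = 0.5, antisense = 0.2, sense_overlapping = 0.2,
      intronic = 0.2, bidirectional = 0.2
    )),
    "sum to 1"
  )
  expect_error(simulation_config(replicates_per_stage = 1), "replicates")
  expect_error(simulation_config(dispersion = 0), "dispersion")
  expect_error(
    simulation_config(n_mirna = 3, n_planted_triplets = 5),
    "miRNA"
  )
})

test_that("same seed and config give byte-identical outputs", {
  cfg <- small_sim_config(seed = 11)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a, b)
  expect_identical(simulate_annotation(cfg), simulate_annotation(cfg))
  expect_identical(
    simulate_targets(cfg, a$truth),
    simulate_targets(cfg, b$truth)
  )
  c <- simulate_expression(small_sim_config(seed = 12))
  expect_false(identical(a$lnc, c$lnc))
})

test_that("noise-free planted triplets have Spearman -1 and Pearson +1", {
  cfg <- small_sim_config(seed = 3, noise_sd = 0)
  sim <- simulate_expression(cfg, noise_model = "means")
  mir <- counts_to_mat(sim$mirna)
  lnc <- counts_to_mat(sim$lnc)
  mrna <- counts_to_mat(sim$mrna)
  for (i in seq_len(nrow(sim$truth$planted_triplets))) {
    tr <- sim$truth$planted_triplets[i, ]
    expect_equal(
      cor(mir[tr$mirna_id, ], lnc[tr$lncrna_id, ], method = "spearman"),
      -1
    )
    expect_equal(
      cor(mir[tr$mirna_id, ], mrna[tr$mrna_id, ], method = "spearman"),
      -1
    )
    expect_equal(
      cor(lnc[tr$lncrna_id, ], mrna[tr$mrna_id, ]), 1,
      tolerance = 1e-12
    )
  }
  # planted miRNA stage means strictly monotone
  stages <- unique(sim$samples$stage)
  mu <- sapply(stages, function(s) {
    rowMeans(mir[, sim$samples$sample_id[sim$samples$stage == s], drop = FALSE])
  })
  for (id in unique(sim$truth$planted_triplets$mirna_id)) {
    d <- diff(mu[id, ])
    expect_true(all(d > 0) || all(d < 0))
  }
})

test_that("empirical feature means converge to configured means over replicates", {
  cfg <- simulation_config(
    seed = 5, n_lncrna = 30, n_mrna = 30, n_mirna = 10,
    n_planted_triplets = 2, replicates_per_stage = 200, noise_sd = 0
  )
  sim <- simulate_expression(cfg)
  mu <- counts_to_mat(simulate_expression(cfg, noise_model = "means")$lnc)
  counts <- counts_to_mat(sim$lnc)
  stage1 <- sim$samples$sample_id[sim$samples$stage == cfg$stages[1]]
  m_emp <- rowMeans(counts[, stage1])
  m_true <- mu[rownames(counts), stage1[1]]
  se <- sqrt((m_true + cfg$dispersion * m_true^2) / length(stage1))
  expect_true(all(abs(m_emp - m_true) <= 3 * se))
})

test_that("target tables plant passing records and threshold-failing decoys", {
  cfg <- small_sim_config(seed = 9)
  sim <- simulate_expression(cfg)
  tg <- simulate_targets(cfg, sim$truth)
  tr <- sim$truth$planted_triplets
  planted_keys <- c(
    paste(tr$mirna_id, tr$lncrna_id),
    paste(tr$mirna_id, tr$mrna_id)
  )
  tg_keys <- paste(tg$mirna_id, tg$target_id)
  expect_true(all(planted_keys %in% tg_keys))
  planted_rows <- tg[tg_keys %in% planted_keys, ]
  expect_true(all(planted_rows$targetscan_score >= 50))
  expect_true(all(planted_rows$miranda_energy <= -10))
  expect_true(all(planted_rows$source == "both"))
  # failing records exist and are dropped by the filter
  filt <- filter_targets(tg)
  dropped <- dplyr::anti_join(tg, filt, by = c("mirna_id", "target_id"))
  expect_gt(nrow(dropped), 0)
  expect_true(all(
    dropped$source != "both" |
      dropped$targetscan_score < 50 | dropped$miranda_energy > -10
  ))
})

test_that("qPCR generator round-trips planted folds through 2^-ddCt", {
  cfg <- small_sim_config(seed = 4)
  # noise-free closed form: planted fold 2 in stage 2 -> ddct -1 -> fold 2
  folds <- tidyr::expand_grid(gene = "g1", stage = cfg$stages) |>
    dplyr::mutate(fold = c(1, 2, 4, 8))
  qp <- simulate_qpcr(cfg, genes = "g1", folds = folds, ct_noise_sd = 0)
  est <- ddct(qp$ct, "beta-actin", cfg$stages[1])
  got <- est |>
    dplyr::group_by(group) |>
    dplyr::summarise(fold = exp(mean(log(fold))))
  expect_equal(
    got$fold[match(cfg$stages, got$group)], c(1, 2, 4, 8),
    tolerance = 1e-10
  )
  # noisy version recovers folds approximately
  qp2 <- simulate_qpcr(cfg, genes = "g1", folds = folds, ct_noise_sd = 0.05)
  est2 <- ddct(qp2$ct, "beta-actin", cfg$stages[1]) |>
    dplyr::group_by(group) |>
    dplyr::summarise(fold = exp(mean(log(fold))))
  expect_equal(
    est2$fold[match(cfg$stages, est2$group)], c(1, 2, 4, 8),
    tolerance = 0.2
  )
})

test_that("luciferase generator plants suppression in WT only", {
  cfg <- small_sim_config(seed = 6)
  luc <- simulate_luciferase(cfg, suppression_wt = 0.5, noise_sd = 0)
  rel <- luciferase_relative(luc)$relative
  expect_equal(rel$relative_activity[rel$construct == "WT"], 0.5, tolerance = 1e-12)
  expect_equal(rel$relative_activity[rel$construct == "MUT"], 1, tolerance = 1e-12)
  luc2 <- simulate_luciferase(cfg, suppression_wt = 0.5, noise_sd = 0.05)
  rel2 <- luciferase_relative(luc2)$relative
  expect_equal(rel2$relative_activity[rel2$construct == "MUT"], 1, tolerance = 0.15)
})
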