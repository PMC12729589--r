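test_that("target filtering applies both thresholds and the intersection rule", {
  rec <- tibble::tibble(
    mirna_id = paste0("m", 1:5), target_id = paste0("t", 1:5),
    targetscan_score = c(55, 45, 80, 50, 90),
    miranda_energy = c(-12, -20, -5, -10, -25),
    source = c("both", "both", "both", "both", "targetscan")
  )
  kept <- filter_targets(rec)
  # m1 passes; m2 fails score; m3 fails energy; m4 sits exactly on both
  # thresholds (inclusive); m5 is in one predictor only
  expect_setequal(kept$mirna_id, c("m1", "m4"))
  # NA scores fail
  rec$targetscan_score[1] <- NA
  expect_false("m1" %in% filter_targets(rec)$mirna_id)
})

test_that("spearman edges match the rank-then-Pearson oracle, ties included", {
  set.seed(61)
  n <- 12
  mk <- function(ids, mat) {
    tibble::as_tibble(mat, .name_repair = ~ paste0("s", seq_len(ncol(mat)))) |>
      dplyr::mutate(feature_id = ids, .before = 1)
  }
  mir <- matrix(rpois(5 * n, 20), 5) # small counts force ties
  cer <- matrix(rpois(4 * n, 20), 4)
  targets <- tidyr::expand_grid(
    mirna_id = paste0("mir", 1:5), target_id = paste0("c", 1:4)
  ) |>
    dplyr::mutate(targetscan_score = 60, miranda_energy = -20, source = "both")
  edges <- spearman_edges(
    mk(paste0("mir", 1:5), mir), mk(paste0("c", 1:4), cer),
    targets,
    rho_max = 1 # keep everything to compare values
  )
  for (r in seq_len(nrow(edges))) {
    i <- as.integer(sub("mir", "", edges$mirna_id[r]))
    j <- as.integer(sub("c", "", edges$cerna_id[r]))
    oracle <- cor(
      rank(mir[i, ], ties.method = "average"),
      rank(cer[j, ], ties.method = "average")
    )
    expect_equal(edges$rho[r], oracle, tolerance = 1e-12)
  }
  # perfectly anti-monotone kept at the default threshold, monotone dropped
  anti <- mk("mono", matrix(12:1, 1))
  mono <- mk("c1", matrix(1:12, 1))
  tg1 <- tibble::tibble(
    mirna_id = "mono", target_id = "c1",
    targetscan_score = 60, miranda_energy = -20, source = "both"
  )
  e1 <- spearman_edges(anti, mono, tg1)
  expect_equal(e1$rho, -1)
  e2 <- spearman_edges(mono |> dplyr::mutate(feature_id = "mono"),
    mono, tg1,
    rho_max = -0.7
  )
  expect_equal(nrow(e2), 0)
  # constant profile: pair skipped with a warning
  const <- mk("mono", matrix(5, 1, 12))
  expect_warning(e3 <- spearman_edges(const, mono, tg1), "constant")
  expect_equal(nrow(e3), 0)
})

test_that("screen_pairs populates hypergeometric fields and honours thresholds", {
  cfg <- small_sim_config(seed = 62)
  sim <- simulate_expression(cfg)
  tg <- filter_targets(simulate_targets(cfg, sim$truth))
  sc <- cerna_screen(sim$lnc, sim$mrna, sim$mirna, sim$samples,
    simulate_targets(cfg, sim$truth),
    de_gate = FALSE
  )
  pairs <- sc$pairs
  expect_gt(nrow(pairs), 0)
  expect_true(all(pairs$pearson_r >= 0.9))
  expect_true(all(pairs$hyper_p < 0.05))
  expect_true(all(pairs$k >= 1))
  expect_true(all(pairs$k <= pmin(pairs$K, pairs$n)))
  expect_true(all(pairs$type_a == "lncRNA" & pairs$type_b == "mRNA"))
  # k, K, n recompute from the retained edges
  sets <- split(sc$edges$mirna_id, sc$edges$cerna_id)
  for (r in seq_len(nrow(pairs))) {
    expect_equal(pairs$k[r], length(intersect(
      sets[[pairs$rna_a[r]]], sets[[pairs$rna_b[r]]]
    )))
    expect_equal(pairs$K[r], length(sets[[pairs$rna_a[r]]]))
    expect_equal(pairs$n[r], length(sets[[pairs$rna_b[r]]]))
    expect_equal(
      pairs$hyper_p[r],
      hypergeom_shared(pairs$k[r], pairs$K[r], pairs$n[r], pairs$N[r])
    )
  }
  expect_equal(unique(pairs$N), dplyr::n_distinct(sc$edges$mirna_id))
})

test_that("noise-free planted triplets survive the full screen by construction", {
  cfg <- small_sim_config(seed = 63, noise_sd = 0, dispersion = 1e-4)
  sim <- simulate_expression(cfg)
  tg <- simulate_targets(cfg, sim$truth)
  sc <- cerna_screen(sim$lnc, sim$mrna, sim$mirna, sim$samples, tg)
  ev <- evaluate_screen(sc$pairs, sim$truth)
  expect_equal(ev$recovery, 1)
  expect_equal(ev$n_decoy_passed, 0)
})

test_that("tightening any one threshold yields a subset of the default pairs", {
  cfg <- small_sim_config(seed = 64)
  sim <- simulate_expression(cfg)
  tg <- simulate_targets(cfg, sim$truth)
  run <- function(...) {
    sc <- cerna_screen(sim$lnc, sim$mrna, sim$mirna, sim$samples, tg, ...)
    paste(sc$pairs$rna_a, sc$pairs$rna_b)
  }
  base <- run()
  expect_gt(length(base), 0)
  tighter <- list(
    run(score_min = 70), run(energy_max = -20), run(rho_max = -0.9),
    run(r_min = 0.97), run(p_max = 0.01), run(alpha = 0.001), run(lfc = 2)
  )
  for (tt in tighter) expect_true(all(tt %in% base))
})

test_that("network connectivity counts distinct miRNA partners", {
  pairs <- tibble::tibble(
    rna_a = c("L1", "L1"), rna_b = c("G1", "G2"),
    type_a = "lncRNA", type_b = "mRNA",
    shared_mirnas = list(c("m1", "m2"), "m1"),
    k = c(2L, 1L), K = c(3L, 3L), n = c(2L, 1L), N = 10L,
    pearson_r = c(0.95, 0.99), hyper_p = c(0.01, 0.04)
  )
  edges <- tibble::tibble(
    mirna_id = c("m1", "m2", "m3", "m1", "m2", "m1", "m1"),
    cerna_id = c("L1", "L1", "L1", "G1", "G1", "G2", "G2"),
    rho = -0.9
  ) # duplicated (m1, G2) edge must not double-count
  net <- build_network(pairs, edges)
  conn <- setNames(net$nodes$connectivity, net$nodes$id)
  expect_equal(unname(conn["L1"]), 3L)
  expect_equal(unname(conn["G1"]), 2L)
  expect_equal(unname(conn["G2"]), 1L)
  expect_equal(unname(conn["m1"]), 3L)
  # removing an edge never increases any connectivity
  net2 <- build_network(pairs, edges[-1, ])
  conn2 <- setNames(net2$nodes$connectivity, net2$nodes$id)
  expect_true(all(conn2[names(conn)] <= conn))
  # ranking: L1 first; sankey paths go through shared retained miRNAs
  rk <- connectivity_ranking(net, top_lnc = 3, top_mrna = 6)
  expect_equal(rk$lncrna$id[1], "L1")
  expect_true(all(c("G1", "G2") %in% rk$mrna$id))
  expect_true(all(rk$sankey$lncrna_id == "L1"))
  expect_setequal(
    paste(rk$sankey$mirna_id, rk$sankey$mrna_id),
    c("m1 G1", "m2 G1", "m1 G2")
  )
})

test_that("network and ranking are invariant to input row order", {
  cfg <- small_sim_config(seed = 65)
  sim <- simulate_expression(cfg)
  tg <- simulate_targets(cfg, sim$truth)
  sc <- cerna_screen(sim$lnc, sim$mrna, sim$mirna, sim$samples, tg)
  set.seed(1)
  perm_pairs <- sc$pairs[sample(nrow(sc$pairs)), ]
  perm_edges <- sc$edges[sample(nrow(sc$edges)), ]
  net1 <- build_network(sc$pairs, sc$edges)
  net2 <- build_network(perm_pairs, perm_edges)
  expect_equal(net1$nodes, net2$nodes)
  expect_equal(
    dplyr::arrange(net1$edges, edge_type, from, to),
    dplyr::arrange(net2$edges, edge_type, from, to)
  )
  expect_equal(
    connectivity_ranking(net1)$sankey,
    connectivity_ranking(net2)$sankey
  )
})

test_that("planted hub lncRNA ranks first by connectivity", {
  # hub: one lncRNA in three triplets via a shared mRNA pool
  cfg <- small_sim_config(seed = 66)
  sim <- simulate_expression(cfg)
  tg <- simulate_targets(cfg, sim$truth)
  # add two extra planted-style miRNA edges to lncRNA 1 by duplicating
  # records of other planted miRNAs targeting it
  extra <- tibble::tibble(
    mirna_id = unique(sim$truth$planted_triplets$mirna_id)[3:6],
    target_id = sim$truth$planted_pairs$lncrna_id[1],
    targetscan_score = 80, miranda_energy = -20, source = "both"
  )
  sc <- cerna_screen(
    sim$lnc, sim$mrna, sim$mirna, sim$samples,
    dplyr::bind_rows(tg, extra)
  )
  rk <- connectivity_ranking(sc$network)
  hub <- sim$truth$planted_pairs$lncrna_id[1]
  expect_equal(rk$lncrna$id[1], hub)
})
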