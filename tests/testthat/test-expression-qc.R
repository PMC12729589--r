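test_that("fpkm matches its closed form and scale invariances", {
  counts <- tibble::tibble(feature_id = c("f1", "f2"), s1 = c(100L, 0L))
  lens <- tibble::tibble(feature_id = c("f1", "f2"), length = c(1000, 500))
  libs <- tibble::tibble(sample_id = "s1", library_size = 1e6)
  x <- fpkm(counts, lens, libs)
  expect_equal(x$s1, c(100, 0)) # 100 * 1e9 / (1e3 * 1e6); zero count -> zero
  # doubling counts and library size leaves FPKM unchanged
  counts2 <- dplyr::mutate(counts, s1 = s1 * 2L)
  libs2 <- dplyr::mutate(libs, library_size = library_size * 2)
  expect_equal(fpkm(counts2, lens, libs2)$s1, x$s1)
  # linear in counts at fixed length/library
  expect_equal(fpkm(counts2, lens, libs)$s1, 2 * x$s1)
  expect_error(fpkm(counts, lens[1, ], libs), "f2")
})

test_that("median-of-ratios size factors match the hand-derived two-sample case", {
  # sample B = 2 x sample A, no zeros -> factors (1/sqrt(2), sqrt(2))
  counts <- tibble::tibble(
    feature_id = c("f1", "f2"), A = c(10L, 40L), B = c(20L, 80L)
  )
  sf <- size_factors(counts)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # identical samples -> all factors one
  eqc <- tibble::tibble(feature_id = c("f1", "f2"), A = c(5L, 9L), B = c(5L, 9L))
  expect_equal(size_factors(eqc)$size_factor, c(1, 1))
})

test_that("scaling one sample scales only its factor (up to the geometric reference)", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(rpois(40, 50) + 1L, 8, 5)
    counts <- tibble::as_tibble(m, .name_repair = ~ paste0("s", 1:5)) |>
      dplyr::mutate(feature_id = paste0("f", 1:8), .before = 1)
    sf <- size_factors(counts)$size_factor
    cscale <- 3L
    counts2 <- dplyr::mutate(counts, s2 = s2 * cscale)
    sf2 <- size_factors(counts2)$size_factor
    # geomean reference shifts by cscale^(1/n_samples); ratios are exact
    adj <- cscale^(1 / 5)
    expect_equal(sf2[2], sf[2] * cscale / adj, tolerance = 1e-10)
    expect_equal(sf2[-2], sf[-2] / adj, tolerance = 1e-10)
  }
})

test_that("size factors agree with an independent median-of-ratios implementation", {
  cfg <- small_sim_config(seed = 33)
  sim <- simulate_expression(cfg)
  m <- counts_to_mat(sim$mrna)
  mine <- size_factors(sim$mrna)$size_factor
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(m))
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("size factors error without an everywhere-expressed feature unless pseudo-reference", {
  counts <- tibble::tibble(
    feature_id = c("f1", "f2"), A = c(0L, 10L), B = c(10L, 0L)
  )
  expect_error(size_factors(counts), "pseudo_reference")
  sf <- size_factors(counts, pseudo_reference = TRUE)
  expect_true(all(is.finite(sf$size_factor) & sf$size_factor > 0))
})

test_that("PCA coordinates behave: duplicates coincide, variance fractions decrease", {
  cfg <- small_sim_config(seed = 34)
  sim <- simulate_expression(cfg)
  dup <- sim$lnc
  dup[["10mo-3"]] <- dup[["10mo-2"]] # duplicate a sample
  p <- pca_coordinates(dup, n_components = 4)
  sc <- p$scores
  expect_equal(
    unlist(sc[sc$sample_id == "10mo-3", -1]),
    unlist(sc[sc$sample_id == "10mo-2", -1]),
    tolerance = 1e-8
  )
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  expect_lte(sum(p$variance_explained), 1 + 1e-12)
  expect_error(pca_coordinates(sim$lnc, n_components = 1000), "n_components")
})

test_that("stages separate on PC1-PC2 better than permuted labels", {
  cfg <- small_sim_config(seed = 35)
  sim <- simulate_expression(cfg)
  p <- pca_coordinates(sim$lnc)
  xy <- as.matrix(p$scores[, c("PC1", "PC2")])
  sil <- function(labels) {
    d <- as.matrix(dist(xy))
    mean(vapply(seq_len(nrow(xy)), function(i) {
      a <- mean(d[i, labels == labels[i]][-which(which(labels == labels[i]) == i)])
      b <- min(vapply(
        setdiff(unique(labels), labels[i]),
        function(l) mean(d[i, labels == l]), numeric(1)
      ))
      (b - a) / max(a, b)
    }, numeric(1)))
  }
  truth <- sil(sim$samples$stage)
  set.seed(1)
  perm <- replicate(20, sil(sample(sim$samples$stage)))
  expect_gt(truth, max(perm))
})

test_that("sample correlation matches the covariance-formula oracle", {
  set.seed(36)
  m <- matrix(rpois(25, 40), 5, 5)
  counts <- tibble::as_tibble(m, .name_repair = ~ paste0("s", 1:5)) |>
    dplyr::mutate(feature_id = paste0("f", 1:5), .before = 1)
  r <- sample_correlation(counts, log_transform = FALSE)
  x <- m
  oracle <- matrix(1, 5, 5)
  for (i in 1:5) {
    for (j in 1:5) {
      xi <- x[, i] - mean(x[, i])
      xj <- x[, j] - mean(x[, j])
      oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  expect_equal(unname(r), oracle, tolerance = 1e-12)
  expect_equal(diag(r), setNames(rep(1, 5), paste0("s", 1:5)))
  # positive semi-definite within tolerance
  expect_gte(min(eigen(r, symmetric = TRUE)$values), -1e-10)
  # duplicate -> off-diagonal 1; negated deviations -> -1
  counts$s2 <- counts$s1
  r2 <- sample_correlation(counts, log_transform = FALSE)
  expect_equal(unname(r2["s1", "s2"]), 1)
  counts$s3 <- 2 * mean(counts$s1) - counts$s1
  r3 <- sample_correlation(counts, log_transform = FALSE)
  expect_equal(unname(r3["s1", "s3"]), -1, tolerance = 1e-12)
})

test_that("zero-variance samples are flagged undefined, not silently zero", {
  counts <- tibble::tibble(
    feature_id = c("f1", "f2"), s1 = c(1L, 5L), s2 = c(4L, 4L)
  )
  expect_warning(r <- sample_correlation(counts, log_transform = FALSE), "s2")
  expect_true(is.na(r["s1", "s2"]))
  expect_equal(unname(r["s2", "s2"]), 1)
})
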