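test_that("GTF coordinates convert between 1-based inclusive and 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    f
  )
  tx <- read_gtf(f)
  expect_equal(tx$start, 100L)
  expect_equal(tx$end, 200L)
  expect_equal(tx$end - tx$start, 100L)
  # write converts back
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(tx, f2)
  expect_match(readLines(f2), "\t101\t200\t", all = FALSE)
})

test_that("GTF round trip reproduces the synthetic annotation exactly", {
  ann <- simulate_annotation(small_sim_config(seed = 2))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann$novel, f)
  back <- read_gtf(f)
  key <- function(x) dplyr::arrange(x, transcript_id, start)
  expect_equal(key(back), key(ann$novel))
})

test_that("read_gtf agrees with an independent GTF parser on the synthetic annotation", {
  ann <- simulate_annotation(small_sim_config(seed = 8))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann$coding, f)
  mine <- read_gtf(f) |> dplyr::arrange(transcript_id, start)
  gr <- rtracklayer::import(f, format = "gtf")
  ref <- tibble::tibble(
    transcript_id = gr$transcript_id,
    start = as.integer(GenomicRanges::start(gr)) - 1L,
    end = as.integer(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr))
  ) |> dplyr::arrange(transcript_id, start)
  expect_equal(mine$start, ref$start)
  expect_equal(mine$end, ref$end)
  expect_equal(mine$strand, ref$strand)
})

test_that("malformed GTF lines raise errors naming the line", {
  f <- withr::local_tempfile(fileext = ".gtf")
  ok <- 'chr1\tsrc\texon\t10\t20\t.\t+\t.\tgene_id "g"; transcript_id "t";'
  writeLines(c(ok, "chr1\tbroken line"), f)
  expect_error(read_gtf(f), "line 2")
  writeLines(
    c(ok, 'chr1\tsrc\texon\t30\t20\t.\t+\t.\tgene_id "g"; transcript_id "t";'),
    f
  )
  expect_error(read_gtf(f), "line 2.*end < start")
  writeLines(
    c(ok, 'chr1\tsrc\texon\t30\t40\t.\t?\t.\tgene_id "g"; transcript_id "t";'),
    f
  )
  expect_error(read_gtf(f), "line 2.*strand")
  writeLines(c(ok, "chr1\tsrc\texon\t30\t40\t.\t+\t.\tfoo bar;"), f)
  expect_error(read_gtf(f), "line 2.*gene_id")
})

test_that("count readers validate instead of coercing", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "f1\t3\t4", "f2\t1\t2"), f)
  x <- read_counts(f)
  expect_equal(names(x), c("feature_id", "s1", "s2"))
  writeLines(c("feature_id\ts1", "f1\t-3"), f)
  expect_error(read_counts(f), "negative")
  writeLines(c("feature_id\ts1", "f1\t2.5"), f)
  expect_error(read_counts(f), "non-integer")
  writeLines(c("feature_id\ts1", "f1\t1", "f1\t2"), f)
  expect_error(read_counts(f), "duplicated")
  writeLines(c("feature_id\ts1", "bad id\t1"), f)
  expect_error(read_counts(f), "invalid")
})

test_that("sample sheet and count matrix are cross-validated", {
  counts <- tibble::tibble(feature_id = "f1", s1 = 1L, s2 = 2L)
  sheet <- tibble::tibble(
    sample_id = c("s1", "s3"), stage = "A", replicate = 1:2
  )
  expect_error(validate_counts_samples(counts, sheet), "s2")
  expect_error(validate_counts_samples(counts, sheet), "s3")
  good <- tibble::tibble(sample_id = c("s1", "s2"), stage = "A", replicate = 1:2)
  expect_silent(validate_counts_samples(counts, good))
})

test_that("an empty count matrix is valid and yields empty downstream results", {
  counts <- tibble::tibble(
    feature_id = character(), s1 = integer(), s2 = integer(),
    s3 = integer(), s4 = integer()
  )
  sheet <- tibble::tibble(
    sample_id = paste0("s", 1:4), stage = rep(c("A", "B"), each = 2),
    replicate = rep(1:2, 2)
  )
  de <- call_de(counts, sheet)
  expect_equal(nrow(de), 0)
})

test_that("synthetic pipeline outputs all load back without error", {
  out <- withr::local_tempdir()
  cfg <- cerna_config(seed = 5, sim = small_sim_config(seed = 5))
  run_cerna_pipeline(cfg, out)
  expect_s3_class(read_gtf(file.path(out, "novel_candidates.gtf")), "tbl_df")
  counts <- read_counts(file.path(out, "lncrna_counts.tsv"))
  sheet <- read_samplesheet(file.path(out, "samples.tsv"))
  expect_silent(validate_counts_samples(counts, sheet))
  expect_s3_class(read_targets(file.path(out, "targets.tsv")), "tbl_df")
})

test_that("network serialization round-trips through JSON and TSV", {
  cfg <- small_sim_config(seed = 13)
  sim <- simulate_expression(cfg)
  tg <- simulate_targets(cfg, sim$truth)
  sc <- cerna_screen(sim$lnc, sim$mrna, sim$mirna, sim$samples, tg)
  net <- sc$network
  expect_gt(nrow(net$edges), 0)
  f <- withr::local_tempfile(fileext = ".json")
  write_network(net, f, format = "json")
  back <- read_network(f, format = "json")
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  stem <- file.path(withr::local_tempdir(), "net")
  write_network(net, stem, format = "tsv")
  back2 <- read_network(stem, format = "tsv")
  expect_equal(back2$edges$from, net$edges$from)
  expect_equal(back2$edges$rho, net$edges$rho)
  # every planted pair recovered by the screen appears as a cerna-cerna edge
  cc <- net$edges[net$edges$edge_type == "cerna-cerna", ]
  expect_setequal(
    paste(cc$from, cc$to),
    paste(sc$pairs$rna_a, sc$pairs$rna_b)
  )
  g <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, g, format = "graphml")
  expect_true(file.size(g) > 0)
  expect_error(write_network(net, f, format = "xlsx"))
})

test_that("an empty network serializes to valid files with headers only", {
  empty_pairs <- tibble::tibble(
    rna_a = character(), rna_b = character(), type_a = character(),
    type_b = character(), shared_mirnas = list(), k = integer(),
    K = integer(), n = integer(), N = integer(),
    pearson_r = numeric(), hyper_p = numeric()
  )
  empty_edges <- tibble::tibble(
    mirna_id = character(), cerna_id = character(), rho = numeric()
  )
  net <- build_network(empty_pairs, empty_edges)
  expect_equal(nrow(net$nodes), 0)
  f <- withr::local_tempfile(fileext = ".json")
  write_network(net, f, format = "json")
  back <- read_network(f, format = "json")
  expect_equal(nrow(back$edges), 0)
  stem <- file.path(withr::local_tempdir(), "empty")
  write_network(net, stem, format = "tsv")
  expect_equal(readLines(paste0(stem, "_edges.tsv")),
    "from\tto\tedge_type\trho\tpearson_r\thyper_p\tk")
})
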