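# a small, fast configuration used across these tests
small_cfg <- function(...) {
  sim_config(n_chroms = 2L, chrom_len = 2e5, telomere_copies = 30L,
             private_rate = 0, ...)
}

test_that("recipient genomes have the planned structure", {
  cfg <- small_cfg(seed = 5L)
  g <- simulate_recipient(cfg)
  expect_equal(unname(g$lengths), rep(2e5, 2))
  expect_equal(names(g$sequences), c("chr01", "chr02"))
  # determinism
  expect_identical(simulate_recipient(cfg)$sequences, g$sequences)
  # background composition ~ uniform (3 sigma binomial on the non-planted run)
  core <- substr(g$sequences[[1]], 5000, 195000)
  n <- nchar(core)
  for (b in c("A", "C", "G", "T")) {
    f <- lengths(regmatches(core, gregexpr(b, core, fixed = TRUE))) / n
    expect_lt(abs(f - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  }
  # telomere termini present
  telo <- find_telomeres(g, terminal_len = 250L)
  expect_true(all(telo$start_telomere))
  expect_true(all(telo$end_telomere))
})

test_that("centromeric arrays are planted at the stated location", {
  cfg <- sim_config(n_chroms = 1L, chrom_len = 2e5,
                    centromeres = data.frame(seq = "chr01", position = 1e5,
                                             array_len = 2e4),
                    telomere_copies = 0L, seed = 6L)
  g <- simulate_recipient(cfg)
  monomer <- attr(g, "monomer")
  arr <- substr(g$sequences[[1]], 1e5 - 1e4 + 1, 1e5 + 1e4)
  expect_equal(arr, substr(strrep(monomer, ceiling(2e4 / nchar(monomer))),
                           1, 2e4))
})

test_that("donor divergence follows the substitution model", {
  cfg <- small_cfg(seed = 7L, divergence = 0)
  r <- simulate_recipient(cfg)
  expect_identical(derive_donor(r, cfg)$sequences, r$sequences)

  cfg <- small_cfg(seed = 7L, divergence = 0.01,
                   lowdiv = data.frame(seq = "chr01", start = 50000,
                                       end = 100000))
  d <- derive_donor(simulate_recipient(cfg), cfg)
  r <- simulate_recipient(cfg)
  mm <- count_mismatches(r$sequences[[2]], d$sequences[[2]])
  n <- nchar(r$sequences[[2]])
  expect_lt(abs(mm / n - 0.01), 4 * sqrt(0.01 * 0.99 / n))
  # zero mismatches inside the protected low-divergence segment
  expect_equal(count_mismatches(substr(r$sequences[[1]], 50001, 100000),
                                substr(d$sequences[[1]], 50001, 100000)), 0L)
})

test_that("cultivar construction is the recipient plus planted donor blocks", {
  cfg <- small_cfg(seed = 8L)
  r <- simulate_recipient(cfg)
  d <- derive_donor(r, cfg)
  cult <- build_cultivar(r, d, cfg)
  expect_identical(cult$genome$sequences, r$sequences)

  cfg <- small_cfg(seed = 8L,
                   introgressions = data.frame(seq = "chr01", start = 60000,
                                               end = 120000))
  cult <- build_cultivar(r, d, cfg)
  cs <- cult$genome$sequences[[1]]
  expect_equal(count_mismatches(substr(cs, 1, 60000),
                                substr(r$sequences[[1]], 1, 60000)), 0L)
  expect_equal(substr(cs, 60001, 120000), substr(d$sequences[[1]], 60001,
                                                 120000))
  expect_identical(cult$genome$sequences[[2]], r$sequences[[2]])
  # truth records the plan exactly
  expect_equal(cult$truth$introgressions[, c("seq", "start", "end")],
               data.frame(seq = "chr01", start = 60000, end = 120000))
})

test_that("overlapping planned introgressions are rejected", {
  expect_error(small_cfg(introgressions = data.frame(
    seq = c("chr01", "chr01"), start = c(0, 5000), end = c(10000, 20000))),
    "overlapping")
  expect_error(small_cfg(introgressions = data.frame(
    seq = "chr01", start = 0, end = 5e5)), "bounds")
})

test_that("fixtures round-trip through the manifest", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(seed = 9L,
                   introgressions = data.frame(seq = "chr02", start = 10000,
                                               end = 60000))
  trio <- simulate_trio(cfg)
  write_fixture(trio, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "recipient.fa", "donor.fa", "cultivar.fa", "truth.introgressions.bed",
    "truth.lowdiv.bed", "truth.centromeres.bed", "truth.telomeres.tsv",
    "manifest.json")))))
  # regeneration from the manifest is byte-identical
  cfg2 <- read_manifest(file.path(dir, "manifest.json"))
  trio2 <- simulate_trio(cfg2)
  expect_identical(trio2$cultivar$sequences, trio$cultivar$sequences)
  expect_identical(trio2$donor$sequences, trio$donor$sequences)
  # truth BED round-trips through the package reader
  bed <- read_bed(file.path(dir, "truth.introgressions.bed"))
  expect_equal(bed[, c("seq", "start", "end")],
               trio$truth$introgressions[, c("seq", "start", "end")])
  # written FASTA re-reads to the same genome
  expect_equal(read_fasta(file.path(dir, "cultivar.fa"))$sequences,
               trio$cultivar$sequences)
})

test_that("indel mode still permits block recovery (robustness)", {
  cfg <- sim_config(n_chroms = 1L, chrom_len = 5e5, divergence = 0.01,
                    private_rate = 0.001, indel_rate = 5e-4,
                    introgressions = data.frame(seq = "chr01", start = 150000,
                                                end = 350000),
                    seed = 10L)
  trio <- simulate_trio(cfg)
  expect_false(nchar(trio$donor$sequences[[1]]) ==
                 nchar(trio$recipient$sequences[[1]]))
  res <- introgression_scan(trio$cultivar, trio$recipient, trio$donor,
                            lowdiv_identity = 0.995)
  calls <- res$blocks[res$blocks$label == "introgressed", , drop = FALSE]
  expect_gte(interval_jaccard(calls, trio$truth$introgressions), 0.5)
})
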