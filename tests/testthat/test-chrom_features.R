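# direct recount of a k-mer (canonical, overlapping) in a sequence
oracle_kmer_count <- function(s, km) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(km, "")[[1]]), collapse = ""))
  cnt <- function(m) {
    g <- gregexpr(paste0("(?=", m, ")"), s, perl = TRUE)[[1]]
    if (g[1] == -1) 0L else length(g)
  }
  if (km == rc) cnt(km) else cnt(km) + cnt(rc)
}

test_that("diagnostic kmers obey the inside-count and outside-veto rules", {
  set.seed(31)
  monomer <- "GATTACA"                       # 7 bp monomer
  array <- strrep(monomer, 1000)             # 7 kb array
  s <- paste0(rand_bases(5000), array, rand_bases(5000))
  g <- genome(c(chr1 = s), "toy")
  region <- intervals("chr1", 5000, 5000 + nchar(array))
  dk <- extract_diagnostic_kmers(g, region, k = 25L, min_count = 25L)
  expect_gt(length(dk$kmers), 0L)
  expect_true(all(nchar(dk$kmers) == 25L))
  expect_false(any(duplicated(dk$kmers)))
  # the monomer-phase 25-mers occur ~1000 times each; spot-verify by recount
  inside <- substr(s, 5001, 5000 + nchar(array))
  outside <- paste0(substr(s, 1, 5000), substr(s, 5000 + nchar(array) + 1,
                                               nchar(s)))
  for (km in dk$kmers[seq_len(min(5, length(dk$kmers)))]) {
    expect_gte(oracle_kmer_count(inside, km), 25L)
    expect_equal(oracle_kmer_count(outside, km), 0L)
  }
})

test_that("kmers below min_count or seen outside are excluded", {
  set.seed(32)
  km <- rand_bases(25)
  # 24 inside copies, none outside -> excluded by min_count
  s <- paste0(rand_bases(2000), strrep(paste0(km, "TT"), 24), rand_bases(2000))
  g <- genome(c(chr1 = s), "toy")
  region <- intervals("chr1", 2000, 2000 + 24 * 27)
  dk <- extract_diagnostic_kmers(g, region, k = 25L, min_count = 25L)
  expect_false(km %in% dk$kmers)
  expect_false(chartr("ACGT", "TGCA",
                      paste(rev(strsplit(km, "")[[1]]), collapse = "")) %in%
                 dk$kmers)
  # 100 inside copies but one outside occurrence -> vetoed
  s2 <- paste0(rand_bases(2000), strrep(paste0(km, "TT"), 100), rand_bases(500),
               km, rand_bases(500))
  g2 <- genome(c(chr1 = s2), "toy")
  region2 <- intervals("chr1", 2000, 2000 + 100 * 27)
  dk2 <- extract_diagnostic_kmers(g2, region2, k = 25L, min_count = 25L)
  canon <- function(x) {
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]),
                                       collapse = ""))
    min(x, rc)
  }
  expect_false(canon(km) %in% dk2$kmers)
  # empty regions -> empty set
  expect_equal(length(extract_diagnostic_kmers(g, intervals())$kmers), 0L)
})

test_that("kmer density equals the per-base union oracle", {
  set.seed(33)
  monomer <- "GATTACA"
  array <- strrep(monomer, ceiling(10000 / 7))
  array <- substr(array, 1, 10000)
  s <- paste0(rand_bases(120000), array, rand_bases(120000))
  g <- genome(c(chr1 = s), "toy")
  region <- intervals("chr1", 120000, 130000)
  dk <- extract_diagnostic_kmers(g, region)
  prof <- kmer_density_scan(g, dk, block_len = 250000, step = 50000)
  expect_true(all(prof$blocks$coverage_fraction >= 0 &
                    prof$blocks$coverage_fraction <= 1))
  # oracle: mark all bases covered by any occurrence of any diagnostic kmer
  mask <- logical(nchar(s))
  for (km in dk$kmers) {
    for (m in c(km, chartr("ACGT", "TGCA",
                           paste(rev(strsplit(km, "")[[1]]), collapse = "")))) {
      gpos <- gregexpr(paste0("(?=", m, ")"), s, perl = TRUE)[[1]]
      if (gpos[1] == -1) next
      for (p in gpos) mask[p:(p + 24)] <- TRUE
    }
  }
  for (i in seq_len(nrow(prof$blocks))) {
    b <- prof$blocks[i, ]
    expect_equal(b$coverage_fraction,
                 mean(mask[(b$start + 1):b$end]))
  }
  # a block fully outside the array scores 0
  last <- nrow(prof$blocks)
  expect_equal(prof$blocks$coverage_fraction[last], 0)
})

test_that("a single occurrence in a full block scores k/block_len", {
  set.seed(34)
  km <- rand_bases(25)
  s <- paste0(rand_bases(100000), km, rand_bases(149975))
  g <- genome(c(chr1 = s), "toy")
  dk <- structure(list(k = 25L, kmers = km, min_count = 25L),
                  class = "diagnostic_kmers")
  prof <- kmer_density_scan(g, dk, block_len = 250000, step = 50000)
  expect_equal(prof$blocks$coverage_fraction[1], 25 / 250000)
})

test_that("centromere calling selects, merges and stays monotone", {
  blocks <- data.frame(
    seq = "chr1", start = (0:9) * 50000, end = (0:9) * 50000 + 250000,
    coverage_fraction = c(0, 0, 0.021, 0.05, 0.021, 0, 0, 0.01, 0, 0),
    stringsAsFactors = FALSE)
  prof <- structure(list(blocks = blocks, block_len = 250000, step = 50000),
                    class = "density_profile")
  calls <- call_centromeres(prof, 0.0204)
  expect_equal(nrow(calls), 1L)
  expect_equal(c(calls$start, calls$end), c(100000, 450000))
  expect_equal(nrow(call_centromeres(prof, 0.9)), 0L)
  # monotone: a higher threshold calls a subset
  lo <- call_centromeres(prof, 0.0204)
  hi <- call_centromeres(prof, 0.05)
  expect_equal(overlap_bases(hi, lo), covered_bases(hi))
})

test_that("threshold calibration is the 5th percentile of per-sequence peaks", {
  mkprof <- function(peaks) {
    blocks <- do.call(rbind, lapply(seq_along(peaks), function(i)
      data.frame(seq = sprintf("c%02d", i), start = c(0, 50000),
                 end = c(250000, 300000),
                 coverage_fraction = c(peaks[i] / 2, peaks[i]),
                 stringsAsFactors = FALSE)))
    structure(list(blocks = blocks, block_len = 250000, step = 50000),
              class = "density_profile")
  }
  expect_equal(calibrate_threshold(mkprof(rep(0.05, 20))), 0.05)
  peaks <- seq(0.02, 0.21, by = 0.01)
  expect_equal(calibrate_threshold(mkprof(peaks)),
               unname(quantile(peaks, 0.05, type = 7)))
  expect_error(calibrate_threshold(mkprof(0.05)), "2 sequences")
  expect_error(calibrate_threshold(mkprof(c(0, 0))), "zero")
})

test_that("telomere termini are detected from motif counts", {
  set.seed(35)
  g <- genome(c(
    end_telo = paste0(rand_bases(5000), strrep("TTTAGGG", 20)),
    start_telo = paste0(strrep("CCCTAAA", 15), rand_bases(5000)),
    none = gsub("[AT]", "G", rand_bases(6000))), "toy")
  res <- find_telomeres(g)
  expect_equal(res$end_telomere, c(TRUE, FALSE, FALSE))
  expect_equal(res$start_telomere, c(FALSE, TRUE, FALSE))
})

test_that("hierarchical composition follows the class priority", {
  set.seed(36)
  g <- genome(c(chr1 = rand_bases(100000)), "toy")
  # a base inside both an exon and a ty3 interval counts as exon
  comp <- hierarchical_composition(
    g, exons = intervals("chr1", 1000, 2000),
    ty3 = intervals("chr1", 1500, 3000),
    win = 100000, step = 100000)
  expect_equal(comp$totals[["exon"]], 1000 / 100000)
  expect_equal(comp$totals[["ty3"]], 1000 / 100000)  # [1500,3000) minus exon
  # empty layers -> all "other"
  empty <- hierarchical_composition(g, win = 100000, step = 100000)
  expect_equal(empty$totals[["other"]], 1)
})

test_that("composition fractions equal a per-base priority oracle", {
  set.seed(37)
  g <- genome(c(chr1 = rand_bases(100000)), "toy")
  L <- 100000
  layers <- replicate(4, rand_intervals(15, "chr1", L, max_w = 5000),
                      simplify = FALSE)
  comp <- hierarchical_composition(
    g, exons = layers[[1]], ty3 = layers[[2]], other_repeats = layers[[3]],
    introns = layers[[4]], win = 20000, step = 10000)
  # oracle: integer class per base, priority order, 0 = other
  cls <- integer(L)
  for (j in 4:1) {
    for (i in seq_len(nrow(layers[[j]]))) {
      cls[(layers[[j]]$start[i] + 1):layers[[j]]$end[i]] <- j
    }
  }
  names <- c("exon", "ty3", "other_repeat", "intron")
  for (i in seq_len(nrow(comp$windows))) {
    w <- comp$windows[i, ]
    seg <- cls[(w$start + 1):w$end]
    for (j in 1:4) expect_equal(w[[names[j]]], mean(seg == j))
    expect_equal(w$other, mean(seg == 0))
    expect_equal(w$exon + w$ty3 + w$other_repeat + w$intron + w$other, 1,
                 tolerance = 1e-9)
  }
  # totals invariant to layer interval order
  shuf <- lapply(layers, function(x) x[sample.int(nrow(x)), ])
  comp2 <- hierarchical_composition(
    g, exons = shuf[[1]], ty3 = shuf[[2]], other_repeats = shuf[[3]],
    introns = shuf[[4]], win = 20000, step = 10000)
  expect_equal(comp2$totals, comp$totals)
})
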