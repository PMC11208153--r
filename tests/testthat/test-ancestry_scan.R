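test_that("low-divergence masking follows the strict >50% / >98% tile rule", {
  recipient <- genome(c(chr1 = rand_bases(400000)), "r")
  spec <- window_spec(10000L, 5000L)
  # tile [0, 200000) holds windows 1..40 (starts 0..195000)
  mask_for <- function(n_hot) {
    ident <- c(rep(0.995, n_hot), rep(0.95, 40 - n_hot))
    h <- mk_hits("chr1", 1:40, score = ident * 10000, identity = ident,
                 window_start = (0:39) * 5000)
    low_divergence_mask(h, recipient, spec = spec)
  }
  masked <- mask_for(21)   # 52.5% > 50%
  expect_equal(masked$intervals[, c("seq", "start", "end")],
               data.frame(seq = "chr1", start = 0, end = 200000))
  expect_equal(nrow(mask_for(20)$intervals), 0L)  # exactly 50% is not enough
  expect_equal(nrow(mask_for(0)$intervals), 0L)
  # no hits at all -> empty mask
  expect_equal(nrow(low_divergence_mask(mk_hits("chr1", 1L, 1)[0, ],
                                        recipient, spec = spec)$intervals), 0L)
})

test_that("identity > threshold is strict in the mask rule", {
  recipient <- genome(c(chr1 = rand_bases(400000)), "r")
  spec <- window_spec(10000L, 5000L)
  h <- mk_hits("chr1", 1:40, score = 9800, identity = 0.98,
               window_start = (0:39) * 5000)  # exactly at threshold
  expect_equal(nrow(low_divergence_mask(h, recipient,
                                        spec = spec)$intervals), 0L)
})

make_concat <- function() {
  concat_ref(genome(c(chrA = rand_bases(1000)), "rec"),
             genome(c(chrA = rand_bases(1000)), "don"))
}

test_that("competitive classification labels by best-hit origin", {
  set.seed(21)
  cc <- make_concat()
  win <- data.frame(seq = "q", start = (0:3) * 2500, end = (0:3) * 2500 + 10000,
                    index = 1:4)
  h <- rbind(
    mk_hits("q", 1L, 9950, target_seq = "donor::chrA"),
    mk_hits("q", 2L, c(9900, 9900),
            target_seq = c("recipient::chrA", "donor::chrA")),
    mk_hits("q", 3L, c(9980, 9920),
            target_seq = c("recipient::chrA", "donor::chrA")))
  tr <- competitive_classify(h, cc, win)
  expect_equal(tr$windows$label, c("donor", "ambiguous", "recipient",
                                   "unmapped"))
  # partition: one label per window
  expect_equal(sum(table(tr$windows$label)), nrow(win))
})

test_that("ties dropped by filter_hits surface as ambiguous", {
  set.seed(22)
  cc <- make_concat()
  win <- data.frame(seq = "q", start = 0, end = 10000, index = 1L)
  h <- mk_hits("q", c(1L, 1L), c(9900, 9900),
               target_seq = c("recipient::chrA", "donor::chrA"))
  f <- filter_hits(h, filter_config(min_identity = 0.9))
  expect_equal(nrow(f), 0L)
  tr <- competitive_classify(f, cc, win)
  expect_equal(tr$windows$label, "ambiguous")
})

test_that("mask overlap forces the masked label regardless of hits", {
  set.seed(23)
  cc <- make_concat()
  win <- data.frame(seq = "q", start = 0, end = 10000, index = 1L)
  h <- mk_hits("q", 1L, 9950, target_seq = "donor::chrA")
  mask <- structure(list(intervals = intervals("q", 5000, 20000)),
                    class = "lowdiv_mask")
  tr <- competitive_classify(h, cc, win, mask = mask)
  expect_equal(tr$windows$label, "masked")
})

test_that("hits referencing unknown windows raise a consistency error", {
  cc <- make_concat()
  win <- data.frame(seq = "q", start = 0, end = 10000, index = 1L)
  h <- mk_hits("q", 7L, 9950, target_seq = "donor::chrA")
  expect_error(competitive_classify(h, cc, win), "window table")
})

test_that("seed blocks need >= min_run consecutive donor windows", {
  cfg <- scan_config()
  expect_equal(nrow(seed_blocks(mk_track(rep("donor", 10)), cfg)), 1L)
  expect_equal(nrow(seed_blocks(mk_track(rep("donor", 9)), cfg)), 0L)
  tr <- mk_track(c(rep("donor", 12), "recipient", rep("donor", 10)))
  sb <- seed_blocks(tr, cfg)
  expect_equal(nrow(sb), 2L)
  # block spans first window start to last window end
  expect_equal(sb$start[1], 0)
  expect_equal(sb$end[1], 11 * 2500 + 10000)
  # masked and unmapped windows break runs
  tr <- mk_track(c(rep("donor", 9), "masked", rep("donor", 9)))
  expect_equal(nrow(seed_blocks(tr, cfg)), 0L)
})

test_that("percent-donor smoothing counts only decided windows", {
  cfg <- scan_config()
  p <- percent_donor_intervals(mk_track(rep("donor", 50)), cfg)
  expect_equal(p$pct_donor, 100)
  p <- percent_donor_intervals(mk_track(c(rep("donor", 35),
                                          rep("recipient", 15))), cfg)
  expect_equal(p$pct_donor, 70)
  p <- percent_donor_intervals(mk_track(c(rep("donor", 10),
                                          rep("recipient", 10),
                                          rep("ambiguous", 30))), cfg)
  expect_equal(p$pct_donor, 50)
  # chromosome shorter than one smoothing interval -> no intervals
  expect_equal(nrow(percent_donor_intervals(mk_track(rep("donor", 49)), cfg)),
               0L)
  # masked windows are excluded from the interval sequence
  tr <- mk_track(c(rep("masked", 10), rep("donor", 50)))
  p <- percent_donor_intervals(tr, cfg)
  expect_equal(nrow(p), 1L)
  expect_equal(p$first_index, 11L)
})

test_that("interval classes are exhaustive with the stated boundaries", {
  cfg <- scan_config()
  cls <- function(pct) classify_intervals(
    data.frame(seq = "c", pos = 1L, first_index = 1L, last_index = 50L,
               n_donor = 0L, n_recipient = 0L, pct_donor = pct), cfg)$class
  expect_equal(cls(70), "introgressed")
  expect_equal(cls(29.9), "recipient")
  expect_equal(cls(50), "ambiguous")
  expect_equal(cls(30), "ambiguous")
  expect_equal(cls(100), "introgressed")
  expect_equal(cls(0), "recipient")
})

test_that("final blocks merge smoothing classes with seed-run overrides", {
  cfg <- scan_config()
  tr <- mk_track(rep("donor", 60))
  fb <- final_blocks(tr, classify_intervals(percent_donor_intervals(tr, cfg),
                                            cfg), cfg)
  expect_equal(nrow(fb), 1L)
  expect_equal(fb$label, "introgressed")
  expect_equal(c(fb$start, fb$end), c(0, 59 * 2500 + 10000))

  tr <- mk_track(rep("recipient", 60))
  fb <- final_blocks(tr, classify_intervals(percent_donor_intervals(tr, cfg),
                                            cfg), cfg)
  expect_equal(nrow(fb), 0L)

  # a 12-window donor run inside a recipient chromosome is below the
  # smoothing threshold but seeds force it through
  tr <- mk_track(c(rep("recipient", 40), rep("donor", 12),
                   rep("recipient", 40)))
  fb <- final_blocks(tr, classify_intervals(percent_donor_intervals(tr, cfg),
                                            cfg), cfg)
  intro <- fb[fb$label == "introgressed", ]
  expect_equal(nrow(intro), 1L)
  expect_equal(c(intro$start, intro$end), c(40 * 2500, 51 * 2500 + 10000))
})

test_that("raising hi_threshold never increases introgressed bases", {
  set.seed(29)
  labs <- sample(c("donor", "recipient", "ambiguous"), 300, TRUE,
                 prob = c(0.45, 0.45, 0.1))
  tr <- mk_track(labs)
  total <- vapply(c(50, 60, 70, 80, 90), function(hi) {
    cfg <- scan_config(hi_threshold = hi, lo_threshold = 30)
    fb <- final_blocks(tr, classify_intervals(
      percent_donor_intervals(tr, cfg), cfg), cfg)
    covered_bases(fb[fb$label == "introgressed", , drop = FALSE])
  }, numeric(1))
  expect_true(all(diff(total) <= 0))
})

test_that("synteny projection interpolates, shifts and reports unplaced", {
  idmap <- build_synteny_map(mk_hits("q", 1:10, 10000,
                                     tstart = (0:9) * 2500))
  iv <- intervals("q", 5000, 6000)
  expect_equal(project_interval(idmap, iv)[, c("start", "end")],
               data.frame(start = 5000, end = 6000))

  shift <- build_synteny_map(mk_hits("q", 1:10, 10000,
                                     tstart = (0:9) * 2500 + 1000))
  expect_equal(project_interval(shift, iv)[, c("start", "end")],
               data.frame(start = 6000, end = 7000))

  far <- build_synteny_map(mk_hits("q", 5:10, 10000,
                                   window_start = (4:9) * 2500 + 50000,
                                   tstart = (4:9) * 2500 + 50000))
  unpl <- project_interval(far, intervals("q", 0, 500))
  expect_equal(nrow(unpl), 0L)
  expect_true(isTRUE(attr(unpl, "unplaced")))
  expect_error(project_interval(far, intervals("other", 0, 500)), "anchors")
})

test_that("projection splits at target-sequence discontinuities", {
  h <- mk_hits("q", 1:10, 10000, tstart = c((0:4) * 2500, (0:4) * 2500),
               target_seq = rep(c("t1", "t2"), each = 5))
  map <- build_synteny_map(h)
  res <- project_interval(map, intervals("q", 5000, 30000))
  expect_equal(nrow(res), 2L)
  expect_setequal(res$seq, c("t1", "t2"))
})
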