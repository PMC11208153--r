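#' Window specification
#'
#' Fixed-length overlapping windows: length `window_len`, consecutive starts
#' `step = window_len - overlap` apart. The workhorse geometry is 10 kb
#' windows with 7.5 kb overlap (2.5 kb step); the low-divergence scan uses a
#' 5 kb overlap.
#'
#' @param window_len window length in bases.
#' @param overlap overlap between consecutive windows, `0 <= overlap <
#'   window_len`.
#' @return list of class `window_spec` with `window_len`, `overlap`, `step`.
#' @export
window_spec <- function(window_len = 10000L, overlap = 7500L) {
  window_len <- as.integer(window_len)
  overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= window_len)
    stop_fmt("need 0 <= overlap < window_len")
  structure(list(window_len = window_len, overlap = overlap,
                 step = window_len - overlap), class = "window_spec")
}

#' Enumerate full-length windows over a sequence
#'
#' Windows start at 0, step, 2*step, ...; a trailing partial window is
#' dropped so identity/coverage thresholds stay comparable genome-wide.
#'
#' @param seq_len sequence length in bases.
#' @param spec a [window_spec()].
#' @param seq_name sequence name carried into the output.
#' @return data.frame with columns seq, start, end, index (1-based window
#'   index); zero rows when the sequence is shorter than one window.
#' @export
make_windows <- function(seq_len, spec = window_spec(), seq_name = "seq") {
  if (seq_len < spec$window_len) {
    return(data.frame(seq = character(), start = numeric(), end = numeric(),
                      index = integer(), stringsAsFactors = FALSE))
  }
  n <- (seq_len - spec$window_len) %/% spec$step + 1L
  starts <- as.numeric(0:(n - 1L)) * spec$step
  data.frame(seq = rep(seq_name, n), start = starts,
             end = starts + spec$window_len, index = seq_len(n),
             stringsAsFactors = FALSE)
}

#' Windows over every sequence of a genome
#' @param g a [genome()].
#' @param spec a [window_spec()].
#' @return row-bound [make_windows()] output for all sequences.
#' @export
genome_windows <- function(g, spec = window_spec()) {
  do.call(rbind, lapply(names(g$lengths), function(nm)
    make_windows(g$lengths[[nm]], spec, nm)))
}

#' Aligner configuration
#'
#' The builtin aligner anchors exact `seed_k`-mers between window and target
#' (dense index with an occurrence cap; `minimizer_window` is retained for
#' interface parity with minimizer-based aligners and is not used for
#' subsampling), chains anchors by diagonal consistency, and counts matches
#' by ungapped comparison along the chained diagonals extended to the window
#' boundaries.
#'
#' @param seed_k anchor k-mer length (>= 11).
#' @param minimizer_window minimizer window (interface parity; unused by the
#'   dense index).
#' @param max_secondary extra hits beyond the primary to report per window;
#'   hits tied with the last reported one are always included.
#' @param occ_cap seeds occurring more than this many times in the target are
#'   skipped (repeat shielding).
#' @param band maximum diagonal drift between chained anchor runs (bases).
#' @param chain_gap maximum unanchored query gap within a chain (bases).
#' @param min_anchor_bases minimum anchored query bases for a reportable hit.
#' @param stride window-side seed sampling stride (bases); match counts are
#'   unaffected (they come from full ungapped comparison along the chained
#'   diagonals), only anchor density changes.
#' @return list of class `aligner_config`.
#' @export
aligner_config <- function(seed_k = 25L, minimizer_window = 20L,
                           max_secondary = 0L, occ_cap = 64L, band = 50L,
                           chain_gap = 2000L, min_anchor_bases = 50L,
                           stride = 5L) {
  if (seed_k < 11L) stop_fmt("seed_k must be >= 11")
  if (stride < 1L) stop_fmt("stride must be >= 1")
  structure(list(seed_k = as.integer(seed_k),
                 minimizer_window = as.integer(minimizer_window),
                 max_secondary = as.integer(max_secondary),
                 occ_cap = as.integer(occ_cap), band = as.integer(band),
                 chain_gap = as.integer(chain_gap),
                 min_anchor_bases = as.integer(min_anchor_bases),
                 stride = as.integer(stride)),
            class = "aligner_config")
}

#' Hit filter configuration
#'
#' Defaults follow the standard windowed-mapping filter chain: single best
#' hit per query window, identity >= 0.98, query coverage >= 0.75, then
#' collinearity pruning with a block size of 5 hits in a neighbourhood of 10.
#'
#' @param nhits maximum hits kept per query window.
#' @param min_identity minimum matches/block_length.
#' @param min_coverage minimum aligned query fraction.
#' @param blk_size collinear neighbours (including the hit itself) required.
#' @param n_window neighbourhood size in hits.
#' @param max_gap maximum consecutive target-position gap (bases) within a
#'   collinear neighbourhood.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(nhits = 1L, min_identity = 0.98, min_coverage = 0.75,
                          blk_size = 5L, n_window = 10L, max_gap = 250000) {
  if (nhits < 1L) stop_fmt("nhits must be >= 1")
  if (blk_size > n_window) stop_fmt("blk_size must be <= n_window")
  structure(list(nhits = as.integer(nhits), min_identity = min_identity,
                 min_coverage = min_coverage, blk_size = as.integer(blk_size),
                 n_window = as.integer(n_window), max_gap = max_gap),
            class = "filter_config")
}

#' Named parameter presets for the four windowed scans
#'
#' `synteny`: 10 kb / 7.5 kb overlap, identity 0.98. `lowdiv`: 10 kb / 5 kb
#' overlap, identity thresholding deferred to the mask rule.
#' `introgression`: 10 kb / 7.5 kb overlap (2.5 kb step), identity 0.99.
#' `subgenome`: identity 0.75 for homoeologous comparisons.
#'
#' @param name one of "synteny", "lowdiv", "introgression", "subgenome".
#' @return list with elements `window` ([window_spec()]) and `filter`
#'   ([filter_config()]).
#' @export
scan_preset <- function(name = c("synteny", "lowdiv", "introgression",
                                 "subgenome")) {
  switch(match.arg(name),
    synteny = list(window = window_spec(10000L, 7500L),
                   filter = filter_config(min_identity = 0.98)),
    lowdiv = list(window = window_spec(10000L, 5000L),
                  filter = filter_config(min_identity = 0)),
    introgression = list(window = window_spec(10000L, 7500L),
                         filter = filter_config(min_identity = 0.99)),
    subgenome = list(window = window_spec(10000L, 7500L),
                     filter = filter_config(min_identity = 0.75)))
}

#' Align query windows to a target genome
#'
#' The builtin route for desk-scale genomes; alignments computed elsewhere
#' (e.g. a minimap2 PAF) can be substituted via [read_paf()] under the same
#' hit contract.
#'
#' @param query a [genome()] the windows were derived from.
#' @param windows window table from [genome_windows()]/[make_windows()].
#' @param target a [genome()] or [concat_ref()].
#' @param cfg an [aligner_config()].
#' @return window-hit data.frame: one row per reported hit with window
#'   bookkeeping (query_seq, window_index, window_start), window-relative
#'   query coordinates (qstart/qend/qlen), forward-strand target coordinates
#'   (target_seq, tstart, tend, strand), and derived matches, block_len,
#'   identity, coverage, score (= matches).
#' @export
align_windows <- function(query, windows, target, cfg = aligner_config()) {
  if (is.null(windows) || nrow(windows) == 0L) return(empty_hits())
  tg <- if (inherits(target, "concat_ref")) target$genome else target
  wseq <- substring(query$sequences[windows$seq], windows$start + 1,
                    windows$end)
  res <- cpp_align_windows(wseq, unname(tg$sequences), cfg$seed_k,
                           cfg$occ_cap, cfg$max_secondary + 1L, cfg$band,
                           cfg$chain_gap, cfg$min_anchor_bases, cfg$stride)
  if (nrow(res) == 0L) return(empty_hits())
  tnames <- names(tg$sequences)
  hits <- data.frame(
    query_seq = windows$seq[res$win],
    window_index = windows$index[res$win],
    window_start = windows$start[res$win],
    qlen = windows$end[res$win] - windows$start[res$win],
    qstart = as.numeric(res$qstart), qend = as.numeric(res$qend),
    strand = as.character(res$strand),
    target_seq = tnames[res$sid],
    tlen = as.numeric(tg$lengths[res$sid]),
    tstart = as.numeric(res$tstart), tend = as.numeric(res$tend),
    matches = as.numeric(res$matches), block_len = as.numeric(res$block_len),
    stringsAsFactors = FALSE)
  finish_hits(hits)
}

window_key <- function(hits) paste(hits$query_seq, hits$window_index, sep = "\r")

#' Filter window hits
#'
#' Per query window, keeps the top-`nhits` hits by score; under `nhits = 1`
#' an exact tie for best is dropped from the output but recorded in the
#' `"tie_hits"` attribute so the competitive classifier can label the window
#' ambiguous. Hits below the identity or coverage thresholds are then
#' removed. Original relative order is preserved; the filter is idempotent.
#'
#' @param hits window-hit data.frame.
#' @param cfg a [filter_config()].
#' @return filtered hits, with attribute `tie_hits` (the dropped tied rows).
#' @export
filter_hits <- function(hits, cfg = filter_config()) {
  if (nrow(hits) == 0L) {
    attr(hits, "tie_hits") <- hits
    return(hits)
  }
  key <- window_key(hits)
  best <- tapply(hits$score, key, max)[key]
  is_best <- hits$score == best
  n_best <- tapply(is_best, key, sum)[key]
  if (cfg$nhits == 1L) {
    tied <- is_best & n_best >= 2L
    keep <- is_best & !tied
    ties <- hits[tied, , drop = FALSE]
  } else {
    ord <- order(key, -hits$score)
    rank <- integer(nrow(hits))
    rank[ord] <- sequence(rle(key[ord])$lengths)
    keep <- rank <= cfg$nhits
    ties <- hits[0L, , drop = FALSE]
  }
  out <- hits[keep, , drop = FALSE]
  pass <- out$identity >= cfg$min_identity & out$coverage >= cfg$min_coverage
  out <- out[pass, , drop = FALSE]
  rownames(out) <- NULL
  rownames(ties) <- NULL
  attr(out, "tie_hits") <- ties
  out
}

#' Prune window hits to collinear runs
#'
#' For each hit (at most one per window; run after [filter_hits()]) the
#' neighbourhood is the up-to-`n_window` hits nearest in query order on the
#' same query sequence, balanced around the hit and truncated at sequence
#' ends. The hit is retained iff at least `blk_size` neighbourhood hits
#' (counting itself) share its target sequence and, ordered by query
#' position, have target positions monotone in one direction with every
#' consecutive gap at most `max_gap` bases.
#'
#' @param hits filtered window hits.
#' @param cfg a [filter_config()].
#' @return the retained hits, original order preserved.
#' @export
prune_collinear <- function(hits, cfg = filter_config()) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query_seq, hits$window_start)
  h <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(h))
  for (qs in unique(h$query_seq)) {
    idx <- which(h$query_seq == qs)
    n <- length(idx)
    half <- cfg$n_window %/% 2L
    for (i in seq_len(n)) {
      lo <- i - half
      hi <- lo + cfg$n_window - 1L
      if (lo < 1L) { lo <- 1L; hi <- min(n, cfg$n_window) }
      if (hi > n) { hi <- n; lo <- max(1L, n - cfg$n_window + 1L) }
      nb <- idx[lo:hi]
      same <- nb[h$target_seq[nb] == h$target_seq[idx[i]]]
      if (length(same) < cfg$blk_size) next
      tpos <- h$tstart[same]  # ordered by query position already
      d <- diff(tpos)
      mono <- all(d >= 0) || all(d <= 0)
      keep[idx[i]] <- mono && (length(d) == 0L || max(abs(d)) <= cfg$max_gap)
    }
  }
  out <- hits[sort(ord[keep]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
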