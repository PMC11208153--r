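#' Concatenated two-species reference
#'
#' Competitive classification maps each query window against the recipient
#' and donor genomes joined into one target, so the best hit's origin decides
#' the window's ancestry. Sequence names are prefixed `recipient::` /
#' `donor::` to guarantee uniqueness.
#'
#' @param recipient,donor [genome()] objects.
#' @return list of class `concat_ref` with `genome` (merged) and `name_map`
#'   (data.frame target_seq, origin, source_seq).
#' @export
concat_ref <- function(recipient, donor) {
  rn <- paste0("recipient::", names(recipient$sequences))
  dn <- paste0("donor::", names(donor$sequences))
  seqs <- c(stats::setNames(recipient$sequences, rn),
            stats::setNames(donor$sequences, dn))
  structure(list(
    genome = genome(seqs, paste0(recipient$genome_id, "+", donor$genome_id)),
    name_map = data.frame(
      target_seq = c(rn, dn),
      origin = rep(c("recipient", "donor"), c(length(rn), length(dn))),
      source_seq = c(names(recipient$sequences), names(donor$sequences)),
      stringsAsFactors = FALSE)),
    class = "concat_ref")
}

hit_origin <- function(hits, concat) {
  concat$name_map$origin[match(hits$target_seq, concat$name_map$target_seq)]
}

#' Scan configuration for introgression calling
#'
#' @param min_run consecutive donor windows required for a seed block.
#' @param smooth_n smoothing interval size in windows.
#' @param smooth_overlap overlap between consecutive smoothing intervals
#'   (step = smooth_n - smooth_overlap).
#' @param hi_threshold percent-donor at or above which an interval is
#'   introgressed.
#' @param lo_threshold percent-donor below which an interval is recipient;
#'   the band in between is ambiguous.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(min_run = 10L, smooth_n = 50L, smooth_overlap = 49L,
                        hi_threshold = 70, lo_threshold = 30) {
  if (smooth_overlap >= smooth_n) stop_fmt("smooth_overlap must be < smooth_n")
  if (lo_threshold >= hi_threshold) stop_fmt("need lo_threshold < hi_threshold")
  structure(list(min_run = as.integer(min_run),
                 smooth_n = as.integer(smooth_n),
                 smooth_overlap = as.integer(smooth_overlap),
                 hi_threshold = hi_threshold, lo_threshold = lo_threshold),
            class = "scan_config")
}

#' Low-divergence mask
#'
#' Regions where recipient and donor are too similar for windowed mapping to
#' discriminate ancestry. Recipient chromosomes are tiled into consecutive
#' non-overlapping `interval_len` tiles (the last one shorter); a tile is
#' masked when strictly more than `frac_threshold` of the windows starting in
#' it align to the donor with identity strictly above `identity_threshold`.
#' Adjacent masked tiles are merged.
#'
#' The default `identity_threshold` (0.98) presupposes background
#' recipient-donor divergence clearly above 2%; for other divergences use
#' a threshold above the background window identity, e.g. `1 - divergence/2`
#' (see the methods vignette).
#'
#' @param hits recipient-window hits against the donor (10 kb windows, 5 kb
#'   overlap), at most one hit per window.
#' @param recipient the recipient [genome()].
#' @param interval_len tile length in bases.
#' @param frac_threshold strict window-fraction threshold.
#' @param identity_threshold strict identity threshold.
#' @param spec the [window_spec()] the hits were generated with.
#' @return list of class `lowdiv_mask` with `intervals` (merged masked tiles)
#'   and the parameters.
#' @export
low_divergence_mask <- function(hits, recipient, interval_len = 200000,
                                frac_threshold = 0.5,
                                identity_threshold = 0.98,
                                spec = window_spec(10000L, 5000L)) {
  masked <- list()
  for (nm in names(recipient$lengths)) {
    len <- recipient$lengths[[nm]]
    win <- make_windows(len, spec, nm)
    if (nrow(win) == 0L) next
    h <- hits[hits$query_seq == nm, , drop = FALSE]
    ident <- rep(0, nrow(win))
    if (nrow(h) > 0L) {
      best <- tapply(h$identity, h$window_index, max)
      ident[as.integer(names(best))] <- best
    }
    tile <- win$start %/% interval_len  # tile of each window, by start
    hot <- tapply(ident > identity_threshold, tile, mean)
    sel <- as.numeric(names(hot))[hot > frac_threshold]
    if (length(sel)) {
      masked[[nm]] <- data.frame(
        seq = nm, start = sel * interval_len,
        end = pmin((sel + 1) * interval_len, len),
        label = NA_character_, stringsAsFactors = FALSE)
    }
  }
  iv <- if (length(masked)) merge_intervals(do.call(rbind, masked), max_gap = 0)
        else intervals()
  structure(list(intervals = iv, interval_len = interval_len,
                 frac_threshold = frac_threshold,
                 identity_threshold = identity_threshold),
            class = "lowdiv_mask")
}

#' Build a synteny anchor map from pruned window hits
#'
#' Each surviving hit (one per window after [filter_hits()] and
#' [prune_collinear()]) becomes an anchor pairing its query interval (genome
#' coordinates) with its target interval and orientation.
#'
#' @param hits pruned window hits.
#' @return object of class `synteny_map`: anchor data.frame sorted by
#'   (query_seq, qstart).
#' @export
build_synteny_map <- function(hits) {
  if (nrow(hits) == 0L) {
    anchors <- data.frame(query_seq = character(), qstart = numeric(),
                          qend = numeric(), target_seq = character(),
                          tstart = numeric(), tend = numeric(),
                          strand = character(), stringsAsFactors = FALSE)
  } else {
    anchors <- data.frame(query_seq = hits$query_seq,
                          qstart = hits$window_start + hits$qstart,
                          qend = hits$window_start + hits$qend,
                          target_seq = hits$target_seq,
                          tstart = hits$tstart, tend = hits$tend,
                          strand = hits$strand, stringsAsFactors = FALSE)
    anchors <- anchors[order(anchors$query_seq, anchors$qstart), , drop = FALSE]
    rownames(anchors) <- NULL
  }
  structure(list(anchors = anchors), class = "synteny_map")
}

# target position of query point p within/at the edge of one anchor
anchor_point <- function(a, p) {
  f <- (p - a$qstart) / (a$qend - a$qstart)
  f <- min(max(f, 0), 1)
  if (a$strand == "+") a$tstart + f * (a$tend - a$tstart)
  else a$tend - f * (a$tend - a$tstart)
}

#' Project an interval through a synteny map
#'
#' Endpoints are located against the flanking anchors and linearly
#' interpolated between anchor target positions (orientation-aware).
#' Intervals spanning a target-sequence discontinuity are split there;
#' intervals entirely outside anchor coverage are unplaced (zero rows).
#'
#' @param map a [build_synteny_map()] result.
#' @param interval one-row interval data.frame (seq, start, end).
#' @return projected interval data.frame (0, 1 or more rows).
#' @export
project_interval <- function(map, interval) {
  stopifnot(nrow(interval) == 1L)
  anc <- map$anchors[map$anchors$query_seq == interval$seq, , drop = FALSE]
  if (nrow(anc) == 0L) {
    known <- unique(map$anchors$query_seq)
    if (!interval$seq %in% known)
      stop_fmt("no anchors for sequence '%s'", interval$seq)
  }
  out <- list()
  # runs of constant target sequence
  if (nrow(anc)) {
    run_id <- cumsum(c(1L, diff(as.integer(factor(anc$target_seq,
                                                  levels = unique(anc$target_seq)))) != 0L))
    for (r in unique(run_id)) {
      ar <- anc[run_id == r, , drop = FALSE]
      span <- c(ar$qstart[1L], ar$qend[nrow(ar)])
      s <- max(interval$start, span[1L])
      e <- min(interval$end, span[2L])
      if (e <= s) next
      tp <- vapply(c(s, e), function(p) project_point_run(ar, p), numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        seq = ar$target_seq[1L], start = min(tp), end = max(tp),
        label = interval$label %||% NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    res <- intervals()
    attr(res, "unplaced") <- TRUE
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[res$end > res$start, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# project a point known to lie within the query span of an anchor run
project_point_run <- function(ar, p) {
  inside <- which(ar$qstart <= p & p <= ar$qend)
  if (length(inside)) return(anchor_point(ar[inside[1L], ], p))
  before <- which(ar$qend < p)
  i <- before[length(before)]          # last anchor left of p; i+1 exists
  t1 <- anchor_point(ar[i, ], ar$qend[i])
  t2 <- anchor_point(ar[i + 1L, ], ar$qstart[i + 1L])
  f <- (p - ar$qend[i]) / (ar$qstart[i + 1L] - ar$qend[i])
  t1 + f * (t2 - t1)
}

#' Competitive ancestry classification of query windows
#'
#' Each window of the query genome is labelled `masked` (its
#' recipient-projected position overlaps the low-divergence mask),
#' `unmapped` (no surviving hit), `donor` / `recipient` (origin of its
#' unique best competitive hit), or `ambiguous` (best scores to the two
#' origins tie, including ties recorded by [filter_hits()] under nhits = 1).
#'
#' @param hits window hits against the [concat_ref()], already thresholded on
#'   identity/coverage (keep several hits per window, e.g. nhits = 4, so both
#'   origins' best scores are visible).
#' @param concat the [concat_ref()] the hits were produced against.
#' @param windows the query window table the hits derive from.
#' @param mask optional [low_divergence_mask()].
#' @param synteny optional [build_synteny_map()] projecting query coordinates
#'   onto the recipient; when NULL, query coordinates are compared to the
#'   mask directly.
#' @return object of class `ancestry_track`: per-window data.frame with
#'   label and best scores per origin.
#' @export
competitive_classify <- function(hits, concat, windows, mask = NULL,
                                 synteny = NULL) {
  if (is.null(windows) || nrow(windows) == 0L)
    stop_fmt("query windows are required")
  wkey <- paste(windows$seq, windows$index, sep = "\r")
  key <- window_key(hits)
  extra <- setdiff(unique(key), wkey)
  if (length(extra)) stop_fmt("hits reference windows not in the window table")
  origin <- hit_origin(hits, concat)
  if (anyNA(origin)) stop_fmt("hit target not present in the concat reference")
  score_for <- function(orig) {
    sel <- origin == orig
    if (!any(sel)) return(rep(NA_real_, nrow(windows)))
    s <- tapply(hits$score[sel], key[sel], max)
    as.numeric(s[wkey])
  }
  sr <- score_for("recipient")
  sd <- score_for("donor")
  label <- rep("unmapped", nrow(windows))
  label[!is.na(sr) & (is.na(sd) | sr > sd)] <- "recipient"
  label[!is.na(sd) & (is.na(sr) | sd > sr)] <- "donor"
  label[!is.na(sr) & !is.na(sd) & sr == sd] <- "ambiguous"
  ties <- attr(hits, "tie_hits")
  if (!is.null(ties) && nrow(ties)) {
    label[wkey %in% unique(window_key(ties))] <- "ambiguous"
  }
  if (!is.null(mask) && nrow(mask$intervals)) {
    for (i in seq_len(nrow(windows))) {
      iv <- windows[i, c("seq", "start", "end")]
      iv$label <- NA_character_
      pos <- if (is.null(synteny)) iv else project_interval(synteny, iv)
      if (nrow(pos) && overlap_bases(pos, mask$intervals) > 0)
        label[i] <- "masked"
    }
  }
  structure(list(
    windows = data.frame(windows[, c("seq", "start", "end", "index")],
                         label = label, score_recipient = sr,
                         score_donor = sd, stringsAsFactors = FALSE)),
    class = "ancestry_track")
}

#' @export
print.ancestry_track <- function(x, ...) {
  tb <- table(factor(x$windows$label, levels = c("recipient", "donor",
                                                 "ambiguous", "masked",
                                                 "unmapped")))
  cat("<ancestry_track> ", nrow(x$windows), " windows: ",
      paste(names(tb), tb, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# maximal runs (by consecutive window index) satisfying a predicate
label_runs <- function(track_df, predicate, min_len = 1L) {
  out <- list()
  for (nm in unique(track_df$seq)) {
    d <- track_df[track_df$seq == nm, , drop = FALSE]
    d <- d[order(d$index), , drop = FALSE]
    ok <- predicate(d)
    if (!any(ok)) next
    brk <- cumsum(c(TRUE, diff(d$index) != 1L)) # index gaps break runs
    grp <- paste(brk, cumsum(c(0L, diff(ok) != 0L))[seq_along(ok)])
    for (g in unique(grp[ok])) {
      rows <- which(grp == g & ok)
      if (length(rows) >= min_len) {
        out[[length(out) + 1L]] <- data.frame(
          seq = nm, start = d$start[rows[1L]], end = d$end[rows[length(rows)]],
          first_index = d$index[rows[1L]], last_index = d$index[rows[length(rows)]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(seq = character(), start = numeric(), end = numeric(),
                      first_index = integer(), last_index = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Seed introgression blocks
#'
#' Maximal runs of at least `min_run` consecutive donor-labelled windows
#' (masked, unmapped, ambiguous or recipient windows break runs) become
#' candidate blocks spanning first window start to last window end.
#'
#' @param track an [competitive_classify()] result.
#' @param cfg a [scan_config()].
#' @return interval data.frame of seed blocks.
#' @export
seed_blocks <- function(track, cfg = scan_config()) {
  runs <- label_runs(track$windows, function(d) d$label == "donor",
                     min_len = cfg$min_run)
  if (nrow(runs) == 0L) return(intervals())
  intervals(runs$seq, runs$start, runs$end, label = "seed")
}

#' Percent-donor over sliding window intervals
#'
#' Intervals of `smooth_n` consecutive non-masked windows slide by
#' `smooth_n - smooth_overlap` along each chromosome. Percent-donor is
#' 100 * donor / (donor + recipient) within the interval; ambiguous and
#' unmapped windows do not enter the denominator, and intervals with no
#' decided window are skipped. Chromosomes with fewer than `smooth_n`
#' non-masked windows yield no intervals.
#'
#' @param track an [competitive_classify()] result.
#' @param cfg a [scan_config()].
#' @return data.frame with one row per interval: seq, pos (1-based position
#'   of the interval in the chromosome's non-masked window sequence),
#'   first_index/last_index (window indices), n_donor, n_recipient,
#'   pct_donor.
#' @export
percent_donor_intervals <- function(track, cfg = scan_config()) {
  step <- cfg$smooth_n - cfg$smooth_overlap
  out <- list()
  for (nm in unique(track$windows$seq)) {
    d <- track$windows[track$windows$seq == nm, , drop = FALSE]
    d <- d[order(d$index), , drop = FALSE]
    d <- d[d$label != "masked", , drop = FALSE]
    n <- nrow(d)
    if (n < cfg$smooth_n) next
    starts <- seq.int(1L, n - cfg$smooth_n + 1L, by = step)
    don <- cumsum(d$label == "donor")
    rec <- cumsum(d$label == "recipient")
    at <- function(cs, i) ifelse(i == 0L, 0, cs[pmax(i, 1L)])
    ends <- starts + cfg$smooth_n - 1L
    nd <- at(don, ends) - at(don, starts - 1L)
    nr <- at(rec, ends) - at(rec, starts - 1L)
    dec <- nd + nr
    keep <- dec > 0
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      seq = nm, pos = starts[keep], first_index = d$index[starts[keep]],
      last_index = d$index[ends[keep]], n_donor = nd[keep],
      n_recipient = nr[keep], pct_donor = 100 * nd[keep] / dec[keep],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(seq = character(), pos = integer(),
                      first_index = integer(), last_index = integer(),
                      n_donor = integer(), n_recipient = integer(),
                      pct_donor = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify smoothing intervals by percent-donor
#'
#' `pct >= hi_threshold` is introgressed; `lo_threshold <= pct < hi` is
#' ambiguous; `pct < lo` is recipient -- the only exhaustive reading of the
#' three published classes.
#'
#' @param pcts result of [percent_donor_intervals()].
#' @param cfg a [scan_config()].
#' @return `pcts` with an added `class` column.
#' @export
classify_intervals <- function(pcts, cfg = scan_config()) {
  cls <- ifelse(pcts$pct_donor >= cfg$hi_threshold, "introgressed",
                ifelse(pcts$pct_donor >= cfg$lo_threshold, "ambiguous",
                       "recipient"))
  pcts$class <- cls
  pcts
}

#' Final introgression blocks
#'
#' Each non-masked window takes the class of the covering smoothing interval
#' whose centre is nearest (ties to the left interval). Windows inside seed
#' runs (>= `min_run` consecutive donor windows) are introgressed regardless,
#' so block edges follow the underlying donor runs rather than the smoothing
#' resolution. Consecutive windows of equal non-recipient class merge into
#' blocks spanning first window start to last window end.
#'
#' @param track an [competitive_classify()] result.
#' @param interval_classes result of [classify_intervals()].
#' @param cfg a [scan_config()].
#' @return interval data.frame with label `introgressed` or `ambiguous`.
#' @export
final_blocks <- function(track, interval_classes, cfg = scan_config()) {
  tw <- track$windows
  cls <- rep(NA_character_, nrow(tw))
  half <- (cfg$smooth_n - 1) / 2
  for (nm in unique(tw$seq)) {
    rows <- which(tw$seq == nm)
    rows <- rows[order(tw$index[rows])]
    nonmask <- rows[tw$label[rows] != "masked"]
    ic <- interval_classes[interval_classes$seq == nm, , drop = FALSE]
    if (nrow(ic) && length(nonmask)) {
      J <- ic$pos                       # interval start positions (non-masked)
      for (p in seq_along(nonmask)) {
        covering <- which(J <= p & p <= J + cfg$smooth_n - 1L)
        if (!length(covering)) next
        centre_dist <- abs(p - (J[covering] + half))
        j <- covering[which.min(centre_dist)]   # which.min takes the left tie
        cls[nonmask[p]] <- ic$class[j]
      }
    }
  }
  # seed runs override: donor runs of >= min_run windows are introgressed
  seeds <- label_runs(tw, function(d) d$label == "donor",
                      min_len = cfg$min_run)
  if (nrow(seeds)) {
    for (i in seq_len(nrow(seeds))) {
      sel <- tw$seq == seeds$seq[i] & tw$index >= seeds$first_index[i] &
        tw$index <= seeds$last_index[i]
      cls[sel] <- "introgressed"
    }
  }
  tw$final <- cls
  blocks <- lapply(c("introgressed", "ambiguous"), function(lab) {
    runs <- label_runs(tw, function(d) !is.na(d$final) & d$final == lab)
    if (nrow(runs) == 0L) return(NULL)
    intervals(runs$seq, runs$start, runs$end, label = lab)
  })
  blocks <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  if (is.null(blocks)) return(intervals())
  blocks <- blocks[order(blocks$seq, blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

#' End-to-end introgression scan of a cultivar genome
#'
#' Runs the full pipeline: low-divergence masking (recipient windows vs the
#' donor), synteny map (cultivar vs recipient), competitive trio mapping
#' against the concatenated reference, seed blocks, percent-donor smoothing
#' and final block construction.
#'
#' @param cultivar,recipient,donor [genome()] objects.
#' @param cfg a [scan_config()].
#' @param lowdiv_identity strict identity threshold of the low-divergence
#'   mask; choose a value above the background recipient-donor window
#'   identity (default 0.98 targets species-scale divergence > 2%; use
#'   `1 - divergence/2` otherwise).
#' @param aligner an [aligner_config()].
#' @param trio_preset,lowdiv_preset,synteny_preset [scan_preset()] lists.
#' @return list of class `introgression_scan`: `track`, `mask`, `synteny`,
#'   `seed_blocks`, `smoothing` (classified intervals), `blocks` (final
#'   calls), `blocks_projected` (recipient coordinates), `params`.
#' @export
introgression_scan <- function(cultivar, recipient, donor,
                               cfg = scan_config(), lowdiv_identity = 0.98,
                               aligner = aligner_config(),
                               trio_preset = scan_preset("introgression"),
                               lowdiv_preset = scan_preset("lowdiv"),
                               synteny_preset = scan_preset("synteny")) {
  # 1. low-divergence mask: recipient windows vs donor
  ld_win <- genome_windows(recipient, lowdiv_preset$window)
  ld_hits <- filter_hits(align_windows(recipient, ld_win, donor, aligner),
                         lowdiv_preset$filter)
  mask <- low_divergence_mask(ld_hits, recipient,
                              identity_threshold = lowdiv_identity,
                              spec = lowdiv_preset$window)
  # 2. synteny map: cultivar windows vs recipient
  sy_win <- genome_windows(cultivar, synteny_preset$window)
  sy_hits <- prune_collinear(
    filter_hits(align_windows(cultivar, sy_win, recipient, aligner),
                synteny_preset$filter),
    synteny_preset$filter)
  synteny <- build_synteny_map(sy_hits)
  # 3. competitive trio scan against the concatenated reference
  concat <- concat_ref(recipient, donor)
  tr_win <- genome_windows(cultivar, trio_preset$window)
  tr_cfg <- trio_preset$filter
  tr_cfg$nhits <- 4L   # keep both origins' best hits visible
  tr_hits <- filter_hits(align_windows(cultivar, tr_win, concat, aligner),
                         tr_cfg)
  track <- competitive_classify(tr_hits, concat, tr_win, mask = mask,
                                synteny = synteny)
  seeds <- seed_blocks(track, cfg)
  smoothing <- classify_intervals(percent_donor_intervals(track, cfg), cfg)
  blocks <- final_blocks(track, smoothing, cfg)
  projected <- if (nrow(blocks)) {
    do.call(rbind, lapply(seq_len(nrow(blocks)), function(i)
      project_interval(synteny, blocks[i, , drop = FALSE])))
  } else intervals()
  structure(list(track = track, mask = mask, synteny = synteny,
                 seed_blocks = seeds, smoothing = smoothing, blocks = blocks,
                 blocks_projected = projected,
                 params = list(scan = cfg, lowdiv_identity = lowdiv_identity)),
            class = "introgression_scan")
}

#' @export
print.introgression_scan <- function(x, ...) {
  cat("<introgression_scan>\n")
  print(x$track)
  cat("  masked bases:", covered_bases(x$mask$intervals), "\n")
  cat("  seed blocks:", nrow(x$seed_blocks), "\n")
  nb <- table(x$blocks$label)
  cat("  final blocks:", if (nrow(x$blocks)) paste(names(nb), nb, sep = "=",
                                                   collapse = ", ") else "none",
      "\n")
  invisible(x)
}
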