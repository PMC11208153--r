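# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (per-base boolean arrays, exhaustive loops) so they are
# a separate route from the interval-algebra / compiled implementations.

rand_bases <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

rand_intervals <- function(n, seq_names, seq_len, max_w = 1000) {
  s <- sample.int(seq_len - max_w, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  intervals(sample(seq_names, n, replace = TRUE), s, s + w)
}

# per-base union mask of an interval set over one sequence
oracle_mask <- function(x, seq_name, seq_len) {
  m <- logical(seq_len)
  for (i in which(x$seq == seq_name)) {
    m[(x$start[i] + 1):x$end[i]] <- TRUE
  }
  m
}

oracle_covered <- function(x, seq_lens) {
  sum(vapply(names(seq_lens), function(nm)
    sum(oracle_mask(x, nm, seq_lens[[nm]])), numeric(1)))
}

oracle_overlap <- function(a, b, seq_lens) {
  sum(vapply(names(seq_lens), function(nm)
    sum(oracle_mask(a, nm, seq_lens[[nm]]) &
          oracle_mask(b, nm, seq_lens[[nm]])), numeric(1)))
}

# merged intervals recovered from a per-base mask
oracle_merge <- function(x, seq_lens, max_gap = 0) {
  out <- list()
  for (nm in sort(unique(x$seq))) {
    m <- oracle_mask(x, nm, seq_lens[[nm]])
    if (max_gap > 0) {
      # fill gaps of length <= max_gap between covered stretches
      r <- rle(m)
      ends <- cumsum(r$lengths)
      for (j in seq_along(r$values)) {
        if (!r$values[j] && j > 1 && j < length(r$values) &&
            r$lengths[j] <= max_gap) {
          m[(ends[j] - r$lengths[j] + 1):ends[j]] <- TRUE
        }
      }
    }
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(seq = nm, start = starts[j] - 1,
                                            end = ends[j],
                                            label = NA_character_,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(intervals())
  do.call(rbind, out)
}

# exhaustive collinearity-pruning oracle; same neighbourhood contract,
# independent bookkeeping
oracle_prune <- function(hits, cfg) {
  ord <- order(hits$query_seq, hits$window_start)
  h <- hits[ord, , drop = FALSE]
  retained <- rep(FALSE, nrow(h))
  for (i in seq_len(nrow(h))) {
    same_seq <- which(h$query_seq == h$query_seq[i])
    pos <- match(i, same_seq)
    n <- length(same_seq)
    half <- cfg$n_window %/% 2L
    lo <- pos - half
    hi <- lo + cfg$n_window - 1L
    if (lo < 1L) { lo <- 1L; hi <- min(n, cfg$n_window) }
    if (hi > n) { hi <- n; lo <- max(1L, n - cfg$n_window + 1L) }
    nb <- same_seq[lo:hi]
    sel <- nb[h$target_seq[nb] == h$target_seq[i]]
    if (length(sel) < cfg$blk_size) next
    tp <- h$tstart[sel]
    inc <- !is.unsorted(tp)
    dec <- !is.unsorted(rev(tp))
    gaps_ok <- length(tp) < 2 || max(abs(diff(tp))) <= cfg$max_gap
    retained[i] <- (inc || dec) && gaps_ok
  }
  hits[sort(ord[retained]), , drop = FALSE]
}

# literal per-window reimplementation of the hit filter contract
oracle_filter <- function(hits, cfg) {
  keep <- logical(nrow(hits))
  keys <- paste(hits$query_seq, hits$window_index)
  for (k in unique(keys)) {
    rows <- which(keys == k)
    sc <- hits$score[rows]
    if (cfg$nhits == 1L) {
      best <- max(sc)
      if (sum(sc == best) > 1L) next       # tie: drop all
      keep[rows[which.max(sc)]] <- TRUE
    } else {
      keep[rows[order(-sc)][seq_len(min(cfg$nhits, length(rows)))]] <- TRUE
    }
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[out$identity >= cfg$min_identity &
               out$coverage >= cfg$min_coverage, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# build a window-hit row set from minimal fields
mk_hits <- function(query_seq, window_index, score, target_seq = "t",
                    window_start = (window_index - 1) * 2500,
                    tstart = window_start, identity = 0.999,
                    coverage = 1, qlen = 10000, strand = "+") {
  n <- max(length(query_seq), length(window_index), length(score),
           length(target_seq))
  h <- data.frame(query_seq = rep_len(query_seq, n),
                  window_index = rep_len(window_index, n),
                  window_start = rep_len(window_start, n),
                  qlen = rep_len(qlen, n), qstart = 0,
                  qend = rep_len(qlen * coverage, n),
                  strand = rep_len(strand, n),
                  target_seq = rep_len(target_seq, n),
                  tlen = 1e9, tstart = rep_len(tstart, n),
                  tend = rep_len(tstart, n) + qlen,
                  matches = rep_len(score, n),
                  block_len = round(rep_len(score, n) / rep_len(identity, n)),
                  stringsAsFactors = FALSE)
  h$identity <- h$matches / h$block_len
  h$coverage <- (h$qend - h$qstart) / h$qlen
  h$score <- h$matches
  h
}

# hand-built ancestry track from label runs
mk_track <- function(labels, seq = "chr1", step = 2500, window_len = 10000) {
  n <- length(labels)
  structure(list(windows = data.frame(
    seq = rep(seq, n), start = (seq_len(n) - 1) * step,
    end = (seq_len(n) - 1) * step + window_len, index = seq_len(n),
    label = labels, score_recipient = NA_real_, score_donor = NA_real_,
    stringsAsFactors = FALSE)), class = "ancestry_track")
}

count_mismatches <- function(a, b) {
  va <- strsplit(a, "")[[1L]]
  vb <- strsplit(b, "")[[1L]]
  sum(va != vb)
}

plant_substitutions <- function(s, rate) {
  v <- strsplit(s, "")[[1L]]
  pos <- which(runif(length(v)) < rate)
  bases <- c("A", "C", "G", "T")
  v[pos] <- vapply(v[pos], function(x) sample(setdiff(bases, x), 1L),
                   character(1))
  list(seq = paste0(v, collapse = ""), n = length(pos))
}
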