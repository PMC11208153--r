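#' Extract centromere-diagnostic k-mers
#'
#' Canonical k-mers (lexicographic minimum of a k-mer and its reverse
#' complement) that occur at least `min_count` times with their start inside
#' the union of the putative centromere regions and never start outside it.
#' K-mers containing N are excluded.
#'
#' @param g a [genome()].
#' @param regions putative centromere intervals on `g`.
#' @param k k-mer length.
#' @param min_count minimum inside-occurrence count.
#' @return object of class `diagnostic_kmers`: list with `k`, `kmers`
#'   (sorted canonical strings) and `min_count`.
#' @export
extract_diagnostic_kmers <- function(g, regions, k = 25L, min_count = 25L) {
  regions <- validate_intervals(as.data.frame(regions), g)
  if (nrow(regions) == 0L) {
    return(structure(list(k = as.integer(k), kmers = character(),
                          min_count = as.integer(min_count)),
                     class = "diagnostic_kmers"))
  }
  sid <- match(regions$seq, names(g$sequences))
  km <- cpp_diag_kmers(unname(g$sequences), sid, as.integer(regions$start),
                       as.integer(regions$end), as.integer(k),
                       as.integer(min_count))
  structure(list(k = as.integer(k), kmers = km,
                 min_count = as.integer(min_count)),
            class = "diagnostic_kmers")
}

#' @export
print.diagnostic_kmers <- function(x, ...) {
  cat(sprintf("<diagnostic_kmers> k=%d, %d kmers (min inside count %d)\n",
              x$k, length(x$kmers), x$min_count))
  invisible(x)
}

#' Diagnostic k-mer density profile
#'
#' Overlapping blocks (`block_len` wide, `step` apart; the last block may be
#' short and its fraction uses the actual width) are scored by the fraction
#' of their bases covered by at least one diagnostic k-mer occurrence
#' (union of occurrence spans on either strand -- overlaps are not double
#' counted).
#'
#' @param g a [genome()].
#' @param kmers a [extract_diagnostic_kmers()] result.
#' @param block_len block width in bases.
#' @param step block start spacing in bases.
#' @return object of class `density_profile`: data.frame with seq, start,
#'   end, coverage_fraction.
#' @export
kmer_density_scan <- function(g, kmers, block_len = 250000, step = 50000) {
  masks <- cpp_kmer_coverage(unname(g$sequences), kmers$kmers, kmers$k)
  out <- list()
  for (i in seq_along(g$sequences)) {
    nm <- names(g$sequences)[i]
    len <- g$lengths[[i]]
    starts <- seq.int(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + block_len, len)
    cum <- c(0, cumsum(masks[[i]]))
    frac <- (cum[ends + 1] - cum[starts + 1]) / (ends - starts)
    out[[nm]] <- data.frame(seq = nm, start = starts, end = ends,
                            coverage_fraction = frac,
                            stringsAsFactors = FALSE)
  }
  structure(list(blocks = do.call(rbind, out), block_len = block_len,
                 step = step), class = "density_profile")
}

#' Call centromeres from a density profile
#'
#' Blocks with coverage at or above `threshold` are selected and
#' overlapping/adjacent selected blocks merge into one interval per
#' centromere.
#'
#' @param profile a [kmer_density_scan()] result.
#' @param threshold minimum coverage fraction (default 0.0204).
#' @return sorted interval data.frame of centromere calls.
#' @export
call_centromeres <- function(profile, threshold = 0.0204) {
  sel <- profile$blocks[profile$blocks$coverage_fraction >= threshold, ,
                        drop = FALSE]
  if (nrow(sel) == 0L) return(intervals())
  merge_intervals(intervals(sel$seq, sel$start, sel$end), max_gap = 0)
}

#' Calibrate the centromere density threshold
#'
#' The per-sequence peak (maximum block coverage fraction) distribution is
#' summarized by its 5th percentile (linear interpolation between order
#' statistics), giving a conservative genome-specific calling threshold.
#'
#' @param profile a [kmer_density_scan()] result over a reference genome.
#' @return threshold fraction.
#' @export
calibrate_threshold <- function(profile) {
  peaks <- tapply(profile$blocks$coverage_fraction, profile$blocks$seq, max)
  if (length(peaks) < 2L) stop_fmt("calibration needs >= 2 sequences")
  if (all(peaks == 0)) stop_fmt("calibration impossible: all profiles zero")
  unname(stats::quantile(peaks, probs = 0.05, type = 7))
}

TELOMERE_MOTIFS <- c("CCCGAAA", "CCCTAAA", "TTTCGGG", "TTTAGGG")

count_motifs <- function(s, motifs) {
  sum(vapply(motifs, function(m) {
    hits <- gregexpr(paste0("(?=", m, ")"), s, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) 0L else length(hits)
  }, integer(1)))
}

#' Detect telomeric termini
#'
#' A chromosome terminus is telomeric when the listed motifs (overlapping
#' matches allowed, any motif) occur at least `min_copies` times within its
#' terminal `terminal_len` bases.
#'
#' @param g a [genome()].
#' @param motifs telomeric 7-mers (plant-type defaults, both strands).
#' @param terminal_len terminal span examined, bases.
#' @param min_copies minimum motif occurrences.
#' @return data.frame with seq, start_telomere, end_telomere.
#' @export
find_telomeres <- function(g, motifs = TELOMERE_MOTIFS, terminal_len = 1000L,
                           min_copies = 10L) {
  res <- lapply(names(g$sequences), function(nm) {
    s <- g$sequences[[nm]]
    len <- nchar(s)
    tl <- min(terminal_len, len)
    head_n <- count_motifs(substr(s, 1L, tl), motifs)
    tail_n <- count_motifs(substr(s, len - tl + 1L, len), motifs)
    data.frame(seq = nm, start_telomere = head_n >= min_copies,
               end_telomere = tail_n >= min_copies, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Hierarchical base-composition profile
#'
#' Every base is assigned exactly one class by the priority
#' exon > ty3 > other_repeat > intron > other, then sliding windows report
#' per-class fractions (which sum to 1), alongside whole-genome totals.
#' Overlapping intervals within one layer are pre-merged.
#'
#' @param g a [genome()].
#' @param exons,ty3,other_repeats,introns interval data.frames (any may be
#'   empty).
#' @param win window width, bases.
#' @param step window start spacing, bases.
#' @return list with `windows` (seq, start, end and one fraction column per
#'   class) and `totals` (named genome-wide fractions).
#' @export
hierarchical_composition <- function(g, exons = intervals(),
                                     ty3 = intervals(),
                                     other_repeats = intervals(),
                                     introns = intervals(),
                                     win = 5e6, step = 1e6) {
  layers <- list(exon = exons, ty3 = ty3, other_repeat = other_repeats,
                 intron = introns)
  layers <- lapply(layers, function(x) merge_intervals(validate_intervals(
    as.data.frame(x), g)))
  # peel each layer by the union of the higher-priority ones
  assigned <- list()
  higher <- intervals()
  for (nm in names(layers)) {
    cur <- layers[[nm]]
    if (nrow(higher) && nrow(cur)) {
      la <- as_iranges_by_seq(cur)
      lb <- as_iranges_by_seq(higher)
      kept <- lapply(names(la), function(sq) {
        if (is.null(lb[[sq]])) la[[sq]]
        else BiocGenerics::setdiff(la[[sq]], lb[[sq]])
      })
      names(kept) <- names(la)
      cur <- from_iranges(kept)
    }
    assigned[[nm]] <- cur
    higher <- if (nrow(cur)) merge_intervals(rbind(higher, cur)) else higher
  }
  per_window <- function(nm) {
    len <- g$lengths[[nm]]
    starts <- seq.int(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + win, len)
    wiv <- IRanges::IRanges(start = starts + 1, end = ends)
    frac <- sapply(names(layers), function(cl) {
      x <- assigned[[cl]]
      x <- x[x$seq == nm, , drop = FALSE]
      if (nrow(x) == 0L) return(rep(0, length(wiv)))
      ir <- IRanges::IRanges(start = x$start + 1, end = x$end)
      cov <- IRanges::coverage(ir, width = len)
      cum <- c(0, cumsum(as.numeric(cov)))
      (cum[ends + 1] - cum[starts + 1]) / (ends - starts)
    })
    frac <- matrix(frac, nrow = length(starts),
                   dimnames = list(NULL, names(layers)))
    data.frame(seq = nm, start = starts, end = ends, frac,
               other = 1 - rowSums(frac), stringsAsFactors = FALSE)
  }
  wins <- do.call(rbind, lapply(names(g$sequences), per_window))
  gl <- sum(as.numeric(g$lengths))
  totals <- vapply(assigned, covered_bases, numeric(1)) / gl
  totals <- c(totals, other = 1 - sum(totals))
  list(windows = wins, totals = totals)
}
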