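#' Genome container
#'
#' A genome is a named set of uppercase nucleotide sequences over
#' \{A,C,G,T,N\}. All coordinates in this package are 0-based half-open;
#' 1-based rendering happens only in human-readable reports.
#'
#' @param sequences named character vector of nucleotide sequences.
#' @param genome_id short identifier.
#' @param n_replaced count of non-ACGTN characters squashed to N at read time.
#' @return an object of class `genome` with elements `genome_id`,
#'   `sequences` (named character) and `lengths` (named integer).
#' @export
genome <- function(sequences, genome_id = "genome", n_replaced = 0L) {
  if (length(sequences) == 0L) stop_fmt("genome '%s' has no sequences", genome_id)
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) stop_fmt("all sequences must be named")
  if (anyDuplicated(nm)) {
    stop_fmt("duplicate sequence name: %s", nm[duplicated(nm)][1L])
  }
  len <- nchar(sequences)
  if (any(len == 0L)) stop_fmt("zero-length sequence: %s", nm[len == 0L][1L])
  structure(
    list(genome_id = genome_id,
         sequences = sequences,
         lengths = stats::setNames(as.integer(len), nm),
         n_replaced = as.integer(n_replaced)),
    class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d sequence(s), %s bases\n", x$genome_id,
              length(x$sequences), format(sum(as.numeric(x$lengths)),
                                          big.mark = ",")))
  invisible(x)
}

#' Read a FASTA file into a genome
#'
#' Sequences are uppercased; characters outside \{A,C,G,T,N\} (e.g. IUPAC
#' ambiguity codes) are replaced by N and counted in `$n_replaced` -- the
#' windowed analyses treat them as unalignable rather than rejecting the
#' assembly.
#'
#' @param path FASTA file (wrapped or unwrapped records).
#' @param genome_id identifier; defaults to the file name without extension.
#' @return a [genome()].
#' @export
read_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_fmt("FASTA format error in %s: %s",
                                               path, conditionMessage(e)))
  if (length(set) == 0L) stop_fmt("empty FASTA file: %s", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) stop_fmt("duplicate FASTA record name: %s",
                                  nm[duplicated(nm)][1L])
  seqs <- toupper(as.character(set))
  n_bad <- sum(vapply(seqs, function(s) nchar(gsub("[ACGTN]", "", s)),
                      integer(1)))
  if (n_bad > 0L) seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- nm
  genome(seqs, genome_id %||% sub("\\.(fa|fasta|fna)$", "", basename(path)),
         n_replaced = n_bad)
}

#' Write a genome to FASTA
#' @param g a [genome()].
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 80L) {
  set <- Biostrings::DNAStringSet(g$sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Interval table constructor
#'
#' Intervals are rows of a data.frame with 0-based half-open `start`/`end` on
#' a named sequence, plus an optional label. This is the package's universal
#' coordinate currency (BED-compatible).
#'
#' @param seq sequence names.
#' @param start,end 0-based half-open bounds.
#' @param label optional character labels.
#' @param genome optional [genome()] to bound-check against.
#' @return data.frame with columns seq, start, end, label.
#' @export
intervals <- function(seq = character(), start = integer(), end = integer(),
                      label = NA_character_, genome = NULL) {
  if (length(seq) == 0L) label <- character()
  x <- data.frame(seq = as.character(seq), start = as.numeric(start),
                  end = as.numeric(end), label = label,
                  stringsAsFactors = FALSE)
  validate_intervals(x, genome)
}

validate_intervals <- function(x, genome = NULL) {
  if (nrow(x) == 0L) return(x)
  if (any(x$start < 0)) stop_fmt("negative interval start")
  if (any(x$end <= x$start)) stop_fmt("interval end must exceed start")
  if (!is.null(genome)) {
    unknown <- setdiff(x$seq, names(genome$lengths))
    if (length(unknown)) stop_fmt("interval on unknown sequence: %s", unknown[1L])
    if (any(x$end > genome$lengths[x$seq]))
      stop_fmt("interval exceeds sequence length")
  }
  x
}

#' Write intervals as BED3/BED4
#'
#' 0-based half-open, tab-separated, one line per interval in input order;
#' the label becomes the 4th column when any label is non-NA.
#'
#' @param x interval data.frame (see [intervals()]).
#' @param path output path.
#' @param genome optional [genome()] for bound checks.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, genome = NULL) {
  x <- validate_intervals(as.data.frame(x)[, intersect(c("seq", "start", "end",
                                                         "label"), names(x))],
                          genome)
  if (nrow(x) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  cols <- list(x$seq, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(x$label) && any(!is.na(x$label))) {
    cols <- c(cols, list(ifelse(is.na(x$label), ".", x$label)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a BED3/BED4 file
#' @param path BED file path.
#' @param genome optional [genome()] for bound checks.
#' @return interval data.frame.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  if (file.size(path) == 0L) return(intervals())
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (ncol(dt) < 3L) stop_fmt("BED needs >= 3 columns: %s", path)
  x <- data.frame(seq = as.character(dt[[1L]]), start = as.numeric(dt[[2L]]),
                  end = as.numeric(dt[[3L]]),
                  label = if (ncol(dt) >= 4L) as.character(dt[[4L]]) else
                    NA_character_,
                  stringsAsFactors = FALSE)
  validate_intervals(x, genome)
}

#' Read a PAF alignment file into window hits
#'
#' Standard 12+-column PAF; columns 10/11 are residue matches and alignment
#' block length. Identity is matches/block_length (gap-compressed differences
#' count against identity) and coverage is the aligned query fraction.
#' Query names written by [write_paf()] (`seq|index|window_start`) round-trip
#' the window bookkeeping; foreign query names are kept verbatim with an NA
#' window index.
#'
#' @param path PAF file path.
#' @return a window-hit data.frame (see [align_windows()] for columns).
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop_fmt("PAF line %d has %d < 12 columns", which(nf < 12L)[1L],
             nf[nf < 12L][1L])
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  qname <- m[, 1L]
  parsed <- regmatches(qname, regexec("^(.+)\\|(\\d+)\\|(\\d+)$", qname))
  has <- lengths(parsed) == 4L
  hits <- data.frame(
    query_seq = ifelse(has, vapply(parsed, function(p) if (length(p)) p[2L] else
      NA_character_, character(1)), qname),
    window_index = ifelse(has, as.integer(vapply(parsed, function(p)
      if (length(p)) p[3L] else NA_character_, character(1))), NA_integer_),
    window_start = ifelse(has, as.numeric(vapply(parsed, function(p)
      if (length(p)) p[4L] else NA_character_, character(1))), NA_real_),
    qlen = as.numeric(m[, 2L]), qstart = as.numeric(m[, 3L]),
    qend = as.numeric(m[, 4L]), strand = m[, 5L],
    target_seq = m[, 6L], tlen = as.numeric(m[, 7L]),
    tstart = as.numeric(m[, 8L]), tend = as.numeric(m[, 9L]),
    matches = as.numeric(m[, 10L]), block_len = as.numeric(m[, 11L]),
    stringsAsFactors = FALSE)
  finish_hits(hits)
}

#' Write window hits as PAF
#' @param hits window-hit data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(hits, path) {
  if (nrow(hits) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  qname <- ifelse(is.na(hits$window_index), hits$query_seq,
                  sprintf("%s|%d|%.0f", hits$query_seq, hits$window_index,
                          hits$window_start))
  num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  writeLines(paste(qname, num(hits$qlen), num(hits$qstart), num(hits$qend),
                   hits$strand, hits$target_seq, num(hits$tlen),
                   num(hits$tstart), num(hits$tend), num(hits$matches),
                   num(hits$block_len), 60L, sep = "\t"), path)
  invisible(path)
}

empty_hits <- function() {
  finish_hits(data.frame(query_seq = character(), window_index = integer(),
                         window_start = numeric(), qlen = numeric(),
                         qstart = numeric(), qend = numeric(),
                         strand = character(), target_seq = character(),
                         tlen = numeric(), tstart = numeric(),
                         tend = numeric(), matches = numeric(),
                         block_len = numeric(), stringsAsFactors = FALSE))
}

# derive identity/coverage/score columns
finish_hits <- function(hits) {
  hits$identity <- ifelse(hits$block_len > 0, hits$matches / hits$block_len, 0)
  hits$coverage <- ifelse(hits$qlen > 0, (hits$qend - hits$qstart) / hits$qlen, 0)
  hits$score <- hits$matches
  hits
}

# ---- interval algebra (IRanges-backed; per-base oracles live in the tests) --

as_iranges_by_seq <- function(x) {
  if (nrow(x) == 0L) return(list())
  split(IRanges::IRanges(start = x$start + 1L, end = x$end), x$seq)
}

from_iranges <- function(lst) {
  if (length(lst) == 0L) return(intervals())
  parts <- lapply(names(lst), function(nm) {
    ir <- lst[[nm]]
    data.frame(seq = rep(nm, length(ir)), start = BiocGenerics::start(ir) - 1,
               end = BiocGenerics::end(ir), label = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out[order(out$seq, out$start), , drop = FALSE]
}

#' Merge intervals
#'
#' Coalesces, per sequence, intervals that overlap or lie within `max_gap`
#' bases of one another. With `max_gap = 0` the total covered base count is
#' preserved. Output is sorted by (seq, start); labels are dropped.
#'
#' @param x interval data.frame.
#' @param max_gap maximum gap (bases) to bridge; 0 merges only overlapping or
#'   book-ended intervals.
#' @return merged, sorted interval data.frame.
#' @export
merge_intervals <- function(x, max_gap = 0) {
  if (nrow(x) == 0L) return(intervals())
  lst <- as_iranges_by_seq(x)
  merged <- lapply(lst, IRanges::reduce, min.gapwidth = max_gap + 1)
  out <- from_iranges(merged)
  rownames(out) <- NULL
  out
}

#' Total bases covered by an interval set
#' @param x interval data.frame.
#' @return numeric base count (overlaps counted once).
#' @export
covered_bases <- function(x) {
  if (nrow(x) == 0L) return(0)
  sum(vapply(as_iranges_by_seq(x),
             function(ir) sum(as.numeric(BiocGenerics::width(IRanges::reduce(ir)))),
             numeric(1)))
}

#' Bases covered by both of two interval sets
#'
#' The intersection of the two set unions; symmetric in its arguments.
#'
#' @param a,b interval data.frames on the same genome.
#' @return numeric base count.
#' @export
overlap_bases <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  la <- lapply(as_iranges_by_seq(a), IRanges::reduce)
  lb <- lapply(as_iranges_by_seq(b), IRanges::reduce)
  common <- intersect(names(la), names(lb))
  if (length(common) == 0L) return(0)
  sum(vapply(common, function(nm) {
    sum(as.numeric(BiocGenerics::width(BiocGenerics::intersect(la[[nm]],
                                                               lb[[nm]]))))
  }, numeric(1)))
}

#' Jaccard similarity of two interval sets
#'
#' Intersection bases over union bases; the planted-truth recovery score.
#'
#' @param a,b interval data.frames.
#' @return value in \[0, 1\] (1 when both sets are empty).
#' @export
interval_jaccard <- function(a, b) {
  inter <- overlap_bases(a, b)
  uni <- covered_bases(a) + covered_bases(b) - inter
  if (uni == 0) return(1)
  inter / uni
}
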