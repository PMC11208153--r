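#' Permutation test for genomic interval overlap
#'
#' The observed statistic is the base overlap (or the count of A blocks
#' touching B) between the two sets. The null re-places every A interval
#' uniformly at random on its own sequence, preserving length and
#' chromosome and forbidding self-overlap among the placed intervals
#' (rejection sampling, at most `max_attempts` tries per interval) -- the
#' standard conservative null for interval-overlap enrichment. The p-value
#' uses the add-one estimator (1 + exceedances) / (n_perm + 1), which never
#' returns zero.
#'
#' @param a,b interval data.frames bound to `genome`.
#' @param genome a [genome()]; the placement universe.
#' @param n_perm number of permutations.
#' @param seed RNG seed; identical inputs and seed give identical results.
#' @param stat "bases" (overlap base count) or "blocks" (number of A
#'   intervals overlapping B).
#' @param max_attempts rejection budget per interval per permutation.
#' @return list of class `permutation_result`: observed_stat, null_stats,
#'   p_value, n_perm, seed.
#' @export
permutation_overlap_test <- function(a, b, genome, n_perm = 1000L,
                                     seed = NULL, stat = c("bases", "blocks"),
                                     max_attempts = 1000L) {
  stat <- match.arg(stat)
  a <- validate_intervals(as.data.frame(a), genome)
  b <- validate_intervals(as.data.frame(b), genome)
  widths <- a$end - a$start
  if (any(widths > genome$lengths[a$seq]))
    stop_fmt("interval longer than its sequence; cannot permute")
  # reduced per-seq representation of B for fast sweeps
  bred <- merge_intervals(b)
  bs <- split(bred[, c("start", "end")], bred$seq)
  stat_fun <- function(s1, e1, s2, e2) {
    # both sets internally non-overlapping -> pairwise sum is exact
    ov <- pmin(rep(e1, times = length(e2)), rep(e2, each = length(e1))) -
      pmax(rep(s1, times = length(s2)), rep(s2, each = length(s1)))
    ov[ov < 0] <- 0
    if (stat == "bases") sum(ov)
    else sum(tapply(ov, rep(seq_along(s1), times = length(s2)), max) > 0)
  }
  observed_for <- function(x) {
    xs <- split(x[, c("start", "end")], x$seq)
    tot <- 0
    for (nm in intersect(names(xs), names(bs))) {
      tot <- tot + stat_fun(xs[[nm]]$start, xs[[nm]]$end,
                            bs[[nm]]$start, bs[[nm]]$end)
    }
    tot
  }
  ared <- merge_intervals(a)
  observed <- observed_for(ared)
  run <- function() {
    null_stats <- numeric(n_perm)
    ord <- order(a$seq)
    seqs <- a$seq[ord]
    w <- widths[ord]
    for (p in seq_len(n_perm)) {
      placed_s <- numeric(length(w))
      placed_e <- numeric(length(w))
      for (i in seq_along(w)) {
        L <- genome$lengths[[seqs[i]]]
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          s <- floor(stats::runif(1, 0, L - w[i] + 1))
          e <- s + w[i]
          prev <- which(seqs[seq_len(i - 1)] == seqs[i])
          if (!length(prev) ||
              all(e <= placed_s[prev] | s >= placed_e[prev])) {
            ok <- TRUE
            break
          }
        }
        if (!ok) stop_fmt(
          "rejection budget exhausted placing a %d-base interval; use a larger genome",
          w[i])
        placed_s[i] <- s
        placed_e[i] <- e
      }
      tot <- 0
      for (nm in intersect(unique(seqs), names(bs))) {
        sel <- seqs == nm
        tot <- tot + stat_fun(placed_s[sel], placed_e[sel],
                              bs[[nm]]$start, bs[[nm]]$end)
      }
      null_stats[p] <- tot
    }
    null_stats
  }
  null_stats <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  p <- (1 + sum(null_stats >= observed)) / (n_perm + 1)
  structure(list(observed_stat = observed, null_stats = null_stats,
                 p_value = p, n_perm = n_perm, seed = seed, stat = stat),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %s = %g, n_perm = %d, p = %g\n",
              x$stat, x$observed_stat, x$n_perm, x$p_value))
  invisible(x)
}

#' Read an orthogroup presence-absence matrix
#'
#' Tab-separated, header row of genome ids, rows of orthogroup id followed
#' by 0/1 flags.
#'
#' @param path TSV path.
#' @return data.frame: orthogroup column plus one logical column per genome.
#' @export
read_pav_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  if (ncol(dt) < 3L) stop_fmt("PAV matrix needs >= 2 genome columns")
  out <- data.frame(orthogroup = as.character(dt[[1L]]),
                    stringsAsFactors = FALSE)
  for (j in 2:ncol(dt)) out[[names(dt)[j]]] <- as.logical(dt[[j]])
  out
}

#' Count presence-absence patterns over orthogroups
#'
#' Each orthogroup's presence flags across the ordered genomes form a
#' pattern string (e.g. "1101"); counts over all observed patterns are
#' returned together with per-genome private counts (present only there)
#' and the shared-in-all count.
#'
#' @param mat data.frame as from [read_pav_matrix()]: orthogroup id column
#'   plus one logical/0-1 column per genome (>= 2 genomes).
#' @return list with `patterns` (data.frame pattern, count), `private`
#'   (named per-genome counts), `shared_all`, `total`.
#' @export
pav_patterns <- function(mat) {
  genomes <- setdiff(names(mat), "orthogroup")
  if (length(genomes) < 2L) stop_fmt("need >= 2 genomes")
  flags <- as.matrix(as.data.frame(lapply(mat[genomes], function(x)
    as.integer(as.logical(x)))))
  if (any(rowSums(flags) == 0L))
    stop_fmt("orthogroup present in no genome: %s",
             mat$orthogroup[rowSums(flags) == 0L][1L])
  pattern <- apply(flags, 1L, paste0, collapse = "")
  counts <- sort(table(pattern), decreasing = TRUE)
  private <- vapply(seq_along(genomes), function(j) {
    sum(flags[, j] == 1L & rowSums(flags) == 1L)
  }, numeric(1))
  names(private) <- genomes
  list(patterns = data.frame(pattern = names(counts),
                             count = as.integer(counts),
                             stringsAsFactors = FALSE),
       private = private,
       shared_all = sum(rowSums(flags) == length(genomes)),
       total = nrow(flags))
}

#' Printed-summary arithmetic
#'
#' The fixed rounding conventions behind headline assembly statistics:
#' percentages, ratios and fold-changes round half away from zero; rates
#' and per-group means truncate. Each rule is deliberate -- they reproduce
#' how such numbers are conventionally printed.
#'
#' @param part,whole,a,b,count,units,total,n_groups numeric inputs; the
#'   denominator must be non-zero.
#' @return the derived statistic.
#' @name summary_arithmetic
NULL

check_denom <- function(x) if (any(x == 0)) stop_fmt("zero denominator")

#' @rdname summary_arithmetic
#' @export
percent <- function(part, whole) {
  check_denom(whole)
  round_half_up(100 * part / whole, 1)
}

#' @rdname summary_arithmetic
#' @export
ratio <- function(a, b) {
  check_denom(b)
  round_half_up(a / b, 1)
}

#' @rdname summary_arithmetic
#' @export
fold <- function(a, b) {
  check_denom(b)
  round_half_up(a / b, 0)
}

#' @rdname summary_arithmetic
#' @export
rate_per_unit_trunc <- function(count, units) {
  check_denom(units)
  trunc_digits(count / units, 1)
}

#' @rdname summary_arithmetic
#' @export
mean_per_group_trunc <- function(total, n_groups) {
  check_denom(n_groups)
  trunc_digits(total / n_groups, 0)
}

#' Derived summary statistics from named inputs
#'
#' Convenience wrapper computing a named list of derived statistics from a
#' named list like `list(percent = list(part =, whole =), ...)`; see the
#' individual functions in [summary_arithmetic].
#'
#' @param values named list; each element is a list of arguments for the
#'   function of the same name (`percent`, `ratio`, `fold`,
#'   `rate_per_unit_trunc`, `mean_per_group_trunc`).
#' @return named numeric vector of derived statistics.
#' @export
summary_report <- function(values) {
  vapply(names(values), function(nm) {
    fn <- sub("\\.\\d+$", "", nm)
    do.call(match.fun(fn), as.list(values[[nm]]))
  }, numeric(1))
}
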