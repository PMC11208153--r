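BASES <- c("A", "C", "G", "T")

#' Simulation configuration for a recipient/donor/cultivar trio
#'
#' The generator states a world with the statistical structure the scan
#' assumes: two parent genomes at a configurable substitution divergence,
#' cultivars carrying planted donor blocks, optional zero-divergence
#' segments, tandem centromeric arrays and terminal telomere motifs.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len chromosome length, bases (all equal).
#' @param divergence recipient-donor per-base substitution probability
#'   (0 to 0.25).
#' @param private_rate cultivar-private substitution probability.
#' @param introgressions data.frame (seq, start, end) of donor blocks
#'   planted into the cultivar; mutually non-overlapping.
#' @param lowdiv data.frame (seq, start, end) of segments copied verbatim
#'   into the donor (zero divergence).
#' @param centromeres data.frame (seq, position, array_len) of tandem-array
#'   midlocations; `monomer_len` sets the repeated unit length (one random
#'   monomer per genome).
#' @param monomer_len centromeric monomer length, bases.
#' @param telomere_copies telomere motif copies overwritten onto each
#'   terminus (0 disables).
#' @param indel_rate optional small-indel rate (events per base, geometric
#'   lengths of mean 2) applied with the divergence; 0 disables.
#' @param seed RNG seed; all generators are pure functions of (cfg, seed).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 3L, chrom_len = 1e6, divergence = 0.01,
                       private_rate = 0.001, introgressions = NULL,
                       lowdiv = NULL, centromeres = NULL, monomer_len = 150L,
                       telomere_copies = 150L, indel_rate = 0, seed = 1L) {
  if (divergence < 0 || divergence > 0.25)
    stop_fmt("divergence must be in [0, 0.25]")
  chk <- function(x, what) {
    if (is.null(x) || nrow(x) == 0L) return(x)
    if (any(x$start < 0 | x$end > chrom_len))
      stop_fmt("%s interval outside chromosome bounds", what)
    for (nm in unique(x$seq)) {
      iv <- x[x$seq == nm, , drop = FALSE]
      iv <- iv[order(iv$start), , drop = FALSE]
      if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)]))
        stop_fmt("overlapping %s intervals on %s", what, nm)
    }
    x
  }
  if (!is.null(centromeres) && nrow(centromeres)) {
    if (any(centromeres$array_len > chrom_len))
      stop_fmt("centromeric array longer than chromosome")
  }
  structure(list(n_chroms = as.integer(n_chroms), chrom_len = chrom_len,
                 divergence = divergence, private_rate = private_rate,
                 introgressions = chk(introgressions, "introgression"),
                 lowdiv = chk(lowdiv, "low-divergence"),
                 centromeres = centromeres, monomer_len = as.integer(monomer_len),
                 telomere_copies = as.integer(telomere_copies),
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "sim_config")
}

chrom_names <- function(cfg) sprintf("chr%02d", seq_len(cfg$n_chroms))

# deterministic sub-seeds per generation stage, kept below 2^31
stage_seed <- function(cfg, stage) {
  (cfg$seed * 97L + stage * 7919L) %% .Machine$integer.max
}

#' Simulate the recipient genome
#'
#' I.i.d. uniform A/C/G/T background; one random centromeric monomer per
#' genome tiled into the planned arrays; telomere motifs (CCCTAAA at the 5'
#' terminus, TTTAGGG at the 3' terminus) overwrite the terminal bases so
#' chromosome length is exactly `chrom_len`.
#'
#' @param cfg a [sim_config()].
#' @return a [genome()].
#' @export
simulate_recipient <- function(cfg) {
  withr::with_seed(stage_seed(cfg, 1L), {
    monomer <- paste0(sample(BASES, cfg$monomer_len, replace = TRUE),
                      collapse = "")
    seqs <- vapply(chrom_names(cfg), function(nm) {
      v <- sample(BASES, cfg$chrom_len, replace = TRUE)
      cen <- cfg$centromeres
      if (!is.null(cen) && nm %in% cen$seq) {
        row <- cen[cen$seq == nm, , drop = FALSE][1L, ]
        arr <- strsplit(strrep(monomer, ceiling(row$array_len /
                                                  cfg$monomer_len)), "")[[1L]]
        s <- row$position - row$array_len %/% 2
        s <- max(0, min(s, cfg$chrom_len - row$array_len))
        v[(s + 1):(s + row$array_len)] <- arr[seq_len(row$array_len)]
      }
      if (cfg$telomere_copies > 0L) {
        tl <- strsplit(strrep("CCCTAAA", cfg$telomere_copies), "")[[1L]]
        tr <- strsplit(strrep("TTTAGGG", cfg$telomere_copies), "")[[1L]]
        v[seq_along(tl)] <- tl
        v[(cfg$chrom_len - length(tr) + 1):cfg$chrom_len] <- tr
      }
      paste0(v, collapse = "")
    }, character(1))
    g <- genome(seqs, "recipient")
    attr(g, "monomer") <- monomer
    g
  })
}

# substitute bases at `pos` (1-based) to a uniformly chosen different base
substitute_bases <- function(v, pos) {
  if (length(pos) == 0L) return(v)
  code <- match(v[pos], BASES) - 1L
  v[pos] <- BASES[((code + sample(1:3, length(pos), replace = TRUE)) %% 4L) + 1L]
  v
}

#' Derive the donor genome from the recipient
#'
#' Each base substitutes with probability `divergence` to a uniformly chosen
#' different base, except inside planned low-divergence segments (copied
#' verbatim). With `indel_rate > 0`, small insertions/deletions (geometric
#' lengths, mean 2) are additionally applied outside those segments.
#'
#' @param recipient the [simulate_recipient()] output.
#' @param cfg a [sim_config()].
#' @return a [genome()].
#' @export
derive_donor <- function(recipient, cfg) {
  withr::with_seed(stage_seed(cfg, 2L), {
    seqs <- vapply(names(recipient$sequences), function(nm) {
      v <- strsplit(recipient$sequences[[nm]], "")[[1L]]
      protected <- rep(FALSE, length(v))
      ld <- cfg$lowdiv
      if (!is.null(ld) && nm %in% ld$seq) {
        for (i in which(ld$seq == nm))
          protected[(ld$start[i] + 1):ld$end[i]] <- TRUE
      }
      pos <- which(stats::runif(length(v)) < cfg$divergence & !protected)
      v <- substitute_bases(v, pos)
      if (cfg$indel_rate > 0) {
        ev <- which(stats::runif(length(v)) < cfg$indel_rate & !protected)
        if (length(ev)) {
          lens <- 1L + stats::rgeom(length(ev), prob = 0.5)
          del <- stats::runif(length(ev)) < 0.5
          pieces <- character(length(ev))
          keep_to <- c(ev - 1L, length(v))
          chunks <- mapply(function(a, b) paste0(v[seq2(a, b)], collapse = ""),
                           c(1L, ev + ifelse(del, lens, 0L)),
                           keep_to, SIMPLIFY = TRUE)
          ins <- ifelse(del, "",
                        vapply(lens, function(L) paste0(
                          sample(BASES, L, replace = TRUE), collapse = ""),
                          character(1)))
          return_val <- paste0(paste0(chunks, c(ins, "")), collapse = "")
          return(return_val)
        }
      }
      paste0(v, collapse = "")
    }, character(1))
    genome(seqs, "donor")
  })
}

seq2 <- function(a, b) if (a > b) integer() else seq.int(a, b)

#' Build the cultivar genome and its truth set
#'
#' The cultivar is the recipient with each planned introgression interval
#' replaced by the donor's bases over the same coordinates
#' (coordinate-preserving, so truth comparison needs no liftover), plus
#' cultivar-private substitutions at `private_rate`.
#'
#' @param recipient,donor parent [genome()]s with identical chromosome
#'   structure.
#' @param cfg a [sim_config()].
#' @return list with `genome` (the cultivar) and `truth` (list of
#'   introgressions, lowdiv, centromeres, telomeres on cultivar
#'   coordinates).
#' @export
build_cultivar <- function(recipient, donor, cfg) {
  withr::with_seed(stage_seed(cfg, 3L), {
    seqs <- vapply(names(recipient$sequences), function(nm) {
      v <- strsplit(recipient$sequences[[nm]], "")[[1L]]
      intro <- cfg$introgressions
      if (!is.null(intro) && nm %in% intro$seq) {
        dv <- strsplit(donor$sequences[[nm]], "")[[1L]]
        for (i in which(intro$seq == nm)) {
          idx <- (intro$start[i] + 1):min(intro$end[i], length(dv), length(v))
          v[idx] <- dv[idx]
        }
      }
      if (cfg$private_rate > 0) {
        pos <- which(stats::runif(length(v)) < cfg$private_rate)
        v <- substitute_bases(v, pos)
      }
      paste0(v, collapse = "")
    }, character(1))
    cultivar <- genome(seqs, "cultivar")
    empty <- intervals()
    to_iv <- function(x, lab) {
      if (is.null(x) || nrow(x) == 0L) return(empty)
      intervals(x$seq, x$start, x$end, label = lab)
    }
    cen <- cfg$centromeres
    cen_iv <- if (is.null(cen) || nrow(cen) == 0L) empty else {
      s <- pmax(0, pmin(cen$position - cen$array_len %/% 2,
                        cfg$chrom_len - cen$array_len))
      intervals(cen$seq, s, s + cen$array_len, label = "centromere")
    }
    telo <- data.frame(seq = chrom_names(cfg),
                       start_telomere = cfg$telomere_copies > 0L,
                       end_telomere = cfg$telomere_copies > 0L,
                       stringsAsFactors = FALSE)
    list(genome = cultivar,
         truth = list(introgressions = to_iv(cfg$introgressions,
                                             "introgression"),
                      lowdiv = to_iv(cfg$lowdiv, "lowdiv"),
                      centromeres = cen_iv, telomeres = telo))
  })
}

#' Simulate a full trio
#' @param cfg a [sim_config()].
#' @return list with `recipient`, `donor`, `cultivar`, `truth`, `cfg`.
#' @export
simulate_trio <- function(cfg = sim_config()) {
  recipient <- simulate_recipient(cfg)
  donor <- derive_donor(recipient, cfg)
  cult <- build_cultivar(recipient, donor, cfg)
  list(recipient = recipient, donor = donor, cultivar = cult$genome,
       truth = cult$truth, cfg = cfg)
}

#' Write a simulated trio fixture to disk
#'
#' Emits recipient.fa, donor.fa, cultivar.fa, truth BED/TSV layers, and a
#' JSON manifest holding the full configuration (including the seed), so
#' the fixture regenerates byte-identically.
#'
#' @param trio a [simulate_trio()] result.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(trio, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_fmt("cannot create directory: %s", out_dir)
  write_fasta(trio$recipient, file.path(out_dir, "recipient.fa"))
  write_fasta(trio$donor, file.path(out_dir, "donor.fa"))
  write_fasta(trio$cultivar, file.path(out_dir, "cultivar.fa"))
  write_bed(trio$truth$introgressions,
            file.path(out_dir, "truth.introgressions.bed"))
  write_bed(trio$truth$lowdiv, file.path(out_dir, "truth.lowdiv.bed"))
  write_bed(trio$truth$centromeres, file.path(out_dir, "truth.centromeres.bed"))
  utils::write.table(trio$truth$telomeres,
                     file.path(out_dir, "truth.telomeres.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- trio$cfg
  cfg_json <- lapply(unclass(cfg), function(x)
    if (is.data.frame(x)) as.list(x) else x)
  jsonlite::write_json(cfg_json, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Rebuild a simulation configuration from a fixture manifest
#' @param path manifest.json path.
#' @return a [sim_config()].
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_df <- function(x) {
    if (is.null(x) || length(x) == 0L) return(NULL)
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  sim_config(n_chroms = m$n_chroms, chrom_len = m$chrom_len,
             divergence = m$divergence, private_rate = m$private_rate,
             introgressions = as_df(m$introgressions),
             lowdiv = as_df(m$lowdiv), centromeres = as_df(m$centromeres),
             monomer_len = m$monomer_len,
             telomere_copies = m$telomere_copies,
             indel_rate = m$indel_rate %||% 0, seed = m$seed)
}

#' The default planted-truth trio world
#'
#' Three 1 Mb chromosomes at 1% recipient-donor divergence with one 300 kb
#' donor block on each of the first two chromosomes and the third left
#' block-free (so recovery and false-positive behaviour are visible in one
#' run), 0.1% cultivar-private substitutions, telomeres, no centromeric
#' arrays and no forced low-divergence segments.
#'
#' @param seed RNG seed.
#' @return a [sim_config()].
#' @export
trio_world <- function(seed = 1L) {
  sim_config(
    n_chroms = 3L, chrom_len = 1e6, divergence = 0.01, private_rate = 0.001,
    introgressions = data.frame(
      seq = c("chr01", "chr02"), start = c(350000, 200000),
      end = c(650000, 500000), stringsAsFactors = FALSE),
    seed = seed)
}

#' The low-divergence-mask world
#'
#' Background divergence 3% (clearly discriminable against the mask rule's
#' identity threshold of 1 - 0.03/2 = 0.985) with planted zero-divergence
#' segments of 450 kb on the first two chromosomes and a fully diverged
#' third chromosome.
#'
#' @param seed RNG seed.
#' @return a [sim_config()].
#' @export
lowdiv_world <- function(seed = 1L) {
  sim_config(
    n_chroms = 3L, chrom_len = 1e6, divergence = 0.03, private_rate = 0,
    lowdiv = data.frame(seq = c("chr01", "chr02"),
                        start = c(300000, 100000), end = c(750000, 550000),
                        stringsAsFactors = FALSE),
    seed = seed)
}

#' The centromere world
#'
#' One 100 kb tandem array (150 bp monomer) centred at 450 kb on every
#' 1 Mb chromosome.
#'
#' @param seed RNG seed.
#' @param n_chroms number of chromosomes.
#' @return a [sim_config()].
#' @export
centromere_world <- function(seed = 1L, n_chroms = 3L) {
  sim_config(
    n_chroms = n_chroms, chrom_len = 1e6, divergence = 0.01,
    private_rate = 0,
    centromeres = data.frame(seq = sprintf("chr%02d", seq_len(n_chroms)),
                             position = 450000, array_len = 100000,
                             stringsAsFactors = FALSE),
    seed = seed)
}
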