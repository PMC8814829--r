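# Synthetic reference and library generator.
#
# Produces a self-contained stand-in for the reference side of the analysis
# (pre-miRNA hairpins with one annotated mature each, genomic placements,
# 3' UTRs with planted target sites, contaminant ncRNA surrogates) and
# two-condition replicate FASTQ libraries with known per-miRNA enrichment
# truth, so that every downstream stage can be tested against ground
# truth without any external download.

#' Default 3' adapter (Illumina TruSeq small RNA)
#' @export
TRUSEQ_SMALL_RNA_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

# mature length distribution (nt 18..24), peaked at 22 as in typical
# miRBase mature catalogues and milk small-RNA length profiles
MATURE_LEN_PROBS <- c(`18` = 0.03, `19` = 0.05, `20` = 0.10, `21` = 0.25,
                      `22` = 0.45, `23` = 0.08, `24` = 0.04)

random_dna <- function(n_chars) {
  paste(sample(c("A", "C", "G", "T"), n_chars, replace = TRUE), collapse = "")
}

#' Generate a synthetic small-RNA reference
#'
#' Each hairpin (60-120 nt) embeds exactly one mature annotation of
#' 18-24 nt placed so that the counting window `[x-2, y+5]` (and the
#' wider straggler offsets used by [simulate_libraries()]) stays inside
#' the hairpin. Genomic placements include at least one pair of hairpins
#' closer than 10 kb (when `n_hairpins >= 2`) to exercise cluster
#' detection, and at least one isolated hairpin (when `n_hairpins >= 3`).
#' UTRs (200-2000 nt) carry planted perfect reverse-complement sites for
#' at least three mature sequences (when available). Output is
#' deterministic for a fixed seed.
#'
#' @param n_hairpins number of hairpins (>= 1).
#' @param n_utrs number of 3' UTR records (>= 1).
#' @param seed integer RNG seed.
#' @param adapter 3' adapter sequence; candidate reads are re-drawn if
#'   they contain its 6-nt prefix, so that simulated adapter trimming is
#'   unambiguous.
#' @return an object of class `mir_reference`: list with data frames
#'   `hairpins` (name, sequence, chrom, start, end, strand), `matures`
#'   (name, hairpin, x, y, sequence), `utrs` (gene, transcript,
#'   sequence) and a named character vector `contaminants`.
#' @export
make_reference <- function(n_hairpins, n_utrs, seed = 1,
                           adapter = TRUSEQ_SMALL_RNA_ADAPTER) {
  n_hairpins <- stopifnot_scalar_count(n_hairpins, "n_hairpins")
  n_utrs <- stopifnot_scalar_count(n_utrs, "n_utrs")
  set.seed(as.integer(seed))
  adapter <- normalize_dna(adapter)
  adapter6 <- substr(adapter, 1, 6)

  hp_names <- sprintf("sim-mir-%03d", seq_len(n_hairpins))
  mat_names <- sprintf("sim-miR-%03d", seq_len(n_hairpins))
  hp_len <- sample(60:120, n_hairpins, replace = TRUE)
  mat_len <- as.integer(sample(names(MATURE_LEN_PROBS), n_hairpins,
                               replace = TRUE, prob = MATURE_LEN_PROBS))

  hp_seq <- character(n_hairpins)
  x <- integer(n_hairpins)
  y <- integer(n_hairpins)
  for (i in seq_len(n_hairpins)) {
    # rejection-sample the hairpin so no achievable read (any isomiR or
    # straggler offset) trips a composition filter or embeds the adapter
    repeat {
      xi <- sample(6:(hp_len[i] - 5L - mat_len[i] + 1L), 1)
      yi <- xi + mat_len[i] - 1L
      si <- random_dna(hp_len[i])
      combos <- expand.grid(d5 = -4:0, d3 = 0:5)
      reads <- substring(si, xi + combos$d5, yi + combos$d3)
      fl <- flags_matrix(reads)
      flagged <- rowSums(fl) > 0 | grepl(adapter6, reads, fixed = TRUE)
      if (!any(flagged)) {
        hp_seq[i] <- si; x[i] <- xi; y[i] <- yi
        break
      }
    }
  }
  mat_seq <- substring(hp_seq, x, y)

  # genomic placement: hairpins 1 and 2 close together on chr1 (gap 500 bp),
  # everything else spaced >= 50 kb round-robin over four chromosomes
  chroms <- paste0("chr", 1:4)
  chrom <- character(n_hairpins)
  gstart <- integer(n_hairpins)
  cursor <- setNames(rep(100000L, length(chroms)), chroms)
  for (i in seq_len(n_hairpins)) {
    if (i == 1L) {
      chrom[i] <- "chr1"; gstart[i] <- cursor[["chr1"]]
    } else if (i == 2L) {
      chrom[i] <- "chr1"
      gstart[i] <- gstart[1L] + hp_len[1L] + 500L
    } else {
      ch <- chroms[((i - 3L) %% length(chroms)) + 1L]
      cursor[[ch]] <- cursor[[ch]] + 50000L + sample.int(5000L, 1)
      chrom[i] <- ch; gstart[i] <- cursor[[ch]]
    }
  }
  cursor[["chr1"]] <- max(cursor[["chr1"]], gstart[min(2L, n_hairpins)])
  strand <- sample(c("+", "-"), n_hairpins, replace = TRUE)

  utr_len <- sample(200:2000, n_utrs, replace = TRUE)
  utr_seq <- vapply(utr_len, random_dna, "")
  planted <- data.frame(mature = character(0), gene = character(0),
                        pos = integer(0))
  occupied <- vector("list", n_utrs)  # keep planted sites from overlapping
  plant_into <- function(m_idx, u_idx) {
    site <- revcomp_dna(mat_seq[m_idx])
    w <- nchar(site)
    for (try in 1:50) {
      pos <- sample(20:(utr_len[u_idx] - w - 5L), 1)
      clash <- any(vapply(occupied[[u_idx]], function(iv)
        pos <= iv[2] + 2L && pos + w - 1L >= iv[1] - 2L, logical(1)))
      if (!clash) {
        substr(utr_seq[u_idx], pos, pos + w - 1L) <<- site
        occupied[[u_idx]] <<- c(occupied[[u_idx]], list(c(pos, pos + w - 1L)))
        planted <<- rbind(planted, data.frame(
          mature = mat_names[m_idx], gene = sprintf("gene%03d", u_idx),
          pos = pos))
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_len(min(3L, n_hairpins))) {
    plant_into(i, ((i - 1L) %% n_utrs) + 1L)
  }
  if (n_hairpins > 3L) {
    for (i in 4:n_hairpins) {
      if (runif(1) < 0.3) plant_into(i, sample.int(n_utrs, 1))
    }
  }

  contaminants <- c(
    rRNA_surrogate = random_dna(500),
    tRNA_surrogate = random_dna(150),
    snRNA_surrogate = random_dna(200),
    repeat_surrogate = random_dna(300))

  structure(list(
    hairpins = data.frame(name = hp_names, sequence = hp_seq, chrom = chrom,
                          start = gstart, end = gstart + hp_len - 1L,
                          strand = strand, stringsAsFactors = FALSE),
    matures = data.frame(name = mat_names, hairpin = hp_names, x = x, y = y,
                         sequence = mat_seq, stringsAsFactors = FALSE),
    utrs = data.frame(gene = sprintf("gene%03d", seq_len(n_utrs)),
                      transcript = sprintf("tx%03d", seq_len(n_utrs)),
                      sequence = utr_seq, stringsAsFactors = FALSE),
    contaminants = contaminants,
    planted_sites = planted,
    adapter = adapter,
    seed = as.integer(seed)), class = "mir_reference")
}

#' @export
print.mir_reference <- function(x, ...) {
  cat(sprintf("mir_reference: %d hairpins / %d matures, %d UTRs, %d contaminants\n",
              nrow(x$hairpins), nrow(x$matures), nrow(x$utrs),
              length(x$contaminants)))
  invisible(x)
}

#' Define the enrichment ground truth for a simulation
#'
#' Holds the per-miRNA baseline relative abundance, the true
#' exosome-versus-milk fold change, replicate design, sequencing depth,
#' junk-read composition, and noise parameters for
#' [simulate_libraries()].
#'
#' @param ref a `mir_reference`.
#' @param fold named numeric vector of true linear fold changes (exosome
#'   vs milk) keyed by mature name; unnamed scalar recycles; default 1
#'   for all. Must be finite and >= 0.
#' @param baseline optional named baseline relative abundances; default
#'   is a log-normal draw (sdlog 1.5) normalized to sum 1.
#' @param depth reads per replicate library (default 1e5).
#' @param n_reps replicates per condition (default 3: three biological
#'   replicates per group).
#' @param dispersion replicate-level negative-binomial overdispersion of
#'   the gamma-scaled multinomial means (default 0.05).
#' @param junk_fractions named fractions of library depth per junk class
#'   (`mono`, `ac`, `gt`, `dimer`, `trimer`, `contaminant`).
#' @param straggler_fraction fraction of genuine reads drawn with 5'
#'   offsets outside the `[x-2, y+5]` counting window (default 0.02).
#' @param adapter 3' adapter appended to every read before truncation to
#'   `read_length`.
#' @param read_length instrument read length (default 36 nt single-end).
#' @param seed integer RNG seed controlling both the baseline draw and
#'   the simulation.
#' @return an object of class `mir_truth`.
#' @export
make_truth <- function(ref, fold = 1, baseline = NULL, depth = 1e5,
                       n_reps = 3, dispersion = 0.05,
                       junk_fractions = c(mono = 0.01, ac = 0.01, gt = 0.01,
                                          dimer = 0.01, trimer = 0.01,
                                          contaminant = 0.02),
                       straggler_fraction = 0.02,
                       adapter = TRUSEQ_SMALL_RNA_ADAPTER,
                       read_length = 36, seed = 1) {
  stopifnot(inherits(ref, "mir_reference"))
  mirnas <- ref$matures$name
  n <- length(mirnas)
  if (is.null(names(fold))) {
    fold <- setNames(rep_len(fold, n), mirnas)
  } else {
    full <- setNames(rep(1, n), mirnas)
    if (!all(names(fold) %in% mirnas)) {
      stop("fold names must be mature miRNA names from the reference",
           call. = FALSE)
    }
    full[names(fold)] <- fold
    fold <- full
  }
  if (any(!is.finite(fold)) || any(fold < 0)) {
    stop("fold changes must be finite and >= 0", call. = FALSE)
  }
  depth <- stopifnot_scalar_count(depth, "depth", positive = FALSE)
  n_reps <- stopifnot_scalar_count(n_reps, "n_reps")
  jf <- c(mono = 0, ac = 0, gt = 0, dimer = 0, trimer = 0, contaminant = 0)
  if (length(junk_fractions)) {
    if (is.null(names(junk_fractions)) ||
        !all(names(junk_fractions) %in% names(jf))) {
      stop("junk_fractions must be named with classes ",
           paste(names(jf), collapse = ", "), call. = FALSE)
    }
    jf[names(junk_fractions)] <- junk_fractions
  }
  junk_fractions <- jf
  stopifnot(dispersion >= 0, straggler_fraction >= 0, straggler_fraction < 1,
            all(junk_fractions >= 0), sum(junk_fractions) < 1)
  set.seed(derive_seed(seed, 1))
  if (is.null(baseline)) {
    # log-normal abundances, weighted toward 22-nt matures so aggregate
    # libraries peak at 22 nt as real milk small-RNA libraries do
    len_pref <- dnorm(ref$matures$y - ref$matures$x + 1L, 22, 1)
    baseline <- setNames(rlnorm(n, meanlog = 0, sdlog = 1.5) * len_pref,
                         mirnas)
  } else {
    baseline <- baseline[mirnas]
    if (any(is.na(baseline) | baseline < 0)) {
      stop("baseline must be a non-negative vector named by mature miRNAs",
           call. = FALSE)
    }
  }
  baseline <- baseline / sum(baseline)
  structure(list(
    mirnas = mirnas, baseline = baseline, fold = fold, depth = depth,
    n_reps = n_reps, dispersion = dispersion,
    junk_fractions = junk_fractions,
    straggler_fraction = straggler_fraction,
    adapter = normalize_dna(adapter),
    read_length = as.integer(read_length), seed = as.integer(seed)),
    class = "mir_truth")
}

# ---- junk-read generators: each class is constructed to fail exactly its
# corresponding cleaning filter (after adapter trimming) ----

junk_mono_reads <- function(n) {
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i) {
    len <- sample(20:28, 1)
    main <- sample(c("A", "C", "G", "T"), 1)
    others <- if (main %in% c("A", "C")) c("G", "T") else c("A", "C")
    n_other <- sample(seq_len(max(1L, floor(len * 0.2))), 1)
    chars <- c(rep(main, len - n_other), sample(others, n_other, replace = TRUE))
    paste(sample(chars), collapse = "")
  }, "")
}

junk_two_letter_reads <- function(n, letters2) {
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i) {
    len <- sample(20:28, 1)
    n1 <- round(len * runif(1, 0.4, 0.6))
    chars <- c(rep(letters2[1], n1), rep(letters2[2], len - n1))
    paste(sample(chars), collapse = "")
  }, "")
}

junk_dimer_reads <- function(n) {
  if (n == 0) return(character(0))
  units <- c("AG", "GA", "AT", "TA", "CG", "GC", "CT", "TC")
  vapply(seq_len(n), function(i) {
    len <- sample(20:28, 1)
    substr(strrep(sample(units, 1), 15), 1, len)
  }, "")
}

junk_trimer_reads <- function(n) {
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i) {
    len <- sample(20:28, 1)
    unit <- paste(sample(c("A", "C", "G", "T"), 3), collapse = "")
    substr(strrep(unit, 10), 1, len)
  }, "")
}

junk_contaminant_reads <- function(n, contaminants) {
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i) {
    repeat {
      src <- contaminants[[sample.int(length(contaminants), 1)]]
      len <- sample(20:30, 1)
      pos <- sample.int(nchar(src) - len + 1L, 1)
      frag <- substr(src, pos, pos + len - 1L)
      # must survive the composition stage so removal is attributed to the
      # contaminant filter
      if (length(composition_flags(frag)) == 0L) return(frag)
    }
  }, "")
}

#' Simulate two-condition replicate FASTQ libraries with known truth
#'
#' Writes one FASTQ per replicate per condition (`milk` = whole milk,
#' `exo` = exosome; the truth fold change applies to `exo`). Genuine
#' reads are drawn from the mature windows with 5' offset in `{-2..0}`
#' and 3' offset in `{0..+5}` (so they satisfy the `[x-2, y+5]` counting
#' rule); a configurable fraction of stragglers uses 5' offsets
#' `{-4,-3}` that fall outside the window. Every read gets the 3'
#' adapter appended and is truncated to the instrument read length.
#' Per-replicate miRNA counts are multinomial draws from
#' `baseline * fold`, with per-replicate gamma scaling of the means
#' (negative-binomial overdispersion). Junk reads per class are planted
#' to trigger the corresponding cleaning filter. A truth table records
#' realized expected counts and true fold changes.
#'
#' @param ref a `mir_reference`.
#' @param truth a `mir_truth` built from the same reference.
#' @param out_dir output directory (created if needed).
#' @return an object of class `mir_simulation`: list with `manifest`
#'   (condition, replicate, path, n_reads), `truth_table` (miRNA,
#'   condition, replicate, expected_count, expected_in_window,
#'   simulated_count, fold), and the file paths of the written
#'   `manifest.tsv` / `truth.tsv`.
#' @export
simulate_libraries <- function(ref, truth, out_dir) {
  stopifnot(inherits(ref, "mir_reference"), inherits(truth, "mir_truth"))
  if (!identical(truth$mirnas, ref$matures$name)) {
    stop("truth and reference disagree on miRNA identifiers", call. = FALSE)
  }
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  set.seed(derive_seed(truth$seed, 2))
  m <- ref$matures
  hp_seq <- setNames(ref$hairpins$sequence, ref$hairpins$name)[m$hairpin]
  n_mir <- nrow(m)
  conditions <- c("milk", "exo")
  reps <- seq_len(truth$n_reps)
  depth <- truth$depth

  n_junk <- round(depth * truth$junk_fractions)
  n_genuine_total <- depth - sum(n_junk)
  if (n_genuine_total < 0) stop("junk fractions exceed depth", call. = FALSE)

  combos <- expand.grid(d5 = -2:0, d3 = 0:5)
  strag_combos <- expand.grid(d5 = c(-4L, -3L), d3 = 0:2)

  manifest <- list()
  truth_rows <- list()
  for (cond in conditions) {
    prob_mean <- truth$baseline * (if (cond == "exo") truth$fold else 1)
    for (r in reps) {
      g <- if (truth$dispersion > 0) {
        rgamma(n_mir, shape = 1 / truth$dispersion, rate = 1 / truth$dispersion)
      } else rep(1, n_mir)
      w <- prob_mean * g
      p <- if (sum(w) > 0) w / sum(w) else rep(0, n_mir)
      counts <- if (n_genuine_total > 0 && sum(p) > 0) {
        as.vector(rmultinom(1, n_genuine_total, p))
      } else rep(0L, n_mir)
      n_strag <- rbinom(n_mir, counts, truth$straggler_fraction)

      seqs <- character(0); classes <- character(0)
      for (i in seq_len(n_mir)) {
        n_in <- counts[i] - n_strag[i]
        if (n_in > 0) {
          lens <- m$y[i] - m$x[i] + 1L + combos$d3 - combos$d5
          wts <- 0.5 * (combos$d5 == 0 & combos$d3 == 0) +
            0.5 * dnorm(lens, 22, 1) / sum(dnorm(lens, 22, 1))
          k <- sample.int(nrow(combos), n_in, replace = TRUE, prob = wts)
          seqs <- c(seqs, substring(hp_seq[i], m$x[i] + combos$d5[k],
                                    m$y[i] + combos$d3[k]))
          classes <- c(classes, rep(paste0("genuine:", m$name[i]), n_in))
        }
        if (n_strag[i] > 0) {
          k <- sample.int(nrow(strag_combos), n_strag[i], replace = TRUE)
          seqs <- c(seqs, substring(hp_seq[i], m$x[i] + strag_combos$d5[k],
                                    m$y[i] + strag_combos$d3[k]))
          classes <- c(classes, rep(paste0("straggler:", m$name[i]), n_strag[i]))
        }
      }
      junk <- list(
        mono = junk_mono_reads(n_junk[["mono"]]),
        ac = junk_two_letter_reads(n_junk[["ac"]], c("A", "C")),
        gt = junk_two_letter_reads(n_junk[["gt"]], c("G", "T")),
        dimer = junk_dimer_reads(n_junk[["dimer"]]),
        trimer = junk_trimer_reads(n_junk[["trimer"]]),
        contaminant = junk_contaminant_reads(n_junk[["contaminant"]],
                                             ref$contaminants))
      for (cls in names(junk)) {
        seqs <- c(seqs, junk[[cls]])
        classes <- c(classes, rep(paste0("junk:", cls), length(junk[[cls]])))
      }

      # sequencer view: read into the 3' adapter, fixed instrument length
      adapter_fill <- strrep(truth$adapter,
                             ceiling(truth$read_length / nchar(truth$adapter)) + 1L)
      raw <- if (length(seqs)) {
        substr(paste0(seqs, adapter_fill), 1, truth$read_length)
      } else character(0)
      ord <- sample.int(length(raw))
      raw <- raw[ord]; classes <- classes[ord]
      names(raw) <- sprintf("%s-%d:%06d:%s", cond, r, seq_along(raw), classes)

      path <- file.path(out_dir, sprintf("lib_%s_%d.fastq", cond, r))
      write_fastq_reads(raw, path)
      manifest[[length(manifest) + 1L]] <- data.frame(
        condition = cond, replicate = r, path = path, n_reads = length(raw),
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        miRNA = m$name, condition = cond, replicate = r,
        expected_count = n_genuine_total * p,
        expected_in_window = n_genuine_total * p * (1 - truth$straggler_fraction),
        simulated_count = counts, fold = unname(truth$fold),
        # fold change on the relative (CPM) scale: library re-normalization
        # compresses all apparent ratios by the closure factor
        effective_fold = unname(truth$fold) / sum(truth$baseline * truth$fold),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  truth_table <- do.call(rbind, truth_rows)
  write_tsv_table(manifest, file.path(out_dir, "manifest.tsv"))
  write_tsv_table(truth_table, file.path(out_dir, "truth.tsv"))
  structure(list(manifest = manifest, truth_table = truth_table,
                 out_dir = out_dir,
                 manifest_path = file.path(out_dir, "manifest.tsv"),
                 truth_path = file.path(out_dir, "truth.tsv")),
            class = "mir_simulation")
}

#' Write reference files to disk
#'
#' Emits hairpin FASTA, mature GFF3 (hairpin-relative), genomic BED6,
#' UTR FASTA (headers `gene|transcript`) and contaminant FASTA.
#'
#' @param ref a `mir_reference`.
#' @param out_dir output directory.
#' @return named character vector of written paths.
#' @export
write_reference <- function(ref, out_dir) {
  stopifnot(inherits(ref, "mir_reference"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    hairpins = file.path(out_dir, "hairpins.fasta"),
    matures = file.path(out_dir, "matures.gff3"),
    genomic = file.path(out_dir, "hairpins.bed"),
    utrs = file.path(out_dir, "utrs.fasta"),
    contaminants = file.path(out_dir, "contaminants.fasta"))
  write_fasta_seqs(setNames(ref$hairpins$sequence, ref$hairpins$name),
                   paths[["hairpins"]])
  write_mature_gff3(ref$matures, paths[["matures"]])
  write_bed6(ref$hairpins, paths[["genomic"]])
  write_fasta_seqs(setNames(ref$utrs$sequence,
                            paste(ref$utrs$gene, ref$utrs$transcript, sep = "|")),
                   paths[["utrs"]])
  write_fasta_seqs(ref$contaminants, paths[["contaminants"]])
  paths
}

#' Simulate a negative-binomial count matrix directly
#'
#' Count-level shortcut used for statistical calibration studies of the
#' differential stage (no FASTQ round trip): per-sample counts are
#' `NB(mean = depth * cpm/1e6 * fold, dispersion)`.
#'
#' @param baseline_cpm numeric vector of baseline CPM per miRNA.
#' @param fold linear fold change (exo vs milk), recycled.
#' @param depth library size per sample.
#' @param n_reps replicates per condition.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param seed RNG seed.
#' @return list with `counts` (matrix, rows miRNAs, columns samples),
#'   `lib_sizes`, and `groups` (condition factor: milk then exo).
#' @export
simulate_count_matrix <- function(baseline_cpm, fold = 1, depth = 1e6,
                                  n_reps = 3, dispersion = 0.05, seed = 1) {
  set.seed(as.integer(seed))
  n <- length(baseline_cpm)
  fold <- rep_len(fold, n)
  mu_milk <- baseline_cpm / 1e6 * depth
  mu_exo <- mu_milk * fold
  draw <- function(mu) {
    if (dispersion > 0) rnbinom(n, size = 1 / dispersion, mu = mu)
    else stats::rpois(n, mu)
  }
  cols <- c(lapply(seq_len(n_reps), function(r) draw(mu_milk)),
            lapply(seq_len(n_reps), function(r) draw(mu_exo)))
  counts <- do.call(cbind, cols)
  rownames(counts) <- if (!is.null(names(baseline_cpm))) names(baseline_cpm)
    else sprintf("mir%04d", seq_len(n))
  colnames(counts) <- c(sprintf("milk_%d", seq_len(n_reps)),
                        sprintf("exo_%d", seq_len(n_reps)))
  list(counts = counts,
       lib_sizes = setNames(rep(depth, 2 * n_reps), colnames(counts)),
       groups = factor(rep(c("milk", "exo"), each = n_reps),
                       levels = c("milk", "exo")))
}
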