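# miRNA target prediction in 3' UTRs: canonical seed-site scan
# (8mer / 7mer-m8 / 7mer-A1) followed by intermolecular duplex
# free-energy scoring of the site plus 15 nt of upstream UTR against the
# full mature sequence, thresholded at dG < -20 kcal/mol.

#' Hybridization free energy of a miRNA:target duplex
#'
#' Minimum free energy of the intermolecular duplex between a mature
#' miRNA and a target-site window, by dynamic programming over
#' nearest-neighbor stack energies (Watson-Crick and G.U wobble pairs)
#' with bulge/interior-loop penalties, a capped asymmetry term, a duplex
#' initiation term, and terminal AU/GU penalties at both helix ends. No
#' intramolecular structure is considered. More negative = more stable.
#'
#' @param mirna mature miRNA sequence, 5'->3' (<= 40 nt).
#' @param target target-site sequence, 5'->3' (<= 40 nt). The strands
#'   pair antiparallel; no reverse-complementing is needed by the
#'   caller.
#' @param params parameter list from [nn_parameters()].
#' @param max_bulge largest loop length considered on either strand.
#' @return free energy in kcal/mol, or `NA` if no canonical pair can
#'   form.
#' @export
duplex_energy <- function(mirna, target, params = nn_parameters(),
                          max_bulge = 10) {
  mirna <- normalize_dna(mirna)
  target <- normalize_dna(target)
  if (nchar(mirna) < 1 || nchar(target) < 1) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  if (nchar(mirna) > 40 || nchar(target) > 40) {
    stop("sequences longer than 40 nt are not supported", call. = FALSE)
  }
  if (grepl("N", mirna, fixed = TRUE) || grepl("N", target, fixed = TRUE)) {
    stop("sequences must not contain ambiguous bases", call. = FALSE)
  }
  mi <- strsplit(mirna, "")[[1]]
  tj <- strsplit(target, "")[[1]]
  n <- length(mi); m <- length(tj)

  # PT[i, j]: pair type code of miRNA base i against target base j
  PT <- outer(seq_len(n), seq_len(m),
              function(i, j) pair_type_code(mi[i], tj[j]))
  if (all(is.na(PT))) return(NA_real_)
  end_pen <- ifelse(is.na(PT), NA,
                    ifelse(PT >= 3L, params$terminal_au, 0))

  # generic loop cost by (a, b) = unpaired bases on miRNA / target side
  # between consecutive pairs; stack and 1-bulge cases are patched in
  # per transition because they need the previous pair type
  loop_grid <- matrix(Inf, max_bulge + 1L, max_bulge + 1L)
  for (a in 0:max_bulge) for (b in 0:max_bulge) {
    if (a == 0 && b == 0) next
    L <- a + b
    loop_grid[a + 1L, b + 1L] <- if (a == 0 || b == 0) {
      params$bulge[L]
    } else {
      params$internal[L] + min(params$ninio_max, params$ninio_m * abs(a - b))
    }
  }

  # E[i, j]: best energy of a duplex whose 3'-most miRNA pair is (i, j),
  # including initiation and the terminal penalty of its leftmost pair.
  # miRNA runs 5'->3' (i ascending), target antiparallel (j descending).
  E <- matrix(Inf, n, m)
  for (i in seq_len(n)) {
    for (j in seq(m, 1L)) {
      p2 <- PT[i, j]
      if (is.na(p2)) next
      best <- params$duplex_init + end_pen[i, j]
      i_lo <- max(1L, i - 1L - max_bulge)
      j_hi <- min(m, j + 1L + max_bulge)
      if (i > 1L && j < m) {
        for (i1 in i_lo:(i - 1L)) {
          prev <- E[i1, (j + 1L):j_hi]
          fin <- which(is.finite(prev))
          if (!length(fin)) next
          for (k in fin) {
            j1 <- j + k
            a <- i - i1 - 1L
            b <- j1 - j - 1L
            p1 <- PT[i1, j1]
            cost <- if (a == 0L && b == 0L) {
              NN_STACK[p1, p2]
            } else if (a + b == 1L) {
              loop_grid[a + 1L, b + 1L] + NN_STACK[p1, p2]
            } else {
              loop_grid[a + 1L, b + 1L]
            }
            cand <- prev[k] + cost
            if (cand < best) best <- cand
          }
        }
      }
      E[i, j] <- best
    }
  }
  total <- E + end_pen
  dg <- suppressWarnings(min(total, na.rm = TRUE))
  if (!is.finite(dg)) NA_real_ else dg
}

#' Scan a UTR for canonical seed-match sites
#'
#' Finds all occurrences of the reverse complement of the seed (mature
#' positions 2-8) in the UTR: `7mer-m8` (perfect match to positions
#' 2-8), `8mer` (the same followed by an A opposite mature position 1),
#' and `7mer-A1` (match to positions 2-7 followed by an A). Overlapping
#' sites are all reported; each genomic span is reported once with its
#' strongest class.
#'
#' @param utr UTR sequence (5'->3').
#' @param mature mature miRNA sequence (length >= 8).
#' @return data frame with columns `start`, `end` (1-based inclusive on
#'   the UTR) and `class`.
#' @export
find_seed_sites <- function(utr, mature) {
  utr <- normalize_dna(utr)
  mature <- normalize_dna(mature)
  if (nchar(mature) < 8) stop("mature sequence must be >= 8 nt", call. = FALSE)
  core7 <- revcomp_dna(substr(mature, 2, 8))   # complements m8..m2
  core6 <- revcomp_dna(substr(mature, 2, 7))   # complements m7..m2
  m8c <- revcomp_dna(substr(mature, 8, 8))
  nutr <- nchar(utr)
  locate_all <- function(pat) {
    hits <- stringi::stri_locate_all_fixed(utr, pat)[[1]]
    if (all(is.na(hits[, 1]))) integer(0) else hits[, 1]
  }
  out <- list()
  for (p in locate_all(core7)) {
    has_a <- p + 7L <= nutr && substr(utr, p + 7L, p + 7L) == "A"
    out[[length(out) + 1L]] <- data.frame(
      start = p, end = if (has_a) p + 7L else p + 6L,
      class = if (has_a) "8mer" else "7mer-m8", stringsAsFactors = FALSE)
  }
  for (p in locate_all(core6)) {
    if (p + 6L > nutr || substr(utr, p + 6L, p + 6L) != "A") next
    # skip spans already covered by a core7 match one base 5'
    if (p > 1L && substr(utr, p - 1L, p - 1L) == m8c) next
    out[[length(out) + 1L]] <- data.frame(
      start = p, end = p + 6L, class = "7mer-A1", stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Predict miRNA targets in 3' UTRs
#'
#' For every seed site of every miRNA in every UTR, extends the site by
#' `upstream` nt of 5' UTR context (where the miRNA 3' region can
#' pair), scores the duplex against the full mature sequence with
#' [duplex_energy()], and retains sites with dG < `dg_max`. A gene is a
#' predicted target of a miRNA iff at least one retained site exists in
#' any of its transcripts.
#'
#' @param matures named character vector of mature sequences, or data
#'   frame with columns `name`, `sequence`.
#' @param utrs data frame with columns `gene`, `transcript`,
#'   `sequence`, or named character vector with names `gene|transcript`.
#' @param dg_max free-energy threshold in kcal/mol (default -20; must
#'   be < 0).
#' @param upstream UTR context added 5' of the seed site (default 15).
#' @return data frame of class `mir_targets` with columns `miRNA`,
#'   `gene`, `transcript`, `start`, `end`, `class`, `dG`.
#' @export
predict_targets <- function(matures, utrs, dg_max = -20, upstream = 15) {
  stopifnot(dg_max < 0)
  if (is.data.frame(matures)) {
    matures <- setNames(matures$sequence, matures$name)
  }
  if (!is.data.frame(utrs)) {
    parts <- strsplit(names(utrs), "|", fixed = TRUE)
    utrs <- data.frame(
      gene = vapply(parts, `[`, "", 1),
      transcript = vapply(parts, function(p) if (length(p) > 1) p[2] else p[1], ""),
      sequence = as.character(utrs), stringsAsFactors = FALSE)
  }
  out <- list()
  for (mi in names(matures)) {
    mseq <- normalize_dna(matures[[mi]])
    for (u in seq_len(nrow(utrs))) {
      useq <- normalize_dna(utrs$sequence[u])
      sites <- find_seed_sites(useq, mseq)
      if (!nrow(sites)) next
      for (k in seq_len(nrow(sites))) {
        win <- substr(useq, max(1L, sites$start[k] - upstream), sites$end[k])
        dg <- duplex_energy(mseq, win)
        if (!is.na(dg) && dg < dg_max) {
          out[[length(out) + 1L]] <- data.frame(
            miRNA = mi, gene = utrs$gene[u], transcript = utrs$transcript[u],
            start = sites$start[k], end = sites$end[k],
            class = sites$class[k], dG = dg, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(miRNA = character(0), gene = character(0),
               transcript = character(0), start = integer(0),
               end = integer(0), class = character(0), dG = numeric(0),
               stringsAsFactors = FALSE)
  class(res) <- c("mir_targets", "data.frame")
  res
}

#' Summarize target predictions
#'
#' Collapses predicted sites to distinct (miRNA, gene) pairs and builds
#' the gene-by-miRNA-count ranking, the per-miRNA target-gene counts,
#' and the histogram of genes binned by how many distinct miRNAs target
#' them.
#'
#' @param predictions a `mir_targets` data frame.
#' @return list of class `mir_target_summary` with `per_gene` (gene,
#'   n_mirnas, mirnas pipe-separated, ranked), `per_mirna` (miRNA,
#'   n_genes), and `histogram` (n_mirnas, n_genes).
#' @export
summarize_targets <- function(predictions) {
  pairs <- unique(predictions[, c("miRNA", "gene")])
  by_gene <- split(pairs$miRNA, pairs$gene)
  per_gene <- data.frame(
    gene = names(by_gene),
    n_mirnas = lengths(by_gene),
    mirnas = vapply(by_gene, function(x) paste(sort(x), collapse = " | "), ""),
    row.names = NULL, stringsAsFactors = FALSE)
  per_gene <- per_gene[order(-per_gene$n_mirnas, per_gene$gene), , drop = FALSE]
  rownames(per_gene) <- NULL
  by_mirna <- split(pairs$gene, pairs$miRNA)
  per_mirna <- data.frame(miRNA = names(by_mirna),
                          n_genes = lengths(by_mirna),
                          row.names = NULL, stringsAsFactors = FALSE)
  hist_tab <- table(per_gene$n_mirnas)
  histogram <- data.frame(n_mirnas = as.integer(names(hist_tab)),
                          n_genes = as.integer(hist_tab),
                          stringsAsFactors = FALSE)
  structure(list(per_gene = per_gene, per_mirna = per_mirna,
                 histogram = histogram), class = "mir_target_summary")
}

#' @export
print.mir_target_summary <- function(x, ...) {
  cat(sprintf("mir_target_summary: %d target genes, %d miRNAs with targets\n",
              nrow(x$per_gene), nrow(x$per_mirna)))
  invisible(x)
}
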