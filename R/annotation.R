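# Genomic clustering of pre-miRNAs and seed-based family assignment of
# mature miRNAs.
#
# Clustering: pre-miRNAs on the same chromosome are chained by single
# linkage when the gap between consecutive intervals (next start minus
# current end minus 1, floored at 0 for overlaps) is at most max_gap
# (10 kb by convention); only chains with >= 2 members are reported.
# Strand is ignored for linking and reported per member.
#
# Families: matures sharing the identical 7-mer seed (positions 2-8,
# 1-based, of the mature body) form one family; names come from an
# optional seed -> family lookup (TargetScan-style), otherwise are
# synthesized as "seed:<7-mer>".

#' Parse a locus string of the form `name (chrom_start_end_strand)`
#'
#' @param text character vector like
#'   `"ssc-mir-34c-1 (9_44166873_44166952_-)"`.
#' @return data frame with columns `name`, `chrom`, `start`, `end`,
#'   `strand` (coordinates 1-based inclusive).
#' @export
parse_locus_string <- function(text) {
  pat <- "^\\s*(\\S+)\\s*\\(([^_()]+)_(\\d+)_(\\d+)_([+-])\\)\\s*$"
  ok <- grepl(pat, text)
  if (!all(ok)) {
    stop("malformed locus string: ", paste(text[!ok], collapse = "; "),
         call. = FALSE)
  }
  m <- regmatches(text, regexec(pat, text))
  out <- data.frame(
    name = vapply(m, `[`, "", 2),
    chrom = vapply(m, `[`, "", 3),
    start = as.integer(vapply(m, `[`, "", 4)),
    end = as.integer(vapply(m, `[`, "", 5)),
    strand = vapply(m, `[`, "", 6),
    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) {
    stop("degenerate interval (start > end) in locus string", call. = FALSE)
  }
  out
}

#' Detect genomic miRNA clusters (single-linkage, 10 kb rule)
#'
#' @param intervals data frame with columns `name`, `chrom`, `start`,
#'   `end` (1-based inclusive) and optionally `strand`.
#' @param max_gap maximum gap (bp) between consecutive intervals to link
#'   them into one cluster (default 10000).
#' @return data frame of class `mir_clusters` with one row per cluster:
#'   `cluster`, `chrom`, `n_members`, `start`, `end` (span) and
#'   `members` (comma-separated pre-miRNA names ordered by start);
#'   attribute `membership` holds the long form (cluster, member,
#'   chrom, start, end, strand).
#' @export
find_clusters <- function(intervals, max_gap = 10000) {
  stopifnot(all(c("name", "chrom", "start", "end") %in% names(intervals)))
  if (!"strand" %in% names(intervals)) intervals$strand <- "*"
  if (any(intervals$start > intervals$end)) {
    stop("degenerate interval (start > end)", call. = FALSE)
  }
  ord <- order(intervals$chrom, intervals$start, intervals$end,
               intervals$name, method = "radix")
  iv <- intervals[ord, , drop = FALSE]
  membership <- list()
  clusters <- list()
  cid <- 0L
  for (ch in unique(iv$chrom)) {
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0) next
    # chain id via gaps between consecutive sorted intervals; running
    # max of ends handles contained intervals
    run_end <- cummax(sub$end)
    gap <- c(0L, pmax(sub$start[-1] - run_end[-n] - 1L, 0L))
    chain <- cumsum(gap > max_gap)
    for (k in unique(chain)) {
      members <- sub[chain == k, , drop = FALSE]
      if (nrow(members) < 2) next
      cid <- cid + 1L
      clusters[[cid]] <- data.frame(
        cluster = sprintf("Cluster %d", cid), chrom = ch,
        n_members = nrow(members),
        start = min(members$start), end = max(members$end),
        members = paste(members$name, collapse = ","),
        stringsAsFactors = FALSE)
      membership[[cid]] <- cbind(cluster = sprintf("Cluster %d", cid),
                                 members[, c("name", "chrom", "start",
                                             "end", "strand")])
    }
  }
  out <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(cluster = character(0), chrom = character(0),
               n_members = integer(0), start = integer(0), end = integer(0),
               members = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "membership") <- if (length(membership))
    do.call(rbind, membership) else NULL
  class(out) <- c("mir_clusters", "data.frame")
  out
}

#' Seed of a mature miRNA (positions 2-8)
#'
#' @param sequence character vector of mature sequences (length >= 8
#'   each); U is mapped to T and case normalized.
#' @return character vector of 7-mer seeds.
#' @export
seed_of <- function(sequence) {
  sequence <- normalize_dna(sequence)
  if (any(nchar(sequence) < 8)) {
    stop("mature sequence shorter than 8 nt has no seed region",
         call. = FALSE)
  }
  substr(sequence, 2, 8)
}

#' Partition mature miRNAs into seed families
#'
#' @param matures data frame with columns `name`, `sequence` and
#'   optionally `hairpin`, or a named character vector of mature
#'   sequences.
#' @param family_table optional data frame with columns `seed`,
#'   `family` mapping 7-mer seeds to family names.
#' @return data frame of class `mir_families` with columns `mature`,
#'   `pre_mirna`, `seed`, `family`, sorted by family then mature;
#'   attribute `families` holds one row per family (family, seed,
#'   n_members, members).
#' @export
assign_families <- function(matures, family_table = NULL) {
  if (!is.data.frame(matures)) {
    matures <- data.frame(name = names(matures),
                          sequence = as.character(matures),
                          stringsAsFactors = FALSE)
  }
  if (!"hairpin" %in% names(matures)) matures$hairpin <- NA_character_
  if (!nrow(matures)) {
    long <- data.frame(mature = character(0), pre_mirna = character(0),
                       seed = character(0), family = character(0),
                       stringsAsFactors = FALSE)
    attr(long, "families") <- data.frame(
      family = character(0), seed = character(0), n_members = integer(0),
      members = character(0), stringsAsFactors = FALSE)
    class(long) <- c("mir_families", "data.frame")
    return(long)
  }
  seeds <- seed_of(matures$sequence)
  fam <- paste0("seed:", seeds)
  if (!is.null(family_table)) {
    hit <- match(seeds, normalize_dna(family_table$seed))
    fam[!is.na(hit)] <- family_table$family[hit[!is.na(hit)]]
  }
  long <- data.frame(mature = matures$name, pre_mirna = matures$hairpin,
                     seed = seeds, family = fam, stringsAsFactors = FALSE)
  long <- long[order(long$family, long$mature, method = "radix"), ,
               drop = FALSE]
  rownames(long) <- NULL
  split_members <- split(long$mature, long$family)
  fam_tab <- data.frame(
    family = names(split_members),
    seed = long$seed[match(names(split_members), long$family)],
    n_members = lengths(split_members),
    members = vapply(split_members, paste, "", collapse = ","),
    row.names = NULL,
    stringsAsFactors = FALSE)
  attr(long, "families") <- fam_tab
  class(long) <- c("mir_families", "data.frame")
  long
}
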