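# Mapping of clean reads onto pre-miRNA hairpins and mature-miRNA
# counting by the positional window rule: a read aligned at [s, e] on a
# hairpin is counted toward a mature annotated at [x, y] on that hairpin
# iff s >= x - 2 and e <= y + 5 (full containment of the read span in
# the tolerance window, which absorbs 5'/3' isomiR end variation).

#' Align reads exactly to hairpin sequences
#'
#' Each read must match a hairpin as an exact substring (0 mismatches).
#' A read matching several hairpins/positions is assigned
#' deterministically to the lexicographically lowest hairpin name, then
#' the leftmost position. Duplicate read sequences are collapsed with a
#' multiplicity. Unmatched reads are dropped and counted.
#'
#' @param reads named character vector of clean read sequences.
#' @param hairpins named character vector of hairpin sequences (unique
#'   names), or a `mir_reference`.
#' @return data frame of class `mir_alignments` with columns `sequence`,
#'   `hairpin`, `start`, `end` (1-based inclusive on the hairpin),
#'   `n_reads`; attributes `n_aligned`, `n_unaligned`,
#'   `n_unique_aligned`.
#' @export
align_reads <- function(reads, hairpins) {
  if (inherits(hairpins, "mir_reference")) {
    hairpins <- setNames(hairpins$hairpins$sequence, hairpins$hairpins$name)
  }
  if (anyDuplicated(names(hairpins))) {
    stop("hairpin names must be unique", call. = FALSE)
  }
  reads <- normalize_dna(reads)
  ord <- order(names(hairpins), method = "radix")
  hp <- normalize_dna(hairpins[ord])
  sep <- strrep("#", 40)
  text <- paste(hp, collapse = sep)
  offsets <- cumsum(c(1L, head(nchar(hp) + nchar(sep), -1L)))

  tab <- table(reads)
  uniq <- names(tab)
  pos <- if (length(uniq)) {
    stringi::stri_locate_first_fixed(text, uniq)[, 1]
  } else integer(0)
  found <- !is.na(pos)
  idx <- findInterval(pos[found], offsets)
  start <- pos[found] - offsets[idx] + 1L
  out <- data.frame(
    sequence = uniq[found],
    hairpin = names(hp)[idx],
    start = start,
    end = start + nchar(uniq[found]) - 1L,
    n_reads = as.integer(tab[found]),
    stringsAsFactors = FALSE)
  # guard against matches spanning a separator (cannot happen: reads are
  # ACGT-only and the separator is '#')
  attr(out, "n_aligned") <- sum(out$n_reads)
  attr(out, "n_unaligned") <- sum(as.integer(tab[!found]))
  attr(out, "n_unique_aligned") <- sum(found)
  class(out) <- c("mir_alignments", "data.frame")
  out
}

# resolve each alignment to at most one mature on its hairpin:
# containment in [x-2, y+5]; among eligible matures pick the smallest
# |start - x|, ties to the lower x
assign_alignments <- function(alignments, matures) {
  if (!nrow(alignments)) {
    return(cbind(alignments[0, , drop = FALSE], mature = character(0)))
  }
  mt <- matures[, c("name", "hairpin", "x", "y")]
  merged <- merge(cbind(alignments, .aln = seq_len(nrow(alignments))),
                  mt, by = "hairpin")
  merged <- merged[merged$start >= merged$x - 2L & merged$end <= merged$y + 5L, ,
                   drop = FALSE]
  if (!nrow(merged)) {
    out <- alignments[0, , drop = FALSE]
    out$mature <- character(0)
    return(out)
  }
  merged$dist <- abs(merged$start - merged$x)
  merged <- merged[order(merged$.aln, merged$dist, merged$x), , drop = FALSE]
  best <- merged[!duplicated(merged$.aln), , drop = FALSE]
  out <- alignments[best$.aln, , drop = FALSE]
  out$mature <- best$name
  rownames(out) <- NULL
  out
}

#' Count mature miRNA expression from hairpin alignments
#'
#' Applies the positional window rule to one or more samples and
#' assembles a count matrix. Library size per sample is the number of
#' aligned reads (whether or not they fall in a mature window); the
#' unique count is the number of distinct aligned read sequences.
#'
#' @param alignments a `mir_alignments` data frame (single sample) or a
#'   named list of them (one per sample).
#' @param matures data frame with columns `name`, `hairpin`, `x`, `y`
#'   (1-based inclusive on the hairpin), or a `mir_reference`.
#' @param hairpins optional character vector of known hairpin names (or
#'   named sequences); when given, matures referencing an unknown
#'   hairpin raise an error.
#' @return object of class `mir_counts`: list with `counts` (integer
#'   matrix, rows = mature names, columns = samples), `lib_sizes`,
#'   `unique_mapped`, and `mature2hairpin` (named character vector).
#' @export
count_mature <- function(alignments, matures, hairpins = NULL) {
  if (is.null(hairpins) && inherits(matures, "mir_reference")) {
    hairpins <- matures$hairpins$name
  }
  if (inherits(matures, "mir_reference")) matures <- matures$matures
  if (!is.null(hairpins)) {
    known <- if (!is.null(names(hairpins))) names(hairpins) else hairpins
    bad <- setdiff(matures$hairpin, known)
    if (length(bad)) {
      stop("mature annotation references unknown hairpin: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (inherits(alignments, "data.frame")) {
    alignments <- list(sample_1 = alignments)
  }
  if (is.null(names(alignments))) {
    names(alignments) <- sprintf("sample_%d", seq_along(alignments))
  }
  mat_names <- matures$name
  counts <- matrix(0L, nrow = length(mat_names), ncol = length(alignments),
                   dimnames = list(mat_names, names(alignments)))
  lib_sizes <- setNames(integer(length(alignments)), names(alignments))
  uniq <- lib_sizes
  for (s in names(alignments)) {
    aln <- alignments[[s]]
    assigned <- assign_alignments(aln, matures)
    if (nrow(assigned)) {
      agg <- tapply(assigned$n_reads, assigned$mature, sum)
      counts[names(agg), s] <- as.integer(agg)
    }
    lib_sizes[s] <- sum(aln$n_reads)
    uniq[s] <- nrow(aln)
  }
  structure(list(counts = counts, lib_sizes = lib_sizes,
                 unique_mapped = uniq,
                 mature2hairpin = setNames(matures$hairpin, matures$name)),
            class = "mir_counts")
}

#' @export
print.mir_counts <- function(x, ...) {
  cat(sprintf("mir_counts: %d matures x %d samples; library sizes %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(x$lib_sizes, collapse = ", ")))
  invisible(x)
}

#' Per-sample mapping summary
#'
#' Tabulates, for each sample, the number of pre-miRNAs and mature
#' miRNAs with at least one counted read, the number of distinct mapped
#' sequences, and the total mapped reads (census-table shape).
#'
#' @param counts a `mir_counts` object.
#' @return data frame with columns `sample`, `n_premirna`, `n_mature`,
#'   `unique_mapped`, `total_mapped`.
#' @export
mapping_stats <- function(counts) {
  stopifnot(inherits(counts, "mir_counts"))
  samples <- colnames(counts$counts)
  data.frame(
    sample = samples,
    n_premirna = vapply(samples, function(s) {
      length(unique(counts$mature2hairpin[
        rownames(counts$counts)[counts$counts[, s] > 0]]))
    }, 0L),
    n_mature = vapply(samples, function(s) sum(counts$counts[, s] > 0), 0L),
    unique_mapped = as.integer(counts$unique_mapped[samples]),
    total_mapped = as.integer(counts$lib_sizes[samples]),
    row.names = NULL,
    stringsAsFactors = FALSE)
}
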