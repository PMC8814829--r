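# Read cleaning: 3' adapter removal, length bounds, low-complexity
# composition filters, and contaminant ncRNA subtraction, with exact
# per-filter accounting.
#
# Cascade order (a read is removed at the first failing stage and
# attributed to that reason): adapter trim -> empty check -> length
# bounds -> composition flags (priority: mono_composition, ac_only,
# gt_only, dimer_repeat, trimer_repeat, ambiguous_base) -> contaminant.

QC_REASONS <- c("adapter_only", "too_short", "too_long", "mono_composition",
                "ac_only", "gt_only", "dimer_repeat", "trimer_repeat",
                "contaminant", "ambiguous_base")

#' Trim the 3' adapter from reads
#'
#' Removes the read suffix beginning at the leftmost position where an
#' adapter prefix of at least `min_overlap` bases matches exactly (0
#' mismatches): either the full adapter occurs at that position, or the
#' remainder of the read (>= `min_overlap` bases) equals an adapter
#' prefix. A read trimmed to length zero is adapter-only.
#'
#' @param reads character vector of read sequences (vectorized).
#' @param adapter adapter sequence, length >= `min_overlap`.
#' @param min_overlap minimum adapter prefix length to trigger trimming
#'   (default 5).
#' @return character vector of trimmed reads ("" marks adapter-only).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5) {
  adapter <- normalize_dna(adapter)
  if (nchar(adapter) < min_overlap) {
    stop("adapter must be at least min_overlap (", min_overlap,
         ") bases long", call. = FALSE)
  }
  reads <- normalize_dna(reads)
  if (!length(reads)) return(character(0))
  key <- substr(adapter, 1, min_overlap)
  nr <- nchar(reads)
  alen <- nchar(adapter)
  # candidate = leftmost occurrence of the adapter's min_overlap prefix;
  # the common case (suffix matches an adapter prefix there) is fully
  # vectorized, spurious prefix hits fall back to a per-read scan
  hit <- stringi::stri_locate_first_fixed(reads, key)[, 1]
  out <- reads
  idx <- which(!is.na(hit))
  if (length(idx)) {
    p <- hit[idx]
    k <- pmin(nr[idx] - p + 1L, alen)
    ok <- k >= min_overlap &
      substr(reads[idx], p, p + k - 1L) == substring(adapter, 1L, k)
    out[idx[ok]] <- substr(reads[idx[ok]], 1L, p[ok] - 1L)
    for (i in idx[!ok]) {
      pp <- hit[i]
      repeat {
        nxt <- stringi::stri_locate_first_fixed(
          substr(reads[i], pp + 1L, nr[i]), key)[, 1]
        if (is.na(nxt)) break
        pp <- pp + nxt
        kk <- min(nr[i] - pp + 1L, alen)
        if (kk >= min_overlap &&
            substr(reads[i], pp, pp + kk - 1L) == substr(adapter, 1, kk)) {
          out[i] <- substr(reads[i], 1, pp - 1L)
          break
        }
      }
    }
  }
  out
}

#' Composition flags for a read sequence
#'
#' Returns which low-complexity composition rules a sequence violates:
#' `mono_composition` if any single base makes up >= 80% of the length
#' (inclusive threshold); `ac_only` / `gt_only` if the alphabet is a
#' subset of {A,C} / {G,T}; `dimer_repeat` / `trimer_repeat` if the
#' sequence is a tandem repeat of a 2-mer / 3-mer (one trailing partial
#' unit allowed); `ambiguous_base` if any N is present. Flags are
#' independent and may co-occur.
#'
#' @param sequence a single non-empty nucleotide sequence.
#' @return character vector (possibly empty) of flag names.
#' @export
composition_flags <- function(sequence) {
  sequence <- normalize_dna(sequence)
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  fl <- flags_matrix(sequence)[1, ]
  fl <- fl[setdiff(names(fl), "contaminant")]
  names(fl)[fl]
}

# vectorized core: logical matrix with one row per read and columns
# mono, ac, gt, dimer, trimer, contaminant(placeholder FALSE), ambiguous
flags_matrix <- function(reads) {
  n <- length(reads)
  len <- nchar(reads)
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(reads),
                                        baseOnly = TRUE)
  acgt <- freq[, c("A", "C", "G", "T"), drop = FALSE]
  other <- freq[, "other"]
  mono <- apply(acgt, 1, max) / len >= 0.8
  ac <- (acgt[, "G"] + acgt[, "T"] + other) == 0
  gt <- (acgt[, "A"] + acgt[, "C"] + other) == 0
  tandem <- function(k) {
    unit <- substr(reads, 1, k)
    ok <- len >= k & reads == substr(strrep(unit, ceiling(len / k)), 1, len)
    ok
  }
  dimer <- tandem(2L)
  trimer <- tandem(3L)
  ambiguous <- other > 0
  m <- cbind(mono_composition = mono, ac_only = ac, gt_only = gt,
             dimer_repeat = dimer, trimer_repeat = trimer,
             contaminant = rep(FALSE, n), ambiguous_base = ambiguous)
  m
}

#' Length filter verdict
#'
#' Reads shorter than `min_len` (default 18 nt) are discarded as
#' `too_short`; reads longer than `max_len` (default 34 nt, the upper
#' bound of observed miRNA lengths) as `too_long`.
#'
#' @param sequences character vector of reads.
#' @param min_len,max_len inclusive length bounds.
#' @return character vector in `{"keep", "too_short", "too_long"}`.
#' @export
length_filter <- function(sequences, min_len = 18, max_len = 34) {
  n <- nchar(sequences)
  ifelse(n < min_len, "too_short", ifelse(n > max_len, "too_long", "keep"))
}

#' Contaminant filter
#'
#' A read is a contaminant iff it occurs as an exact substring of any
#' contaminant sequence on either strand.
#'
#' @param sequences character vector of reads.
#' @param contaminants named character vector of contaminant sequences
#'   (rRNA/tRNA/snRNA/repeat fragments); may be empty.
#' @return logical vector, TRUE = contaminant.
#' @export
contaminant_filter <- function(sequences, contaminants) {
  if (length(contaminants) == 0L || length(sequences) == 0L) {
    return(rep(FALSE, length(sequences)))
  }
  contaminants <- normalize_dna(contaminants)
  text <- paste(c(contaminants, revcomp_dna(contaminants)),
                collapse = strrep("#", 40))
  uniq <- unique(sequences)
  hit <- stringi::stri_detect_fixed(text, uniq)
  hit[match(sequences, uniq)]
}

#' Clean a small-RNA library
#'
#' Applies the full cleaning cascade to a FASTQ file (or an in-memory
#' read vector): adapter trimming, length bounds, composition filters,
#' contaminant subtraction. Each read is removed at the first failing
#' stage; the report's accounting is exact
#' (`input == surviving + sum(removed)`).
#'
#' @param fastq path to a FASTQ file, or a (named) character vector of
#'   read sequences.
#' @param adapter 3' adapter sequence.
#' @param contaminants named character vector of contaminant sequences
#'   (possibly empty).
#' @param min_len,max_len length bounds (defaults 18 and 34 nt).
#' @param min_overlap minimum adapter overlap for trimming.
#' @return object of class `qc_result`: list with `reads` (named
#'   character vector of surviving trimmed reads), `report` (list:
#'   `input_reads`, `surviving_reads`, `removed` named count vector),
#'   and `reasons` (per-input-read character vector, "pass" or the
#'   removal reason, named by read id).
#' @export
clean_library <- function(fastq, adapter, contaminants = character(0),
                          min_len = 18, max_len = 34, min_overlap = 5) {
  if (length(fastq) == 1L && !grepl("^[ACGTUNacgtun]*$", fastq)) {
    validate_fastq_file(fastq)
    reads <- read_fastq_reads(fastq)
  } else {
    reads <- normalize_dna(fastq)
    if (is.null(names(reads)) && length(reads)) {
      names(reads) <- sprintf("read_%d", seq_along(reads))
    }
  }
  n <- length(reads)
  reasons <- rep(NA_character_, n)
  trimmed <- if (n) trim_adapter(reads, adapter, min_overlap) else character(0)

  if (n) {
    reasons[nchar(trimmed) == 0L] <- "adapter_only"
    lf <- length_filter(trimmed, min_len, max_len)
    reasons[is.na(reasons) & lf == "too_short"] <- "too_short"
    reasons[is.na(reasons) & lf == "too_long"] <- "too_long"
    open <- which(is.na(reasons))
    if (length(open)) {
      fl <- flags_matrix(trimmed[open])
      prio <- c("mono_composition", "ac_only", "gt_only", "dimer_repeat",
                "trimer_repeat", "ambiguous_base")
      for (p in prio) {
        idx <- open[is.na(reasons[open]) & fl[, p]]
        reasons[idx] <- p
      }
    }
    open <- which(is.na(reasons))
    if (length(open)) {
      contam <- contaminant_filter(trimmed[open], contaminants)
      reasons[open[contam]] <- "contaminant"
    }
  }
  surviving <- is.na(reasons)
  reasons[surviving] <- "pass"
  names(reasons) <- names(reads)
  removed <- vapply(QC_REASONS, function(r) sum(reasons == r), 0L)
  out <- trimmed[surviving]
  names(out) <- names(reads)[surviving]
  structure(list(
    reads = out,
    report = list(input_reads = n, surviving_reads = sum(surviving),
                  removed = removed),
    reasons = reasons), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("qc_result: %d reads in, %d surviving\n",
              x$report$input_reads, x$report$surviving_reads))
  kept <- x$report$removed[x$report$removed > 0]
  if (length(kept)) {
    cat("removed:", paste(sprintf("%s=%d", names(kept), kept), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' QC report as a one-row data frame
#'
#' @param qc a `qc_result`.
#' @param sample optional sample label column.
#' @return data frame with input, surviving and per-reason counts.
#' @export
qc_report_table <- function(qc, sample = NA_character_) {
  stopifnot(inherits(qc, "qc_result"))
  cbind(data.frame(sample = sample,
                   input_reads = qc$report$input_reads,
                   surviving_reads = qc$report$surviving_reads),
        as.data.frame(as.list(qc$report$removed)))
}
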