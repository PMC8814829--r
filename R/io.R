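# Readers and writers for the on-disk formats used by the workflow.
# Conventions: FASTA/FASTQ through Biostrings; mature annotations as GFF3
# with hairpin-relative 1-based inclusive coordinates (attributes ID and
# hairpin); genomic placements as BED6, 0-based half-open on disk and
# converted to 1-based inclusive on read. All sequences are normalized to
# the DNA alphabet (U -> T) on ingest.

#' Read a FASTQ file of small-RNA reads
#'
#' @param path FASTQ file (optionally gzip-compressed).
#' @return named character vector of read sequences (names = read ids).
#' @export
read_fastq_reads <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- normalize_dna(as.character(x))
  names(out) <- names(x)
  out
}

#' Write reads as a 4-line-record FASTQ file
#'
#' Quality strings are constant Phred 40 ('I'); base qualities play no role
#' in any downstream filter.
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq_reads <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(seqs))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(seqs)) {
    rec <- paste0("@", ids, "\n", seqs, "\n+\n",
                  vapply(nchar(seqs), function(n) strrep("I", n), ""))
    writeLines(rec, con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of DNA sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- normalize_dna(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(normalize_dna(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Write mature-miRNA annotations as GFF3
#'
#' Coordinates are hairpin-relative, 1-based inclusive; attributes carry
#' `ID` (mature name) and `hairpin`.
#'
#' @param matures data frame with columns `name`, `hairpin`, `x`, `y`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mature_gff3 <- function(matures, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = matures$hairpin,
    ranges = IRanges::IRanges(start = matures$x, end = matures$y),
    strand = "+")
  S4Vectors::mcols(gr)$type <- "miRNA"
  S4Vectors::mcols(gr)$ID <- matures$name
  S4Vectors::mcols(gr)$hairpin <- matures$hairpin
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read mature-miRNA annotations from GFF3
#'
#' @param path GFF3 path written by [write_mature_gff3()].
#' @return data frame with columns `name`, `hairpin`, `x`, `y`.
#' @export
read_mature_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(
    name = as.character(S4Vectors::mcols(gr)$ID),
    hairpin = as.character(GenomicRanges::seqnames(gr)),
    x = GenomicRanges::start(gr),
    y = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
}

#' Write genomic placements as BED6
#'
#' In-memory intervals are 1-based inclusive; BED on disk is 0-based
#' half-open. The conversion is confined to this writer/reader pair.
#'
#' @param intervals data frame with columns `name`, `chrom`, `start`,
#'   `end`, `strand` (1-based inclusive).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end),
    strand = intervals$strand)
  names(gr) <- intervals$name
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read genomic placements from BED6
#'
#' @param path BED path.
#' @return data frame with columns `name`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive).
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    name = if (!is.null(S4Vectors::mcols(gr)$name))
      as.character(S4Vectors::mcols(gr)$name) else names(gr),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}

#' Write a data frame as tab-separated text
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
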