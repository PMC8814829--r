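# Shared small helpers: sequence normalization and argument checks.

#' Normalize nucleotide text to uppercase DNA
#'
#' Uppercases and maps U to T so that RNA and DNA input are interchangeable
#' at every ingest point.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over the DNA alphabet.
#' @export
normalize_dna <- function(x) {
  out <- chartr("U", "T", toupper(as.character(x)))
  names(out) <- names(x)
  out
}

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(normalize_dna(x))))
}

stopifnot_scalar_count <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) ||
      (positive && x < 1) || (!positive && x < 0)) {
    stop(sprintf("`%s` must be a single %s integer", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  }
  as.integer(x)
}

# deterministic seed derivation for sub-streams, kept below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
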