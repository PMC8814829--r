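#!/usr/bin/env Rscript
# Stage 3: hairpin mapping and mature-miRNA counting.
#
# Aligns cleaned reads exactly to the pre-miRNA hairpins and counts a
# read toward a mature annotated at [x, y] when its span lies inside
# [x-2, y+5]; emits the count matrix and the per-sample mapping census.

suppressMessages(library(exomir))

study <- "scratch/study"
samples <- read.delim(file.path(study, "samples.tsv"))
hairpins <- read_fasta_seqs(file.path(study, "hairpins.fasta"))
matures <- read_mature_gff3(file.path(study, "matures.gff3"))

alns <- lapply(samples$sample, function(s) {
  reads <- read_fastq_reads(file.path(study, paste0("clean_", s, ".fastq")))
  align_reads(reads, hairpins)
})
names(alns) <- samples$sample

counts <- count_mature(alns, matures, hairpins)
write_tsv_table(data.frame(miRNA = rownames(counts$counts), counts$counts,
                           check.names = FALSE), "results/counts.tsv")
stats <- mapping_stats(counts)
write_tsv_table(stats, "results/mapping_stats.tsv")

print(counts)
cat("per-sample mapping census:\n")
print(stats)
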