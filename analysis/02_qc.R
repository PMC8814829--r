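#!/usr/bin/env Rscript
# Stage 2: read cleaning.
#
# Trims the 3' adapter, applies the 18-34 nt length bounds, the
# composition filters (80% single base; A/C-only; G/T-only; tandem
# dimer/trimer repeats; ambiguous bases) and subtracts contaminant
# ncRNA, writing one accounting row per library.

suppressMessages(library(exomir))

study <- "scratch/study"
samples <- read.delim(file.path(study, "samples.tsv"))
contaminants <- read_fasta_seqs(file.path(study, "contaminants.fasta"))

reports <- list()
for (i in seq_len(nrow(samples))) {
  qc <- clean_library(samples$path[i], TRUSEQ_SMALL_RNA_ADAPTER, contaminants)
  write_fastq_reads(qc$reads,
                    file.path(study, paste0("clean_", samples$sample[i], ".fastq")))
  reports[[i]] <- qc_report_table(qc, samples$sample[i])
}
report <- do.call(rbind, reports)
write_tsv_table(report, "results/qc_report.tsv")

cat(sprintf("cleaned %d libraries: %.1f%% of reads survive on average\n",
            nrow(report),
            100 * mean(report$surviving_reads / report$input_reads)))
removed <- colSums(report[, -(1:3)])
cat("reads removed per reason:\n")
print(removed[removed > 0])
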