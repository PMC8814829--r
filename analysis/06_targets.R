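#!/usr/bin/env Rscript
# Stage 6: target prediction for the upregulated miRNAs.
#
# Scans the 3' UTRs for canonical seed sites (8mer, 7mer-m8, 7mer-A1),
# scores each site plus 15 nt of upstream context against the full
# mature with the nearest-neighbor duplex model, keeps sites with
# dG < -20 kcal/mol, and ranks genes by how many distinct miRNAs
# target them.

suppressMessages(library(exomir))

study <- "scratch/study"
de <- read.delim("results/differential.tsv")
up <- de$miRNA[de$mark2 == "UP"]
hairpins <- read_fasta_seqs(file.path(study, "hairpins.fasta"))
matures <- read_mature_gff3(file.path(study, "matures.gff3"))
matures$sequence <- substr(hairpins[matures$hairpin], matures$x, matures$y)
utrs <- read_fasta_seqs(file.path(study, "utrs.fasta"))

pred <- predict_targets(matures[matures$name %in% up, ], utrs, dg_max = -20)
write_tsv_table(as.data.frame(pred), "results/target_sites.tsv")

summ <- summarize_targets(pred)
write_tsv_table(summ$per_gene, "results/target_summary.tsv")
write_tsv_table(summ$histogram, "results/target_histogram.tsv")

cat(sprintf("%d retained sites (dG < -20 kcal/mol) over %d gene(s)\n",
            nrow(pred), nrow(summ$per_gene)))
cat("top genes by distinct targeting miRNAs:\n")
print(head(summ$per_gene, 5))
cat("genes binned by miRNA count:\n")
print(summ$histogram)
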