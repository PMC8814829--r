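#!/usr/bin/env Rscript
# Stage 5: genomic clusters and seed families of the upregulated set.
#
# Pre-miRNAs of miRNAs marked UP at the 2x tier are chained into
# genomic clusters (10 kb single linkage) and their matures partitioned
# into seed families (identical positions 2-8). Also reproduces the
# published two-cluster example from its printed locus strings.

suppressMessages(library(exomir))

study <- "scratch/study"
de <- read.delim("results/differential.tsv")
up <- de$miRNA[de$mark2 == "UP"]
hairpins <- read_fasta_seqs(file.path(study, "hairpins.fasta"))
matures <- read_mature_gff3(file.path(study, "matures.gff3"))
matures$sequence <- substr(hairpins[matures$hairpin], matures$x, matures$y)
up_matures <- matures[matures$name %in% up, ]

loci <- read_bed6(file.path(study, "hairpins.bed"))
clusters <- find_clusters(loci[loci$name %in% up_matures$hairpin, ],
                          max_gap = 10000)
write_tsv_table(as.data.frame(clusters), "results/clusters.tsv")

families <- assign_families(up_matures)
write_tsv_table(as.data.frame(families), "results/families.tsv")

cat(sprintf("%d upregulated miRNAs -> %d genomic cluster(s), %d seed families\n",
            length(up), nrow(clusters),
            nrow(attr(families, "families"))))
if (nrow(clusters)) print(as.data.frame(clusters))

cat("\npublished cluster example (printed locus strings):\n")
published <- parse_locus_string(c(
  "ssc-mir-34c-1 (9_44166873_44166952_-)",
  "ssc-mir-34c-2 (9_44166877_44166950_-)",
  "ssc-mir-221 (X_45274873_45274942_-)",
  "ssc-mir-222 (X_45275613_45275692_-)"))
print(as.data.frame(find_clusters(published, max_gap = 10000)))
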