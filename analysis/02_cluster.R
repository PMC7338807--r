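#!/usr/bin/env Rscript
# Stage 2 — OTU clustering.
#
# Length-filters the reads to the ca. 1.0 kb amplicon window, dereplicates
# them, clusters at 90% nucleotide identity by abundance-sorted greedy
# centroid scanning, and keeps OTUs with at least 50 reads.

suppressPackageStartupMessages(library(nodprofiler))

data_dir <- "results/data"
out <- "results/otu"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

samples <- nodprofiler:::read_tsv_hash(file.path(data_dir, "samples.tsv"))
reads <- do.call(rbind, lapply(samples$sample_id, function(s)
  read_sequences(file.path(data_dir, "reads", paste0(s, ".fastq")),
                 sample_id = s)))

params <- clustering_params()   # 0.90 identity, >= 50 reads, 800-1200 nt
lf <- length_filter(reads, params)
derep <- dereplicate(lf$retained)
otus_all <- greedy_cluster(derep, params)
otus <- filter_otus(otus_all, params)

write_tsv_hash <- nodprofiler:::write_tsv_hash
write_tsv_hash(lf$rejected, file.path(out, "rejected_reads.tsv"))
write_otu_representatives(otus, file.path(out, "otu_representatives.fasta"))
write_otu_table(otus$counts, file.path(out, "otu_table.tsv"))
write_tsv_hash(otus$membership, file.path(out, "otu_membership.tsv"))

cat(sprintf("reads in: %d; retained by length filter: %d (rejected %d)\n",
            nrow(reads), nrow(lf$retained), nrow(lf$rejected)))
cat(sprintf("unique sequences: %d; centroids before size filter: %d\n",
            nrow(derep$seqs), nrow(otus_all$otus)))
cat(sprintf("OTUs with >= %d reads: %d (sizes %s)\n", params$min_size,
            nrow(otus$otus), paste(otus$otus$size, collapse = ", ")))
cat("wrote", out, "\n")
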