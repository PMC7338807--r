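#!/usr/bin/env Rscript
# Stage 5 — community statistics.
#
# Builds the samples x OTUs table, computes per-sample relative abundances,
# qPCR-normalised nod fractions of total bacteria, PCA ordination of the
# community, the shared / habitat-specific OTU report, and checks the
# recovered community against the simulation's truth manifest.

suppressPackageStartupMessages(library(nodprofiler))

counts <- read_otu_table("results/otu/otu_table.tsv")
samples <- nodprofiler:::read_tsv_hash("results/data/samples.tsv")
qpcr <- read_qpcr_table("results/data/qpcr.tsv")
asg <- nodprofiler:::read_tsv_hash("results/tree/assignments.tsv")
truth <- nodprofiler:::read_tsv_hash("results/data/truth_manifest.tsv")
out <- "results/community"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ct <- structure(list(counts = counts, rel = relative_abundance(counts),
                     otu_ids = rownames(counts),
                     sample_ids = colnames(counts)),
                class = "community_table")
habitats <- stats::setNames(samples$habitat, samples$sample_id)
pca <- pca_community(ct)
hab <- habitat_report(ct, habitats, asg)
summ <- community_summary(ct, qpcr, asg)

nodprofiler:::write_tsv_hash(
  data.frame(sample_id = rownames(pca$scores), pca$scores,
             check.names = FALSE),
  file.path(out, "pca_coordinates.tsv"))
nodprofiler:::write_tsv_hash(hab$otu_status,
                             file.path(out, "habitat_report.tsv"))
jsonlite::write_json(summ, file.path(out, "summary.json"),
                     auto_unbox = TRUE, digits = NA)

sil <- habitat_silhouette(pca, habitats)
nodpct <- unlist(summ$nod_percent_of_16S)
cat(sprintf("OTUs x samples: %d x %d\n", nrow(counts), ncol(counts)))
cat(sprintf("PC1/PC2 explain %.0f%% / %.0f%% of community variance\n",
            100 * pca$var_explained[1], 100 * pca$var_explained[2]))
cat(sprintf("habitat silhouette on (PC1, PC2): %.2f (positive = soils and sediments separate)\n",
            sil))
cat(sprintf("nod genes as %% of 16S: soils %.2f-%.2f, sediments %.2f-%.2f\n",
            min(nodpct[samples$habitat == "soil"]),
            max(nodpct[samples$habitat == "soil"]),
            min(nodpct[samples$habitat == "sediment"]),
            max(nodpct[samples$habitat == "sediment"])))
cat("habitat-specific vs shared OTUs:\n")
print(table(hab$otu_status$status))

# sanity against the planted truth: reads per recovered OTU vs manifest
reads_per_otu <- sort(rowSums(counts), decreasing = TRUE)
planted <- sort(table(truth$otu_id), decreasing = TRUE)
cat(sprintf("recovered OTU sizes: %s\n",
            paste(reads_per_otu, collapse = ", ")))
cat(sprintf("planted sizes (>=50): %s\n",
            paste(planted[planted >= 50], collapse = ", ")))
cat("wrote", out, "\n")
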