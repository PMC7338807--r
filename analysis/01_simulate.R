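#!/usr/bin/env Rscript
# Stage 1 — simulate the study system.
#
# Generates the synthetic long-read nod amplicon dataset the rest of the
# workflow analyses: a labelled reference panel (Aquifer / NC10 / Reactor1
# nod lineages, unknown-qNor relatives, a qNor outgroup), eight samples
# (four fertilisation-regime soils, four lake sediments) with planted
# habitat structure, CCS-like per-base errors, and a matching qPCR table.
# Abundances are scaled to desk size so the noisy demo run stays fast; the
# planted community design is otherwise the package default.

suppressPackageStartupMessages(library(nodprofiler))

seed <- 2026L
out <- "results/data"

panel <- make_reference_panel(seed)
spec0 <- default_community_spec(panel, seed = seed + 1L)
spec <- community_spec(spec0$samples, spec0$otus,
                       pmax(round(spec0$abundance * 0.25),
                            (spec0$abundance > 0) * 1),
                       error_model = spec0$error_model, seed = spec0$seed)

ds <- simulate_nod_dataset(seed = seed, spec = spec, out_dir = out)

cat(sprintf("panel: %d reference sequences in %d lineages\n",
            nrow(panel$entries), length(unique(panel$entries$cluster_label))))
cat(sprintf("reads: %d across %d samples (error model: sub %.3f, ins %.3f, del %.3f)\n",
            nrow(ds$sim$reads), nrow(spec$samples),
            spec$error_model[["sub_rate"]], spec$error_model[["ins_rate"]],
            spec$error_model[["del_rate"]]))
cat(sprintf("planted OTUs: %d (%d expected to survive the 50-read filter)\n",
            nrow(spec$otus), sum(colSums(spec$abundance) >= 50)))
cat("wrote", out, "\n")
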