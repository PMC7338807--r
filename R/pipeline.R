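#' Run the whole profiling pipeline on a set of reads
#'
#' Stages, in order: length filter, dereplication, greedy centroid
#' clustering, OTU size filter, frame recovery and translation,
#' signature-residue calling, progressive alignment + neighbor-joining
#' tree + bootstrap, clade-based cluster assignment with the joint
#' final call, and community statistics (relative abundances, PCA,
#' habitat report, qPCR normalisation when a table is supplied).
#' Deterministic for a fixed seed; when `out_dir` is given every stage's
#' outputs plus a machine-readable run manifest are written there.
#'
#' @param reads data.frame of reads (`read_id`, `sample_id`, `nt_seq`).
#' @param panel a [make_reference_panel()] result (or equivalent: entries,
#'   nt, numbering_ref, signature).
#' @param sig signature table; defaults to the panel's.
#' @param qpcr optional qPCR data.frame; without it the community stage
#'   emits relative abundances only, with a warning.
#' @param habitats optional named vector sample -> habitat for the habitat
#'   report and silhouette.
#' @param params a [clustering_params()].
#' @param B bootstrap replicates.
#' @param min_support decision-edge support threshold.
#' @param seed global seed; stage seeds are derived by fixed offsets.
#' @param out_dir optional output directory.
#' @return list with every stage's result (`otu_set`, `translations`,
#'   `signature`, `msa`, `tree`, `assignments`, `community`, `pca`,
#'   `habitat`, `summary`, `manifest`).
#' @export
run_nod_pipeline <- function(reads, panel, sig = panel$signature,
                             qpcr = NULL, habitats = NULL,
                             params = clustering_params(), B = 1000L,
                             min_support = 50, seed = 1L, out_dir = NULL) {
  lf <- length_filter(reads, params)
  derep <- dereplicate(lf$retained)
  otus_all <- greedy_cluster(derep, params)
  otus <- filter_otus(otus_all, params)

  empty <- nrow(otus$otus) == 0L
  translations <- NULL; sig_res <- NULL; msa <- NULL; tree <- NULL
  assignments <- NULL; pca <- NULL; habrep <- NULL

  if (!empty) {
    translations <- translate_representatives(
      otus, panel$numbering_ref, ref_nt_panel = panel$nt)
    sig_res <- signature_calls(translations, panel$numbering_ref, sig,
                               anchors = panel$aa)
    seqs <- c(stats::setNames(otus$otus$representative, otus$otus$otu_id),
              panel$nt)
    msa <- align_representatives(seqs)
    if (!is.null(msa)) {
      tree <- bootstrap_supports(msa, B = B, seed = seed + 1L)
      assignments <- assign_cluster(
        tree, stats::setNames(panel$entries$cluster_label, panel$entries$id),
        sig_res$labels, min_support = min_support)
      assignments$frameshift_flag <-
        translations$frameshift_flag[match(assignments$otu_id,
                                           translations$otu_id)]
    }
  }

  ct <- if (!empty) community_table(otus) else NULL
  if (is.null(qpcr))
    warning("no qPCR table supplied; reporting relative abundances only",
            call. = FALSE)
  if (!empty && nrow(ct$counts) >= 2L && ncol(ct$counts) >= 2L)
    pca <- pca_community(ct)
  if (!empty && !is.null(habitats))
    habrep <- habitat_report(ct, habitats, assignments)
  summary <- if (!empty) community_summary(ct, qpcr, assignments) else NULL

  manifest <- list(
    seed = seed,
    params = list(identity_threshold = params$identity_threshold,
                  min_size = params$min_size,
                  length_window = params$length_window,
                  bootstrap_B = B, min_support = min_support),
    n_reads_in = nrow(reads),
    n_reads_retained = nrow(lf$retained),
    n_unique = nrow(derep$seqs),
    n_otus_prefilter = nrow(otus_all$otus),
    n_otus = if (empty) 0L else nrow(otus$otus))

  res <- list(length_filter = lf, derep = derep, otu_set = otus,
              translations = translations, signature = sig_res, msa = msa,
              tree = tree, assignments = assignments, community = ct,
              pca = pca, habitat = habrep, summary = summary,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# write every stage's artifacts under out_dir
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_tsv_hash(res$length_filter$rejected, p("rejected_reads.tsv"))
  if (nrow(res$otu_set$otus)) {
    write_otu_representatives(res$otu_set, p("otu_representatives.fasta"))
    write_otu_table(res$otu_set$counts, p("otu_table.tsv"))
    write_tsv_hash(res$otu_set$membership, p("otu_membership.tsv"))
  }
  if (!is.null(res$translations))
    write_tsv_hash(res$translations, p("translations.tsv"))
  if (!is.null(res$signature))
    write_tsv_hash(res$signature$site_report, p("signature_report.tsv"))
  if (!is.null(res$msa))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unclass(res$msa)), p("alignment.fasta"))
  if (!is.null(res$tree)) write_newick(res$tree, p("tree.nwk"))
  if (!is.null(res$assignments))
    write_tsv_hash(res$assignments, p("assignments.tsv"))
  if (!is.null(res$pca)) {
    sc <- data.frame(sample_id = rownames(res$pca$scores),
                     res$pca$scores, check.names = FALSE)
    write_tsv_hash(sc, p("pca_coordinates.tsv"))
  }
  if (!is.null(res$habitat))
    write_tsv_hash(res$habitat$otu_status, p("habitat_report.tsv"))
  if (!is.null(res$summary))
    jsonlite::write_json(res$summary, p("summary.json"), auto_unbox = TRUE,
                         digits = NA)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' Simulate a complete synthetic dataset on disk
#'
#' Wraps the synthetic-community generator: reference panel, reads (FASTQ
#' per sample), qPCR table, signature table and truth manifest.
#'
#' @param seed global seed.
#' @param spec optional [community_spec()]; defaults to
#'   [default_community_spec()] of the generated panel.
#' @param out_dir optional directory; when given, everything is written
#'   there (per-sample FASTQ under `reads/`).
#' @param error_model forwarded to [default_community_spec()] when `spec`
#'   is not supplied.
#' @return list: `panel`, `spec`, `sim` (reads + truth), `qpcr`.
#' @export
simulate_nod_dataset <- function(seed = 1L, spec = NULL, out_dir = NULL,
                                 error_model = c(sub_rate = 0.004,
                                                 ins_rate = 0.003,
                                                 del_rate = 0.003)) {
  panel <- make_reference_panel(seed)
  if (is.null(spec))
    spec <- default_community_spec(panel, seed = seed + 1L,
                                   error_model = error_model)
  sim <- simulate_reads(spec, panel)
  qpcr <- simulate_qpcr(spec)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "reads"), showWarnings = FALSE,
               recursive = TRUE)
    write_reference_panel(panel, file.path(out_dir, "panel"))
    for (s in spec$samples$sample_id) {
      sub <- sim$reads[sim$reads$sample_id == s, , drop = FALSE]
      write_reads(sub, file.path(out_dir, "reads", paste0(s, ".fastq")),
                  format = "fastq")
    }
    write_tsv_hash(sim$truth, file.path(out_dir, "truth_manifest.tsv"))
    write_tsv_hash(spec$samples, file.path(out_dir, "samples.tsv"))
    write_qpcr_table(qpcr, file.path(out_dir, "qpcr.tsv"))
  }
  list(panel = panel, spec = spec, sim = sim, qpcr = qpcr)
}
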