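#' Per-sample relative abundances
#'
#' Each sample's counts are divided by the sample total; an all-zero
#' sample stays all-zero and is flagged.
#'
#' @param counts OTUs x samples count matrix.
#' @return matrix of fractions; per-sample columns sum to 1 except flagged
#'   empty samples (attribute `empty_samples`).
#' @export
relative_abundance <- function(counts) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  rel <- sweep(counts, 2L, ifelse(tot > 0, tot, 1), `/`)
  empty <- colnames(counts)[tot == 0]
  if (length(empty))
    warning("samples without counts: ", paste(empty, collapse = ", "),
            call. = FALSE)
  attr(rel, "empty_samples") <- empty
  rel
}

#' Build a community table from clustered OTUs
#'
#' @param otu_set an `otu_set` after [filter_otus()].
#' @return `community_table`: `counts` (OTUs x samples), `rel`
#'   (per-sample fractions), `otu_ids`, `sample_ids`.
#' @export
community_table <- function(otu_set) {
  counts <- otu_set$counts
  structure(list(counts = counts,
                 rel = suppressWarnings(relative_abundance(counts)),
                 otu_ids = rownames(counts),
                 sample_ids = colnames(counts)),
            class = "community_table")
}

#' nod genes as a percentage of total bacteria
#'
#' @param nod,sixteenS positive copy numbers per gram (vectorised).
#' @return `100 * nod / sixteenS`; unchanged when both inputs are scaled
#'   by the same factor.
#' @export
qpcr_fraction <- function(nod, sixteenS) {
  if (any(nod <= 0) || any(sixteenS <= 0))
    stop("copy numbers must be positive", call. = FALSE)
  100 * nod / sixteenS
}

#' PCA of the community composition
#'
#' Principal components of the per-sample relative abundances:
#' column-centred (one column per OTU), no unit scaling, eigendecomposition
#' of the sample covariance via `stats::prcomp`. Sign convention: within
#' each component the largest-magnitude OTU loading is positive, so
#' coordinates do not depend on OTU column order.
#'
#' @param rel OTUs x samples fraction matrix (or a `community_table`).
#' @param n_components components to keep (capped at the available rank).
#' @return list: `scores` (samples x components), `loadings`
#'   (OTUs x components), `var_explained` fractions (sum <= 1).
#' @export
pca_community <- function(rel, n_components = 2L) {
  if (inherits(rel, "community_table")) rel <- rel$rel
  x <- t(as.matrix(rel))                  # samples x OTUs
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need >= 2 samples and >= 2 OTUs", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-12)
  if (rank < 2L)
    warning("community variation has rank < 2; returning available components",
            call. = FALSE)
  k <- min(n_components, max(rank, 1L))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings,
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

#' Mean silhouette of habitats on the first two PCA axes
#'
#' @param pca a [pca_community()] result.
#' @param habitats named character vector sample -> habitat.
#' @return mean silhouette width (positive when habitats separate).
#' @export
habitat_silhouette <- function(pca, habitats) {
  x <- pca$scores[, seq_len(min(2L, ncol(pca$scores))), drop = FALSE]
  cl <- as.integer(factor(habitats[rownames(x)]))
  sil <- cluster::silhouette(cl, stats::dist(x))
  mean(sil[, "sil_width"])
}

#' Shared and habitat-specific OTUs with per-cluster tallies
#'
#' An OTU is habitat-specific when all of its nonzero counts fall in one
#' habitat; OTUs detected in both habitats are shared; OTUs with zero
#' total count are excluded with a warning.
#'
#' @param ct a `community_table` (or counts matrix).
#' @param habitats named character vector sample -> habitat; every sample
#'   column must be mapped.
#' @param assignments optional [assign_cluster()] data.frame for
#'   per-cluster tallies.
#' @return list: `otu_status` data.frame (`otu_id`, `status` in
#'   soil_specific/sediment_specific/shared), `cluster_tally` (cluster x
#'   status counts, when assignments are given).
#' @export
habitat_report <- function(ct, habitats, assignments = NULL) {
  counts <- if (inherits(ct, "community_table")) ct$counts else as.matrix(ct)
  if (!all(colnames(counts) %in% names(habitats)))
    stop("every sample needs a habitat", call. = FALSE)
  hab <- habitats[colnames(counts)]
  status <- vapply(rownames(counts), function(o) {
    present <- unique(hab[counts[o, ] > 0])
    if (length(present) == 0L) return(NA_character_)
    if (length(present) > 1L) return("shared")
    paste0(present, "_specific")
  }, "")
  if (anyNA(status)) {
    warning("zero-count OTUs excluded: ",
            paste(names(status)[is.na(status)], collapse = ", "),
            call. = FALSE)
  }
  otu_status <- data.frame(otu_id = names(status)[!is.na(status)],
                           status = status[!is.na(status)],
                           stringsAsFactors = FALSE, row.names = NULL)
  tally <- NULL
  if (!is.null(assignments)) {
    m <- merge(otu_status, assignments[c("otu_id", "cluster")],
               by = "otu_id", all.x = TRUE)
    m$cluster[is.na(m$cluster)] <- "unassigned"
    tally <- as.data.frame.matrix(table(m$cluster, m$status))
  }
  list(otu_status = otu_status, cluster_tally = tally)
}

#' Per-sample community summary
#'
#' @param ct a `community_table`.
#' @param qpcr optional qPCR data.frame (`sample_id`, `gene`,
#'   `copies_per_gram`); when absent, qPCR-scaled quantities are omitted.
#' @param assignments optional [assign_cluster()] result.
#' @return list ready for JSON: per-sample OTU richness, nod percentage of
#'   16S and absolute nod copies (when qPCR present), per-cluster OTU
#'   tallies (when assignments present).
#' @export
community_summary <- function(ct, qpcr = NULL, assignments = NULL) {
  richness <- colSums(ct$counts > 0)
  out <- list(samples = ct$sample_ids,
              otu_richness = as.list(richness))
  if (!is.null(qpcr)) {
    nod <- qpcr[qpcr$gene == "nod", ]
    s16 <- qpcr[qpcr$gene == "16S", ]
    common <- intersect(intersect(nod$sample_id, s16$sample_id),
                        ct$sample_ids)
    frac <- qpcr_fraction(nod$copies_per_gram[match(common, nod$sample_id)],
                          s16$copies_per_gram[match(common, s16$sample_id)])
    out$nod_percent_of_16S <- as.list(stats::setNames(frac, common))
    out$nod_copies_per_gram <- as.list(stats::setNames(
      nod$copies_per_gram[match(common, nod$sample_id)], common))
  }
  if (!is.null(assignments))
    out$otus_per_cluster <- as.list(table(assignments$cluster))
  out
}
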