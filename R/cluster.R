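#' Clustering parameters
#'
#' @param identity_threshold minimum nucleotide identity for a sequence to
#'   join an OTU centroid (inclusive); default 0.90.
#' @param min_size minimum OTU size after clustering (inclusive); default
#'   50 reads.
#' @param length_window retained read length range in nt (inclusive);
#'   default 800-1200 for a ca. 1.0 kb amplicon.
#' @return list of class `clustering_params`.
#' @export
clustering_params <- function(identity_threshold = 0.90, min_size = 50L,
                              length_window = c(800L, 1200L)) {
  stopifnot_scalar_number(identity_threshold, "identity_threshold", 1e-9, 1)
  stopifnot_scalar_number(min_size, "min_size", 0)
  stopifnot(length(length_window) == 2L, length_window[1] <= length_window[2])
  structure(list(identity_threshold = identity_threshold,
                 min_size = as.integer(min_size),
                 length_window = as.integer(length_window)),
            class = "clustering_params")
}

#' Length-filter reads
#'
#' @param reads data.frame with `read_id`, `nt_seq` (and anything else).
#' @param params a [clustering_params()].
#' @return list `retained` (subset of `reads`) and `rejected`
#'   (`read_id`, `length`, `reason`).
#' @export
length_filter <- function(reads, params = clustering_params()) {
  len <- nchar(reads$nt_seq)
  keep <- len >= params$length_window[1] & len <= params$length_window[2]
  rejected <- data.frame(
    read_id = reads$read_id[!keep], length = len[!keep],
    reason = ifelse(len[!keep] < params$length_window[1],
                    "too_short", "too_long"),
    stringsAsFactors = FALSE)
  list(retained = reads[keep, , drop = FALSE], rejected = rejected)
}

#' Dereplicate reads to unique sequences with per-sample counts
#'
#' Exact-string dereplication. Output order is the greedy-clustering input
#' order: total count descending, ties broken by sequence length descending
#' and then by the lexicographically smallest member read id.
#'
#' @param reads data.frame with `read_id`, `sample_id`, `nt_seq`.
#' @return list: `seqs` data.frame (`uniq_id` = smallest member read id,
#'   `nt_seq`, `total`) and `counts`, an integer matrix unique-seqs x
#'   samples; row order matches `seqs`.
#' @export
dereplicate <- function(reads) {
  if (nrow(reads) == 0L)
    return(list(seqs = data.frame(uniq_id = character(),
                                  nt_seq = character(), total = integer(),
                                  stringsAsFactors = FALSE),
                counts = matrix(0L, 0L, 0L)))
  grp <- match(reads$nt_seq, unique(reads$nt_seq))
  uniq_seq <- unique(reads$nt_seq)
  samples <- unique(reads$sample_id)
  counts <- matrix(0L, length(uniq_seq), length(samples),
                   dimnames = list(NULL, samples))
  tab <- table(grp, factor(reads$sample_id, levels = samples))
  counts[as.integer(rownames(tab)), ] <- as.integer(tab)
  first_id <- vapply(split(reads$read_id, grp),
                     function(x) min(x), "")[as.character(seq_along(uniq_seq))]
  total <- rowSums(counts)
  ord <- order(-total, -nchar(uniq_seq), first_id)
  counts <- counts[ord, , drop = FALSE]
  seqs <- data.frame(uniq_id = first_id[ord], nt_seq = uniq_seq[ord],
                     total = as.integer(total[ord]),
                     stringsAsFactors = FALSE)
  rownames(counts) <- seqs$uniq_id
  list(seqs = seqs, counts = counts)
}

#' Pairwise nucleotide identity under global alignment
#'
#' Identity is matching columns over the full alignment length, end gaps
#' included (the strictest common convention). Scoring: match +1,
#' mismatch -1, gap open -2, gap extend -1, end gaps penalised.
#'
#' @param a,b nonempty nucleotide strings.
#' @return identity fraction in \[0, 1\]; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b))
    stop("sequences must be nonempty", call. = FALSE)
  identity_vs_subject(a, b)
}

# vectorised workhorse: identities of many patterns against one subject
identity_vs_subject <- function(patterns, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(aln) / Biostrings::width(Biostrings::alignedPattern(aln))
}

#' Greedy centroid clustering of dereplicated sequences
#'
#' UCLUST-style abundance-sorted greedy scan: each sequence, visited in
#' dereplication order, joins the first (oldest) existing centroid whose
#' identity is at or above the threshold, otherwise founds a new centroid.
#' Centroids never change after founding, so the result is deterministic
#' given the input order.
#'
#' @param derep output of [dereplicate()].
#' @param params a [clustering_params()].
#' @return `otu_set`: list with `otus` data.frame (`otu_id` = centroid
#'   uniq_id at this stage, `representative`, `size`) and `counts`
#'   (OTUs x samples), plus `membership` mapping every unique sequence to
#'   its OTU.
#' @export
greedy_cluster <- function(derep, params = clustering_params()) {
  n <- nrow(derep$seqs)
  cent_idx <- integer(0)                  # indices into derep$seqs
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    if (length(cent_idx)) {
      ident <- identity_vs_subject(derep$seqs$nt_seq[cent_idx],
                                   derep$seqs$nt_seq[i])
      j <- which(ident >= params$identity_threshold)
      if (length(j)) hit <- j[1L]         # first centroid in founding order
    }
    if (hit == 0L) {
      cent_idx <- c(cent_idx, i)
      assign[i] <- length(cent_idx)
    } else assign[i] <- hit
  }
  k <- length(cent_idx)
  counts <- matrix(0L, k, ncol(derep$counts),
                   dimnames = list(derep$seqs$uniq_id[cent_idx],
                                   colnames(derep$counts)))
  for (c in seq_len(k)) {
    m <- derep$counts[assign == c, , drop = FALSE]
    counts[c, ] <- as.integer(colSums(m))
  }
  otus <- data.frame(otu_id = derep$seqs$uniq_id[cent_idx],
                     representative = derep$seqs$nt_seq[cent_idx],
                     size = as.integer(rowSums(counts)),
                     stringsAsFactors = FALSE)
  membership <- data.frame(uniq_id = derep$seqs$uniq_id,
                           otu_id = otus$otu_id[assign],
                           stringsAsFactors = FALSE)
  structure(list(otus = otus, counts = counts, membership = membership),
            class = "otu_set")
}

#' Filter OTUs by size and rename by rank
#'
#' Keeps OTUs with at least `min_size` member reads and renames the
#' survivors `OTU1..OTUk` by descending size (ties by centroid id). Warns,
#' but proceeds, when nothing survives.
#'
#' @param otu_set result of [greedy_cluster()].
#' @param params a [clustering_params()].
#' @return filtered, renamed `otu_set`.
#' @export
filter_otus <- function(otu_set, params = clustering_params()) {
  keep <- otu_set$otus$size >= params$min_size
  if (!any(keep))
    warning("no OTU reaches min_size = ", params$min_size,
            "; downstream stages will be empty", call. = FALSE)
  otus <- otu_set$otus[keep, , drop = FALSE]
  counts <- otu_set$counts[keep, , drop = FALSE]
  ord <- order(-otus$size, otus$otu_id)
  otus <- otus[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  new_id <- sprintf("OTU%d", seq_len(nrow(otus)))
  membership <- otu_set$membership
  membership$otu_id <- new_id[match(membership$otu_id, otus$otu_id)]
  membership <- membership[!is.na(membership$otu_id), , drop = FALSE]
  otus$otu_id <- new_id
  rownames(counts) <- new_id
  rownames(otus) <- NULL
  structure(list(otus = otus, counts = counts, membership = membership),
            class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat(sprintf("otu_set: %d OTUs over %d samples, %d reads\n",
              nrow(x$otus), ncol(x$counts), sum(x$counts)))
  utils::head(x$otus[c("otu_id", "size")], 10L)
}

#' Write OTU representatives as FASTA
#'
#' Headers follow the usual `OTU<k>;size=<n>` convention.
#'
#' @param otu_set an `otu_set`.
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_otu_representatives <- function(otu_set, path) {
  ids <- sprintf("%s;size=%d", otu_set$otus$otu_id, otu_set$otus$size)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(otu_set$otus$representative,
                                             ids)), path)
  invisible(path)
}
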