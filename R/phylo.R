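# --- progressive multiple alignment ---------------------------------------

# (K+1) x L frequency profile (last row = gap) of a character matrix
profile_of <- function(chmat, alphabet) {
  out <- matrix(0, length(alphabet) + 1L, ncol(chmat))
  for (k in seq_along(alphabet))
    out[k, ] <- colMeans(chmat == alphabet[k])
  out[nrow(out), ] <- colMeans(chmat == "-")
  # rare letters outside the alphabet are treated as uninformative
  tot <- colSums(out)
  bad <- tot < 1 - 1e-9
  if (any(bad)) out[nrow(out), bad] <- out[nrow(out), bad] + (1 - tot[bad])
  out
}

merge_profiles <- function(ma, mb, S, alphabet, gap_open, gap_ext) {
  ops <- .profile_align_ops(profile_of(ma, alphabet),
                            profile_of(mb, alphabet), S, gap_open, gap_ext)
  n <- length(ops)
  out <- matrix("-", nrow(ma) + nrow(mb), n,
                dimnames = list(c(rownames(ma), rownames(mb)), NULL))
  ia <- 0L; ib <- 0L
  for (k in seq_len(n)) {
    if (ops[k] != 2L) { ia <- ia + 1L; out[seq_len(nrow(ma)), k] <- ma[, ia] }
    if (ops[k] != 1L) { ib <- ib + 1L
      out[nrow(ma) + seq_len(nrow(mb)), k] <- mb[, ib] }
  }
  out
}

# guide-tree progressive profile alignment, shared by the nucleotide and
# protein front ends; d is a precomputed distance matrix in input order
progressive_msa <- function(seqs, d, S, alphabet, gap_open, gap_ext) {
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  mats <- lapply(seq_along(seqs), function(i) {
    m <- matrix(strsplit(seqs[[i]], "")[[1]], nrow = 1L)
    rownames(m) <- names(seqs)[i]
    m
  })
  merged <- vector("list", nrow(hc$merge))
  grab <- function(k) if (k < 0) mats[[-k]] else merged[[k]]
  for (r in seq_len(nrow(hc$merge)))
    merged[[r]] <- merge_profiles(grab(hc$merge[r, 1]), grab(hc$merge[r, 2]),
                                  S, alphabet, gap_open, gap_ext)
  final <- merged[[nrow(hc$merge)]][names(seqs), , drop = FALSE]
  stats::setNames(apply(final, 1L, paste, collapse = ""), names(seqs))
}

#' Progressive multiple alignment of OTU representatives and references
#'
#' Guide tree: average-linkage clustering of pairwise global-alignment
#' distances (1 - identity, the clustering module's scoring); profiles are
#' then merged in guide-tree order with an affine-gap profile aligner using
#' the same match/mismatch/gap scores. Fully deterministic.
#'
#' @param seqs named character vector of >= 4 nucleotide sequences.
#' @return named character vector of equal-length aligned sequences
#'   (class `nt_msa`), in input order; `NULL` with a warning when fewer
#'   than 4 sequences are supplied.
#' @export
align_representatives <- function(seqs) {
  if (length(seqs) < 4L) {
    warning("need >= 4 sequences for an alignment; skipping", call. = FALSE)
    return(NULL)
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names", call. = FALSE)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    idx <- (i + 1L):n
    d[idx, i] <- d[i, idx] <- 1 - identity_vs_subject(seqs[idx], seqs[[i]])
  }
  alphabet <- c("A", "C", "G", "T")
  S <- matrix(-1, 4, 4); diag(S) <- 1
  structure(progressive_msa(seqs, d, S, alphabet,
                            gap_open = 2, gap_ext = 1),
            class = "nt_msa")
}

# protein progressive alignment (BLOSUM62, ClustalW-like 10/0.5), used for
# multiple-alignment-anchored numbering transfer
align_protein_msa <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("proteins must carry unique names", call. = FALSE)
  S <- blosum62()
  alphabet <- rownames(S)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    idx <- (i + 1L):n
    pid <- Biostrings::pid(Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs[idx]), Biostrings::AAString(seqs[[i]]),
      type = "global", substitutionMatrix = S,
      gapOpening = 10, gapExtension = 0.5), type = "PID1")
    d[idx, i] <- d[i, idx] <- 1 - pid / 100
  }
  progressive_msa(seqs, d, S, alphabet, gap_open = 10, gap_ext = 0.5)
}

# --- distances -------------------------------------------------------------

#' Pairwise p-distances from a multiple alignment
#'
#' The p-distance is the proportion of differing sites over columns where
#' both rows are non-gap. Pairs with fewer than `min_comparable` comparable
#' columns are flagged and set to the maximum observed distance plus 0.01,
#' so they never look artificially close.
#'
#' @param msa named character vector of aligned sequences (`nt_msa`).
#' @param min_comparable minimum shared non-gap columns (default 50).
#' @return symmetric matrix with zero diagonal; attribute `flagged` is a
#'   logical matrix marking low-overlap pairs.
#' @export
p_distance <- function(msa, min_comparable = 50L) {
  if (length(msa) < 2L) stop("need >= 2 aligned rows", call. = FALSE)
  chm <- do.call(rbind, strsplit(unclass(msa), ""))
  rownames(chm) <- names(msa)
  n <- nrow(chm)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  comp <- matrix(ncol(chm), n, n)
  gap <- chm == "-"
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    comp[i, j] <- comp[j, i] <- sum(ok)
    d[i, j] <- d[j, i] <- if (sum(ok) == 0L) NA_real_
      else mean(chm[i, ok] != chm[j, ok])
  }
  flagged <- comp < min_comparable
  diag(flagged) <- FALSE
  dimnames(flagged) <- dimnames(d)
  if (any(flagged)) {
    fill <- max(d[!flagged & upper.tri(d)], 0, na.rm = TRUE) + 0.01
    d[flagged] <- fill
  }
  attr(d, "flagged") <- flagged
  d
}

# --- neighbor joining ------------------------------------------------------

fmt_len <- function(x) formatC(x, digits = 10, format = "g")

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the Q criterion. Ties in Q are broken
#' by the lexicographically smallest pair of taxon ids (an internal node
#' carries the smallest leaf id of its subtree). Negative branch-length
#' estimates are clamped to zero with the deficit moved onto the sister
#' edge, so all branch lengths are nonnegative. Additive matrices are
#' recovered exactly.
#'
#' @param D symmetric distance matrix with >= 4 taxa, zero diagonal,
#'   dimnames set.
#' @return unrooted `ape::phylo` (trifurcating root node).
#' @export
neighbor_joining <- function(D) {
  if (is.null(rownames(D))) stop("D needs taxon names", call. = FALSE)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(!is.finite(D))) stop("distances must be finite", call. = FALSE)
  n <- nrow(D)
  if (n < 4L) stop("need >= 4 taxa", call. = FALSE)
  labs <- rownames(D)          # tie-break label: smallest leaf id in subtree
  nwk <- labs                  # growing newick fragment per active node
  d <- D
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      p <- sort(c(labs[ij[1]], labs[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    node_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt_len(li),
                        nwk[j], fmt_len(lj))
    node_lab <- min(labs[i], labs[j])
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    labs <- c(labs[keep], node_lab)
    nwk <- c(nwk[keep], node_nwk)
  }
  # final three-way join at the (unrooted) root
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  l <- pmax(c(l1, l2, l3), 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt_len(l[1]),
                 nwk[2], fmt_len(l[2]), nwk[3], fmt_len(l[3]))
  ape::read.tree(text = txt)
}

# --- bootstrap -------------------------------------------------------------

# canonical key per non-trivial bipartition: the side not containing the
# globally smallest label, sorted and joined
bipartition_keys <- function(tree, all_labels = sort(tree$tip.label)) {
  anchor <- all_labels[1L]
  pp <- ape::prop.part(tree)
  ntip <- length(tree$tip.label)
  keys <- vapply(seq_along(pp), function(k) {
    side <- tree$tip.label[pp[[k]]]
    if (length(side) %in% c(1L, ntip - 1L, ntip)) return(NA_character_)
    if (anchor %in% side) side <- setdiff(all_labels, side)
    paste(sort(side), collapse = "\r")
  }, "")
  names(keys) <- ntip + seq_along(pp)     # internal node numbers
  keys
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `B` times; each
#' replicate is rerun through [p_distance()] and [neighbor_joining()], and
#' the support of an internal edge is the percentage of replicate trees
#' containing the same (label-canonicalised) bipartition. Seeded and
#' reproducible.
#'
#' @param msa named character vector of aligned sequences.
#' @param tree the tree to annotate; recomputed from `msa` when `NULL`.
#' @param B number of replicates (>= 1), 1000 for publication-grade runs.
#' @param seed integer seed.
#' @param min_comparable passed to [p_distance()].
#' @return `tree` with integer `node.label` supports (root label empty);
#'   attribute `supports` maps internal node number to percent.
#' @export
bootstrap_supports <- function(msa, tree = NULL, B = 1000L, seed = 1L,
                               min_comparable = 50L) {
  stopifnot(B >= 1L)
  if (is.null(tree)) tree <- neighbor_joining(p_distance(msa, min_comparable))
  chm <- do.call(rbind, strsplit(unclass(msa), ""))
  rownames(chm) <- names(msa)
  orig_keys <- bipartition_keys(tree)
  counts <- stats::setNames(numeric(length(orig_keys)), names(orig_keys))
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      cols <- sample.int(ncol(chm), ncol(chm), replace = TRUE)
      rep_msa <- stats::setNames(
        apply(chm[, cols, drop = FALSE], 1L, paste, collapse = ""),
        rownames(chm))
      rep_tree <- neighbor_joining(p_distance(rep_msa, min_comparable))
      rep_keys <- bipartition_keys(rep_tree, sort(tree$tip.label))
      hit <- orig_keys %in% rep_keys[!is.na(rep_keys)]
      counts[hit] <- counts[hit] + 1
    }
  })
  supports <- round(100 * counts / B)
  supports[is.na(orig_keys)] <- NA        # root / trivial: no edge
  lab <- ifelse(is.na(supports), "", as.character(as.integer(supports)))
  tree$node.label <- lab
  attr(tree, "supports") <- supports
  tree
}

# --- cluster assignment ----------------------------------------------------

#' Assign OTUs to named nod clusters from the tree
#'
#' For every OTU leaf, the smallest edge-induced bipartition side that
#' contains the OTU and at least one labelled reference is the decision
#' clade. When all references in it share one label and the edge's
#' bootstrap support is at least `min_support`, the OTU takes that cluster;
#' otherwise it is `unassigned`. The joint decision with the signature
#' label is: nod cluster (Aquifer/NC10/Reactor1) + `nod_type` -> `nod`;
#' qNor-related cluster + `qnor_type` -> `qnor_like`; `unknown_qNor` +
#' `nod_type` -> `candidate` (phylogeny and residues disagree about
#' ancestry, so the functional call is cautious); anything else ->
#' `undetermined`.
#'
#' @param tree annotated tree from [bootstrap_supports()] (needs
#'   `node.label` supports).
#' @param ref_labels named character vector: reference leaf id -> cluster
#'   label.
#' @param signature_labels named character vector: OTU id -> signature
#'   label from [signature_calls()].
#' @param min_support minimum bootstrap support of the decision edge
#'   (default 50, inclusive).
#' @return data.frame `otu_id`, `cluster`, `support`, `signature_label`,
#'   `final_call`.
#' @export
assign_cluster <- function(tree, ref_labels, signature_labels,
                           min_support = 50) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  refs <- intersect(tips, names(ref_labels))
  if (!length(refs)) stop("tree contains no labelled reference", call. = FALSE)
  otus <- setdiff(tips, refs)
  ntip <- length(tips)
  pp <- ape::prop.part(tree)
  supports <- attr(tree, "supports")
  if (is.null(supports)) {
    supports <- suppressWarnings(as.numeric(tree$node.label))
    names(supports) <- ntip + seq_along(tree$node.label)
  }
  # candidate sides: each internal (non-root) clade and its complement
  sides <- list(); side_support <- numeric(0)
  for (k in seq_along(pp)) {
    clade <- tips[pp[[k]]]
    if (length(clade) %in% c(ntip, 1L)) next
    node <- as.character(ntip + k)
    s <- supports[[node]]
    if (is.na(s)) next                    # root pseudo-clade
    sides <- c(sides, list(clade), list(setdiff(tips, clade)))
    side_support <- c(side_support, s, s)
  }
  res <- lapply(otus, function(x) {
    has_x <- vapply(sides, function(s) x %in% s, TRUE)
    has_ref <- vapply(sides, function(s) any(refs %in% s), TRUE)
    ok <- which(has_x & has_ref)
    cluster <- "unassigned"; supp <- NA_real_
    if (length(ok)) {
      sz <- vapply(sides[ok], length, 0L)
      keyed <- vapply(sides[ok], function(s) paste(sort(s), collapse = "\r"),
                      "")
      best <- ok[order(sz, keyed)][1L]
      in_refs <- intersect(sides[[best]], refs)
      labs <- unique(ref_labels[in_refs])
      supp <- side_support[[best]]
      if (length(labs) == 1L && !is.na(supp) && supp >= min_support)
        cluster <- labs
    }
    sig <- signature_labels[[x]] %||% NA_character_
    final <- if (cluster %in% c("Aquifer", "NC10", "Reactor1") &&
                 identical(sig, "nod_type")) "nod"
    else if (cluster %in% c("unknown_qNor", "qNor_outgroup") &&
             identical(sig, "qnor_type")) "qnor_like"
    else if (identical(cluster, "unknown_qNor") &&
             identical(sig, "nod_type")) "candidate"
    else "undetermined"
    data.frame(otu_id = x, cluster = cluster, support = supp,
               signature_label = sig, final_call = final,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
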