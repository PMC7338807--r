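#' Align a query protein to the reference qNor
#'
#' Needleman-Wunsch with BLOSUM62, gap open 10 / extend 0.5 (ClustalW-like
#' defaults); tie-breaking is the aligner's deterministic high-road
#' traceback. End gaps are free (`overlap` mode): queries are partial
#' amplicons laid onto a full-length reference, so penalised end gaps
#' would smear the query's ends across the reference overhangs and
#' fabricate residue observations outside the amplified region. Reference
#' positions outside the aligned span stay uncovered.
#'
#' @param query_aa,ref_aa nonempty amino-acid strings.
#' @return list of class `aa_alignment`: aligned core strings `query` and
#'   `ref` (equal length, gaps as `-`), 1-based span starts `q_start` /
#'   `r_start`, and `r_len`, the full reference length.
#' @export
align_to_reference <- function(query_aa, ref_aa) {
  if (!nzchar(query_aa) || !nzchar(ref_aa))
    stop("sequences must be nonempty", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query_aa), Biostrings::AAString(ref_aa),
    type = "overlap", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5)
  structure(list(query = as.character(Biostrings::alignedPattern(aln)),
                 ref = as.character(Biostrings::alignedSubject(aln)),
                 q_start = Biostrings::start(Biostrings::pattern(aln)),
                 r_start = Biostrings::start(Biostrings::subject(aln)),
                 r_len = nchar(ref_aa),
                 score = Biostrings::score(aln)),
            class = "aa_alignment")
}

#' Transfer reference numbering onto a query protein
#'
#' Reference positions count non-gap reference columns from 1; query
#' positions likewise. Columns where the query is gapped map the reference
#' position to `NA` (uncovered).
#'
#' @param alignment an `aa_alignment` from [align_to_reference()].
#' @return data.frame `ref_pos`, `query_pos` (NA where the query is
#'   gapped), one row per reference residue inside the aligned span,
#'   `ref_pos` strictly increasing; reference positions outside the span
#'   are absent (uncovered).
#' @export
map_numbering <- function(alignment) {
  q <- strsplit(alignment$query, "")[[1]]
  r <- strsplit(alignment$ref, "")[[1]]
  stopifnot(length(q) == length(r))
  q_off <- (alignment$q_start %||% 1L) - 1L
  r_off <- (alignment$r_start %||% 1L) - 1L
  ref_col <- r != "-"
  qpos <- cumsum(q != "-") + q_off
  qpos[q == "-"] <- NA_integer_
  data.frame(ref_pos = r_off + seq_len(sum(ref_col)),
             query_pos = as.integer(qpos[ref_col]))
}

# numbering transfer from two rows of one multiple alignment
map_numbering_msa <- function(ref_row, query_row) {
  r <- strsplit(ref_row, "")[[1]]
  q <- strsplit(query_row, "")[[1]]
  stopifnot(length(r) == length(q))
  ref_col <- r != "-"
  qpos <- cumsum(q != "-")
  qpos[q == "-"] <- NA_integer_
  data.frame(ref_pos = seq_len(sum(ref_col)),
             query_pos = as.integer(qpos[ref_col]))
}

#' Call signature sites on a numbered query protein
#'
#' Per signature site: `uncovered` when the reference position maps to a
#' gap or is absent from the map; `conserved` when the observed residue is
#' the qNor residue; `nod_substitution` when it is one of the allowed Nod
#' substitutions; `other_substitution` otherwise.
#'
#' @param query_aa the (unaligned) query protein.
#' @param rmap a [map_numbering()] result.
#' @param sig a [signature_table()].
#' @return data.frame `ref_pos`, `observed` (residue or NA), `call`.
#' @export
call_sites <- function(query_aa, rmap, sig) {
  q <- strsplit(query_aa, "")[[1]]
  res <- lapply(seq_len(nrow(sig$sites)), function(i) {
    pos <- sig$sites$ref_pos[i]
    qpos <- rmap$query_pos[match(pos, rmap$ref_pos)]
    if (is.na(qpos) || qpos < 1L || qpos > length(q))
      return(data.frame(ref_pos = pos, observed = NA_character_,
                        call = "uncovered", stringsAsFactors = FALSE))
    obs <- q[qpos]
    call <- if (obs == sig$sites$qnor_residue[i]) "conserved"
    else if (obs %in% sig$nod_residues[[i]]) "nod_substitution"
    else "other_substitution"
    data.frame(ref_pos = pos, observed = obs, call = call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify a protein from its signature-site calls
#'
#' With fewer than `min_covered_sites` covered sites the label is
#' `uncovered`. Otherwise `nod_type` requires *every* covered site to carry
#' a Nod substitution, `qnor_type` every covered site conserved; any
#' mixture (including `other_substitution`, which never counts toward
#' `nod_type`) is `ambiguous`.
#'
#' @param site_calls a [call_sites()] result.
#' @param sig a [signature_table()] (supplies `min_covered_sites`).
#' @return one of `"nod_type"`, `"qnor_type"`, `"ambiguous"`,
#'   `"uncovered"`.
#' @export
classify_signature <- function(site_calls, sig) {
  covered <- site_calls$call[site_calls$call != "uncovered"]
  if (length(covered) < sig$min_covered_sites) return("uncovered")
  if (all(covered == "nod_substitution")) return("nod_type")
  if (all(covered == "conserved")) return("qnor_type")
  "ambiguous"
}

#' Signature calling for a set of proteins
#'
#' Convenience wrapper: transfer the reference numbering onto each protein,
#' call sites, classify.
#'
#' Numbering transfer is pairwise by default. When `anchors` (additional
#' homologous proteins, typically the reference panel) are supplied, all
#' queries, anchors and the reference are aligned in one progressive
#' multiple alignment and numbering is read off the reference row — the
#' usual alignment-figure construction. At the substantial divergence
#' between Nod lineages and qNor, the conserved columns contributed by the
#' anchors make the position transfer markedly more reliable than any
#' single pairwise alignment.
#'
#' @param proteins named character vector (or data.frame from
#'   [translate_representatives()] with `otu_id`, `aa_seq`).
#' @param ref_aa the numbering-reference qNor protein.
#' @param sig a [signature_table()].
#' @param anchors optional named character vector of homologous proteins
#'   included in the alignment to stabilise the numbering.
#' @return list with `labels` (named character), `site_calls` (long
#'   data.frame `otu_id`, `ref_pos`, `observed`, `call`), and
#'   `site_report` (wide, one column per reference position, mirroring the
#'   usual alignment-figure layout).
#' @export
signature_calls <- function(proteins, ref_aa, sig, anchors = NULL) {
  if (is.data.frame(proteins))
    proteins <- stats::setNames(proteins$aa_seq, proteins$otu_id)
  if (is.null(anchors)) {
    rmaps <- lapply(names(proteins), function(id)
      map_numbering(align_to_reference(proteins[[id]], ref_aa)))
  } else {
    ref_name <- ".numbering_ref"
    anchors <- anchors[setdiff(names(anchors), names(proteins))]
    all <- c(stats::setNames(ref_aa, ref_name), anchors, proteins)
    msa <- align_protein_msa(all)
    rmaps <- lapply(names(proteins), function(id)
      map_numbering_msa(msa[[ref_name]], msa[[id]]))
  }
  calls <- lapply(seq_along(proteins), function(i) {
    sc <- call_sites(proteins[[i]], rmaps[[i]], sig)
    sc$otu_id <- names(proteins)[i]
    sc
  })
  long <- do.call(rbind, calls)
  labels <- vapply(calls, classify_signature, "", sig = sig)
  names(labels) <- names(proteins)
  wide <- data.frame(otu_id = names(proteins), stringsAsFactors = FALSE)
  for (pos in sig$sites$ref_pos) {
    obs <- long$observed[long$ref_pos == pos][
      match(wide$otu_id, long$otu_id[long$ref_pos == pos])]
    wide[[sprintf("pos%d", pos)]] <- ifelse(is.na(obs), ".", obs)
  }
  wide$label <- labels
  list(labels = labels,
       site_calls = long[c("otu_id", "ref_pos", "observed", "call")],
       site_report = wide)
}
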