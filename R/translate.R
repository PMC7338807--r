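#' Six-frame translation
#'
#' Standard genetic code; reverse frames translate the reverse complement;
#' a trailing partial codon is dropped. Frames are named
#' `"1","2","3","-1","-2","-3"`.
#'
#' @param nt nucleotide string of length >= 3.
#' @return named character vector of 6 amino-acid strings (stops as `*`).
#' @export
six_frame <- function(nt) {
  if (nchar(nt) < 3L) stop("need at least one codon", call. = FALSE)
  rc <- revcomp(nt)
  fwd <- vapply(1:3, function(f) translate_nt(substr(nt, f, nchar(nt))), "")
  rev <- vapply(1:3, function(f) translate_nt(substr(rc, f, nchar(rc))), "")
  stats::setNames(c(fwd, rev), c("1", "2", "3", "-1", "-2", "-3"))
}

# best local protein alignment score against a reference (BLOSUM62, open 11
# / extend 1); returns score only
local_score <- function(query_aa, ref_aa) {
  if (!nzchar(query_aa)) return(-Inf)
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(query_aa), Biostrings::AAString(ref_aa),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
}

#' Recover the reading frame of an amplicon against a reference protein
#'
#' All six frame translations are scored by local protein alignment
#' (BLOSUM62, gap open 11 / extend 1) against `ref_aa`; the best-scoring
#' frame wins, ties broken in frame order 1, 2, 3, -1, -2, -3.
#'
#' The frameshift flag is raised when the chosen translation has an
#' internal stop codon, when the best score falls below
#' `min_score_frac` of the reference self-score (scaled by the fraction
#' of the reference the amplicon can cover, so partial amplicons are not
#' penalised for their length), or — when a
#' frame-preserving nucleotide reference `ref_nt` is supplied (amplicons
#' are primer-to-primer, so length is informative) — when the length
#' offset to that reference is not a multiple of 3. Flagged results are
#' returned, never dropped; downstream stages decide.
#'
#' @param nt nucleotide sequence.
#' @param ref_aa reference protein (nonempty).
#' @param ref_nt optional in-frame nucleotide reference for indel-aware
#'   frameshift detection.
#' @param min_score_frac score floor as a fraction of the coverable
#'   reference self-score (default 0.1: correct-frame homologs down to
#'   about 40 percent amino-acid identity score well above it, wrong-frame
#'   translations far below).
#' @param otu_id carried through into the result.
#' @return list of class `translation_result`: `otu_id`, `frame`, `aa_seq`,
#'   `frameshift_flag`, `alignment_score_to_ref`.
#' @export
best_frame <- function(nt, ref_aa, ref_nt = NULL, min_score_frac = 0.1,
                       otu_id = NA_character_) {
  if (!nzchar(ref_aa)) stop("reference protein is empty", call. = FALSE)
  frames <- six_frame(nt)
  scores <- vapply(frames, local_score, 0, ref_aa = ref_aa)
  best <- which.max(scores)               # which.max keeps the first tie
  self_score <- local_score(ref_aa, ref_aa)
  coverable <- min(1, (nchar(nt) / 3) / nchar(ref_aa))
  flag <- has_internal_stop(frames[[best]]) ||
    scores[[best]] < min_score_frac * self_score * coverable
  if (!is.null(ref_nt) && (nchar(nt) - nchar(ref_nt)) %% 3L != 0L)
    flag <- TRUE
  structure(list(otu_id = otu_id,
                 frame = as.integer(names(frames)[best]),
                 aa_seq = frames[[best]],
                 frameshift_flag = flag,
                 alignment_score_to_ref = scores[[best]]),
            class = "translation_result")
}

#' Translate every OTU representative
#'
#' @param otu_set an `otu_set` after [filter_otus()].
#' @param ref_aa reference protein for frame selection.
#' @param ref_nt_panel optional named vector of in-frame nucleotide
#'   references; each representative is checked against its most similar
#'   entry for indel-aware frameshift flagging.
#' @param min_score_frac see [best_frame()].
#' @return data.frame `otu_id`, `frame`, `aa_seq`, `frameshift_flag`,
#'   `alignment_score_to_ref`.
#' @export
translate_representatives <- function(otu_set, ref_aa, ref_nt_panel = NULL,
                                      min_score_frac = 0.1) {
  res <- lapply(seq_len(nrow(otu_set$otus)), function(i) {
    nt <- otu_set$otus$representative[i]
    ref_nt <- NULL
    if (!is.null(ref_nt_panel)) {
      ident <- identity_vs_subject(ref_nt_panel, nt)
      ref_nt <- ref_nt_panel[[which.max(ident)]]
    }
    tr <- best_frame(nt, ref_aa, ref_nt = ref_nt,
                     min_score_frac = min_score_frac,
                     otu_id = otu_set$otus$otu_id[i])
    data.frame(otu_id = tr$otu_id, frame = tr$frame, aa_seq = tr$aa_seq,
               frameshift_flag = tr$frameshift_flag,
               alignment_score_to_ref = tr$alignment_score_to_ref,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
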