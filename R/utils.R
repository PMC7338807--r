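# internal helpers shared across modules

# 61 sense codons of the standard code, fixed order (used for seeded draws)
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# deterministic codon per amino acid: first sense codon in table order
codon_for_aa <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  cods <- names(gc)[gc != "*"]
  stats::setNames(cods, gc[cods])[aa]  # named-vector lookup keeps the first hit
}

translate_nt <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(nt, 1L, n)),
                                     if.fuzzy.codon = "solve"))
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

has_internal_stop <- function(aa) {
  if (nchar(aa) <= 1L) return(FALSE)
  grepl("\\*", substr(aa, 1L, nchar(aa) - 1L))
}

blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
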