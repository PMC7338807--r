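#' Read amplicon sequences from FASTA or FASTQ
#'
#' Sequences are uppercased and RNA-style `U` is normalised to `T`; record
#' order is preserved. An empty file yields a zero-row data.frame, not an
#' error; malformed records propagate a parse error naming the file.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @param sample_id sample the reads belong to (recorded per read).
#' @return data.frame `read_id`, `sample_id`, `nt_seq`, `quality`
#'   (Sanger-encoded string, `NA` for FASTA).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           sample_id = "sample1") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  if (file.size(path) == 0L)
    return(data.frame(read_id = character(), sample_id = character(),
                      nt_seq = character(), quality = character(),
                      stringsAsFactors = FALSE))
  if (format == "fastq") {
    # validate 4-line record structure up front: the backend reader does
    # not reliably reject quality strings shorter than the sequence
    lines <- readLines(path, warn = FALSE)
    if (length(lines) %% 4L == 0L &&
        all(startsWith(lines[seq(1L, length(lines), 4L)], "@"))) {
      seq_len_ok <- nchar(lines[seq(2L, length(lines), 4L)]) ==
        nchar(lines[seq(4L, length(lines), 4L)])
      if (!all(seq_len_ok))
        stop("FASTQ parse error in ", path,
             ": sequence/quality length mismatch at record ",
             which(!seq_len_ok)[1L], " (line ",
             (which(!seq_len_ok)[1L] - 1L) * 4L + 2L, ")", call. = FALSE)
    }
    parsed <- tryCatch({
      set <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
      q <- as.character(methods::slot(set, "quality"))
      if (any(nchar(q) != Biostrings::width(set)))
        stop("sequence/quality length mismatch")
      list(set = set, qual = q)
    }, error = function(e) stop("FASTQ parse error in ", path, ": ",
                                conditionMessage(e), call. = FALSE))
    set <- parsed$set
    qual <- parsed$qual
  } else {
    set <- tryCatch(
      Biostrings::readBStringSet(path),
      error = function(e) stop("FASTA parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    qual <- rep(NA_character_, length(set))
  }
  seqs <- chartr("u", "t", as.character(set))
  seqs <- chartr("U", "T", toupper(seqs))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate read ids in ", path, call. = FALSE)
  data.frame(read_id = ids, sample_id = sample_id, nt_seq = unname(seqs),
             quality = unname(qual), stringsAsFactors = FALSE)
}

#' Write reads as FASTA or FASTQ
#'
#' @param reads data.frame as returned by [read_sequences()] /
#'   [simulate_reads()].
#' @param path output file; format follows `format`.
#' @param format `"fasta"` or `"fastq"` (FASTQ requires a quality column).
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::DNAStringSet(stats::setNames(reads$nt_seq,
                                                    reads$read_id))
    Biostrings::writeXStringSet(set, path)
  } else {
    if (is.null(reads$quality) || anyNA(reads$quality))
      stop("FASTQ output needs per-read quality strings", call. = FALSE)
    set <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(stats::setNames(reads$nt_seq, reads$read_id)),
      Biostrings::PhredQuality(reads$quality))
    Biostrings::writeQualityScaledXStringSet(set, path)
  }
  invisible(path)
}

# TSV convention used across the package: one header row prefixed "#"
write_tsv_hash <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_tsv_hash <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("expected a '#'-prefixed header in ", path, call. = FALSE)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = cols, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  df
}

#' Write / read an OTU count table
#'
#' Orientation on disk: rows are OTUs, columns are samples (the common
#' amplicon convention); the single header row starts with `#`. Reading
#' back reproduces counts exactly.
#'
#' @param counts integer matrix, OTUs x samples, or a `community_table`.
#' @param path file path.
#' @return `write_otu_table`: `path` invisibly; `read_otu_table`: the
#'   counts matrix.
#' @export
write_otu_table <- function(counts, path) {
  if (inherits(counts, "community_table")) counts <- counts$counts
  df <- data.frame(otu_id = rownames(counts),
                   as.data.frame(counts, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_hash(df, path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  df <- read_tsv_hash(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read a phylogeny as newick
#'
#' Branch lengths are always written; bootstrap supports travel as integer
#' internal-node labels. Output is parseable by standard tree readers.
#'
#' @param tree an `ape::phylo`, optionally with `node.label` supports.
#' @param path file path.
#' @return `write_newick`: `path` invisibly; `read_newick`: an `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write / read a signature-site table
#'
#' TSV columns: `ref_pos`, `qnor_residue`, `nod_residues` (comma-joined).
#' `min_covered_sites` is carried in a `#!min_covered_sites=` pragma line.
#'
#' @param sig a [signature_table()].
#' @param path file path.
#' @return `write_signature_table`: `path` invisibly;
#'   `read_signature_table`: a `signature_table`.
#' @export
write_signature_table <- function(sig, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#!min_covered_sites=%d", sig$min_covered_sites), con)
  writeLines("#ref_pos\tqnor_residue\tnod_residues", con)
  df <- data.frame(sig$sites,
                   nod = vapply(sig$nod_residues, paste, "", collapse = ","))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_table
#' @export
read_signature_table <- function(path) {
  lines <- readLines(path)
  pragma <- grep("^#!min_covered_sites=", lines, value = TRUE)
  mcs <- if (length(pragma))
    as.integer(sub("^#!min_covered_sites=", "", pragma[1])) else 2L
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stop("empty signature table: ", path, call. = FALSE)
  parts <- strsplit(body, "\t", fixed = TRUE)
  signature_table(
    ref_pos = as.integer(vapply(parts, `[`, "", 1L)),
    qnor_residue = vapply(parts, `[`, "", 2L),
    nod_residues = lapply(parts, function(p)
      strsplit(p[3L], ",", fixed = TRUE)[[1]]),
    min_covered_sites = mcs)
}

#' Write a reference panel to a directory
#'
#' Emits paired FASTA (nucleotide amplicon region, protein), the cluster
#' label map as TSV, the numbering-reference protein, and the signature
#' table.
#'
#' @param panel a [make_reference_panel()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reference_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(panel$nt),
                              file.path(dir, "panel_nt.fasta"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(panel$aa),
                              file.path(dir, "panel_aa.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(c(numbering_ref = panel$numbering_ref)),
    file.path(dir, "numbering_ref_aa.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(numbering_ref = panel$numbering_ref_nt)),
    file.path(dir, "numbering_ref_nt.fasta"))
  write_tsv_hash(panel$entries, file.path(dir, "panel_labels.tsv"))
  write_signature_table(panel$signature, file.path(dir, "signature.tsv"))
  invisible(dir)
}

#' @rdname write_reference_panel
#' @export
read_reference_panel <- function(dir) {
  rd <- function(f) file.path(dir, f)
  nt <- Biostrings::readDNAStringSet(rd("panel_nt.fasta"))
  aa <- Biostrings::readAAStringSet(rd("panel_aa.fasta"))
  entries <- read_tsv_hash(rd("panel_labels.tsv"))
  ref_aa <- Biostrings::readAAStringSet(rd("numbering_ref_aa.fasta"))
  ref_nt <- Biostrings::readDNAStringSet(rd("numbering_ref_nt.fasta"))
  structure(list(entries = entries,
                 nt = stats::setNames(as.character(nt), names(nt)),
                 aa = stats::setNames(as.character(aa), names(aa)),
                 numbering_ref = unname(as.character(ref_aa)[1]),
                 numbering_ref_nt = unname(as.character(ref_nt)[1]),
                 amplicon_codons = NA_integer_,
                 signature = read_signature_table(rd("signature.tsv"))),
            class = "nod_reference_panel")
}

#' Write / read a qPCR table
#'
#' @param qpcr data.frame `sample_id`, `gene`, `copies_per_gram`.
#' @param path file path.
#' @return path invisibly / the data.frame.
#' @export
write_qpcr_table <- function(qpcr, path) write_tsv_hash(qpcr, path)

#' @rdname write_qpcr_table
#' @export
read_qpcr_table <- function(path) {
  df <- read_tsv_hash(path)
  stopifnot(all(c("sample_id", "gene", "copies_per_gram") %in% names(df)))
  if (anyDuplicated(df[c("sample_id", "gene")]))
    stop("one record per (sample, gene) expected in ", path, call. = FALSE)
  if (any(df$copies_per_gram <= 0))
    stop("copy numbers must be positive in ", path, call. = FALSE)
  df
}
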