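#' Default signature-site table for the synthetic qNor/Nod system
#'
#' Signature sites are alignment positions, numbered on a reference qNor
#' protein, whose conserved versus substituted state discriminates the
#' nitric oxide dismutase (Nod) lineages from conventional quinol-dependent
#' NO reductases (qNor): qNor carries the conserved quinol-binding /
#' catalytic residue, Nod a characteristic substitution.
#'
#' This table is a *synthetic placeholder*: the residue identities and
#' positions are generated to be internally consistent with
#' [make_reference_panel()], not transcribed from any published structure.
#' Users profiling real data must supply their own table (see
#' [read_signature_table()] and the blank template in
#' `inst/extdata/signature_template.tsv`).
#'
#' @param ref_pos 1-based residue positions on the reference qNor protein.
#' @param qnor_residue conserved qNor residue per site (single letters).
#' @param nod_residues list of character vectors: allowed Nod substitutions
#'   per site; must not contain the site's qNor residue.
#' @param min_covered_sites minimum number of covered signature sites needed
#'   before a protein is labelled at all (default 2; partial amplicons cover
#'   only part of the reference, so single-site calls are refused).
#' @return An object of class `signature_table`.
#' @export
signature_table <- function(ref_pos = c(160L, 285L, 390L, 470L),
                            qnor_residue = c("H", "E", "H", "F"),
                            nod_residues = list(c("N", "S"), c("Q", "V"),
                                                c("Y", "F"), "L"),
                            min_covered_sites = 2L) {
  ref_pos <- as.integer(ref_pos)
  if (is.unsorted(ref_pos, strictly = TRUE))
    stop("`ref_pos` must be strictly increasing", call. = FALSE)
  if (length(qnor_residue) != length(ref_pos) ||
      length(nod_residues) != length(ref_pos))
    stop("signature table columns must have equal length", call. = FALSE)
  for (i in seq_along(ref_pos)) {
    if (!nzchar(qnor_residue[i]) || nchar(qnor_residue[i]) != 1L)
      stop("qnor_residue entries must be single letters", call. = FALSE)
    if (length(nod_residues[[i]]) < 1L)
      stop("each site needs at least one nod residue", call. = FALSE)
    if (qnor_residue[i] %in% nod_residues[[i]])
      stop(sprintf("site %d: qNor residue may not be a Nod substitution",
                   ref_pos[i]), call. = FALSE)
  }
  stopifnot_scalar_number(min_covered_sites, "min_covered_sites", 1)
  structure(list(sites = data.frame(ref_pos = ref_pos,
                                    qnor_residue = qnor_residue,
                                    stringsAsFactors = FALSE),
                 nod_residues = nod_residues,
                 min_covered_sites = as.integer(min_covered_sites)),
            class = "signature_table")
}

#' @export
print.signature_table <- function(x, ...) {
  cat(sprintf("signature_table: %d sites (min %d covered for a call)\n",
              nrow(x$sites), x$min_covered_sites))
  df <- x$sites
  df$nod_residues <- vapply(x$nod_residues, paste, "", collapse = ",")
  print(df, row.names = FALSE)
  invisible(x)
}

# random sense-codon gene of `n_codons`, planted qNor residues at sig sites
random_gene <- function(n_codons, sig) {
  cods <- sample(sense_codons(), n_codons, replace = TRUE)
  cods[sig$sites$ref_pos] <- codon_for_aa(sig$sites$qnor_residue)
  paste(cods, collapse = "")
}

# codon-aware point mutation: expected per-site substitution fraction
# `divergence`; codons listed in `protect` (codon indices) and codons that
# would become stops are restored, so frame and signature residues survive.
mutate_codon_aware <- function(nt, divergence, protect = integer()) {
  if (divergence <= 0) return(nt)
  bases <- strsplit(nt, "")[[1]]
  hit <- which(stats::runif(length(bases)) < divergence)
  if (length(hit)) {
    alts <- c("A", "C", "G", "T")
    bases[hit] <- vapply(bases[hit],
                         function(b) sample(setdiff(alts, b), 1L), "")
  }
  mut <- paste(bases, collapse = "")
  n_cod <- nchar(nt) %/% 3L
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  cods <- substring(mut, starts, starts + 2L)
  orig <- substring(nt, starts, starts + 2L)
  bad <- Biostrings::GENETIC_CODE[cods] == "*"
  cods[bad | seq_len(n_cod) %in% protect] <-
    orig[bad | seq_len(n_cod) %in% protect]
  paste(cods, collapse = "")
}

# plant a target residue at given codon indices of an in-frame gene
plant_residues <- function(nt, codon_idx, aa) {
  bases <- strsplit(nt, "")[[1]]
  for (k in seq_along(codon_idx)) {
    i <- 3L * (codon_idx[k] - 1L) + 1L
    bases[i:(i + 2L)] <- strsplit(codon_for_aa(aa[k]), "")[[1]]
  }
  paste(bases, collapse = "")
}

#' Generate a labelled reference panel of nod-cluster and qNor sequences
#'
#' Builds a fully synthetic reference panel by descending a two-level
#' mutation tree from one random base gene: each named lineage (`Aquifer`,
#' `NC10`, `Reactor1`, `unknown_qNor`, `qNor_outgroup`) gets its own
#' ancestor at `between_divergence` expected substitutions per site from the
#' base, and `n_per_cluster` members at `within_divergence` from that
#' ancestor, so within-cluster nucleotide identity exceeds between-cluster
#' identity by construction. Signature codons and reading frame are
#' preserved throughout; nod-cluster members then receive Nod substitutions
#' at every signature site, qNor outgroup members the conserved qNor
#' residues, and `unknown_qNor` members the mixture selected by
#' `unknown_signature`.
#'
#' The first qNor outgroup ancestor's full-length protein is the numbering
#' authority for all residue positions; panel entries themselves are the
#' amplicon region only (codons `amplicon_codons[1]..amplicon_codons[2]`,
#' about 1.0 kb of nucleotide sequence), which is why downstream site
#' reports can contain uncovered signature sites.
#'
#' @param seed integer seed; the same seed reproduces the panel byte for
#'   byte.
#' @param n_per_cluster members per lineage (>= 1; default 4 so that the
#'   default community can derive every planted OTU from a distinct
#'   reference, which keeps the phylogenetic decision edges crisp).
#' @param sig a [signature_table()]; positions must lie on the full gene.
#' @param n_codons full reference gene length in codons.
#' @param amplicon_codons first and last codon of the amplified region.
#' @param between_divergence,within_divergence expected per-site nucleotide
#'   substitution fractions for cluster ancestors and members.
#' @param unknown_signature residues carried by the `unknown_qNor` lineage
#'   at signature sites: `"mixed"` (default; each site independently qNor or
#'   Nod), `"qnor"` or `"nod"`.
#' @return An object of class `nod_reference_panel`: `entries`
#'   (id, cluster_label), `nt`/`aa` named vectors over the amplicon region,
#'   `numbering_ref` (full reference qNor protein), `numbering_ref_nt`,
#'   `amplicon_codons`, and the `signature` table.
#' @export
make_reference_panel <- function(seed,
                                 n_per_cluster = 4L,
                                 sig = signature_table(),
                                 n_codons = 500L,
                                 amplicon_codons = c(101L, 433L),
                                 between_divergence = 0.20,
                                 within_divergence = 0.04,
                                 unknown_signature = c("mixed", "qnor", "nod")) {
  unknown_signature <- match.arg(unknown_signature)
  stopifnot_scalar_number(n_per_cluster, "n_per_cluster", 1)
  stopifnot_scalar_number(between_divergence, "between_divergence", 0, 0.5)
  stopifnot_scalar_number(within_divergence, "within_divergence", 0, 0.5)
  if (max(sig$sites$ref_pos) > n_codons)
    stop("signature positions exceed the reference gene", call. = FALSE)

  labels <- c("Aquifer", "NC10", "Reactor1", "unknown_qNor", "qNor_outgroup")
  withr::with_seed(seed, {
    base <- random_gene(n_codons, sig)
    protect <- sig$sites$ref_pos
    ancestors <- stats::setNames(
      vapply(labels, function(l) mutate_codon_aware(base, between_divergence,
                                                    protect), ""),
      labels)

    ids <- character(0); labs <- character(0); genes <- character(0)
    for (l in labels) {
      for (k in seq_len(n_per_cluster)) {
        g <- mutate_codon_aware(ancestors[[l]], within_divergence, protect)
        target <- switch(l,
          qNor_outgroup = sig$sites$qnor_residue,
          unknown_qNor = switch(unknown_signature,
            qnor = sig$sites$qnor_residue,
            nod = vapply(sig$nod_residues, function(s) sample(s, 1L), ""),
            mixed = mapply(function(q, s)
              if (stats::runif(1) < 0.5) q else sample(s, 1L),
              sig$sites$qnor_residue, sig$nod_residues)),
          # nod clusters: Aquifer / NC10 / Reactor1
          vapply(sig$nod_residues, function(s) sample(s, 1L), ""))
        g <- plant_residues(g, sig$sites$ref_pos, target)
        ids <- c(ids, sprintf("%s_%d", l, k))
        labs <- c(labs, l)
        genes <- c(genes, g)
      }
    }

    a0 <- 3L * (amplicon_codons[1] - 1L) + 1L
    a1 <- 3L * amplicon_codons[2]
    nt <- stats::setNames(substr(genes, a0, a1), ids)
    aa <- vapply(nt, translate_nt, "")
    if (any(grepl("\\*", aa)))
      stop("internal error: stop codon in panel amplicon", call. = FALSE)

    ref_full_nt <- plant_residues(ancestors[["qNor_outgroup"]],
                                  sig$sites$ref_pos, sig$sites$qnor_residue)
    structure(list(entries = data.frame(id = ids, cluster_label = labs,
                                        stringsAsFactors = FALSE),
                   nt = nt, aa = aa,
                   numbering_ref = translate_nt(ref_full_nt),
                   numbering_ref_nt = ref_full_nt,
                   amplicon_codons = as.integer(amplicon_codons),
                   signature = sig, seed = seed),
              class = "nod_reference_panel")
  })
}

#' @export
print.nod_reference_panel <- function(x, ...) {
  cat(sprintf("nod_reference_panel: %d entries, %d lineages, amplicon codons %d-%d\n",
              nrow(x$entries), length(unique(x$entries$cluster_label)),
              x$amplicon_codons[1], x$amplicon_codons[2]))
  print(table(x$entries$cluster_label))
  invisible(x)
}

#' Specify a synthetic amplicon community
#'
#' @param samples data.frame with columns `sample_id`, `habitat`
#'   (`"soil"` or `"sediment"`).
#' @param otus data.frame with columns `otu_id`, `source_ref_id` (a panel
#'   entry id), `divergence` (expected per-site nucleotide substitution
#'   fraction of the planted centroid from its source, in \[0, 0.5\]) and
#'   `is_nod` (logical; decides which signature residues the centroid
#'   carries).
#' @param abundance numeric matrix of expected read counts,
#'   samples x otus, dimnames matching `samples$sample_id` / `otus$otu_id`.
#' @param error_model named numeric vector `sub_rate`, `ins_rate`,
#'   `del_rate`, each in \[0, 0.2\]: per-base sequencing error rates applied
#'   to every read independently (CCS-like, frame-agnostic).
#' @param amplicon_window allowed centroid length range in nt.
#' @param seed integer seed driving read simulation.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(samples, otus, abundance,
                           error_model = c(sub_rate = 0.004,
                                           ins_rate = 0.003,
                                           del_rate = 0.003),
                           amplicon_window = c(800L, 1200L),
                           seed = 1L) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "habitat") %in% names(samples)),
            is.data.frame(otus),
            all(c("otu_id", "source_ref_id", "divergence", "is_nod") %in%
                  names(otus)))
  if (!all(samples$habitat %in% c("soil", "sediment")))
    stop("habitat must be 'soil' or 'sediment'", call. = FALSE)
  if (anyDuplicated(samples$sample_id) || anyDuplicated(otus$otu_id))
    stop("sample and OTU ids must be unique", call. = FALSE)
  for (r in c("sub_rate", "ins_rate", "del_rate"))
    stopifnot_scalar_number(error_model[[r]], r, 0, 0.2)
  if (any(otus$divergence < 0 | otus$divergence > 0.5))
    stop("divergence must lie in [0, 0.5]", call. = FALSE)
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("abundance must be >= 0", call. = FALSE)
  if (is.null(dimnames(abundance)))
    dimnames(abundance) <- list(samples$sample_id, otus$otu_id)
  stopifnot(identical(rownames(abundance), samples$sample_id),
            identical(colnames(abundance), otus$otu_id))
  structure(list(samples = samples, otus = otus, abundance = abundance,
                 error_model = error_model,
                 amplicon_window = as.integer(amplicon_window),
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Default synthetic community emulating the soil/sediment study design
#'
#' Eight samples (four fertilisation-regime soils, four lake sediments) and
#' eleven planted OTUs covering all reference lineages: habitat-specific and
#' shared nod OTUs (including one soil-only abundant OTU and one
#' sediment-dominant OTU derived from the unknown-qNor lineage that still
#' carries Nod signature residues — the "interpret with caution" case), one
#' qNor-like OTU, and one rare OTU whose expected total stays below the
#' 50-read OTU filter.
#'
#' @param panel a [make_reference_panel()] result; with fewer than 4
#'   members per lineage, source references are reused cyclically (OTUs
#'   sharing a source form star-like clades with weaker edge support).
#' @param seed seed stored in the spec (drives read simulation).
#' @param error_model per-base error rates; use all zeros for ground-truth
#'   recovery experiments.
#' @return A [community_spec()].
#' @export
default_community_spec <- function(panel, seed = 1L,
                                   error_model = c(sub_rate = 0.004,
                                                   ins_rate = 0.003,
                                                   del_rate = 0.003)) {
  samples <- data.frame(
    sample_id = c("CF", "CFstraw", "CFmanure", "control",
                  "Stechlin", "Dagow", "SW", "NE"),
    habitat = rep(c("soil", "sediment"), each = 4L),
    stringsAsFactors = FALSE)
  pick <- function(label, k) {
    ids <- panel$entries$id[panel$entries$cluster_label == label]
    ids[1L + (k - 1L) %% length(ids)]
  }
  otus <- data.frame(
    otu_id = c("aq_soilA", "aq_soilB", "aq_sed", "aq_shared", "nc_sed",
               "nc_soil", "re_lake", "uq462", "qn_bg", "rare"),
    source_ref_id = c(pick("Aquifer", 1), pick("Aquifer", 2),
                      pick("Aquifer", 3), pick("Aquifer", 4),
                      pick("NC10", 1), pick("NC10", 2),
                      pick("Reactor1", 1), pick("unknown_qNor", 1),
                      pick("qNor_outgroup", 1), pick("Aquifer", 1)),
    divergence = c(0.08, 0.08, 0.08, 0.08, 0.08, 0.08, 0.06, 0.06, 0.06, 0.14),
    is_nod = c(rep(TRUE, 8L), FALSE, TRUE),
    stringsAsFactors = FALSE)
  soil <- samples$habitat == "soil"
  ab <- matrix(0, nrow(samples), nrow(otus),
               dimnames = list(samples$sample_id, otus$otu_id))
  ab[soil, "aq_soilA"] <- 250   # abundant in every soil, absent in lakes
  ab[soil, "aq_soilB"] <- 100
  ab[!soil, "aq_sed"] <- 150
  ab[, "aq_shared"] <- 80
  ab[!soil, "nc_sed"] <- 100
  ab[soil, "nc_soil"] <- 90
  ab[c("Stechlin", "Dagow"), "re_lake"] <- 60
  ab[c("SW", "NE"), "uq462"] <- 200
  ab[, "qn_bg"] <- 70
  ab[, "rare"] <- 4             # expected total 32 < min_size 50
  community_spec(samples, otus, ab, error_model = error_model, seed = seed)
}

# per-read error process: deletions, then substitutions, then insertions
apply_read_errors <- function(seq, sub, ins, del) {
  b <- strsplit(seq, "")[[1]]
  if (del > 0) b <- b[stats::runif(length(b)) >= del]
  n <- length(b)
  if (n == 0L) return("")
  if (sub > 0) {
    hit <- which(stats::runif(n) < sub)
    if (length(hit)) {
      alts <- c("A", "C", "G", "T")
      b[hit] <- vapply(b[hit], function(x) sample(setdiff(alts, x), 1L), "")
    }
  }
  if (ins > 0) {
    insmask <- stats::runif(n) < ins
    if (any(insmask)) {
      out <- vector("list", n)
      newb <- sample(c("A", "C", "G", "T"), sum(insmask), replace = TRUE)
      j <- 0L
      for (i in seq_len(n)) {
        if (insmask[i]) { j <- j + 1L; out[[i]] <- c(newb[j], b[i]) }
        else out[[i]] <- b[i]
      }
      b <- unlist(out)
    }
  }
  paste(b, collapse = "")
}

#' Simulate long-read amplicon sets with a planted ground truth
#'
#' Per planted OTU, a centroid is derived from its source panel entry by
#' codon-aware mutation at the spec's divergence (frame and signature codons
#' preserved), after which the signature residues are set according to
#' `is_nod`. Read counts per (sample, OTU) are Poisson with the spec's
#' expectation; each read is the centroid passed through the per-base
#' substitution/insertion/deletion error model (which may break the reading
#' frame, as real CCS errors do). Every emitted read id is recorded in the
#' truth manifest.
#'
#' @param spec a [community_spec()].
#' @param panel a [make_reference_panel()] result supplying the source
#'   sequences.
#' @return list with `reads` (data.frame: read_id, sample_id, nt_seq,
#'   quality), `truth` (read_id, sample_id, otu_id, source_ref_id,
#'   cluster_label, is_nod), `centroids` (named nt vector) and
#'   `centroid_truth` (per-OTU metadata).
#' @export
simulate_reads <- function(spec, panel) {
  stopifnot(inherits(spec, "community_spec"),
            inherits(panel, "nod_reference_panel"))
  missing_ref <- setdiff(spec$otus$source_ref_id, panel$entries$id)
  if (length(missing_ref))
    stop("unknown source_ref_id: ", paste(missing_ref, collapse = ", "),
         call. = FALSE)

  sig <- panel$signature
  off <- panel$amplicon_codons[1] - 1L
  sig_local <- sig$sites$ref_pos - off
  sig_local <- sig_local[sig_local >= 1L &
                           sig$sites$ref_pos <= panel$amplicon_codons[2]]
  in_amp <- sig$sites$ref_pos - off >= 1L &
    sig$sites$ref_pos <= panel$amplicon_codons[2]

  withr::with_seed(spec$seed, {
    centroids <- character(nrow(spec$otus))
    for (i in seq_len(nrow(spec$otus))) {
      src <- panel$nt[[spec$otus$source_ref_id[i]]]
      g <- mutate_codon_aware(src, spec$otus$divergence[i],
                              protect = sig_local)
      aa_now <- translate_nt(g)
      current <- substring(aa_now, sig_local, sig_local)
      allowed <- if (spec$otus$is_nod[i]) sig$nod_residues[in_amp]
        else as.list(sig$sites$qnor_residue[in_amp])
      # keep the inherited residue when it already satisfies is_nod;
      # otherwise plant one (zero divergence from a compliant source is
      # then the identity)
      target <- vapply(seq_along(current), function(k)
        if (current[k] %in% allowed[[k]]) current[k]
        else sample(allowed[[k]], 1L), "")
      centroids[i] <- plant_residues(g, sig_local, target)
    }
    names(centroids) <- spec$otus$otu_id
    lens <- nchar(centroids)
    if (any(lens < spec$amplicon_window[1] | lens > spec$amplicon_window[2]))
      stop("centroid length outside amplicon window", call. = FALSE)

    em <- spec$error_model
    rows <- list(); truths <- list(); k <- 0L
    for (s in spec$samples$sample_id) {
      cnt <- 0L
      for (o in spec$otus$otu_id) {
        n <- stats::rpois(1L, spec$abundance[s, o])
        if (n == 0L) next
        seqs <- vapply(seq_len(n), function(.)
          apply_read_errors(centroids[[o]], em[["sub_rate"]],
                            em[["ins_rate"]], em[["del_rate"]]), "")
        ids <- sprintf("%s_read%05d", s, cnt + seq_len(n))
        cnt <- cnt + n
        qual <- vapply(nchar(seqs), function(L)
          rawToChar(as.raw(33L + sample(25:40, L, replace = TRUE))), "")
        k <- k + 1L
        rows[[k]] <- data.frame(read_id = ids, sample_id = s, nt_seq = seqs,
                                quality = qual, stringsAsFactors = FALSE)
        src <- spec$otus$source_ref_id[spec$otus$otu_id == o]
        truths[[k]] <- data.frame(
          read_id = ids, sample_id = s, otu_id = o, source_ref_id = src,
          cluster_label = panel$entries$cluster_label[panel$entries$id == src],
          is_nod = spec$otus$is_nod[spec$otus$otu_id == o],
          stringsAsFactors = FALSE)
      }
    }
    reads <- do.call(rbind, rows) %||% data.frame(
      read_id = character(), sample_id = character(), nt_seq = character(),
      quality = character(), stringsAsFactors = FALSE)
    truth <- do.call(rbind, truths) %||% data.frame()
    rownames(reads) <- rownames(truth) <- NULL
    list(reads = reads, truth = truth, centroids = centroids,
         centroid_truth = data.frame(
           otu_id = spec$otus$otu_id,
           source_ref_id = spec$otus$source_ref_id,
           cluster_label = panel$entries$cluster_label[
             match(spec$otus$source_ref_id, panel$entries$id)],
           is_nod = spec$otus$is_nod, stringsAsFactors = FALSE))
  })
}

#' Simulate a qPCR table of 16S rRNA and nod gene copy numbers
#'
#' Per sample, total-bacteria 16S copies per gram are drawn log-uniformly
#' within `sixteenS_range`; nod copies are `fraction * 16S` with
#' multiplicative lognormal noise of standard deviation `sigma` (on the log
#' scale). Default fractions are habitat-typical: soils around 1-1.3% of
#' total bacteria, sediments 0.4-3%.
#'
#' @param spec a [community_spec()] (supplies samples, habitats and seed).
#' @param nod_fraction_by_sample optional named numeric vector of nod/16S
#'   fractions in (0, 1); defaults drawn per habitat as above.
#' @param sixteenS_range range of 16S copies per gram (log-uniform draw).
#' @param sigma lognormal noise sd; 0 gives the exact product.
#' @param seed defaults to `spec$seed + 1000`.
#' @return data.frame `sample_id`, `gene` (`"nod"`/`"16S"`),
#'   `copies_per_gram`.
#' @export
simulate_qpcr <- function(spec, nod_fraction_by_sample = NULL,
                          sixteenS_range = c(1e8, 1e10), sigma = 0.1,
                          seed = spec$seed + 1000L) {
  stopifnot(inherits(spec, "community_spec"))
  withr::with_seed(seed, {
    ids <- spec$samples$sample_id
    if (is.null(nod_fraction_by_sample)) {
      soil <- spec$samples$habitat == "soil"
      nod_fraction_by_sample <- stats::setNames(numeric(length(ids)), ids)
      nod_fraction_by_sample[soil] <- stats::runif(sum(soil), 0.010, 0.013)
      nod_fraction_by_sample[!soil] <- stats::runif(sum(!soil), 0.004, 0.030)
    }
    frac <- nod_fraction_by_sample[ids]
    if (any(is.na(frac)) || any(frac <= 0) || any(frac >= 1))
      stop("nod fractions must be given for every sample and lie in (0,1)",
           call. = FALSE)
    s16 <- exp(stats::runif(length(ids), log(sixteenS_range[1]),
                            log(sixteenS_range[2])))
    noise <- if (sigma > 0) exp(stats::rnorm(length(ids), 0, sigma)) else 1
    data.frame(sample_id = rep(ids, 2L),
               gene = rep(c("16S", "nod"), each = length(ids)),
               copies_per_gram = c(s16, frac * s16 * noise),
               stringsAsFactors = FALSE)
  })
}
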