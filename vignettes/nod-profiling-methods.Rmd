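---
title: "Methods: profiling oxygenic denitrifiers from long-read nod amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling oxygenic denitrifiers from long-read nod amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Oxygenic denitrification is a proposed nitrogen-transforming process in
which nitric oxide is disproportionated directly into N~2~ and O~2~ by a
nitric oxide dismutase (Nod), bypassing N~2~O. The *nod* gene is the marker
for this guild, but it is a close homolog of the gene for quinol-dependent
nitric oxide reductase (qNor), a conventional denitrification enzyme.
Telling the two apart in environmental amplicon data therefore needs two
independent lines of evidence:

1. **Signature residues.** qNor's quinol-binding and catalytic residues are
   conserved in true qNor sequences; Nod lineages carry characteristic
   substitutions at those positions. Residue positions are numbered on a
   reference qNor protein.
2. **Phylogeny.** Environmental *nod* sequences fall into named lineages
   (the Aquifer, NC10 and Reactor clusters), distinct from qNor and from a
   set of "unknown-qNor-related" sequences of unresolved function.

Neither line is sufficient on its own: a sequence that sits among the
unknown-qNor relatives in the tree yet carries Nod-type substitutions
cannot be functionally resolved and is reported as a *candidate* that must
be interpreted with caution. This joint decision rule is the analytical
core of the package.

`nodprofiler` implements the complete workflow for ~1.0 kb *nod* amplicons
from environmental samples: greedy centroid OTU clustering at 90%
nucleotide identity with a 50-read size floor, frame recovery and
translation of OTU representatives, signature-site classification against
qNor numbering, a bootstrapped neighbor-joining phylogeny with clade-based
cluster assignment, and community statistics (relative abundances,
qPCR-scaled abundances, ordination, habitat specificity). Because no public
read set accompanies the study design this reproduces, a seeded synthetic
community generator with a planted ground truth is a first-class module:
every downstream stage is validated by parameter recovery on data whose
answer is known by construction.

## The synthetic community generator

`make_reference_panel()` descends a two-level mutation tree from one random
in-frame gene (500 codons, no internal stops): each lineage gets an
ancestor at an expected 0.20 substitutions per site from the base, and
members at 0.04 from their ancestor, so within-lineage identity exceeds
between-lineage identity by construction. Panel mutations are codon-aware
(stops and signature codons are never touched), which separates
*biological divergence* (frame-preserving) from *sequencing error*
(frame-agnostic) — the distinction the frame-recovery stage must tolerate.
The amplified region is codons 101–433 (999 nt), emulating a partial
amplicon on a full-length reference: one shipped signature site (position
470) deliberately falls outside it, so uncovered-site handling is always
exercised. The resulting Nod-vs-qNor amino-acid identity is roughly 40–50%,
which we consider the realistic difficulty for this marker; the
signature-site table itself is a documented synthetic placeholder (the
residues are planted, not curated biology), and users of real data must
supply their own table (`inst/extdata/signature_template.tsv`).

`default_community_spec()` mirrors a two-habitat design: four
fertilisation-regime soils (CF, CF+straw, CF+manure, control) and four lake
sediments (Stechlin, Dagow, SW, NE). Ten OTUs are planted with expected
per-sample read counts of 60–250: a soil-only abundant OTU, habitat-specific
and shared OTUs across the Aquifer/NC10/Reactor1 lineages, one
qNor-outgroup-derived OTU, one OTU derived from the unknown-qNor lineage
that nevertheless carries Nod residues (the *candidate* case), and one rare
OTU whose expected total (32 reads) stays below the 50-read filter. Each
planted OTU derives from a *distinct* panel reference (hence the panel
default of four members per lineage): two OTUs hanging off the same
reference form a star-like clade whose internal edges have no signal, and
no clustering rule can be expected to resolve a star. Read counts are
Poisson; read errors are per-base substitutions/insertions/deletions at
CCS-like defaults (0.004/0.003/0.003), all driven by one explicit seed.
qPCR tables draw 16S copies log-uniformly (soils constrained to the
10^8^–10^9^ decade) and set *nod* copies as a habitat-typical fraction
(soils 1.0–1.3%, sediments 0.4–3.0%) with multiplicative lognormal noise
(σ = 0.1).

What the generator does **not** emulate: PacBio instrument physics
(polymerase passes, quality-error correlation), chimeras, primer-site
variation, truncated amplicons, and contaminant (non-*nod*) reads. Passing
tests on this generator therefore demonstrate correctness of the
*computational* pipeline under its stated error model, not robustness to
every artefact of real sequencing runs.

## OTU clustering

Reads are length-filtered to 800–1200 nt (the configurable stand-in for
read QC), dereplicated exactly, and scanned in abundance order (ties:
longer sequence first, then smallest read id — every ordering rule in the
package is written down so results are bit-reproducible). A sequence joins
the first existing centroid with pairwise identity at or above the
threshold (0.90, inclusive), else founds a new centroid; centroids never
move. Identity is matching columns over the full global alignment length
*including end gaps* (match +1, mismatch −1, gap open 2, extend 1) — the
strictest common convention, chosen and stated because "percent similarity"
alone underdetermines the denominator. OTUs below 50 reads are dropped and
the survivors renamed `OTU1..k` by descending size. There is no
denoising/polishing stage: representatives are raw reads, and at ~1% read
error most representatives carry indels. The frameshift flag (below) exists
precisely to carry that information downstream instead of silently dropping
diversity.

## Frame recovery and the frameshift flag

All six frame translations are scored by local BLOSUM62 alignment (open 11
/ extend 1) against the reference qNor protein; the best frame wins, ties
resolved in frame order 1, 2, 3, −1, −2, −3. The flag for a disrupted frame
is raised by any of:

* an internal stop codon in the chosen translation;
* a score below 0.1 of the reference self-score scaled by the fraction of
  the reference the amplicon can cover. The 0.1 floor is calibrated from
  the score distributions on the synthetic panel: correct-frame homologs at
  ~40–45% amino-acid identity score 0.12–0.19 of the coverable self-score,
  wrong-frame translations 0.02–0.04, so 0.1 cleanly separates the two
  populations while staying conservative for more diverged homologs;
* with a frame-preserving nucleotide reference available (the pipeline
  passes each representative's nearest panel sequence), a length offset to
  that reference that is not a multiple of 3. Amplicons are primer-to-primer
  products, so length is informative; this catches the frameshifts the
  other two signals miss, namely indels within the last few codons that
  neither create a stop nor dent the alignment score.

Flagged representatives are carried through classification, never dropped.

## Signature classification

Numbering transfer is the fragile step at 40–50% amino-acid identity: a
single pairwise query-to-reference alignment occasionally slips by one
residue around a signature site. The package therefore transfers numbering
through a *multiple* protein alignment: queries, the reference panel
proteins and the numbering reference are aligned together (progressive
profile alignment, BLOSUM62, gap open 10 / extend 0.5), and positions are
read off the reference row. The conserved columns contributed by the panel
anchor the reference placement — the same construction as the classical
ClustalW alignment figures this module reproduces. The pairwise route
(`align_to_reference()` + `map_numbering()`) remains available and is used
when no anchors are supplied; it performs end-gap-free (overlap) global
alignment because a partial amplicon on a full-length reference must leave
reference overhangs unaligned — penalised end gaps would smear query
residues across the overhang and fabricate observations at sites outside
the amplified region.

Per site the call is `uncovered` (gap or outside the aligned span),
`conserved` (the qNor residue), `nod_substitution` (in the site's allowed
set) or `other_substitution`. The protein label is a pure function of the
calls: fewer than `min_covered_sites` (default 2 — partial amplicons are
classifiable, single-site calls are not) covered sites gives `uncovered`;
all covered sites Nod-substituted gives `nod_type`; all conserved gives
`qnor_type`; any mixture gives `ambiguous`. `other_substitution` never
counts toward `nod_type`: an unknown residue at a catalytic position is not
evidence of dismutase function.

## Phylogeny and cluster assignment

OTU representatives and panel references are aligned by deterministic
progressive profile alignment (guide tree from average-linkage clustering
of pairwise identity distances; profile merges use the clustering scoring
with affine gaps, implemented once in C++ and shared by the nucleotide and
protein front ends). Distances are p-distances over columns where both rows
are non-gap — matching the convention of reporting "% nucleotide
divergence" — with a Jukes–Cantor-free default kept deliberately simple;
pairs sharing fewer than 50 comparable columns are flagged and set to the
maximum observed distance + 0.01 so they can never look artificially close.

Neighbor joining follows the Saitou–Nei Q-criterion with two stated
determinism rules: ties in Q break toward the lexicographically smallest
pair of taxon ids (an internal node carries its subtree's smallest leaf
id), and negative branch-length estimates are clamped to zero with the
deficit moved to the sister edge, preserving the pair's joint path length.
Additive matrices are recovered exactly (tested against a four-point-
condition oracle and an independent NJ implementation). Bootstrap supports
resample alignment columns with replacement; an internal edge's support is
the percentage of replicate trees containing the same label-canonicalised
bipartition. 1000 replicates is the publication-grade setting; tests and
the acceptance script use 200, which bounds the Monte-Carlo standard error
of a true ~100% support well below the 95% check threshold.

Cluster assignment is an explicit, testable stand-in for reading clades off
a figure: for each OTU, the smallest edge-induced bipartition side
containing the OTU and at least one reference decides; if all references in
it share one label and the edge's support is ≥ 50 (inclusive — displayed
supports are conventionally "> 50%", a decision rule needs a closed
boundary), the OTU takes that cluster, else it is `unassigned`. The
reported cluster is the reference label itself, including `qNor_outgroup`
(the label set would otherwise be unable to express an OTU that is
phylogenetically plain qNor). The joint final call: nod-cluster +
`nod_type` → `nod`; qNor-related cluster + `qnor_type` → `qnor_like`;
`unknown_qNor` + `nod_type` → `candidate`; everything else →
`undetermined`.

## Community statistics

Relative abundances are per-sample fractions (all-zero samples flagged, not
silently renormalised). qPCR normalisation reports *nod* copies as a
percentage of 16S copies and is homogeneous of degree zero. Ordination is
PCA of column-centred relative abundances without unit scaling or a
Hellinger transform — "occurrence and relative abundance" is the stated
input and the default stays closest to it; the transform choice is exposed
to the caller by passing any transformed matrix. The sign of each component
is fixed by making the largest-magnitude loading positive, so coordinates
do not depend on OTU column order. Habitat specificity is exact: an OTU is
habitat-specific iff all its nonzero counts fall in one habitat.
Habitat separation is summarised as the mean silhouette of habitats on
(PC1, PC2).

## Numerical and degenerate-input choices

* Every stochastic step takes an explicit seed; one run seed fans out to
  stages by fixed offsets, and reruns are byte-identical (the run manifest
  contains no timestamps for this reason).
* Empty inputs degrade, they do not crash: an empty FASTA yields zero
  reads; no surviving OTU yields a warning and an empty community; a
  missing qPCR table downgrades the community stage to relative abundances
  with a warning.
* Branch lengths are written with 10 significant digits; newick round-trips
  preserve counts exactly and lengths to 6 decimals.
* `which.max` tie behaviour (first maximum) is relied on only where the
  surrounding order is itself specified.

## Problem sizes

The bundled analyses run at desk scale, chosen to exercise every code path
rather than to reach survey depth: panels of 20 references, communities of
~1000–5000 reads over 8 samples, trees of ~30 leaves, bootstrap B = 200.
The zero-error fixture used for parameter-recovery checks recovers 9 of 10
planted OTUs (the tenth is planted below the size filter on purpose), with
100% signature-label, cluster and final-call accuracy and a positive
habitat silhouette; these are the quantities `scripts/acceptance.R`
recomputes from scratch.

## Known limitations

* No denoising/consensus polishing: at realistic CCS error rates most OTU
  representatives are flagged as frame-disrupted and signature labels on
  raw noisy representatives degrade toward `ambiguous`/`uncovered`. The
  flags make this visible; fixing it (e.g. per-OTU consensus calling or a
  frameshift-correcting protein-guided aligner) is future work.
* The shipped signature table is synthetic. Conclusions about real
  sequences require a user-curated table on a real qNor numbering.
* p-distances are uncorrected; deep-branch attraction at high divergence is
  mitigated only by the reference panel's density.
* The clade-assignment rule intentionally refuses weakly supported
  placements rather than guessing; sparse reference panels will therefore
  produce `unassigned` OTUs.
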