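test_that("reference panel construction honours its invariants", {
  panel <- make_reference_panel(seed = 1, n_per_cluster = 2)
  expect_s3_class(panel, "nod_reference_panel")
  expect_equal(nrow(panel$entries), 10L)
  expect_setequal(unique(panel$entries$cluster_label),
                  c("Aquifer", "NC10", "Reactor1", "unknown_qNor",
                    "qNor_outgroup"))
  expect_false(anyDuplicated(panel$entries$id) > 0)
  # aa is the frame-1 translation of nt, stop-free
  expect_identical(unname(vapply(panel$nt, nodprofiler:::translate_nt, "")),
                   unname(panel$aa))
  expect_false(any(grepl("\\*", panel$aa)))
})

test_that("panel generation is deterministic and seed-sensitive", {
  p1 <- make_reference_panel(seed = 3, n_per_cluster = 2)
  p2 <- make_reference_panel(seed = 3, n_per_cluster = 2)
  p3 <- make_reference_panel(seed = 4, n_per_cluster = 2)
  expect_identical(p1$nt, p2$nt)
  expect_identical(p1$numbering_ref, p2$numbering_ref)
  expect_false(identical(p1$nt, p3$nt))
})

test_that("signature residues are planted as labelled", {
  panel <- make_reference_panel(seed = 5, n_per_cluster = 3)
  sig <- panel$signature
  off <- panel$amplicon_codons[1] - 1L
  covered <- sig$sites$ref_pos[sig$sites$ref_pos > off &
                                 sig$sites$ref_pos <= panel$amplicon_codons[2]]
  for (i in seq_len(nrow(panel$entries))) {
    aa <- panel$aa[[i]]
    lab <- panel$entries$cluster_label[i]
    for (k in seq_along(covered)) {
      site_i <- match(covered[k], sig$sites$ref_pos)
      obs <- substr(aa, covered[k] - off, covered[k] - off)
      if (lab %in% c("Aquifer", "NC10", "Reactor1"))
        expect_true(obs %in% sig$nod_residues[[site_i]])
      if (lab == "qNor_outgroup")
        expect_identical(obs, sig$sites$qnor_residue[site_i])
    }
  }
  # numbering reference carries the conserved residue at every site
  for (i in seq_len(nrow(sig$sites)))
    expect_identical(substr(panel$numbering_ref, sig$sites$ref_pos[i],
                            sig$sites$ref_pos[i]),
                     sig$sites$qnor_residue[i])
})

test_that("within-cluster identity exceeds between-cluster identity", {
  panel <- make_reference_panel(seed = 6, n_per_cluster = 2)
  labs <- panel$entries$cluster_label
  n <- length(panel$nt)
  within <- c(); between <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    id <- pairwise_identity(panel$nt[[i]], panel$nt[[j]])
    if (labs[i] == labs[j]) within <- c(within, id)
    else between <- c(between, id)
  }
  expect_gt(min(within), max(between))
})

test_that("zero-error reads are exact centroid copies with Poisson counts", {
  panel <- make_reference_panel(seed = 2, n_per_cluster = 1)
  spec <- community_spec(
    samples = data.frame(sample_id = "s1", habitat = "soil"),
    otus = data.frame(otu_id = "o1",
                      source_ref_id = panel$entries$id[1],
                      divergence = 0, is_nod = TRUE),
    abundance = matrix(50, 1, 1, dimnames = list("s1", "o1")),
    error_model = c(sub_rate = 0, ins_rate = 0, del_rate = 0),
    seed = 9)
  sim <- simulate_reads(spec, panel)
  expect_true(all(sim$reads$nt_seq == sim$centroids[["o1"]]))
  expect_gt(nrow(sim$reads), 20)   # Poisson(50), far from 0
  expect_lt(nrow(sim$reads), 90)
  # truth manifest is total over read ids
  expect_setequal(sim$truth$read_id, sim$reads$read_id)
  # zero divergence: centroid equals the source reference exactly
  expect_identical(sim$centroids[["o1"]], unname(panel$nt[1]))
})

test_that("deletions in the error model produce frameshifted reads", {
  panel <- make_reference_panel(seed = 2, n_per_cluster = 1)
  spec <- community_spec(
    samples = data.frame(sample_id = "s1", habitat = "soil"),
    otus = data.frame(otu_id = "o1", source_ref_id = panel$entries$id[1],
                      divergence = 0, is_nod = TRUE),
    abundance = matrix(40, 1, 1, dimnames = list("s1", "o1")),
    error_model = c(sub_rate = 0, ins_rate = 0, del_rate = 0.01),
    seed = 10)
  sim <- simulate_reads(spec, panel)
  shifted <- nchar(sim$reads$nt_seq) %% 3L != nchar(sim$centroids[["o1"]]) %% 3L
  expect_gt(sum(shifted), 0)
  aa <- vapply(sim$reads$nt_seq[shifted], nodprofiler:::translate_nt, "")
  expect_true(any(grepl("\\*", aa)))
})

test_that("read simulation is reproducible for a fixed seed", {
  panel <- make_reference_panel(seed = 4, n_per_cluster = 2)
  spec <- default_community_spec(panel, seed = 21)
  s1 <- simulate_reads(spec, panel)
  s2 <- simulate_reads(spec, panel)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("unknown source reference ids are reported by name", {
  panel <- make_reference_panel(seed = 2, n_per_cluster = 1)
  spec <- community_spec(
    samples = data.frame(sample_id = "s1", habitat = "soil"),
    otus = data.frame(otu_id = "o1", source_ref_id = "nope_1",
                      divergence = 0, is_nod = TRUE),
    abundance = matrix(10, 1, 1, dimnames = list("s1", "o1")), seed = 1)
  expect_error(simulate_reads(spec, panel), "nope_1")
})

test_that("qPCR simulation has the stated closed form at sigma = 0", {
  panel <- make_reference_panel(seed = 2, n_per_cluster = 1)
  spec <- default_community_spec(panel, seed = 30)
  frac <- stats::setNames(rep(0.01, 8),
                          spec$samples$sample_id)
  q <- simulate_qpcr(spec, nod_fraction_by_sample = frac, sigma = 0)
  s16 <- q$copies_per_gram[q$gene == "16S"]
  nod <- q$copies_per_gram[q$gene == "nod"]
  expect_equal(nod, 0.01 * s16, tolerance = 1e-12)
  # determinism
  q2 <- simulate_qpcr(spec, nod_fraction_by_sample = frac, sigma = 0)
  expect_identical(q, q2)
})

test_that("default qPCR fractions land in habitat-typical ranges", {
  panel <- make_reference_panel(seed = 2, n_per_cluster = 1)
  spec <- default_community_spec(panel, seed = 31)
  q <- simulate_qpcr(spec, sigma = 0)
  wide <- merge(q[q$gene == "nod", c("sample_id", "copies_per_gram")],
                q[q$gene == "16S", c("sample_id", "copies_per_gram")],
                by = "sample_id", suffixes = c("_nod", "_16S"))
  pct <- qpcr_fraction(wide$copies_per_gram_nod, wide$copies_per_gram_16S)
  hab <- spec$samples$habitat[match(wide$sample_id, spec$samples$sample_id)]
  expect_true(all(pct[hab == "soil"] >= 1.0 & pct[hab == "soil"] <= 1.3))
  expect_true(all(pct[hab == "sediment"] >= 0.4 &
                    pct[hab == "sediment"] <= 3.0))
})
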