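test_that("identical sequences align gap-free", {
  seqs <- stats::setNames(rep("ACGTACGTACGT", 4), paste0("t", 1:4))
  msa <- align_representatives(seqs)
  expect_true(all(nchar(msa) == 12L))
  expect_false(any(grepl("-", msa)))
})

test_that("progressive alignment places a planted insertion as one gap block", {
  base <- "ACGTTGCAACGT"
  with_ins <- paste0(substr(base, 1, 6), "GGG", substr(base, 7, 12))
  seqs <- c(a = base, b = base, c = base, d = with_ins)
  msa <- align_representatives(seqs)
  expect_equal(nchar(msa[["a"]]), 15L)
  expect_equal(msa[["d"]], with_ins)
  expect_equal(gsub("-", "", msa[["a"]]), base)
  # the three unmodified rows are identical
  expect_equal(msa[["a"]], msa[["b"]])
  expect_equal(msa[["a"]], msa[["c"]])
})

test_that("alignment sum-of-pairs score is invariant to input order", {
  withr::local_seed(81)
  base <- rand_dna(60)
  seqs <- c(s1 = base, s2 = mutate_subs(base, 4),
            s3 = mutate_subs(base, 14), s4 = mutate_subs(base, 15))
  sp_score <- function(msa) {
    chm <- do.call(rbind, strsplit(unclass(msa), ""))
    tot <- 0
    for (i in 1:(nrow(chm) - 1)) for (j in (i + 1):nrow(chm)) {
      ok <- chm[i, ] != "-" & chm[j, ] != "-"
      tot <- tot + sum(chm[i, ok] == chm[j, ok]) - sum(chm[i, ok] != chm[j, ok])
    }
    tot
  }
  m1 <- align_representatives(seqs)
  m2 <- align_representatives(seqs[c(3, 1, 4, 2)])
  expect_equal(sp_score(m1), sp_score(m2))
  expect_lt(nchar(m1[[1]]), 66)   # no runaway gapping
})

test_that("p-distance counts differences over comparable columns", {
  msa <- structure(c(a = "ACGTACGTAC", b = "ACGTACGTAA",
                     c = "ACGTACGTAC"), class = "nt_msa")
  d <- p_distance(msa, min_comparable = 5)
  expect_equal(d["a", "b"], 0.1)
  expect_equal(d["a", "c"], 0.0)
  expect_equal(d, t(d), ignore_attr = TRUE)
  # gapped columns are excluded from the denominator
  msa2 <- structure(c(a = "AC-TACGTAC", b = "ACGTACGTAA"), class = "nt_msa")
  d2 <- p_distance(msa2, min_comparable = 5)
  expect_equal(d2["a", "b"], 1 / 9)
})

test_that("low-overlap pairs are flagged and pushed to the maximum", {
  msa <- structure(c(a = "ACGT------", b = "------ACGT",
                     c = "ACGTACGTAC", d = "ACGAACGTAC"), class = "nt_msa")
  d <- p_distance(msa, min_comparable = 2)
  expect_true(attr(d, "flagged")["a", "b"])
  expect_gte(d["a", "b"], max(d["c", "d"], d["a", "c"]))
})

test_that("neighbor joining recovers the worked 4-taxon additive tree", {
  # tree ((A:1,B:2):1,(C:3,D:4)) gives the classic additive matrix
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- neighbor_joining(D)
  # four-point condition picks AB|CD; path lengths must reproduce D exactly
  expect_equal(unname(ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]),
               unname(D), tolerance = 1e-9)
  split_ab <- ape::prop.part(tree)
  sides <- lapply(split_ab, function(p) sort(tree$tip.label[p]))
  expect_true(list(c("C", "D")) %in% sides || list(c("A", "B")) %in% sides)
})

test_that("neighbor joining is exact on random additive matrices", {
  withr::local_seed(82)
  for (n in c(4, 5, 6)) {
    for (rep in 1:10) {
      true <- ape::rtree(n, br = function(k) stats::runif(k, 0.2, 1.5))
      D <- ape::cophenetic.phylo(true)
      D <- D[sort(rownames(D)), sort(rownames(D))]
      tree <- neighbor_joining(D)
      expect_equal(unname(ape::cophenetic.phylo(tree)[rownames(D), rownames(D)]),
                   unname(D), tolerance = 1e-8)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), tree)), 0)
    }
  }
})

test_that("neighbor joining matches the reference implementation off-additivity", {
  withr::local_seed(83)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    base <- rand_dna(300)
    seqs <- vapply(1:n, function(i) mutate_subs(base, sample(10:60, 1)), "")
    names(seqs) <- paste0("t", 1:n)
    msa <- structure(seqs, class = "nt_msa")   # equal lengths, no gaps
    D <- p_distance(msa)
    mine <- neighbor_joining(D)
    ref <- ape::nj(stats::as.dist(D))
    expect_equal(as.numeric(ape::dist.topo(mine, ape::unroot(ref))), 0)
  }
})

test_that("taxon order does not change the NJ tree", {
  withr::local_seed(84)
  true <- ape::rtree(6, br = function(k) stats::runif(k, 0.2, 1.5))
  D <- ape::cophenetic.phylo(true)
  t1 <- neighbor_joining(D)
  perm <- sample(rownames(D))
  t2 <- neighbor_joining(D[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("NJ validates its input", {
  D <- matrix(runif(16), 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(neighbor_joining(D), "symmetric")
  expect_error(neighbor_joining(matrix(0, 3, 3,
                                       dimnames = list(letters[1:3],
                                                       letters[1:3]))),
               ">= 4 taxa")
})

test_that("branch lengths are never negative", {
  withr::local_seed(85)
  for (rep in 1:10) {
    n <- 6
    base <- rand_dna(120)
    seqs <- stats::setNames(
      vapply(1:n, function(i) mutate_subs(base, sample(5:40, 1)), ""),
      paste0("t", 1:n))
    D <- p_distance(structure(seqs, class = "nt_msa"))
    tree <- neighbor_joining(D)
    expect_true(all(tree$edge.length >= 0))
  }
})

test_that("bootstrap separates planted clades and reproduces under a seed", {
  withr::local_seed(86)
  base <- rand_dna(600)
  other <- mutate_subs(base, 180)             # 30% between clades
  seqs <- c(A1 = base, A2 = mutate_subs(base, 6), A3 = mutate_subs(base, 6),
            B1 = other, B2 = mutate_subs(other, 6), B3 = mutate_subs(other, 6))
  msa <- align_representatives(seqs)
  tree <- bootstrap_supports(msa, B = 200, seed = 99)
  keys <- nodprofiler:::bipartition_keys(tree)
  sep <- paste(sort(c("B1", "B2", "B3")), collapse = "\r")
  alt <- paste(sort(c("A2", "A3")), collapse = "\r")  # canonical side w/o A1
  supports <- attr(tree, "supports")
  sep_support <- supports[match(sep, keys)]
  expect_gte(sep_support, 95)
  tree2 <- bootstrap_supports(msa, B = 200, seed = 99)
  expect_identical(attr(tree, "supports"), attr(tree2, "supports"))
  # B = 1 gives all-or-nothing supports
  tree3 <- bootstrap_supports(msa, B = 1, seed = 5)
  s3 <- attr(tree3, "supports")
  expect_true(all(s3[!is.na(s3)] %in% c(0, 100)))
})

test_that("bipartition keys are invariant under rerooting", {
  withr::local_seed(87)
  true <- ape::rtree(7, br = function(k) stats::runif(k, 0.2, 1))
  D <- ape::cophenetic.phylo(true)
  tree <- neighbor_joining(D)
  k1 <- sort(stats::na.omit(nodprofiler:::bipartition_keys(tree)))
  rerooted <- ape::unroot(ape::root(tree, outgroup = tree$tip.label[3],
                                    resolve.root = TRUE))
  k2 <- sort(stats::na.omit(nodprofiler:::bipartition_keys(rerooted)))
  expect_identical(unname(k1), unname(k2))
})

test_that("cluster assignment follows the smallest supported clade rule", {
  fx <- zero_error_fixture()
  truth <- recovered_truth(fx)
  asg <- fx$res$assignments
  planted_cluster <- fx$sim$centroid_truth$cluster_label[
    match(truth[asg$otu_id], fx$sim$centroid_truth$otu_id)]
  expect_identical(asg$cluster, planted_cluster)
  # support threshold: raising it beyond observed support unassigns
  strict <- assign_cluster(fx$res$tree,
                           stats::setNames(fx$panel$entries$cluster_label,
                                           fx$panel$entries$id),
                           fx$res$signature$labels, min_support = 101)
  expect_true(all(strict$cluster == "unassigned"))
  expect_true(all(strict$final_call == "undetermined"))
})

test_that("the joint decision table maps lineages to final calls", {
  fx <- zero_error_fixture()
  truth <- recovered_truth(fx)
  asg <- fx$res$assignments
  is_nod <- fx$sim$centroid_truth$is_nod[
    match(truth[asg$otu_id], fx$sim$centroid_truth$otu_id)]
  expected <- ifelse(asg$cluster %in% c("Aquifer", "NC10", "Reactor1") & is_nod,
                     "nod",
              ifelse(asg$cluster == "unknown_qNor" & is_nod, "candidate",
              ifelse(asg$cluster %in% c("qNor_outgroup", "unknown_qNor") &
                       !is_nod, "qnor_like", "undetermined")))
  expect_identical(asg$final_call, expected)
  # the OTU462-like case is present and flagged as candidate
  expect_true("candidate" %in% asg$final_call)
})
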