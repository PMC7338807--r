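test_that("length filter applies the window inclusively and logs rejections", {
  params <- clustering_params(length_window = c(800, 1200))
  reads <- data.frame(
    read_id = c("ok", "short", "long", "edge_lo", "edge_hi"),
    sample_id = "s",
    nt_seq = c(strrep("A", 1000), strrep("A", 500), strrep("A", 1500),
               strrep("A", 800), strrep("A", 1200)),
    stringsAsFactors = FALSE)
  lf <- length_filter(reads, params)
  expect_setequal(lf$retained$read_id, c("ok", "edge_lo", "edge_hi"))
  expect_setequal(lf$rejected$reason, c("too_short", "too_long"))
  empty <- length_filter(reads[0, ], params)
  expect_equal(nrow(empty$retained), 0L)
})

test_that("dereplication conserves counts and orders by the tie-break rule", {
  reads <- data.frame(
    read_id = c("r5", "r1", "r2", "r3", "r4", "r6"),
    sample_id = c("s1", "s1", "s2", "s1", "s2", "s2"),
    nt_seq = c("AAAA", "AAAA", "AAAA", "CCCCC", "CCCCC", "GG"),
    stringsAsFactors = FALSE)
  d <- dereplicate(reads)
  expect_equal(sum(d$counts), nrow(reads))
  expect_equal(d$seqs$nt_seq[1], "AAAA")        # most abundant first
  expect_equal(d$seqs$total, c(3L, 2L, 1L))
  expect_equal(d$seqs$uniq_id[1], "r1")          # smallest member id
  # tie at equal counts: longer sequence first
  tie <- dereplicate(data.frame(
    read_id = c("a", "b", "c", "d"), sample_id = "s",
    nt_seq = c("AC", "AC", "GGGG", "GGGG"), stringsAsFactors = FALSE))
  expect_equal(tie$seqs$nt_seq[1], "GGGG")
})

test_that("pairwise identity matches hand-checked values and is symmetric", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0.0)
  # one substitution in ten columns: 9 matches / 10 columns
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAA"), 0.9)
  a <- "ACGGTTACGGTAACGT"; b <- "ACGTTACCGGTAACGA"
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  expect_error(pairwise_identity("", "ACGT"), "nonempty")
})

test_that("pairwise identity agrees with an independent DP oracle", {
  withr::local_seed(71)
  for (rep in 1:20) {
    a <- rand_dna(sample(40:70, 1))
    b <- mutate_subs(a, sample(0:12, 1))
    expect_equal(pairwise_identity(a, b), oracle_global_identity(a, b)$identity,
                 tolerance = 1e-12)
  }
})

test_that("greedy clustering equals a brute-force replay of the scan", {
  withr::local_seed(72)
  # three planted centroids, ~25% apart, members within ~4%
  centroids <- list(rand_dna(60))
  centroids[[2]] <- mutate_subs(centroids[[1]], 15)
  centroids[[3]] <- mutate_subs(centroids[[2]], 16)
  reads <- list(); truth <- c()
  rid <- 0
  for (ci in 1:3) {
    for (k in 1:sample(5:8, 1)) {
      n <- sample(1:6, 1)                       # copies -> abundance ranks
      seq <- if (k == 1) centroids[[ci]] else mutate_subs(centroids[[ci]], sample(0:2, 1))
      for (cp in seq_len(n)) {
        rid <- rid + 1
        reads[[rid]] <- data.frame(read_id = sprintf("r%03d", rid),
                                   sample_id = sample(c("s1", "s2"), 1),
                                   nt_seq = seq, stringsAsFactors = FALSE)
        truth <- c(truth, ci)
      }
    }
  }
  reads <- do.call(rbind, reads)
  d <- dereplicate(reads)
  expect_lte(nrow(d$seqs), 30)
  got <- greedy_cluster(d, clustering_params(identity_threshold = 0.90,
                                             min_size = 1))
  oracle <- oracle_greedy_assign(d$seqs$nt_seq, 0.90)
  mine <- match(got$membership$otu_id, got$otus$otu_id)
  expect_identical(as.integer(mine), as.integer(oracle))
  # counts conserved through clustering
  expect_equal(sum(got$counts), nrow(reads))
})

test_that("planted partitions straddling the threshold are recovered", {
  withr::local_seed(73)
  # two centroids at 20% divergence; members within 2%
  c1 <- rand_dna(100); c2 <- mutate_subs(c1, 20)
  mk <- function(cen, pre, n) do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(read_id = sprintf("%s%02d", pre, i), sample_id = "s",
               nt_seq = if (i <= 2) cen else mutate_subs(cen, 2),
               stringsAsFactors = FALSE)))
  reads <- rbind(mk(c1, "a", 8), mk(c2, "b", 6))
  got <- greedy_cluster(dereplicate(reads),
                        clustering_params(min_size = 1))
  expect_equal(nrow(got$otus), 2L)
  members <- split(substr(got$membership$uniq_id, 1, 1), got$membership$otu_id)
  expect_true(all(vapply(members, function(x) length(unique(x)) == 1L, TRUE)))
})

test_that("a member exactly at the identity threshold joins its centroid", {
  withr::local_seed(74)
  cen <- rand_dna(100)
  member <- mutate_subs(cen, 10)              # exactly 0.90 identity
  expect_equal(pairwise_identity(cen, member), 0.90)
  reads <- data.frame(read_id = c("c1", "c2", "m1"), sample_id = "s",
                      nt_seq = c(cen, cen, member), stringsAsFactors = FALSE)
  got <- greedy_cluster(dereplicate(reads), clustering_params(min_size = 1))
  expect_equal(nrow(got$otus), 1L)
})

test_that("OTU filtering keeps >= min_size and renames by rank", {
  counts <- matrix(c(120L, 50L, 49L, 0L, 0L, 0L), 3, 2,
                   dimnames = list(c("u2", "u1", "u3"), c("s1", "s2")))
  os <- structure(list(
    otus = data.frame(otu_id = c("u2", "u1", "u3"),
                      representative = c("AA", "CC", "GG"),
                      size = c(120L, 50L, 50L), stringsAsFactors = FALSE),
    counts = counts,
    membership = data.frame(uniq_id = c("u2", "u1", "u3"),
                            otu_id = c("u2", "u1", "u3"),
                            stringsAsFactors = FALSE)),
    class = "otu_set")
  os$otus$size <- as.integer(rowSums(counts))
  kept <- filter_otus(os, clustering_params(min_size = 50))
  expect_equal(kept$otus$otu_id, c("OTU1", "OTU2"))
  expect_equal(kept$otus$size, c(120L, 50L))
  # ties in size resolve by centroid id, deterministically
  os$counts[, 1] <- c(50L, 50L, 10L); os$counts[, 2] <- 0L
  os$otus$size <- as.integer(rowSums(os$counts))
  kept2 <- filter_otus(os, clustering_params(min_size = 50))
  expect_equal(kept2$otus$representative, c("CC", "AA"))  # u1 before u2
  expect_warning(filter_otus(os, clustering_params(min_size = 999)),
                 "min_size")
})
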