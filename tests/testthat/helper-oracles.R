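# Independent, deliberately naive re-implementations used as oracles.
# They share no code with the package: plain R dynamic programming and
# exhaustive scans, usable only at toy scale.

# Gotoh global alignment (match +1, mismatch -1, gap open 2 + extend 1 per
# column, end gaps penalised) returning matches and alignment length of one
# optimal traceback.
oracle_global_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9; open <- 2; ext <- 1
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) 1 else -1
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  # traceback (prefer M, then X, then Y on ties)
  i <- n; j <- m
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  matches <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    if (state == 1 && i > 0 && j > 0) {
      s <- if (A[i] == B[j]) 1 else -1
      prev <- which.max(c(M[i, j], X[i, j], Y[i, j]))
      matches <- matches + (A[i] == B[j]); len <- len + 1L
      i <- i - 1L; j <- j - 1L; state <- prev
    } else if (state == 2 || j == 0) {
      prev <- which.max(c(M[i, j + 1] - open - ext, X[i, j + 1] - ext))
      len <- len + 1L; i <- i - 1L; state <- prev
    } else {
      prev <- which.max(c(M[i + 1, j] - open - ext, Y[i + 1, j] - ext))
      len <- len + 1L; j <- j - 1L; state <- prev
    }
  }
  list(identity = matches / len,
       score = max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
}

# replay the abundance-ordered greedy scan with oracle identities
oracle_greedy_assign <- function(seqs, threshold) {
  centroids <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (ci in seq_along(centroids)) {
      if (oracle_global_identity(seqs[i], seqs[centroids[ci]])$identity >=
          threshold) { hit <- ci; break }
    }
    if (hit == 0L) { centroids <- c(centroids, i); assign[i] <- length(centroids) }
    else assign[i] <- hit
  }
  assign
}

# random DNA and substitution-only mutants (no indels, so pairwise
# identities have an unambiguous gap-free optimum)
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
mutate_subs <- function(seq, k) {
  b <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(b), k)
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  paste(b, collapse = "")
}

# shared zero-error end-to-end fixture, built once per test run
fixture_env <- new.env()
zero_error_fixture <- function(seed = 11) {
  key <- paste0("fx", seed)
  if (is.null(fixture_env[[key]])) {
    panel <- make_reference_panel(seed = seed)
    spec <- default_community_spec(panel, seed = seed + 1,
                                   error_model = c(sub_rate = 0,
                                                   ins_rate = 0,
                                                   del_rate = 0))
    sim <- simulate_reads(spec, panel)
    res <- run_nod_pipeline(
      sim$reads, panel, qpcr = simulate_qpcr(spec),
      habitats = stats::setNames(spec$samples$habitat,
                                 spec$samples$sample_id),
      B = 100, seed = seed + 2)
    fixture_env[[key]] <- list(panel = panel, spec = spec, sim = sim,
                               res = res)
  }
  fixture_env[[key]]
}

# planted OTU id of each recovered representative (zero-error runs only:
# representatives are exact centroid copies)
recovered_truth <- function(fx) {
  stats::setNames(names(fx$sim$centroids)[
    match(fx$res$otu_set$otus$representative, fx$sim$centroids)],
    fx$res$otu_set$otus$otu_id)
}
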