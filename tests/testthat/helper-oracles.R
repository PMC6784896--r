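# Independent oracles used to check the package's own implementations.
# These deliberately share no code with the package internals.

# Full affine-gap Smith-Waterman score by plain dynamic programming.
# Gap of length L costs gap_open + L * gap_extend.
oracle_sw_score <- function(a, b, match = 1, mismatch = -2, gap_open = 5,
                            gap_extend = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  open <- gap_open + gap_extend
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - gap_extend)
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# N50 by brute-force enumeration of the definition.
oracle_n50 <- function(lengths) {
  lengths <- sort(lengths, decreasing = TRUE)
  half <- sum(lengths) / 2
  acc <- 0
  for (l in lengths) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
  0
}

# Greedy incremental gene-family clustering using Biostrings as the
# aligner (independent of the package's Rcpp engine): sort by length
# descending, join the first family whose seed matches at >= identity
# over >= coverage of the shorter sequence.
oracle_greedy_cluster <- function(genes, identity = 0.95, coverage = 0.90) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -2, baseOnly = TRUE)
  ord <- order(-nchar(genes$sequence), genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  seeds <- character(0)
  assign_to <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    s <- genes$sequence[i]
    placed <- FALSE
    for (f in seq_along(seeds)) {
      aln <- Biostrings::pairwiseAlignment(s, seeds[f], type = "local",
                                           substitutionMatrix = mat,
                                           gapOpening = 5, gapExtension = 2)
      cols <- Biostrings::nchar(aln)
      if (cols == 0) next
      idy <- Biostrings::nmatch(aln) / cols
      span_q <- Biostrings::width(Biostrings::pattern(aln))
      span_t <- Biostrings::width(Biostrings::subject(aln))
      shorter <- min(nchar(s), nchar(seeds[f]))
      cov <- max(span_q, span_t) / shorter
      if (idy >= identity && cov >= coverage) {
        assign_to[i] <- f
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seeds <- c(seeds, s)
      assign_to[i] <- length(seeds)
    }
  }
  split(genes$gene_id, assign_to)
}

# Adjusted Rand index between two labelings.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Canonical partition signature for comparing clusterings up to label
# permutation.
partition_signature <- function(labels, ids) {
  groups <- split(ids, labels)
  groups <- lapply(groups, sort)
  paste(sort(vapply(groups, paste, "", collapse = ",")), collapse = ";")
}
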