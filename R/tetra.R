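# Tetranucleotide signature profiles and Pearson pre-ranking of
# references. Profiles are cheap to compute and correlate, so they order
# the reference collection before any expensive ANI or POCP comparison.

#' Tetranucleotide signature profile
#'
#' Counts all 4-mers over both strands of every scaffold (windows with
#' ambiguous bases are skipped) and converts them to z-scores against a
#' maximal-order Markov expectation: for tetramer n1n2n3n4,
#' `E = c(n1n2n3) * c(n2n3n4) / c(n2n3)` with the variance approximation
#' `V = E * (c(n2n3) - c(n1n2n3)) * (c(n2n3) - c(n2n3n4)) / c(n2n3)^2`.
#' Because both strands are counted, the profile is invariant to
#' reverse-complementing the genome. A raw-frequency mode
#' (`markov = FALSE`) returns centred 4-mer frequencies instead.
#'
#' @param assembly A [genome_assembly()] (or a `simulated_genome`) with
#'   >= 2 kb of sequence.
#' @param markov Use the order-2 Markov z-score normalization (default)
#'   rather than raw frequencies.
#' @return A `tetra_profile`: list with `genome_id` and `z`, a named
#'   256-vector in fixed lexicographic tetramer order.
#' @export
tetra_profile <- function(assembly, markov = TRUE) {
  if (inherits(assembly, "simulated_genome"))
    assembly <- genome_assembly(setNames(assembly$sequence, "s1"),
                                id = assembly$id)
  stopifnot(inherits(assembly, "genome_assembly"))
  if (total_length(assembly) < 2000)
    stop("assembly too short for a tetranucleotide profile (< 2 kb)")
  seqs <- assembly$sequences
  both <- c(seqs, Biostrings::reverseComplement(seqs))
  c4 <- colSums(Biostrings::oligonucleotideFrequency(both, 4L))
  if (!markov) {
    f <- c4 / sum(c4)
    return(structure(list(genome_id = assembly$id, z = f - mean(f)),
                     class = "tetra_profile"))
  }
  c3 <- colSums(Biostrings::oligonucleotideFrequency(both, 3L))
  c2 <- colSums(Biostrings::oligonucleotideFrequency(both, 2L))
  kmers <- names(c4)
  left <- substr(kmers, 1L, 3L)
  right <- substr(kmers, 2L, 4L)
  mid <- substr(kmers, 2L, 3L)
  cm <- c2[mid]
  e <- ifelse(cm > 0, c3[left] * c3[right] / cm, 0)
  v <- ifelse(cm > 0,
              e * (cm - c3[left]) * (cm - c3[right]) / cm^2, 0)
  z <- ifelse(v > 0, (c4 - e) / sqrt(v), 0)
  names(z) <- kmers
  structure(list(genome_id = assembly$id, z = z), class = "tetra_profile")
}

#' @export
print.tetra_profile <- function(x, ...) {
  cat(sprintf("tetra_profile '%s': 256 z-scores, range [%.2f, %.2f]\n",
              x$genome_id, min(x$z), max(x$z)))
  invisible(x)
}

#' Pearson correlation between two tetranucleotide profiles
#'
#' Pearson r over the 256 paired z-scores, with a two-sided p-value from
#' the t transform `t = r * sqrt((n - 2) / (1 - r^2))` at n - 2 = 254
#' degrees of freedom.
#'
#' @param p1,p2 `tetra_profile` objects.
#' @return List with `r` and `p`.
#' @export
profile_correlation <- function(p1, p2) {
  stopifnot(inherits(p1, "tetra_profile"), inherits(p2, "tetra_profile"))
  x <- p1$z; y <- p2$z
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance tetranucleotide profile")
  r <- cor(x, y)
  n <- length(x)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t_stat), df = n - 2))
}

#' Rank references by tetranucleotide correlation
#'
#' Correlates a query profile against every reference profile, keeps
#' references with `r > 0` and `p < 0.001`, and sorts by decreasing r
#' (ties broken by reference id). This ranked list is the walk order of
#' the ANI and POCP assignment loops.
#'
#' @param query A `tetra_profile`.
#' @param refs Named list of `tetra_profile`s (names = reference ids; the
#'   profiles' `genome_id` is used when names are absent).
#' @param r_min,p_max Retention thresholds.
#' @return Data frame with `reference_id`, `r`, `p`, sorted by
#'   decreasing r; zero rows when nothing qualifies.
#' @export
rank_references <- function(query, refs, r_min = 0, p_max = 0.001) {
  if (length(refs) == 0L) stop("at least one reference profile is required")
  ids <- names(refs)
  if (is.null(ids)) ids <- vapply(refs, function(p) p$genome_id, "")
  res <- lapply(refs, profile_correlation, p1 = query)
  out <- data.frame(reference_id = ids,
                    r = vapply(res, `[[`, 0, "r"),
                    p = vapply(res, `[[`, 0, "p"),
                    stringsAsFactors = FALSE)
  out <- out[out$r > r_min & out$p < p_max, , drop = FALSE]
  out <- out[order(-out$r, out$reference_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
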