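# Massive taxonomy assignment: tetranucleotide pre-ranking feeds an
# early-stopped fragment-ANI loop (species) and a POCP loop (genus);
# precomputed 16S best identities get rank novelty calls.

#' Fragment-based average nucleotide identity
#'
#' The query is cut into consecutive non-overlapping fragments of
#' `fragment_len` bp per scaffold (sub-fragment tails are dropped), each
#' fragment is mapped onto the reference by seed-and-extend, and a
#' fragment is kept when its alignment has identity >= `min_identity`
#' over >= `min_coverage` of the fragment length. ANI is the mean
#' identity (percent) of kept fragments. Reported per direction
#' (query -> reference); [ani_between()] gives the symmetric two-direction
#' mean used for species clustering.
#'
#' @param query,ref [genome_assembly()] objects (a `simulated_genome` or
#'   a bare character sequence is promoted automatically).
#' @param fragment_len Fragment length in bp.
#' @param min_identity,min_coverage Fragment keep rules.
#' @param k Seed word size.
#' @param scheme DNA [scoring_scheme()].
#' @return An `ani_result`: list with `query_id`, `reference_id`, `ani`
#'   (percent, `NA` when no fragment qualifies — flagged by `defined`),
#'   `n_fragments_total`, `n_fragments_aligned`, `aligned_fraction`.
#' @export
fragment_ani <- function(query, ref, fragment_len = 1020L, min_identity = 0.30,
                         min_coverage = 0.70, k = 15L,
                         scheme = scoring_scheme("dna")) {
  query <- as_assembly(query)
  ref <- as_assembly(ref)
  if (total_length(query) < fragment_len)
    stop("query shorter than one fragment")
  frags <- cut_fragments(query, fragment_len)
  hits <- map_fragments(frags, ref, k, scheme)
  span <- hits$q_end - hits$q_start + 1L
  keep <- hits$has_hit & !is.na(hits$identity) &
    hits$identity >= min_identity & span >= min_coverage * fragment_len
  keep[is.na(keep)] <- FALSE
  n_kept <- sum(keep)
  structure(list(query_id = query$id, reference_id = ref$id,
                 ani = if (n_kept > 0) 100 * mean(hits$identity[keep]) else NA_real_,
                 defined = n_kept > 0,
                 n_fragments_total = length(frags),
                 n_fragments_aligned = n_kept,
                 aligned_fraction = n_kept / length(frags)),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ANI %s -> %s: %s (%d/%d fragments kept)\n", x$query_id,
              x$reference_id,
              if (x$defined) sprintf("%.2f%%", x$ani) else "undefined",
              x$n_fragments_aligned, x$n_fragments_total))
  invisible(x)
}

#' @rdname fragment_ani
#' @param a,b Genomes for the symmetric summary.
#' @param ... Passed on to [fragment_ani()].
#' @export
ani_between <- function(a, b, ...) {
  ab <- fragment_ani(a, b, ...)
  ba <- fragment_ani(b, a, ...)
  vals <- c(ab$ani, ba$ani)
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

as_assembly <- function(x) {
  if (inherits(x, "genome_assembly")) return(x)
  if (inherits(x, "simulated_genome"))
    return(genome_assembly(setNames(x$sequence, "s1"), id = x$id))
  if (is.character(x))
    return(genome_assembly(x, id = "query"))
  stop("cannot interpret input as a genome assembly")
}

cut_fragments <- function(assembly, fragment_len) {
  out <- list()
  for (s in assembly_chars(assembly)) {
    nfrag <- nchar(s) %/% fragment_len
    if (nfrag == 0L) next
    starts <- (seq_len(nfrag) - 1L) * fragment_len + 1L
    out <- c(out, as.list(substring(s, starts, starts + fragment_len - 1L)))
  }
  out
}

# Map character fragments onto a (multi-scaffold) reference. Scaffolds are
# concatenated with ambiguous-base spacers that can neither seed nor align,
# so hits never cross scaffold boundaries.
map_fragments <- function(frags, ref, k, scheme) {
  target <- paste(assembly_chars(ref), collapse = strrep("N", 100L))
  enc <- lapply(frags, encode_seq, scheme = scheme)
  .map_fragments_cpp(enc, encode_seq(target, scheme), as.integer(k),
                     scheme$submat, scheme$gap_open, scheme$gap_extend,
                     120L, 64L)
}

#' Reference database with cached tetranucleotide profiles
#'
#' @param assemblies Named list of [genome_assembly()] (or
#'   `simulated_genome`) reference genomes.
#' @param proteomes Optional named list of proteomes (named character
#'   vectors of amino-acid sequences) for POCP-based genus assignment.
#' @return A `reference_db`: list with `assemblies`, `profiles`,
#'   `proteomes`, `ids`.
#' @export
reference_db <- function(assemblies, proteomes = NULL) {
  assemblies <- lapply(assemblies, as_assembly)
  ids <- names(assemblies)
  if (is.null(ids)) {
    ids <- vapply(assemblies, function(a) a$id, "")
    names(assemblies) <- ids
  }
  for (i in seq_along(assemblies)) assemblies[[i]]$id <- ids[i]
  profiles <- lapply(assemblies, tetra_profile)
  structure(list(assemblies = assemblies, profiles = profiles,
                 proteomes = proteomes, ids = ids),
            class = "reference_db")
}

#' Early-stopped species assignment by ANI
#'
#' Walks the tetranucleotide-ranked reference list in order, computing
#' fragment ANI one reference at a time, and stops at the first reference
#' whose ANI is strictly larger than `ani_threshold` (status `assigned`)
#' or once `max_refs` comparisons (or the ranked list) are exhausted
#' (status `not_assigned`).
#'
#' @param query A [genome_assembly()] or `simulated_genome`.
#' @param refdb A [reference_db()].
#' @param ani_threshold Assignment threshold in percent (strict `>`).
#' @param max_refs Comparison budget.
#' @param ani_fun Function `(query, ref, ...)` returning an object with
#'   an `ani` field; injectable for testing the stop rule.
#' @param ... Passed to `ani_fun`.
#' @return A `tax_assignment`: list with `query_id`, `status`,
#'   `matched_reference`, `value`, `n_comparisons_done`, `level`.
#' @export
assign_species <- function(query, refdb, ani_threshold = 95, max_refs = 500L,
                           ani_fun = fragment_ani, ...) {
  query <- as_assembly(query)
  ranked <- rank_references(tetra_profile(query), refdb$profiles)
  walk_assignment(query, refdb, ranked, threshold = ani_threshold,
                  max_refs = max_refs, level = "species",
                  value_fun = function(q, rid) {
                    r <- ani_fun(q, refdb$assemblies[[rid]], ...)
                    if (inherits(r, "ani_result")) r$ani else r
                  })
}

#' Early-stopped genus assignment by POCP
#'
#' Same loop structure as [assign_species()] with percentage of conserved
#' proteins and a strict `> pocp_threshold` stop rule. Intended for
#' queries that the ANI loop left unassigned.
#'
#' @param query_proteome Named character vector of the query's proteins.
#' @param query_assembly The query [genome_assembly()] (tetranucleotide
#'   ranking is genome-based).
#' @param refdb A [reference_db()] with `proteomes`.
#' @param pocp_threshold Assignment threshold in percent (strict `>`).
#' @param max_refs Comparison budget.
#' @param pocp_fun Function `(proteomeA, proteomeB)` returning an object
#'   with a `pocp` field; injectable for testing the stop rule.
#' @return A `tax_assignment` with `level = "genus"`.
#' @export
assign_genus <- function(query_proteome, query_assembly, refdb,
                         pocp_threshold = 50, max_refs = 500L,
                         pocp_fun = pocp) {
  if (is.null(refdb$proteomes)) stop("reference_db has no proteomes")
  query_assembly <- as_assembly(query_assembly)
  ranked <- rank_references(tetra_profile(query_assembly), refdb$profiles)
  ranked <- ranked[ranked$reference_id %in% names(refdb$proteomes), ,
                   drop = FALSE]
  walk_assignment(query_assembly, refdb, ranked, threshold = pocp_threshold,
                  max_refs = max_refs, level = "genus",
                  value_fun = function(q, rid) {
                    r <- pocp_fun(query_proteome, refdb$proteomes[[rid]])
                    if (inherits(r, "pocp_result")) r$pocp else r
                  })
}

walk_assignment <- function(query, refdb, ranked, threshold, max_refs, level,
                            value_fun) {
  n_done <- 0L
  for (rid in head(ranked$reference_id, max_refs)) {
    n_done <- n_done + 1L
    value <- value_fun(query, rid)
    if (!is.na(value) && value > threshold) {
      return(structure(list(query_id = query$id, status = "assigned",
                            matched_reference = rid, value = value,
                            n_comparisons_done = n_done, level = level),
                       class = "tax_assignment"))
    }
  }
  structure(list(query_id = query$id, status = "not_assigned",
                 matched_reference = NA_character_, value = NA_real_,
                 n_comparisons_done = n_done, level = level),
            class = "tax_assignment")
}

#' @export
print.tax_assignment <- function(x, ...) {
  cat(sprintf("%s-level assignment for '%s': %s%s after %d comparison(s)\n",
              x$level, x$query_id, x$status,
              if (x$status == "assigned")
                sprintf(" to '%s' (%.2f)", x$matched_reference, x$value) else "",
              x$n_comparisons_done))
  invisible(x)
}

#' Percentage of conserved proteins (POCP)
#'
#' A protein counts as conserved when its best local-alignment hit in the
#' other proteome has E-value < `evalue_max`, identity > `min_identity`
#' and an alignable region covering > `min_coverage` of the query protein
#' length. With C1/C2 conserved counts and T1/T2 proteome sizes,
#' `POCP = 100 * (C1 + C2) / (T1 + T2)`; values above 50% conventionally
#' indicate a shared genus.
#'
#' @param proteome_a,proteome_b Named character vectors of amino-acid
#'   sequences.
#' @param evalue_max,min_identity,min_coverage Conservation thresholds.
#' @param scheme Protein [scoring_scheme()].
#' @return A `pocp_result`: list with `C1`, `C2`, `T1`, `T2`, `pocp`.
#' @export
pocp <- function(proteome_a, proteome_b, evalue_max = 1e-5,
                 min_identity = 0.40, min_coverage = 0.50,
                 scheme = scoring_scheme("protein")) {
  if (length(proteome_a) == 0L || length(proteome_b) == 0L)
    stop("proteomes must be non-empty")
  enc_a <- lapply(proteome_a, encode_seq, scheme = scheme)
  enc_b <- lapply(proteome_b, encode_seq, scheme = scheme)
  c1 <- count_conserved(enc_a, enc_b, evalue_max, min_identity, min_coverage,
                        scheme)
  c2 <- count_conserved(enc_b, enc_a, evalue_max, min_identity, min_coverage,
                        scheme)
  t1 <- length(proteome_a); t2 <- length(proteome_b)
  structure(list(C1 = c1, C2 = c2, T1 = t1, T2 = t2,
                 pocp = 100 * (c1 + c2) / (t1 + t2)),
            class = "pocp_result")
}

count_conserved <- function(enc_q, enc_t, evalue_max, min_identity,
                            min_coverage, scheme) {
  db_len <- sum(lengths(enc_t))
  conserved <- 0L
  for (q in enc_q) {
    scores <- vapply(enc_t, function(t) {
      .sw_score_cpp(q, t, scheme$submat, scheme$gap_open, scheme$gap_extend)
    }, 0)
    best <- which.max(scores)
    if (scores[best] <= 0) next
    aln <- .sw_align_cpp(q, enc_t[[best]], scheme$submat, scheme$gap_open,
                         scheme$gap_extend)
    if (aln$empty) next
    e <- scheme$karlin_k * length(q) * db_len *
      exp(-scheme$karlin_lambda * aln$score)
    identity <- if (aln$aligned > 0) aln$matches / aln$aligned else 0
    coverage <- (aln$a_end - aln$a_start + 1) / length(q)
    if (e < evalue_max && identity > min_identity && coverage > min_coverage)
      conserved <- conserved + 1L
  }
  conserved
}

#' @export
print.pocp_result <- function(x, ...) {
  cat(sprintf("POCP = %.2f%% (C1=%d/%d, C2=%d/%d)\n", x$pocp, x$C1, x$T1,
              x$C2, x$T2))
  invisible(x)
}

#' 16S rRNA novelty call
#'
#' Rank novelty from a precomputed best 16S identity against known
#' species: >= 98.7% known; [94.5, 98.7) novel species; [86.5, 94.5)
#' novel genus; < 86.5 novel family. Boundaries are inclusive at the
#' lower bound of each band.
#'
#' @param best_identity Best database identity in percent, in [0, 100].
#' @return A `novelty_call`: list with `best_identity` and `rank`.
#' @examples
#' novelty_call(97)$rank # novel_species
#' @export
novelty_call <- function(best_identity) {
  if (is.na(best_identity) || best_identity < 0 || best_identity > 100)
    stop("best_identity must be in [0, 100]")
  rank <- if (best_identity >= 98.7) "known"
  else if (best_identity >= 94.5) "novel_species"
  else if (best_identity >= 86.5) "novel_genus"
  else "novel_family"
  structure(list(best_identity = best_identity, rank = rank),
            class = "novelty_call")
}

#' @export
print.novelty_call <- function(x, ...) {
  cat(sprintf("16S best identity %.2f%% -> %s\n", x$best_identity, x$rank))
  invisible(x)
}
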