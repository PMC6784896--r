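# Synthetic genome generation: the ground-truth side of the package.
# Everything downstream (taxonomy, quality, splitting, clustering) is
# exercised on genomes produced here, where the true labels are known.

#' Simulate a genome sequence
#'
#' Draws an i.i.d. base sequence with a target GC fraction
#' (`P(G) + P(C) = gc_target`, G/C and A/T split evenly). Deterministic
#' given `seed`; the caller's RNG state is untouched.
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc_target Target GC fraction, strictly inside (0, 1).
#' @param seed Integer seed.
#' @param id Genome identifier.
#' @return A `simulated_genome`: list with `id`, `sequence` (character),
#'   `gc_target`, `seed`.
#' @examples
#' g <- simulate_genome(5000, 0.45, seed = 1)
#' nchar(g$sequence)
#' @export
simulate_genome <- function(length, gc_target, seed, id = "genome") {
  if (length < 1000) stop("length must be >= 1000")
  if (gc_target <= 0 || gc_target >= 1) stop("gc_target must be in (0, 1)")
  sequence <- with_seed(seed, random_dna(length, gc_target))
  structure(list(id = id, sequence = sequence, gc_target = gc_target,
                 seed = seed),
            class = "simulated_genome")
}

#' @export
print.simulated_genome <- function(x, ...) {
  cat(sprintf("simulated_genome '%s': %.1f kb, GC target %.2f (seed %s)\n",
              x$id, nchar(x$sequence) / 1e3, x$gc_target, x$seed))
  invisible(x)
}

gc_fraction <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  valid <- chars %in% c("A", "C", "G", "T")
  sum(chars %in% c("G", "C")) / sum(valid)
}

#' Evolve a sequence to a known identity
#'
#' Applies `n_subs` substitutions at distinct positions (each to a
#' different base) and then `n_indels` short indels (1-5 bp). The true
#' identity is bookkept on the substituted-only copy,
#' `(L - n_subs) / L`; indels are reported separately so that identity
#' recovery targets stay exact.
#'
#' @param seq DNA character sequence.
#' @param n_subs Number of substitutions (<= sequence length).
#' @param n_indels Number of indel events.
#' @param seed Integer seed.
#' @return List with `sequence`, `true_identity`, `n_subs`, `n_indels`.
#' @examples
#' e <- evolve_sequence(simulate_genome(10000, 0.5, 1)$sequence, 500, seed = 2)
#' e$true_identity # 0.95
#' @export
evolve_sequence <- function(seq, n_subs, n_indels = 0, seed = NULL) {
  L <- nchar(seq)
  if (n_subs > L) stop("n_subs exceeds the sequence length")
  with_seed(seed, {
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
    if (n_subs > 0) {
      pos <- sample.int(L, n_subs)
      bases <- c("A", "C", "G", "T")
      chars[pos] <- vapply(chars[pos], function(b) {
        sample(setdiff(bases, b), 1L)
      }, "", USE.NAMES = FALSE)
    }
    if (n_indels > 0) {
      for (i in seq_len(n_indels)) {
        at <- sample.int(length(chars) - 6L, 1L)
        len <- sample.int(5L, 1L)
        if (runif(1) < 0.5) {
          chars <- append(chars, sample(c("A", "C", "G", "T"), len,
                                        replace = TRUE), after = at)
        } else {
          chars <- chars[-(at:(at + len - 1L))]
        }
      }
    }
    list(sequence = paste(chars, collapse = ""),
         true_identity = (L - n_subs) / L,
         n_subs = n_subs, n_indels = n_indels)
  })
}

# Deterministic 300-bp single-copy marker tag sequences; marker i is the
# same sequence in every simulation, so detection is exact string search.
marker_tag <- function(i, len = 300L) {
  with_seed(900000L + as.integer(i), random_dna(len, 0.5))
}

#' Simulate a (possibly multi-genome) isolate assembly
#'
#' Fragments each component genome into scaffolds of uniform random
#' length, draws per-scaffold depth lognormally around the component mean
#' (`sigma` on the log scale), and inserts the same catalog of fixed
#' 300-bp single-copy marker tags once per genome. Scaffold order is
#' shuffled across components. Emulates cultivation isolates whose
#' assembly mixes more than one organism.
#'
#' @param components List of components, each a list with `genome` (a
#'   `simulated_genome`) and `depth` (mean fold-coverage, > 0).
#' @param scaffold_len Length-2 vector: min and max scaffold length (bp).
#' @param markers_per_genome Number of marker tags inserted per genome.
#' @param seed Integer seed.
#' @param depth_sigma Lognormal sigma of per-scaffold depth noise.
#' @return A `mixed_assembly_sim`: list with `assembly`
#'   ([genome_assembly()] with depth), `markers` (data frame
#'   `marker_id`, `scaffold_id`, `copy_count`), `expected_markers`
#'   (character vector) and `truth` (list with `scaffold_map` naming each
#'   scaffold's source genome and `genomes`).
#' @export
simulate_mixed_assembly <- function(components, scaffold_len = c(5000, 15000),
                                    markers_per_genome = 0, seed = 1,
                                    depth_sigma = 0.1) {
  if (length(components) < 1L) stop("at least one component is required")
  for (cmp in components) {
    if (!inherits(cmp$genome, "simulated_genome")) stop("components need $genome")
    if (is.null(cmp$depth) || cmp$depth <= 0) stop("depths must be positive")
    if (scaffold_len[1L] > nchar(cmp$genome$sequence))
      stop("minimum scaffold length exceeds a genome length")
  }
  with_seed(seed, {
    seqs <- character(0); depth <- numeric(0); map <- character(0)
    marker_rows <- list()
    expected <- if (markers_per_genome > 0)
      sprintf("marker_%03d", seq_len(markers_per_genome)) else character(0)
    for (cmp in components) {
      g <- cmp$genome
      L <- nchar(g$sequence)
      cuts <- 0
      while (utils::tail(cuts, 1L) < L) {
        step <- round(runif(1, scaffold_len[1L], scaffold_len[2L]))
        cuts <- c(cuts, min(L, utils::tail(cuts, 1L) + step))
      }
      # merge a short terminal piece into the previous scaffold
      if (length(cuts) > 2L &&
          (cuts[length(cuts)] - cuts[length(cuts) - 1L]) < scaffold_len[1L] / 2)
        cuts <- cuts[-(length(cuts) - 1L)]
      starts <- cuts[-length(cuts)] + 1L
      ends <- cuts[-1L]
      sc <- substring(g$sequence, starts, ends)
      ids <- sprintf("%s_s%03d", g$id, seq_along(sc))
      names(sc) <- ids
      if (markers_per_genome > 0) {
        host <- sample(seq_along(sc), markers_per_genome, replace = TRUE)
        for (m in seq_len(markers_per_genome)) {
          tag <- marker_tag(m)
          s <- sc[[host[m]]]
          at <- sample.int(nchar(s), 1L)
          sc[host[m]] <- paste0(substring(s, 1L, at), tag,
                                substring(s, at + 1L, nchar(s)))
          marker_rows[[length(marker_rows) + 1L]] <-
            data.frame(marker_id = expected[m], scaffold_id = ids[host[m]],
                       copy_count = 1L, stringsAsFactors = FALSE)
        }
      }
      seqs <- c(seqs, sc)
      depth <- c(depth, setNames(cmp$depth * rlnorm(length(sc), 0, depth_sigma),
                                 ids))
      map <- c(map, setNames(rep(g$id, length(sc)), ids))
    }
    ord <- sample(seq_along(seqs))
    seqs <- seqs[ord]; depth <- depth[names(seqs)]; map <- map[names(seqs)]
    markers <- if (length(marker_rows)) do.call(rbind, marker_rows) else
      data.frame(marker_id = character(0), scaffold_id = character(0),
                 copy_count = integer(0), stringsAsFactors = FALSE)
    # aggregate in case two insertions landed on one scaffold
    if (nrow(markers)) {
      agg <- stats::aggregate(copy_count ~ marker_id + scaffold_id, markers, sum)
      markers <- agg[order(agg$marker_id, agg$scaffold_id), ]
      rownames(markers) <- NULL
    }
    structure(list(
      assembly = genome_assembly(seqs, depth = depth, id = "mixed_isolate"),
      markers = markers,
      expected_markers = expected,
      truth = list(scaffold_map = map,
                   genomes = vapply(components, function(cmp) cmp$genome$id, ""))),
      class = "mixed_assembly_sim")
  })
}

#' Write a simulated mixed assembly to disk
#'
#' Emits `assembly.fna` (80-column FASTA), `depth.tsv`, `markers.tsv` and
#' `truth.json` under `dir`.
#'
#' @param sim A `mixed_assembly_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mixed_assembly <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_assembly_fasta(sim$assembly, file.path(dir, "assembly.fna"))
  write_depth_tsv(sim$assembly$depth, file.path(dir, "depth.tsv"))
  write_marker_tsv(sim$markers, file.path(dir, "markers.tsv"))
  jsonlite::write_json(
    list(scaffold_map = as.list(sim$truth$scaffold_map),
         genomes = sim$truth$genomes,
         expected_markers = sim$expected_markers),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Simulate a proteome
#'
#' Random amino-acid sequences used to exercise POCP and protein-space
#' clustering; [evolve_proteome()] derives a relative at a given
#' substitution rate over a shared fraction of proteins.
#'
#' @param n_proteins Number of proteins.
#' @param len_range Min and max protein length (residues).
#' @param seed Integer seed.
#' @return Named character vector of protein sequences.
#' @export
simulate_proteome <- function(n_proteins, len_range = c(100, 300), seed = 1) {
  with_seed(seed, {
    lens <- round(runif(n_proteins, len_range[1L], len_range[2L]))
    setNames(vapply(lens, random_protein, ""),
             sprintf("prot_%04d", seq_len(n_proteins)))
  })
}

#' @rdname simulate_proteome
#' @param proteome Named character vector of proteins.
#' @param shared_fraction Fraction of proteins carried over (mutated);
#'   the remainder are replaced by unrelated random proteins.
#' @param sub_rate Per-residue substitution rate applied to shared
#'   proteins.
#' @export
evolve_proteome <- function(proteome, shared_fraction = 1, sub_rate = 0.1,
                            seed = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  with_seed(seed, {
    n <- length(proteome)
    n_shared <- round(shared_fraction * n)
    shared <- seq_len(n_shared)
    out <- proteome
    for (i in shared) {
      chars <- strsplit(out[[i]], "", fixed = TRUE)[[1L]]
      nmut <- round(sub_rate * length(chars))
      if (nmut > 0) {
        pos <- sample.int(length(chars), nmut)
        chars[pos] <- vapply(chars[pos], function(b) sample(setdiff(aa, b), 1L),
                             "", USE.NAMES = FALSE)
      }
      out[i] <- paste(chars, collapse = "")
    }
    if (n_shared < n)
      for (i in (n_shared + 1L):n)
        out[i] <- random_protein(nchar(proteome[[i]]))
    names(out) <- sprintf("prot_%04d", seq_len(n))
    out
  })
}
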