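# Synthetic pan-genome collections with known core/accessory/unique truth
# and, optionally, a planted Heaps-law pan-size growth exponent.

#' Simulate a pan-genome collection
#'
#' Two modes share one interface. With `gamma_target = NULL` (default)
#' the structure is explicit: `core_n` families present in every genome,
#' `accessory_pool` families each present in a random proper non-singleton
#' subset, and `unique_per_genome` families private to each genome. With a
#' `gamma_target`, family occurrence counts are instead designed by
#' non-negative least squares so that the expected pan-genome
#' accumulation curve over random genome orderings follows
#' `kappa * N^gamma_target`; the truth partition is then derived from the
#' designed occurrence counts (all genomes = core, one genome = unique).
#'
#' Family members are mutated copies of a random family seed sequence
#' (default 2% substitution, i.e. ~98% identity, always >= 90%), so
#' sequence-level clustering at the package defaults recovers the planted
#' families. Each family carries a functional category label;
#' `category_core_bias` multiplies the sampling weight of named
#' categories for core families, planting a core enrichment signal.
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param core_n,accessory_pool,unique_per_genome Explicit-mode family
#'   counts (each >= 0).
#' @param seed Integer seed.
#' @param gamma_target Optional Heaps exponent to plant.
#' @param kappa Expected pan size at N = 1 in gamma mode.
#' @param divergence Per-base substitution rate between a family seed and
#'   each member copy.
#' @param len_range Min and max family seed length (bp).
#' @param categories Category label set (COG-style letters).
#' @param category_core_bias Named numeric weight multipliers applied to
#'   core families' category sampling.
#' @param with_sequences Generate member sequences (disable for
#'   presence/absence-only studies such as accumulation-curve work).
#' @return A `pan_collection`: list with `genes` (data frame `gene_id`,
#'   `genome_id`, `family_id`, `category`, `sequence`), `families`
#'   (data frame `family_id`, `n_genomes_present`, `class`, `category`),
#'   `genome_ids`, `truth` (list of core/accessory/unique family ids) and
#'   `params`.
#' @examples
#' pc <- simulate_pangenome_collection(5, core_n = 20, accessory_pool = 10,
#'                                     unique_per_genome = 2, seed = 1,
#'                                     with_sequences = FALSE)
#' lengths(pc$truth)
#' @export
simulate_pangenome_collection <- function(n_genomes, core_n = 100,
                                          accessory_pool = 50,
                                          unique_per_genome = 10, seed = 1,
                                          gamma_target = NULL, kappa = 300,
                                          divergence = 0.02,
                                          len_range = c(300, 900),
                                          categories = c("C", "E", "F", "G",
                                                         "H", "I", "J", "K",
                                                         "L", "M", "O", "P",
                                                         "T", "U", "V", "S"),
                                          category_core_bias = NULL,
                                          with_sequences = TRUE) {
  if (n_genomes < 2) stop("n_genomes must be >= 2")
  stopifnot(core_n >= 0, accessory_pool >= 0, unique_per_genome >= 0)
  genome_ids <- sprintf("g%03d", seq_len(n_genomes))
  with_seed(seed, {
    if (is.null(gamma_target)) {
      occ <- c(rep(n_genomes, core_n),
               if (accessory_pool > 0 && n_genomes > 2)
                 sample(2:(n_genomes - 1L), accessory_pool, replace = TRUE),
               rep(1L, n_genomes * unique_per_genome))
      owner <- c(rep(NA_integer_, core_n + if (n_genomes > 2) accessory_pool else 0),
                 rep(seq_len(n_genomes), each = unique_per_genome))
      if (accessory_pool > 0 && n_genomes <= 2)
        stop("accessory families need n_genomes > 2")
    } else {
      occ_counts <- design_occurrence_counts(n_genomes, gamma_target, kappa)
      occ <- rep(seq_len(n_genomes), occ_counts)
      owner <- ifelse(occ == 1L, sample.int(n_genomes, length(occ),
                                            replace = TRUE), NA_integer_)
    }
    n_fam <- length(occ)
    family_id <- sprintf("fam_%05d", seq_len(n_fam))
    cls <- ifelse(occ == n_genomes, "core",
                  ifelse(occ == 1L, "unique", "accessory"))
    # category per family, optionally biased toward core
    w <- rep(1, length(categories))
    names(w) <- categories
    fam_cat <- character(n_fam)
    for (i in seq_len(n_fam)) {
      wi <- w
      if (!is.null(category_core_bias) && cls[i] == "core")
        wi[names(category_core_bias)] <-
          wi[names(category_core_bias)] * category_core_bias
      fam_cat[i] <- sample(categories, 1L, prob = wi)
    }
    # presence sets
    presence <- vector("list", n_fam)
    for (i in seq_len(n_fam)) {
      presence[[i]] <- if (occ[i] == n_genomes) seq_len(n_genomes)
      else if (occ[i] == 1L) {
        if (is.na(owner[i])) sample.int(n_genomes, 1L) else owner[i]
      } else sort(sample.int(n_genomes, occ[i]))
    }
    lens <- round(runif(n_fam, len_range[1L], len_range[2L]))
    seeds <- if (with_sequences)
      vapply(lens, random_dna, "", gc = 0.5) else NULL
    rows <- vector("list", n_fam)
    for (i in seq_len(n_fam)) {
      gs <- genome_ids[presence[[i]]]
      sq <- if (with_sequences) {
        vapply(seq_along(gs), function(j) {
          evolve_sequence(seeds[[i]], round(divergence * lens[i]))$sequence
        }, "")
      } else rep(NA_character_, length(gs))
      rows[[i]] <- data.frame(
        gene_id = sprintf("%s|%s", family_id[i], gs),
        genome_id = gs, family_id = family_id[i], category = fam_cat[i],
        sequence = sq, stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, rows)
    rownames(genes) <- NULL
    structure(list(
      genes = genes,
      families = data.frame(family_id = family_id, n_genomes_present = occ,
                            class = cls, category = fam_cat,
                            stringsAsFactors = FALSE),
      genome_ids = genome_ids,
      truth = list(core = family_id[cls == "core"],
                   accessory = family_id[cls == "accessory"],
                   unique = family_id[cls == "unique"]),
      params = list(n_genomes = n_genomes, core_n = core_n,
                    accessory_pool = accessory_pool,
                    unique_per_genome = unique_per_genome,
                    gamma_target = gamma_target, kappa = kappa,
                    divergence = divergence, seed = seed)),
      class = "pan_collection")
  })
}

# Choose how many families occur in exactly k of n genomes so that the
# expected accumulation curve over random orderings tracks kappa * N^gamma.
# E[family with occurrence k visible after N draws] = 1 - C(n-k,N)/C(n,N).
design_occurrence_counts <- function(n_genomes, gamma, kappa) {
  N <- seq_len(n_genomes)
  B <- vapply(seq_len(n_genomes), function(k) {
    1 - choose(n_genomes - k, N) / choose(n_genomes, N)
  }, numeric(n_genomes))
  target <- kappa * N^gamma
  sol <- pracma::lsqnonneg(B, target)
  counts <- round(sol$x)
  if (sum(counts) == 0) stop("degenerate occurrence design")
  counts
}

#' @export
print.pan_collection <- function(x, ...) {
  cat(sprintf(
    "pan_collection: %d genomes, %d families (%d core / %d accessory / %d unique), %d genes\n",
    length(x$genome_ids), nrow(x$families), length(x$truth$core),
    length(x$truth$accessory), length(x$truth$unique), nrow(x$genes)))
  invisible(x)
}
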