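with_fixed_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}

# A small species collection: `n_species` ancestors, `per_species` genomes
# each evolved from its ancestor at up to `intra_rate`/2 substitutions, so
# pairwise intra-species divergence stays at or below `intra_rate`.
make_species_collection <- function(n_species, per_species, genome_len,
                                    intra_rate = 0.02, seed = 1) {
  set.seed(seed)
  genomes <- list()
  truth <- character(0)
  for (s in seq_len(n_species)) {
    gc <- runif(1, 0.35, 0.6)
    anc <- simulate_genome(genome_len, gc, seed = seed * 1000 + s,
                           id = sprintf("sp%02d_anc", s))
    for (g in seq_len(per_species)) {
      id <- sprintf("sp%02d_g%d", s, g)
      rate <- runif(1, intra_rate / 4, intra_rate / 2)
      seq <- evolve_sequence(anc$sequence, round(rate * genome_len))$sequence
      genomes[[id]] <- genome_assembly(stats::setNames(seq, "s1"), id = id)
      truth[id] <- sprintf("sp%02d", s)
    }
  }
  list(genomes = genomes, truth = truth)
}
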