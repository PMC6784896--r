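test_that("simulated genomes hit their GC target and are deterministic", {
  g <- simulate_genome(100000, 0.5, seed = 1)
  gc <- anipan:::gc_fraction(g$sequence)
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)

  g2 <- simulate_genome(100000, 0.5, seed = 1)
  expect_identical(g$sequence, g2$sequence)

  extreme <- simulate_genome(5000, 0.999, seed = 2)
  expect_gte(anipan:::gc_fraction(extreme$sequence), 0.99)

  expect_error(simulate_genome(100, 0.5, seed = 1), "length")
  expect_error(simulate_genome(5000, 1.2, seed = 1), "gc_target")
})

test_that("evolve_sequence bookkeeping matches its definition", {
  g <- simulate_genome(10000, 0.5, seed = 3)
  same <- evolve_sequence(g$sequence, 0, 0, seed = 1)
  expect_identical(same$sequence, g$sequence)
  expect_equal(same$true_identity, 1.0)

  e <- evolve_sequence(g$sequence, 500, seed = 4)
  expect_equal(e$true_identity, 0.95)
  # exactly 500 mismatching positions
  a <- strsplit(g$sequence, "")[[1]]
  b <- strsplit(e$sequence, "")[[1]]
  expect_equal(sum(a != b), 500L)

  e2 <- evolve_sequence(g$sequence, 500, seed = 5)
  expect_equal(e2$true_identity, e$true_identity)
  expect_false(identical(e2$sequence, e$sequence))

  expect_error(evolve_sequence("ACGT", 10), "n_subs")
})

test_that("substitution-only truth identity matches measured alignment identity", {
  g <- simulate_genome(3000, 0.5, seed = 6)
  e <- evolve_sequence(g$sequence, 90, seed = 7) # 3%
  aln <- local_align(g$sequence, e$sequence)
  expect_equal(aln$identity, e$true_identity, tolerance = 0.005)
})

test_that("mixed assemblies conserve sequence and label every scaffold once", {
  g1 <- simulate_genome(40000, 0.35, seed = 10, id = "gA")
  g2 <- simulate_genome(40000, 0.60, seed = 11, id = "gB")
  sim <- simulate_mixed_assembly(list(list(genome = g1, depth = 80),
                                      list(genome = g2, depth = 40)),
                                 scaffold_len = c(3000, 8000),
                                 markers_per_genome = 10, seed = 12)
  sc <- names(sim$assembly$sequences)
  expect_setequal(names(sim$truth$scaffold_map), sc)
  expect_true(all(sim$truth$scaffold_map %in% c("gA", "gB")))

  # conservation: scaffolds of each label reconstruct source length plus
  # the inserted 300-bp marker tags
  lens <- Biostrings::width(sim$assembly$sequences)
  names(lens) <- sc
  for (gid in c("gA", "gB")) {
    tot <- sum(lens[sim$truth$scaffold_map == gid])
    expect_equal(tot, 40000 + 10 * 300)
  }

  # marker table: one row per genome per marker, single copies
  expect_equal(nrow(sim$markers), 20L)
  expect_true(all(sim$markers$copy_count == 1L))
  expect_setequal(unique(sim$markers$marker_id), sim$expected_markers)

  # determinism
  sim2 <- simulate_mixed_assembly(list(list(genome = g1, depth = 80),
                                       list(genome = g2, depth = 40)),
                                  scaffold_len = c(3000, 8000),
                                  markers_per_genome = 10, seed = 12)
  expect_identical(as.character(sim2$assembly$sequences),
                   as.character(sim$assembly$sequences))
})

test_that("well-separated mixture components separate in feature space", {
  g1 <- simulate_genome(60000, 0.35, seed = 20, id = "lo")
  g2 <- simulate_genome(60000, 0.60, seed = 21, id = "hi")
  sim <- simulate_mixed_assembly(list(list(genome = g1, depth = 80),
                                      list(genome = g2, depth = 40)),
                                 seed = 22)
  feats <- scaffold_features(sim$assembly)
  lab <- sim$truth$scaffold_map[feats$scaffold_id]
  for (col in c("gc", "depth")) {
    m1 <- mean(feats[[col]][lab == "lo"]); s1 <- sd(feats[[col]][lab == "lo"])
    m2 <- mean(feats[[col]][lab == "hi"]); s2 <- sd(feats[[col]][lab == "hi"])
    expect_gt(abs(m1 - m2), 3 * max(s1, s2))
  }
})

test_that("mixed assembly round-trips through its file formats", {
  g1 <- simulate_genome(20000, 0.45, seed = 30, id = "solo")
  sim <- simulate_mixed_assembly(list(list(genome = g1, depth = 50)),
                                 markers_per_genome = 5, seed = 31)
  expect_true(all(sim$truth$scaffold_map == "solo"))
  dir <- withr::local_tempdir()
  write_mixed_assembly(sim, dir)
  back <- read_assembly(file.path(dir, "assembly.fna"),
                        depth_path = file.path(dir, "depth.tsv"))
  expect_identical(sort(names(back$sequences)),
                   sort(names(sim$assembly$sequences)))
  expect_identical(as.character(back$sequences[names(sim$assembly$sequences)]),
                   as.character(sim$assembly$sequences))
  expect_equal(back$depth[names(sim$assembly$depth)], sim$assembly$depth,
               tolerance = 1e-6)
  markers <- read_marker_tsv(file.path(dir, "markers.tsv"))
  expect_equal(nrow(markers), nrow(sim$markers))
})

test_that("pan-genome collections honour their planted structure", {
  pc <- simulate_pangenome_collection(5, core_n = 100, accessory_pool = 0,
                                      unique_per_genome = 0, seed = 1,
                                      with_sequences = FALSE)
  expect_equal(length(pc$truth$core), 100L)
  expect_equal(length(pc$truth$accessory), 0L)

  pc2 <- simulate_pangenome_collection(5, core_n = 10, accessory_pool = 50,
                                       unique_per_genome = 10, seed = 2,
                                       with_sequences = FALSE)
  expect_equal(length(pc2$truth$unique), 50L)
  occ <- pc2$families$n_genomes_present
  expect_true(all(occ[pc2$families$class == "core"] == 5L))
  expect_true(all(occ[pc2$families$class == "unique"] == 1L))
  acc <- occ[pc2$families$class == "accessory"]
  expect_true(all(acc >= 2 & acc <= 4))
  # every genome has exactly unique_per_genome private families
  uniq <- pc2$genes[pc2$genes$family_id %in% pc2$truth$unique, ]
  expect_true(all(table(uniq$genome_id) == 10L))

  # member sequences stay close to the family seed (>= 90% identity)
  pc3 <- simulate_pangenome_collection(3, core_n = 5, accessory_pool = 0,
                                       unique_per_genome = 0, seed = 3)
  fam <- split(pc3$genes$sequence, pc3$genes$family_id)[[1]]
  aln <- local_align(fam[1], fam[2])
  expect_gte(aln$identity, 0.9)

  expect_error(simulate_pangenome_collection(1), "n_genomes")
})
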