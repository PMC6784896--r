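test_that("greedy gene-family clustering groups relatives and separates strangers", {
  set.seed(1)
  a <- anipan:::random_dna(1000)
  b <- evolve_sequence(a, 20)$sequence # 2% divergence
  c_ <- anipan:::random_dna(900)
  genes <- data.frame(gene_id = c("A", "B", "C"),
                      genome_id = c("g1", "g2", "g3"),
                      sequence = c(a, b, c_), stringsAsFactors = FALSE)
  fams <- cluster_gene_families(genes, identity = 0.95, coverage = 0.90)
  expect_equal(length(fams), 2L)
  members <- lapply(fams, `[[`, "members")
  expect_true(any(vapply(members, function(m) setequal(m, c("A", "B")), FALSE)))

  # identical duplicates collapse to one family whose seed is the longest
  dup <- data.frame(gene_id = c("x", "y"), genome_id = c("g1", "g2"),
                    sequence = c(a, a), stringsAsFactors = FALSE)
  fam1 <- cluster_gene_families(dup)
  expect_equal(length(fam1), 1L)
  expect_setequal(fam1[[1]]$members, c("x", "y"))
})

test_that("greedy clustering equals the independent reference implementation", {
  pc <- simulate_pangenome_collection(4, core_n = 12, accessory_pool = 6,
                                      unique_per_genome = 2, seed = 2,
                                      len_range = c(200, 400))
  genes <- pc$genes[, c("gene_id", "genome_id", "sequence")]
  expect_lte(nrow(genes), 100)
  got <- cluster_gene_families(genes, identity = 0.95, coverage = 0.90)
  oracle <- oracle_greedy_cluster(genes, identity = 0.95, coverage = 0.90)
  got_sig <- partition_signature(
    rep(seq_along(got), lengths(lapply(got, `[[`, "members"))),
    unlist(lapply(got, `[[`, "members")))
  oracle_sig <- partition_signature(
    rep(seq_along(oracle), lengths(oracle)), unlist(oracle))
  expect_identical(got_sig, oracle_sig)
})

test_that("partition recovers planted core/accessory/unique structure from sequences", {
  pc <- simulate_pangenome_collection(5, core_n = 25, accessory_pool = 10,
                                      unique_per_genome = 3, seed = 3,
                                      len_range = c(200, 400))
  fams <- cluster_gene_families(pc$genes[, c("gene_id", "genome_id", "sequence")],
                                identity = 0.95, coverage = 0.90)
  part <- partition_pangenome(fams, pc$genome_ids)
  expect_equal(length(part$core), 25L)
  expect_equal(length(part$accessory), 10L)
  expect_equal(length(part$unique), 15L)
  expect_equal(length(part$core) + length(part$accessory) +
                 length(part$unique), length(fams))
  # gene count conserved through clustering
  expect_equal(sum(lengths(lapply(fams, `[[`, "members"))), nrow(pc$genes))
})

test_that("partition classifies presence sets by their size", {
  fam_tab <- data.frame(
    family_id = c(rep("f_all", 4), "f_one", rep("f_some", 2)),
    genome_id = c("g1", "g2", "g3", "g4", "g2", "g1", "g3"),
    gene_id = paste0("gene", 1:7))
  part <- partition_pangenome(fam_tab, c("g1", "g2", "g3", "g4"))
  expect_equal(part$core, "f_all")
  expect_equal(part$unique, "f_one")
  expect_equal(part$accessory, "f_some")
  expect_setequal(part$dispensable, c("f_one", "f_some"))
  expect_error(partition_pangenome(fam_tab, c("g1", "g2")), "outside")
})

test_that("accumulation curves are monotone with exact endpoints", {
  pc <- simulate_pangenome_collection(8, core_n = 40, accessory_pool = 30,
                                      unique_per_genome = 5, seed = 4,
                                      with_sequences = FALSE)
  total <- nrow(pc$families)
  curves <- accumulation_curves(pc$genes, pc$genome_ids,
                                n_permutations = 25, seed = 5)
  expect_equal(curves$pan_median[8], total)
  expect_equal(curves$core_median[8], 40)
  expect_equal(curves$pan_median[1], curves$core_median[1])
  expect_true(all(diff(curves$pan_median) >= 0))
  expect_true(all(diff(curves$core_median) <= 0))

  # endpoint is permutation-invariant: two different seeds agree there
  curves2 <- accumulation_curves(pc$genes, pc$genome_ids,
                                 n_permutations = 25, seed = 99)
  expect_equal(curves2$pan_median[8], total)
  expect_error(accumulation_curves(pc$genes, pc$genome_ids, 0), "permutations")
})

test_that("power-law fits recover exact curves and classify openness", {
  N <- 1:12
  exact <- data.frame(N = N, pan_median = 100 * N^0.3)
  fit <- fit_pan_curve(exact)
  expect_equal(fit$gamma, 0.3, tolerance = 1e-10)
  expect_equal(fit$kappa, 100, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1.0)
  expect_equal(fit$classification, "open")

  flat <- data.frame(N = N, pan_median = rep(500, 12))
  fit2 <- fit_pan_curve(flat)
  expect_equal(fit2$gamma, 0)
  expect_equal(fit2$classification, "closed")

  nls_fit <- fit_pan_curve(exact, method = "nls")
  expect_equal(nls_fit$gamma, 0.3, tolerance = 1e-6)
  expect_error(fit_pan_curve(exact[1:2, ]), "points")
})

test_that("planted Heaps exponent is recovered from generated collections", {
  gammas <- vapply(1:5, function(s) {
    pc <- simulate_pangenome_collection(15, seed = s, gamma_target = 0.25,
                                        kappa = 300, with_sequences = FALSE)
    curves <- accumulation_curves(pc$genes, pc$genome_ids,
                                  n_permutations = 50, seed = s + 100)
    fit_pan_curve(curves)$gamma
  }, 0)
  expect_lt(abs(mean(gammas) - 0.25), 0.05)
})

test_that("core-curve exponential fit reports parameters", {
  N <- 1:10
  core <- 800 + 400 * exp(-N / 3)
  fit <- fit_core_curve(data.frame(N = N, core_median = core))
  expect_equal(fit$c, 800, tolerance = 1e-4)
  expect_equal(fit$tau, 3, tolerance = 1e-4)
})

test_that("pathway completeness evaluates both butyrate routes", {
  part <- partition_pangenome(data.frame(
    family_id = c(rep(c("f1", "f2", "f3", "f4", "f5", "f6"), each = 3), "f7"),
    genome_id = c(rep(c("g1", "g2", "g3"), 6), "g2"),
    gene_id = paste0("gene", 1:19)), c("g1", "g2", "g3"))
  expr <- "Thl & Hbd & Cro & Bcd & (But | (Ptb & Buk))"

  ann_core <- data.frame(family_id = c("f1", "f2", "f3", "f4", "f5"),
                         symbol = c("Thl", "Hbd", "Cro", "Bcd", "But"))
  expect_equal(pathway_completeness(part, ann_core, expr), "complete_in_core")

  # But missing, Ptb+Buk in core: the alternative branch suffices
  ann_alt <- data.frame(family_id = c("f1", "f2", "f3", "f4", "f5", "f6"),
                        symbol = c("Thl", "Hbd", "Cro", "Bcd", "Ptb", "Buk"))
  expect_equal(pathway_completeness(part, ann_alt, expr), "complete_in_core")

  # Bcd only in a unique family: complete in the pan-genome only
  ann_pan <- data.frame(family_id = c("f1", "f2", "f3", "f7", "f5"),
                        symbol = c("Thl", "Hbd", "Cro", "Bcd", "But"))
  expect_equal(pathway_completeness(part, ann_pan, expr),
               "complete_in_pan_only")

  ann_missing <- ann_pan[1:3, ]
  expect_equal(pathway_completeness(part, ann_missing, expr), "incomplete")

  expect_error(pathway_completeness(part, ann_core, "Thl & ; drop"),
               "malformed")
  expect_error(pathway_completeness(part, ann_core, "Thl & Zzz",
                                    known_symbols = c("Thl", "Hbd")),
               "unknown symbol")
})
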