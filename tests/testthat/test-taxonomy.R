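test_that("fragment ANI is exact on self and recovers planted divergence", {
  g <- simulate_genome(30000, 0.45, seed = 1, id = "g")
  asm <- anipan:::as_assembly(g)
  self <- fragment_ani(asm, asm)
  expect_equal(self$ani, 100)
  expect_equal(self$aligned_fraction, 1.0)
  expect_equal(self$n_fragments_total, 30000 %/% 1020)

  e <- evolve_sequence(g$sequence, round(0.05 * 30000), seed = 2)
  r <- fragment_ani(asm, genome_assembly(c(s1 = e$sequence), id = "mut"))
  expect_true(r$defined)
  expect_equal(r$ani, 95.0, tolerance = 0.3 / 95)
  expect_equal(r$aligned_fraction, 1.0)
})

test_that("unrelated random genomes yield undefined ANI", {
  a <- anipan:::as_assembly(simulate_genome(20000, 0.45, seed = 3, id = "a"))
  b <- anipan:::as_assembly(simulate_genome(20000, 0.45, seed = 4, id = "b"))
  r <- fragment_ani(a, b)
  expect_false(r$defined)
  expect_true(is.na(r$ani))
  expect_equal(r$n_fragments_aligned, 0L)
})

test_that("ANI parameter recovery across substitution rates", {
  g <- simulate_genome(30000, 0.5, seed = 5, id = "base")
  asm <- anipan:::as_assembly(g)
  for (rate in c(0.01, 0.03, 0.08)) {
    e <- evolve_sequence(g$sequence, round(rate * 30000),
                         seed = round(1000 * rate))
    r <- fragment_ani(asm, genome_assembly(c(s1 = e$sequence), id = "m"))
    expect_lt(abs(r$ani - 100 * (1 - rate)), 0.5)
  }
})

test_that("symmetric ANI averages both directions", {
  g <- simulate_genome(15000, 0.5, seed = 6, id = "a")
  e <- evolve_sequence(g$sequence, 300, seed = 7)
  b <- genome_assembly(c(s1 = e$sequence), id = "b")
  ab <- fragment_ani(g, b)$ani
  ba <- fragment_ani(b, g)$ani
  expect_equal(ani_between(g, b), mean(c(ab, ba)))
})

test_that("species assignment stops early at the true reference", {
  col <- make_species_collection(4, 2, 15000, intra_rate = 0.02, seed = 8)
  refs <- col$genomes[sprintf("sp%02d_g1", 1:4)]
  queries <- col$genomes[sprintf("sp%02d_g2", 1:4)]
  refdb <- reference_db(refs)
  for (qid in names(queries)) {
    res <- assign_species(queries[[qid]], refdb)
    expect_equal(res$status, "assigned")
    expect_equal(col$truth[res$matched_reference], col$truth[qid],
                 ignore_attr = TRUE)
    expect_equal(res$n_comparisons_done, 1L)
    expect_gt(res$value, 95)
  }
})

test_that("assignment against unrelated references fails cleanly", {
  q <- simulate_genome(15000, 0.45, seed = 20, id = "q")
  refs <- list(r1 = simulate_genome(15000, 0.44, seed = 21, id = "r1"),
               r2 = simulate_genome(15000, 0.46, seed = 22, id = "r2"))
  res <- assign_species(q, reference_db(refs))
  expect_equal(res$status, "not_assigned")
  expect_true(is.na(res$matched_reference))
})

test_that("assignment thresholds are strict and the budget is capped", {
  q <- simulate_genome(15000, 0.45, seed = 23, id = "q")
  qp <- tetra_profile(anipan:::as_assembly(q))
  fake_profile <- function(id, i) {
    structure(list(genome_id = id, z = qp$z + rnorm(256, 0, 0.05)),
              class = "tetra_profile")
  }
  set.seed(24)
  n_fake <- 520L
  ids <- sprintf("ref%04d", seq_len(n_fake))
  refdb <- structure(list(
    assemblies = setNames(vector("list", n_fake), ids),
    profiles = setNames(lapply(seq_len(n_fake), function(i)
      fake_profile(ids[i], i)), ids),
    proteomes = NULL, ids = ids), class = "reference_db")

  # ANI exactly at the threshold is NOT an assignment (strict >)
  res <- assign_species(q, refdb, ani_fun = function(q, r, ...) 95)
  expect_equal(res$status, "not_assigned")
  expect_equal(res$n_comparisons_done, 500L) # budget cap, never 520

  res2 <- assign_species(q, refdb, ani_fun = function(q, r, ...) 95.01)
  expect_equal(res2$status, "assigned")
  expect_equal(res2$n_comparisons_done, 1L)

  # POCP loop: exactly 50 is not assigned; strictly above is
  refdb$proteomes <- setNames(as.list(ids), ids)
  resg <- assign_genus("Q", q, refdb, pocp_fun = function(a, b) 50)
  expect_equal(resg$status, "not_assigned")
  expect_equal(resg$n_comparisons_done, 500L)
  resg2 <- assign_genus("Q", q, refdb, pocp_fun = function(a, b) 50.5)
  expect_equal(resg2$status, "assigned")
  expect_equal(resg2$level, "genus")
})

test_that("POCP is exact on identical proteomes, symmetric, and near zero on unrelated ones", {
  pa <- simulate_proteome(40, len_range = c(80, 160), seed = 30)
  expect_equal(pocp(pa, pa)$pocp, 100)

  pb <- evolve_proteome(pa, shared_fraction = 0.5, sub_rate = 0.1, seed = 31)
  ab <- pocp(pa, pb)
  ba <- pocp(pb, pa)
  expect_equal(ab$pocp, ba$pocp)
  expect_equal(ab$C1, ba$C2)
  expect_equal(ab$pocp, 100 * (ab$C1 + ab$C2) / (ab$T1 + ab$T2))

  pu <- simulate_proteome(40, len_range = c(80, 160), seed = 32)
  expect_lt(pocp(pa, pu)$pocp, 5)
  expect_error(pocp(character(0), pa), "non-empty")
})

test_that("genus recovery through the POCP loop on simulated genus structure", {
  g <- simulate_genome(15000, 0.45, seed = 33, id = "q")
  qprot <- simulate_proteome(30, len_range = c(80, 150), seed = 34)
  # same genus: shared proteome + similar genome; other: unrelated
  same_genus_prot <- evolve_proteome(qprot, shared_fraction = 0.9,
                                     sub_rate = 0.08, seed = 35)
  same_genus_gen <- genome_assembly(
    c(s1 = evolve_sequence(g$sequence, 2200, seed = 36)$sequence),
    id = "genusmate")
  other <- simulate_genome(15000, 0.5, seed = 37, id = "other")
  refdb <- reference_db(list(genusmate = same_genus_gen, other = other),
                        proteomes = list(
                          genusmate = same_genus_prot,
                          other = simulate_proteome(30, seed = 38)))
  res <- assign_genus(qprot, g, refdb)
  expect_equal(res$status, "assigned")
  expect_equal(res$matched_reference, "genusmate")
  expect_gt(res$value, 50)
})

test_that("novelty calls honour the 98.7 / 94.5 / 86.5 thresholds", {
  expect_equal(novelty_call(99.1)$rank, "known")
  expect_equal(novelty_call(98.7)$rank, "known")
  expect_equal(novelty_call(97.0)$rank, "novel_species")
  expect_equal(novelty_call(94.5)$rank, "novel_species")
  expect_equal(novelty_call(86.5)$rank, "novel_genus")
  expect_equal(novelty_call(86.4)$rank, "novel_family")
  expect_error(novelty_call(101), "best_identity")
  expect_error(novelty_call(-2), "best_identity")
})
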