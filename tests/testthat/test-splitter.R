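test_that("scaffold features: GC extremes and standardized axes", {
  asm <- genome_assembly(c(a = strrep("GC", 500), b = strrep("AT", 500),
                           c = strrep("ACGT", 250)),
                         depth = c(a = 50, b = 50, c = 50), id = "t")
  f <- scaffold_features(asm)
  expect_equal(f$gc[f$scaffold_id == "a"], 100)
  expect_equal(f$gc[f$scaffold_id == "b"], 0)
  expect_true(all(is.finite(f$gc_z)) && all(is.finite(f$depth_z)))
  expect_equal(mean(f$gc_z), 0, tolerance = 1e-12)
  expect_equal(f$depth_z, rep(0, 3)) # constant depth: zero spread
  expect_error(scaffold_features(genome_assembly(c(x = "ACGT"), id = "n")),
               "depth")
})

test_that("density clustering follows DBSCAN semantics", {
  blob <- function(cx, cy, n, s = 0.05) {
    data.frame(gc_z = rnorm(n, cx, s), depth_z = rnorm(n, cy, s))
  }
  set.seed(1)
  pts <- rbind(blob(-1, -1, 30), blob(1, 1, 30))
  labels <- density_cluster(pts, eps = 0.5, min_pts = 3)
  expect_equal(sort(unique(labels)), c(1L, 2L))
  expect_equal(unname(table(labels)[c("1", "2")]), c(30L, 30L),
               ignore_attr = TRUE)

  same <- data.frame(gc_z = rep(0, 10), depth_z = rep(0, 10))
  expect_equal(unique(density_cluster(same, eps = 0.5, min_pts = 3)), 1L)

  lonely <- rbind(blob(0, 0, 10), data.frame(gc_z = 5, depth_z = 5))
  lab <- density_cluster(lonely, eps = 0.5, min_pts = 3)
  expect_equal(lab[11], -1L)
  expect_error(density_cluster(same, eps = 0), "eps")
})

test_that("multi-genome detection triggers strictly above 5% contamination", {
  expected <- sprintf("m%02d", 1:20)
  clean <- data.frame(marker_id = expected, scaffold_id = "s1",
                      copy_count = 1L)
  expect_false(detect_multigenome(clean, expected))

  double <- rbind(clean, clean)
  double$scaffold_id <- rep(c("s1", "s2"), each = 20)
  expect_true(detect_multigenome(double, expected)) # contamination 100%

  # exactly 5.0% is not a trigger
  one_dup <- rbind(clean, data.frame(marker_id = expected[1],
                                     scaffold_id = "s2", copy_count = 1L))
  expect_equal(marker_completeness(one_dup, expected)$contamination, 5)
  expect_false(detect_multigenome(one_dup, expected))
})

test_that("rescue assignment honours hit-length and coverage thresholds", {
  set.seed(2)
  refA <- anipan:::as_assembly(simulate_genome(5000, 0.5, seed = 3, id = "A"))
  refB <- anipan:::as_assembly(simulate_genome(5000, 0.5, seed = 4, id = "B"))
  refs <- list(A = refA, B = refB)

  # 200-nt scaffold: 150 nt from A + 50 nt random -> A at 75% coverage
  frag <- substr(as.character(refA$sequences[[1]]), 1001, 1150)
  scaffold <- paste0(frag, anipan:::random_dna(50))
  r <- rescue_assign(scaffold, refs)
  expect_equal(r$reference_id, "A")
  expect_gte(r$coverage, 0.5)
  expect_gt(r$best_hit_len, 90)

  # best hit of only ~80 nt: below the >90 nt rule -> unassigned
  short <- paste0(substr(as.character(refA$sequences[[1]]), 2001, 2080),
                  anipan:::random_dna(40))
  r2 <- rescue_assign(short, refs)
  expect_true(is.na(r2$reference_id))

  # hits to both references; tie on covered length -> lexicographic id
  shared <- substr(as.character(refA$sequences[[1]]), 3001, 3200)
  refB2 <- genome_assembly(c(s1 = paste0(
    anipan:::random_dna(500), shared, anipan:::random_dna(500))), id = "B")
  r3 <- rescue_assign(shared, list(B = refB2, A = refA))
  expect_equal(r3$reference_id, "A")
  expect_error(rescue_assign("ACGT", list()), "candidate")
})

test_that("a clean single-genome assembly is returned as one component", {
  g <- simulate_genome(30000, 0.45, seed = 5, id = "solo")
  sim <- simulate_mixed_assembly(list(list(genome = g, depth = 60)),
                                 markers_per_genome = 20, seed = 6)
  res <- split_assembly(sim$assembly, sim$markers, sim$expected_markers)
  expect_false(res$multi_genome)
  expect_equal(length(res$components), 1L)
  expect_equal(nrow(res$rescue_log), 0L)
  expect_setequal(names(res$components[[1]]$sequences),
                  names(sim$assembly$sequences))
})

test_that("a two-genome mixture splits into two accurate components", {
  gA <- simulate_genome(50000, 0.35, seed = 7, id = "gA")
  gB <- simulate_genome(50000, 0.60, seed = 8, id = "gB")
  sim <- simulate_mixed_assembly(list(list(genome = gA, depth = 80),
                                      list(genome = gB, depth = 40)),
                                 scaffold_len = c(3000, 8000),
                                 markers_per_genome = 20, seed = 9)
  refdb <- reference_db(list(refA = anipan:::as_assembly(gA),
                             refB = anipan:::as_assembly(gB)))
  res <- split_assembly(sim$assembly, sim$markers, sim$expected_markers,
                        refdb = refdb)
  expect_true(res$multi_genome)
  expect_equal(length(res$components), 2L)

  # conservation: every input scaffold lands in exactly one output bin
  out_ids <- c(unlist(lapply(res$components, function(a)
    names(a$sequences))), res$unassigned)
  expect_setequal(out_ids, names(sim$assembly$sequences))
  expect_equal(length(out_ids), length(sim$assembly$sequences))

  # accuracy vs truth (labels up to renaming)
  truth <- sim$truth$scaffold_map[names(res$labels)]
  tab <- table(truth, res$labels)
  acc <- sum(apply(tab, 2, max)) / length(res$labels)
  expect_equal(acc, 1.0)

  # per-component validation is clean after the split
  expect_true(all(res$validation$completeness == 100))
  expect_true(all(res$validation$contamination == 0))
})

test_that("split results are deterministic and writable", {
  gA <- simulate_genome(30000, 0.38, seed = 10, id = "gA")
  gB <- simulate_genome(30000, 0.58, seed = 11, id = "gB")
  mk <- function() {
    sim <- simulate_mixed_assembly(list(list(genome = gA, depth = 90),
                                        list(genome = gB, depth = 30)),
                                   markers_per_genome = 10, seed = 12)
    split_assembly(sim$assembly, sim$markers, sim$expected_markers)
  }
  r1 <- mk(); r2 <- mk()
  expect_identical(r1$labels, r2$labels)

  sim <- simulate_mixed_assembly(list(list(genome = gA, depth = 90),
                                      list(genome = gB, depth = 30)),
                                 markers_per_genome = 10, seed = 12)
  dir <- withr::local_tempdir()
  write_split_result(r1, sim$assembly, dir)
  expect_true(file.exists(file.path(dir, "split_report.tsv")))
  expect_true(file.exists(file.path(dir, "validation.json")))
  report <- read.table(file.path(dir, "split_report.tsv"), header = TRUE,
                       sep = "\t")
  expect_equal(nrow(report), length(sim$assembly$sequences))
})
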