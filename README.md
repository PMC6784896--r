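# anipan

Analytics for building curated collections of cultivated bacterial
isolate genomes — the computational steps between "a pile of isolate
assemblies" and "a nonredundant, quality-gated, taxonomically resolved
genome resource with per-species pan-genomes".

Microbiome reference catalogs are built by culturing thousands of
isolates (e.g. from human gut samples), sequencing and assembling them,
then: splitting assemblies that accidentally contain more than one
organism, assigning taxonomy against all available reference genomes,
discarding low-quality drafts, collapsing the survivors into
species-level clusters, and characterising each cluster's pan-genome.
anipan implements each of those steps as tested R functions, driven
end-to-end by a synthetic-data module with known ground truth, so the
whole pipeline is verifiable without any external database.

## What is implemented

- **Alignment core** — affine-gap Smith–Waterman (Rcpp) with
  deterministic tracebacks, seed-and-extend genome search, and
  Karlin–Altschul E-values: `local_align()`, `seed_and_extend()`,
  `karlin_altschul_evalue()`, `scoring_scheme()`.
- **Taxonomy** — tetranucleotide signature profiles (256 z-scores,
  order-2 Markov expectation) rank references by Pearson correlation
  (keep r > 0, p < 0.001); fragment ANI (1,020-bp fragments, keep rule
  identity ≥ 30% over ≥ 70% length, ANI = mean kept identity) is then
  computed reference-by-reference until ANI > 95% (species assigned) or
  500 comparisons are spent; unassigned genomes fall through to POCP,
  POCP = 100·(C1+C2)/(T1+T2), assigned when > 50%. 16S novelty bands at
  98.7/94.5/86.5%: `tetra_profile()`, `rank_references()`,
  `fragment_ani()`, `assign_species()`, `pocp()`, `assign_genus()`,
  `novelty_call()`.
- **Quality** — the six HMP high-quality draft criteria (strict >: 90%
  in contigs > 500 bp, 90% of bases > 5×, contig N50 > 5 kb, scaffold
  N50 > 20 kb, avg contig > 5 kb, > 90% core genes) plus single-copy
  marker completeness/contamination and the completeness > 95% /
  contamination < 5% resource gate: `assembly_stats()`,
  `marker_completeness()`, `hmp_quality()`, `n50()`.
- **Splitter** — DBSCAN over z-standardized (GC%, log10 depth),
  marker-based validation, closest-reference search (ANI > 90) and
  rescue of noise/mis-split scaffolds (hit > 90 nt, coverage ≥ 50%):
  `scaffold_features()`, `density_cluster()`, `detect_multigenome()`,
  `rescue_assign()`, `split_assembly()`.
- **Species clustering** — pairwise two-direction mean ANI distances
  d = 1 − ANI/100 (undefined pairs capped at 0.3), complete-linkage
  hierarchical clustering cut at 0.05 (the 95%-ANI species boundary),
  N50-longest representatives: `ani_distance_matrix()`,
  `cluster_species()`, `representatives()`.
- **Pan-genome** — greedy incremental gene-family clustering (95%
  identity over 90% of the shorter sequence by default), core /
  accessory / unique partition, permutation accumulation curves,
  Heaps-law fit pan(N) = κ·N^γ (open when γ ≥ 0.05), exact paired
  Wilcoxon signed-rank enrichment of functional categories in core vs
  dispensable genomes, boolean pathway-completeness calls:
  `cluster_gene_families()`, `partition_pangenome()`,
  `accumulation_curves()`, `fit_pan_curve()`,
  `exact_signed_rank_test()`, `category_enrichment()`,
  `pathway_completeness()`.
- **Synthetic data** — genomes at target GC, divergence planted as exact
  substitution counts, multi-genome mixed assemblies with depth noise
  and single-copy marker tags, pan-genome collections with explicit
  structure or a planted Heaps exponent: `simulate_genome()`,
  `evolve_sequence()`, `simulate_mixed_assembly()`,
  `simulate_pangenome_collection()`, `simulate_proteome()`.

See the methods vignette
(`vignettes/genome-resource-analytics.Rmd`) for the models, parameter
choices and limitations.

## Worked example

```r
library(anipan)

# a 50-kb isolate genome and a reference diverged by 2% substitutions
g   <- simulate_genome(50000, 0.42, seed = 1, id = "isolateA")
rel <- evolve_sequence(g$sequence, round(0.02 * 50000), seed = 2)
ref <- genome_assembly(c(s1 = rel$sequence), id = "refA")

fragment_ani(g, ref)
#> ANI isolateA -> refA: 98.01% (49/49 fragments kept)

refdb <- reference_db(list(refA = ref,
                           other = simulate_genome(50000, 0.55, seed = 3, id = "other")))
assign_species(g, refdb)
#> species-level assignment for 'isolateA': assigned to 'refA' (98.01) after 1 comparison(s)

# a 6-genome cluster with planted 100/50/(6 x 10) structure
pc   <- simulate_pangenome_collection(6, core_n = 100, accessory_pool = 50,
                                      unique_per_genome = 10, seed = 4)
fams <- cluster_gene_families(pc$genes[, c("gene_id", "genome_id", "sequence")])
partition_pangenome(fams, pc$genome_ids)
#> pan_partition over 6 genomes: 100 core, 50 accessory, 60 unique

curves <- accumulation_curves(pc$genes, pc$genome_ids, n_permutations = 50, seed = 5)
fit_pan_curve(curves)
#> pan curve fit: pan(N) = 140.2 * N^0.220 (r2 = 0.998) -> open

exact_signed_rank_test((1:38) + 0.25, rep(0, 38))
#> signed-rank test: n = 38, W = 741, p = 7.28e-12 (exact)
```

The ANI of 98.01% is the mean identity of all 49 alignable 1,020-bp
fragments — the planted 2% divergence recovered to within a tenth of a
point. The tetranucleotide prefilter put `refA` first, so the assignment
loop stopped after a single ANI computation. Sequence-level clustering
recovered the planted pan-genome partition exactly, the fitted exponent
γ = 0.22 calls the pan-genome open, and 38 paired observations all
differing in the same direction sit at the exact signed-rank two-sided
floor 2/2³⁸ ≈ 7.28 × 10⁻¹².

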