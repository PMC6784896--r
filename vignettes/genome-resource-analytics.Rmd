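---
title: "Methods: building and analysing an isolate genome resource"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and analysing an isolate genome resource}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anipan)
```

# Scope

anipan implements the desk-scale analytics needed to turn a collection of
cultivated bacterial isolate assemblies into a curated genome resource:

1. detecting and **splitting multi-genome isolates** in (GC%, depth) space,
2. **taxonomy assignment** by tetranucleotide-prefiltered fragment ANI
   (species) and POCP (genus), with 16S novelty banding,
3. **draft-quality gating** against the six HMP high-quality draft criteria
   plus single-copy-marker completeness/contamination,
4. **species clustering** of the retained genomes at the 95%-ANI boundary,
5. **pan-genome analytics** per species cluster: core/accessory/unique
   partition, accumulation curves, Heaps-law openness, functional
   enrichment and pathway-completeness calls.

Everything runs on synthetic genomes generated in-package with known
ground truth; no external sequence database is required. Read assembly,
gene prediction, database annotation (KEGG/COG/CARD lookups), 16S
extraction and phylogenetic tree building are out of scope: annotations,
depth summaries and 16S best identities arrive as plain tables.

# The alignment core

All sequence comparison rests on one affine-gap Smith–Waterman engine
(Rcpp). The default DNA scheme is match +1, mismatch −2, gap open 5, gap
extend 2 (a gap of length $L$ costs $\mathrm{open} + L\cdot\mathrm{ext}$);
proteins use BLOSUM62 with gap open 11, extend 1. These are classic
aligner defaults; no published identity threshold in the pipeline is
sensitive to them at the divergences involved. Identity is defined as
matches over aligned columns including gaps. For DNA both strands are
searched; ties prefer the forward strand, and the traceback is fully
deterministic (earliest maximal cell; diagonal preferred over gaps), so
every downstream result is reproducible bit-for-bit.

`seed_and_extend()` accelerates genome-scale search: exact $k$-mers
($k = 15$ by default) of the query are looked up in a hash of the target,
the best-supported diagonal band is chosen by voting (bucket width 16),
and full Smith–Waterman runs on a windowed target (margin 120 bp). When a
seed overlaps the optimal alignment the result equals the full DP; the
suite verifies ≥ 99% score agreement at 95% identity, and sequences
sharing no $k$-mer correctly return no hit.

E-values use the ungapped Karlin–Altschul form $E = K m n e^{-\lambda S}$
with fixed published parameters per scheme (DNA $\lambda = 1.28$,
$K = 0.46$; BLOSUM62 $\lambda = 0.3176$, $K = 0.134$). Reproducing an
external aligner's E-values exactly is a non-goal; the only place E
matters is the POCP conservation cutoff ($E < 10^{-5}$), which true
homologs in the tested regimes pass by many orders of magnitude.

# Taxonomy assignment

**Tetranucleotide prefilter.** A genome's signature is the 256-vector of
4-mer z-scores, $(O - E)/\sqrt{V}$, with expectation from the maximal-order
(order-2) Markov model of the same sequence — the standard tetra
convention; a raw-frequency mode is available behind a flag since the
normalization choice is genuinely open. Counting both strands makes the
profile strand-invariant. References are ranked by Pearson $r$ over the
256 entries (two-sided $p$ from the $t$ transform at 254 df), keeping
only $r > 0$, $p < 0.001$.

**Fragment ANI.** The query is cut into non-overlapping 1,020-bp
fragments; each is mapped by seed-and-extend; fragments with identity
≥ 30% over ≥ 70% of their length are kept, and ANI is the mean identity
of kept fragments. The 1,020/30%/70% parameters follow the established
fragment-ANI method; scaffold tails shorter than one fragment are
dropped, which keeps ANI(g, g) = 100 exact. ANI is reported per
direction; the species-clustering distance uses the two-direction mean,
while the assignment loop uses query→reference only. Both conventions
are exposed because the directionality used for published collections is
typically unstated.

**Assignment loops.** Walking the ranked list, the species loop stops at
the first reference with ANI *strictly* greater than 95, the genus loop
at POCP strictly greater than 50, both capped at 500 comparisons. A
value of exactly 95.0 (or 50.0) is therefore *not* an assignment. POCP is
$100(C_1+C_2)/(T_1+T_2)$ where a protein is conserved if its best hit in
the other proteome has $E < 10^{-5}$, identity > 40% and an alignable
region covering > 50% of the query length.

**16S novelty.** Best-identity bands at 98.7 / 94.5 / 86.5% give
known / novel species / novel genus / novel family, inclusive at each
band's lower bound. The identity itself is an input; 16S extraction is
out of scope.

# Quality gating

The six HMP draft criteria are applied with strict inequalities: > 90%
of the assembly in contigs > 500 bp, > 90% of bases above 5× coverage,
contig N50 > 5 kb, scaffold N50 > 20 kb, average contig > 5 kb, > 90% of
core genes present. Because depth arrives as per-scaffold means, the
coverage criterion weights scaffold lengths by mean depth rather than
using per-base depth. Completeness/contamination use a user-supplied
expected single-copy marker list: completeness is the percentage of
expected markers present, contamination the percentage of extra copies
beyond one. Duplicates never raise completeness, so completeness is
bounded by 100 and the duplicate signal lives entirely in contamination;
the overall resource gate additionally requires completeness > 95% and
contamination < 5%. rRNA completeness (5S/16S/23S flags) is reported but
gates nothing.

# Splitting multi-genome isolates

Splitting triggers when marker contamination exceeds 5%. Scaffolds are
embedded in (GC%, $\log_{10}$ depth) — depth is log-transformed because
coverage is multiplicative — and both axes are z-standardized. DBSCAN
with `eps = 0.5`, `min_pts = 3` in this standardized plane separates the
component clouds; no density parameters are published for this step, so
the defaults are declared choices, configurable, and the acceptance
checks show they split mixtures separated by ≥ 3 SD cleanly. Components
with marker contamination > 15% are flagged; flagged components (and all
noise scaffolds, which are routed to rescue rather than dropped —
conservation over silent loss) are aligned to each component's closest
reference (assignment-style search restricted to ANI > 90). A rescue
candidate qualifies with a best hit > 90 nt covering ≥ 50% of the
scaffold; the greatest covered length wins, ties going to the smaller
reference id. Scaffolds no candidate claims go to an explicit
unassigned bin, so input sequence is always conserved across outputs.

# Species clustering

Pairwise two-direction mean ANI gives distances $d = 1 - \mathrm{ANI}/100$;
pairs with undefined ANI (no qualifying fragments in either direction)
are set to a cap of 0.3. Any cap above the cut yields the identical
partition — the cap only keeps the matrix finite, and the matrix is
documented as non-metric. Agglomerative clustering (complete linkage by
default; the linkage used for published collections is unstated, and
single/average are exposed) is cut at height 0.05, the 95%-ANI species
boundary. Cluster labels are renumbered by smallest member id, making
the partition invariant to input order. Representatives maximise
scaffold N50 (the contig-vs-scaffold choice is unstated in the sources
this package follows; scaffold N50 is the default and configurable),
with ties broken by total length then id.

# Pan-genome analytics

**Gene families.** Greedy incremental clustering: genes sorted by
decreasing length join the first family whose seed they match at the
identity/coverage thresholds, else found a new family — so seeds are
always their family's longest member and the procedure is deterministic.
The gene-catalog preset is 95% identity over 90% of the shorter
sequence; pan-genome analyses default to broader identity (0.50 on
proteins) and the deep protein-space preset measures coverage on the
longer sequence. A shared-$k$-mer prescreen (DNA $k = 12$, protein
$k = 5$) only skips pairs that cannot reach the identity threshold.

**Partition and curves.** Families in all genomes are core, in exactly
one unique, otherwise accessory; accessory ∪ unique is the dispensable
genome. Accumulation curves report median pan/core sizes over random
genome orderings; endpoints are order-invariant by construction.
Openness is fitted as $\mathrm{pan}(N) = \kappa N^{\gamma}$ by ordinary
least squares on the log-log scale (a nonlinear fit is available behind
a flag), with $\gamma \ge 0.05$ called open — a declared threshold, not
an inferred one. The core curve gets a secondary exponential-decay fit,
reported without classification.

**Enrichment.** Core-vs-dispensable category enrichment across clusters
uses the *exact paired Wilcoxon signed-rank test*: per category, the
per-cluster percentages of core and dispensable genes form the pairs,
and the null distribution of the positive-rank sum is enumerated by
dynamic programming (exact for $n \le 50$ without ties; the two-sided
floor at $n$ clusters is $2/2^{n}$, i.e. $7.28\times10^{-12}$ at
$n = 38$). Published legends in this area often label the statistic a
"rank-sum" test while reporting p-value floors only the paired
signed-rank test can attain; this implementation follows the numbers,
and the suite cross-checks against `wilcox.test`. With ties or larger
$n$ it falls back to the tie-corrected normal approximation with
continuity correction.

**Pathways.** Pathway completeness evaluates a boolean expression over
enzyme symbols — e.g. the two acetyl-CoA→butyrate routes
`Thl & Hbd & Cro & Bcd & (But | (Ptb & Buk))` — first against symbols
annotated on core families, then against the whole pan-genome, reporting
the first level satisfied.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
study conditions the package is validated under:

- **Genomes** are i.i.d. base sequences at a target GC; divergence is
  planted as a fixed count of substitutions at distinct positions, so
  true identity is exactly $(L - n_{\mathrm{sub}})/L$. Indels can be
  added but are bookkept separately — substituted-only identity is the
  truth value, which keeps ANI recovery targets exact.
- **Mixed assemblies** fragment each component genome into scaffolds of
  uniform random length (5–15 kb by default), draw per-scaffold depth
  lognormally (σ = 0.1) around the component mean, and insert a fixed
  catalog of 300-bp single-copy marker tags once per genome, so marker
  detection is exact string search and two-genome mixtures carry a 100%
  marker-contamination signal.
- **Pan-genome collections** either take explicit core/accessory/unique
  counts, or plant a Heaps exponent: occurrence counts per family are
  designed by non-negative least squares against
  $\mathbb{E}[\mathrm{pan}(N)] = \sum_f \left(1 - \binom{n-k_f}{N}/\binom{n}{N}\right)$
  so that the expected accumulation curve over random orderings tracks
  $\kappa N^{\gamma}$. (Schemes in which "genome $j$ adds $n_j$ new
  genes" are linear in expectation under permutation and cannot plant a
  power law.) Family members are mutated copies of a family seed at 98%
  identity by default.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: repeats and mobile elements, compositional
heterogeneity along a genome (the tetra prefilter is easier here than in
nature), assembly chimerism, fragmented or frameshifted genes, uneven
strain abundance within an isolate, and real annotation noise. The
recovery results should be read as correctness checks of the
implementation under its stated model, not as field benchmarks.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-variance tetra profiles
and empty expected-marker sets are errors; undefined ANI is flagged, not
silently zero; all-zero signed-rank differences are surfaced (and mapped
to $p = 1$ in the enrichment table); constant feature axes standardize
to zero rather than dividing by zero. All randomized operations take
explicit seeds and restore the caller's RNG state.

The validation suite and the acceptance script run, as the package's own
choice of study sizes: 100-kb genome pairs at substitution rates
1/3/5/8% for ANI recovery (tolerance ±0.5 points); a 10-species ×
4-genome collection of 20-kb genomes for clustering recovery (ARI = 1 at
cut 0.05); 60-kb two-genome mixtures with 5% injected noise scaffolds
for the splitter (≥ 99% assignment accuracy); 160–220-gene collections
for exact partition recovery; and 20 seeds of 15-genome collections for
Heaps recovery (mean γ within ±0.05 of the planted 0.25).

# Known limitations

- The greedy gene-family rule compares members to family *seeds* only
  (as greedy incremental tools do); borderline chains can differ from a
  full-linkage clustering.
- `local_align()` is quadratic and guarded against very large inputs;
  genome-scale comparisons must go through `seed_and_extend()` or
  `fragment_ani()`.
- The splitter assumes components separate in (GC, depth); genuinely
  overlapping clouds will under-split regardless of parameters, which is
  why marker-based validation and rescue exist.
- POCP on very small proteomes is coarse: single conserved proteins move
  the percentage by whole points.
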