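---
title: "Methods: metapangenome and phylosymbiosis analysis with endopan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metapangenome and phylosymbiosis analysis with endopan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endopan)
```

`endopan` analyses plant endosphere shotgun metagenomes downstream of
assembly, annotation, and ortholog clustering: taxonomically binned
scaffolds and Roary-style gene cluster matrices go in; diversity
statistics, core/shell/cloud partitions, GO enrichment tables, and a
host-concordance screen of gene trees come out. This vignette explains
the statistical procedures, the conventions that make them
deterministic, the design of the synthetic-data generator used for
validation, and the limits of what that validation shows.

## Taxonomic binning and abundance profiles

A scaffold is assigned to the subject taxon of its best alignment hit:
among hits with e-value at most `e_threshold` (default 1e-5, the
conventional cutoff for protein-level searches of assembled
metagenomes), the maximum bitscore wins; ties are broken by smaller
e-value and then lexicographically smaller taxon name, so binning does
not depend on row order. We use best-hit rather than lowest common
ancestor binning because the downstream partitions operate on the
lowest annotated rank (species or strain bins); an LCA scheme would
collapse exactly the strain-level resolution the set analyses need.

Read counts are summed per (taxon, sample) over each sample's binned
scaffolds; `"unclassified"` is kept as an ordinary row so column totals
conserve the input reads exactly. Two normalizations are offered:

- `normalize_to_median()` rescales each sample to the median library
  size (the median of all column totals; an idempotent linear scaling,
  with per-sample factors recorded in an attribute). We read "the
  median of the sample read counts" as the median over all samples; the
  alternative reading (the midpoint of only the largest and smallest
  libraries) would be a midrange, not a median.
- `subsample_scaffolds_by_coverage()` equalizes assembly effort before
  presence/absence set comparisons: per sample, scaffolds are sorted by
  coverage (descending, ties by longer length then id) and the top
  `ceiling(R_min/R_s * n_s)` are kept, i.e. low-coverage scaffolds are
  removed in inverse proportion to the sample's read count, and the
  smallest library keeps everything. Retention is by scaffold count;
  a length-weighted variant would change which marginal scaffolds
  survive but not the ordering principle, and is deliberately not
  implemented until a use case needs it.

A taxon "occurs" in a sample when at least one raw read maps to it;
presence thresholds above 1 read are left to the caller.

## Diversity statistics

All indices and tests are computed from their defining formulas (the
test suite checks them against independent brute-force sums, and
against `vegan` and `stats` where those implement the same quantity):

- Shannon `H = -Σ p_i ln p_i` with natural logarithm (the ecology
  default; the base is an argument), Gini–Simpson `D = 1 - Σ p_i²`,
  bias-corrected Chao1 `S_obs + F₁(F₁-1)/(2(F₂+1))`, and ACE with the
  standard rare-abundance cutoff of 10. ACE is undefined when every
  rare taxon is a singleton (sample coverage 0); this raises an error
  rather than returning a silent fallback.
- Rarefaction draws subsamples without replacement via sequential
  hypergeometric sampling; at depth N it returns `S_obs` exactly, and
  the expectation matches the closed form
  `Σ_i [1 - C(N-n_i, d)/C(N, d)]`.
- Bray–Curtis dissimilarity `d(x,y) = Σ|x_i-y_i| / Σ(x_i+y_i)` on
  counts (raw or median-normalized, at the caller's choice).
- PCoA eigendecomposes the Gower-centred matrix `B = -½ J D² J`;
  negative eigenvalues (expected for non-Euclidean dissimilarities) are
  reported and their axes dropped from the coordinates.
- NMDS minimizes Kruskal stress-1 by alternating isotonic regression of
  configuration distances on the dissimilarity ranks (`stats::isoreg`)
  with Guttman-transform majorization updates. Defaults: 2 dimensions,
  20 random starts plus one PCoA start, 300 iterations, stress
  tolerance 1e-6. An all-equal dissimilarity matrix is rejected as
  degenerate (every configuration on a simplex is optimal).
- One-factor PERMANOVA uses the distance-based sums of squares
  `SS_total = (1/N) Σ_{i<j} d²_ij` and
  `SS_within = Σ_g (1/n_g) Σ_{i<j∈g} d²_ij`, with
  `F = ((SS_total - SS_within)/(a-1)) / (SS_within/(N-a))`. When the
  number of distinct label arrangements is at most 10,000 the
  permutation distribution is enumerated exhaustively and
  `p = #(F* ≥ F)/n_arrangements`; otherwise 999 seeded random
  permutations give `p = (1 + #(F* ≥ F))/1000`.
- Welch's t (Satterthwaite degrees of freedom) and one-way ANOVA are
  implemented directly; degenerate zero-variance inputs with equal
  means return statistic 0 and p 1 rather than NaN.

## Metapangenome partitioning

Over a chosen sample subset, a cluster present in every sample is
*core*, in exactly one is *cloud*, and otherwise (≥ 2 but not all) is
*shell*; clusters absent from all chosen samples are excluded from the
partition and counted separately. Percentages everywhere go through one
reporting path, `fmt_percent()` — `100·count/total` rounded
half-to-even at the printed precision — with raw counts always carried
alongside, so reported ratios are exactly reproducible.

Gene-level consolidation strips one trailing `_<integer>` variant
suffix (`adhP_2` → `adhP`, but `abc_1_2` → `abc_1`, matching the
disambiguation scheme Roary uses), removes `group_<k>` placeholder
clusters, optionally removes clusters annotated exactly
"hypothetical protein" (case-insensitive, kept exact-string so the
rule is auditable), rewrites names through a user synonym map, and
merges rows by summed copy counts. A consolidated matrix is flagged
and returned unchanged by further consolidation calls: stripping is
defined on raw Roary names, and re-stripping a canonical name like
`abc_1` would corrupt it. Synonym resolution across annotation sources
is inherently curatorial; only the exact-name merge is automated, with
the synonym map as the hook for curated equivalences.

## GO enrichment

`propagate_annotations()` applies the true-path rule: annotation sets
are closed under `is_a` ancestry, as proper sets, so diamond paths do
not double count. Term significance is the exact upper-tail
hypergeometric probability `P(X ≥ k)` for `k` study genes among `K`
annotated genes in a universe of `N`.

The DAG-decorrelation step is the deterministic *elim* algorithm:
terms are processed in decreasing depth (longest path to the root;
ties in lexicographic term order), and when a term's current p-value
falls below `alpha_elim` (default 0.01) its currently annotated genes
are removed from all its ancestors' sets before those are tested. This
is the fully specifiable half of the weight01 hybrid used by topGO;
the weighted half involves floating-point score ratios that are hard
to pin down as a contract, so elim is the default and classic Fisher
is available for comparison. Because decorrelated p-values are
approximately independent across terms, no multiple-testing correction
is applied by default. One boundary property is worth knowing: for a
term whose classic p is exactly 1 (e.g. the root, annotated to the
whole universe), eliminating genes can only move its p downward; for
all other terms elimination is anti-conservative for ancestors, never
for the significant term itself.

## Phylosymbiosis screen

The screen asks whether a gene tree's genotype-level structure mirrors
the host phylogeny. Because clusters carry many sequences per genotype,
each eligible tree (at least one leaf per host genotype) is reduced to
a genotype × genotype matrix of **mean patristic distances**, clustered
by **UPGMA**, and called concordant when the dendrogram contains every
**required clade** of the host reference as an exact monophyletic
clade. This operationalizes "closest clusters of two and three host
genotypes" as a deterministic pipeline that is scale-invariant in
overall tree depth and does not require per-genotype monophyly.

Conventions: UPGMA merges at height d/2 with ties broken by the
lexicographically smallest member pair, so degenerate inputs produce a
deterministic caterpillar; the required clades are derived from the
host tree as all internal clades of 2–3 genotypes (for the default
*Musa* tree `((((BB,MB),MT),MS),(DC,FH))` this yields {BB,MB},
{BB,MB,MT} and {DC,FH}, leaving MS unconstrained) and can be
overridden; all three clades must hold simultaneously; comparison is on
rooted dendrograms. Under these rules a uniformly random rooted binary
topology on six leaves matches with probability 3/945 — exactly 3 of
the 945 topologies contain all three clades — which the test suite
verifies against a frozen enumeration value and by simulation.

## The synthetic-data generator

The generator produces every input format with known truth labels. Its
defaults describe the study design it emulates: six host genotypes
(codes BB, MB, MT, MS, DC, FH) sampled in paired leaf and root tissue
(12 samples), read totals log-normal around `depth_per_sample`,
root communities of `n_taxa_pool = 400` taxa with leaf communities
drawn as 30%-sized subsets of their paired root pools
(`root_leaf_richness_ratio = 0.3`, giving roots systematically higher
alpha diversity), 5% core taxa present everywhere, log-normal relative
abundances (σ = 1.5) observed through a multinomial draw, a cluster
matrix with target core/shell/cloud fractions (1.4%, 39%, 59.6%)
enforced exactly by largest-remainder apportionment and
rejection-sampled presence patterns, 62% "hypothetical protein"
clusters, and a planted 5.4% fraction of host-concordant gene trees —
magnitudes chosen to mirror a real multi-genotype endosphere survey.
The distributions themselves (log-normal abundances, Bernoulli-0.5
shell patterns, coalescent subtrees, uniform-insertion random
topologies) are standard parameter-sparse nulls; the field's data
constrain the summary structure, not the generative law.

Specifics worth noting:

- Categories are enforced, not sampled: shell patterns are
  rejection-sampled into `[2, n_samples)` presence, so truth labels are
  unambiguous and partition recovery must be exact.
- Each gene is directly annotated to exactly one most-specific GO term,
  so leaf-level annotation sets are disjoint and terms share genes only
  through ancestors; planted terms are drawn among terms with at least
  `min(genes_per_term, 20)` genes so the planted signal is carried by
  enough genes to be recoverable, and the study set oversamples their
  genes with odds `enrichment_odds` (odds 1 reduces to a uniform draw —
  the null).
- Phylosymbiotic gene trees are the host topology with each genotype
  tip replaced by an equal-height coalescent subtree of
  `n_seq_per_genotype` strains, which makes the genotype-mean patristic
  distances equal the host cophenetic distances exactly; at
  `branch_noise_sigma = 0` the screen must therefore recover planted
  clusters with sensitivity 1. Null trees either shuffle genotype
  labels on a host-shaped tree ("permute") or draw a uniform-random
  rooted topology with random ultrametric heights ("uniform"); the
  uniform mode reproduces the 3/945 matcher calibration. About 46% of
  simulated gene-tree leaves carry an `"unbinned"` strain field,
  mirroring the large fraction of endosphere sequences without a
  database match.
- One integer seed determines every output; each simulator draws from
  its own fixed sub-stream, so enlarging the taxon pool does not
  reshuffle the gene trees.

What the generator does **not** emulate: read-level error, assembly
fragmentation and chimerism, compositional coupling between taxa,
copy-number variation correlated with phylogeny, incomplete lineage
sorting or horizontal transfer in gene trees, and biased annotation
databases. Passing tests therefore demonstrate that the statistics and
screens are implemented correctly and calibrated under clean planted
signals — not that a real survey's numbers would be recovered at the
same rates.

## Problem sizes and numerical checks

The validation suite exercises: exact worked-ratio reproduction of the
partition/percentage arithmetic; brute-force agreement (to 1e-9
relative) for the diversity statistics on vectors of length ≤ 10;
exhaustive-enumeration agreement for PERMANOVA at N = 8 and a 1000-run
null calibration of its type-I error at α = 0.05 (N = 10, two groups
of 5); exact planted-partition recovery on 1000 clusters; planted GO
recovery over 20 seeds at odds 5 and a 20-seed null calibration;
and the phylosymbiosis screen's sensitivity on 200 zero-noise planted
clusters, its null match rate on 10,000 uniform-random topologies
against 3/945, and recovery of a planted 5.4% fraction among 2,000
clusters. These sizes keep the complete suite and the acceptance
script each within a few minutes on one CPU while leaving Monte-Carlo
error well inside the tested tolerances.

## Known limitations

- PERMANOVA is one-factor; the two-factor (genotype × tissue) design
  of a paired study must be tested one factor at a time.
- The elim decorrelation approximates, but is not identical to, the
  weight01 hybrid; rankings can differ for terms whose signal is split
  between parent and child.
- The concordance screen is a topology screen, not a formal
  phylosymbiosis test: it does not permute communities or compare
  distance matrices (Mantel/Robinson–Foulds style), and its calibration
  (3/945) applies to the six-genotype, three-clade reference; other
  host trees change the null rate.
- OTU construction, ortholog clustering, tree inference and taxonomy
  resolution are upstream of this package: it consumes their outputs.
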