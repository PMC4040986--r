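---
title: "Methods: differential-coverage binning and phylogenomic classification of population genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential-coverage binning and phylogenomic classification of population genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalineage)
```

# The problem

Many bacterial lineages are known only from 16S rRNA surveys: they are
abundant enough to leave marker-gene traces in community profiles but have
never been isolated, so nothing is known about their genomes. When the same
community is sequenced at several time points (or from several related
samples), the contigs of one population rise and fall together across
samples. `metalineage` implements the computational chain that exploits
this: recover population genomes from multi-sample metagenomes by
differential-coverage binning, audit them with single-copy marker genes,
select phylogenetically well-behaved markers by gene-tree/taxonomy
congruence, place the genomes on a masked concatenated-marker
neighbor-joining tree with bootstrap support, and independently reconstruct
16S rRNA fragments by reference-guided read-pair recruitment. A
synthetic-data module generates every input with known ground truth, so the
whole chain is testable end to end without any external download.

# Differential-coverage binning

Each contig contributes a row of mean per-base coverage across the $s$
samples. The row is mapped to $\log_{10}(x + p)$ (pseudocount $p = 1$ by
default, absorbing zero coverage) and scaled to unit Euclidean norm, so
contigs of the same genome — whose coverage vectors share a direction —
collapse toward a common point regardless of genome abundance. The
transformed matrix is column-centred and projected orthogonally onto its
top three principal axes (eigendecomposition of the sample covariance;
axes ordered by decreasing variance, each sign-fixed so its first nonzero
loading is positive, making the embedding fully deterministic; matrices
with fewer than three samples are zero-padded). Bins are single-linkage
clusters of the embedding cut at `linkage_dist` (default 0.05); clusters
smaller than `min_bin_size` (default 5 contigs) are reported unbinned.

Two caveats matter when interpreting results:

* **Resolution is bounded by the linkage threshold.** Two genomes whose
  transformed profiles sit closer than `linkage_dist` in the embedding are
  indistinguishable to any coverage-only binner, noise or no noise. The
  guarantee "zero noise + separated profiles implies perfect purity and
  recall" therefore carries the hypothesis that planted genome centroids
  are farther apart than the threshold; the tests assert the hypothesis
  before asserting the conclusion.
* **Proportional is not identical.** A between-genome coverage scale
  factor becomes an additive offset after the log, so proportional (as
  opposed to equal) coverage rows only converge in direction as coverage
  magnitudes grow. Contigs of the *same* genome share an identical row (up
  to noise), which is the case the binner relies on.

Composition features (tetranucleotides, GC) are deliberately out of scope;
the binning unit is the contig.

# Marker census and quality gate

Completeness and contamination of a bin are defined against a fixed set of
105 bacterial single-copy marker genes: completeness is the percentage of
the 105 markers found at all in the bin, contamination the percentage found
in more than one copy. Both percentages use the full set size 105 as
denominator — with 103 markers present of which 6 are duplicated this gives
98.1% / 5.7%, and with 99 present / 2 duplicated, 94.3% / 1.9%. Using the
number of markers *found* as the contamination denominator does not
reproduce these reference values, which is why the full-set convention is
hard-wired. Percentages are rounded half-away-from-zero to one decimal
(matching how such tables are conventionally printed; `base::round()`
rounds half to even and would give 98.2 for 98.15).

The quality gate passes a bin only when completeness strictly exceeds 60%
and contamination is strictly below 10%; the boundary values 60.0 and 10.0
both fail. Marker hits are consumed from a table; running the HMM search
that produces such hits is out of scope.

# Gene-tree consistency and marker selection

Concatenating markers only helps if each marker's own gene tree broadly
agrees with the reference taxonomy. Agreement is scored per clade $c$ at a
rank (domain, phylum, class): every edge of the unrooted gene tree splits
the leaves into two sides $R$ and $L$, and with $T(c)$ the number of
genomes of clade $c$ in the tree, $N_x(c)$ the clade members on side $x$
and $I_x(c)$ the non-members there, the node score is

$$ C(c) = \max\!\left(0,\; \max_{x \in \{R, L\}} \frac{N_x(c) - I_x(c)}{T(c)} \right). $$

The clade's consistency is the maximum over all edges; it is 1 exactly when
some edge isolates the clade (perfect monophyly) and is reduced both by
members missing from the best side and by intruders on it. Rank averages
run over clades with at least `min_genomes = 5` leaves in the tree, the
tree score is the unweighted mean of the rank averages (ranks with no
eligible clade are dropped, not scored 0), and markers with a tree score
below 0.86 are discarded — a score of exactly 0.86 is retained, following
the "strictly less is discarded" convention.

Three behaviours are worth knowing:

* The algebraic form above is this package's reconstruction from the
  defined quantities $T$, $N_x$, $I_x$; it is the simplest form using
  exactly those symbols that attains 1 iff the clade is monophyletic and
  penalises both omissions and intrusions.
* Pendant (single-leaf) splits count as nodes. This is harmless for
  eligible clades, which have at least five members.
* A clade containing *every* leaf of a tree can never score 1 — no edge
  isolates the full leaf set — and tops out at $(n-1)/n$. Congruence
  scoring is therefore run against a reference taxonomy in which eligible
  clades are proper subsets of the tree's leaves (as they are in real
  multi-domain reference sets).

# Distance phylogenomics

**Masking.** Alignment columns are dropped when gapped in more than half of
the sequences (a column gapped in exactly half is retained — the rule is
strict), when entirely gaps, or when their non-gap characters are all
ambiguity codes. The full dynamic-programming block selection of dedicated
masking tools is not reproduced; only this gap rule is.

**Supermatrix.** Masked blocks are concatenated in input order, genomes
missing a block padded with gaps, and block coordinates recorded as 0-based
half-open spans.

**Distances.** For nucleotide data the pairwise distance is the LogDet
(paralinear) estimator
$d = -\tfrac14\left(\ln\det F - \tfrac12\sum_k \ln f_{x,k} f_{y,k}\right)$,
with $F$ the $4\times4$ joint base-pattern frequency matrix over columns
where both sequences carry an unambiguous base, and $f_x, f_y$ its
marginals. LogDet remains consistent when base composition drifts across
the tree, the regime for which it is preferred. When $\det F \le 0$ or a
marginal frequency is zero the pair is *saturated*: building a full matrix
then fails with an error listing the offending pairs (a silent `NA` would
poison neighbor joining), while bootstrap replicates with a saturated pair
are skipped and counted. Amino-acid supermatrices fall back to a
gap-excluded normalised mismatch distance — the maximum-likelihood protein
analyses this pipeline deliberately omits are the better tool there, and
the distance arm is exercised on nucleotide fixtures.

**Trees.** Neighbor joining uses the standard Q-criterion agglomeration
(via `ape::nj`); negative branch lengths, which NJ can produce on noisy
matrices, are clamped to 0. On an exactly additive matrix the generating
topology and branch lengths are recovered — this is tested against a
path-length oracle over random trees. Bootstrap support resamples
supermatrix columns with replacement (default 100 replicates), rebuilds the
distance matrix and NJ tree, and reports for every internal bipartition of
the original tree the integer percentage of replicate trees containing it;
supports attach to the split's smaller leaf set. Monophyly of a named group
is exact bipartition membership.

# 16S read-pair recruitment

rRNA genes co-assemble across populations and distort coverage statistics,
so 16S fragments are recovered independently of binning. Read pairs mapped
to a 16S reference database pass the per-read filter when at least 85% of
the read aligned and the edit distance is strictly below 10% of the read
length (a 100 bp read needs edit distance < 10; the strict reading follows
the worked convention, and both thresholds are configurable). Pairs whose
two mates map to references farther than a patristic distance of 0.03
apart on the reference phylogeny are removed — the radius is read as
mate-to-mate path distance, the natural anchor-free interpretation.

Surviving pairs are clustered greedily: repeatedly take the unprocessed
reference with the most assigned pairs (ties broken by lexicographically
smallest id for determinism), absorb every unprocessed reference within the
0.03 radius, and emit the group as one cluster — descending pair count, with a
deterministic tie-break, is the processing order. Each pair is attributed
to its first read's reference — after the concordance filter the two
mates' references are within the cluster radius of each other, so the
choice is immaterial at cluster scale. Clusters partition the pairs; the
per-cluster interleaved read files are inputs for external assembly, which
is out of scope. Lineage relative abundance is the fraction of surviving
pairs whose cluster seed belongs to each lineage.

# The synthetic-data generator

The generator emulates exactly the features the pipeline consumes, and
nothing more:

* **Community.** Per-sample genome abundances are lognormal (meanlog 0,
  sdlog 1) — chosen as the standard heavy-tailed abundance model, since
  only the *relative structure* across samples matters for binning. Contig
  coverage is abundance × depth × $e^{N(0,\sigma)}$ multiplicative noise
  with `noise_sd` = σ on the log scale; `noise_sd = 0` reproduces planted
  abundances exactly. Contig lengths are uniform 5–50 kb and enter only as
  metadata.
* **Markers.** Each genome receives a requested number of distinct markers
  on randomly chosen contigs, a subset duplicated onto a second contig,
  giving exact ground-truth completeness/contamination.
* **Gene trees.** A fully congruent tree nests genomes inside class,
  phylum, and domain groups; incongruence is injected as
  $\mathrm{round}((1-\text{congruence}) \cdot n)$ random leaf prune-and-regraft moves. A
  move can land inside the leaf's own clade, so the planted congruence is
  an upper bound on damage, not an exact score — sweeps are monotone in
  expectation only.
* **Sequences.** Sites evolve independently under the one-parameter
  symmetric 4-state model with uniform root states — the simplest model
  with closed-form expected mismatch
  $p = \tfrac34(1 - e^{-4d/3})$, so simulated fixtures have exactly known
  pairwise distances and LogDet can be validated against truth.
* **Read pairs.** Reads are placed on the reference leaf nearest a
  patristic displacement drawn with `placement_sd` (0 places all reads on
  the source leaf); aligned fractions and edit-ratio draws are uniform in
  configurable ranges so fixtures can deterministically pass or fail the
  filters.

All stochastic operations derive stage-tagged child seeds from one global
integer seed, so a single seed pins down the entire analysis and identical
seeds give byte-identical outputs.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: sequencing error and read-level noise,
assembly artefacts and chimerism, strain-level heterogeneity within a
population, compositional coverage biases (GC, rRNA co-assembly), non-
lognormal abundance structure, and model misspecification in the sequence
evolution (no rate variation, no base-composition drift). The bootstrap
fixture in particular is signal-saturated by construction (10 kb alignment,
internal branches 0.1), demonstrating that the machinery recovers a strong
signal, not that real supports would be high.

# Problem sizes and runtime choices

The bundled analysis (`analysis/01…06`) and the tests use a 12-genome,
4-sample community with 10 contigs per genome, noise-free coverage, a
60-genome (3 domains / 6 phyla / 12 classes) reference taxonomy for
congruence scoring, a 10 kb alignment with 100 bootstrap replicates, and
100 read pairs from two well-separated reference leaves. These sizes make
every planted structure recoverable while each driver completes in seconds
to a couple of minutes on one CPU; they are set in
`analysis/00_config.R` and `pipeline_config()` and scale up freely.

# Known limitations

* The binning transform is this package's own minimal, deterministic
  differential-coverage definition (log, unit-norm, 3-axis projection,
  single linkage). Production binners add composition features, length
  weighting, and refinement; none of that is attempted here.
* The consistency measure's algebraic form is a documented reconstruction
  (see above), not a published formula.
* LogDet is defined for nucleotides; protein distances use the documented
  mismatch fallback.
* Per-cluster 16S assembly, HMM recruitment from raw reads, and all
  external-tool steps (assembly, mapping, ML tree inference) are out of
  scope by design: this package consumes their outputs or emits their
  inputs.
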