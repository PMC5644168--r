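---
title: "Methods: an SSU rRNA gene diversity census on aligned full-length sequences"
author: "ssucensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an SSU rRNA gene diversity census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssucensus)
```

## The problem

Full-length SSU (16S) rRNA genes assembled from shotgun metagenomes give a
view of bacterial diversity that is free of PCR primer bias and largely free
of amplicon chimera artifacts, but turning a pile of such genes into a
census — how many species-like units, how many order-level lineages, how
much of the tree of life is new, where does it live, and would amplicon
primers even have seen it — requires a long chain of processing steps, each
with small, consequential rules: quality filters with strict boundaries,
identity clustering at two thresholds, comparison against an amplicon
reference database, chimera screening, bootstrap phylogenetics with
rogue-taxon removal, monophyly-based taxon assignment, phylogenetic
diversity accounting, and in-silico primer evaluation.

`ssucensus` implements that chain as tested, reusable functions operating on
pre-aligned sequences (covariance-model alignments in fixed match
coordinates), together with a synthetic-community generator that emits
ground truth for every stage.  Running external aligners or maximum
likelihood tree programs is deliberately out of scope; the package consumes
alignments and builds distance trees internally, so every tree-dependent
stage is testable at desk scale.

## Quality control

Sequences are handled as a character matrix over `{A,C,G,T,-}` in fixed
alignment coordinates (0-based, half-open column conventions throughout).
Three QC rules apply, all with strict boundaries:

* **Length**: a sequence is kept iff its *ungapped* length is at least
  `min_bases` (default 1200 bases — gene length, not alignment columns).
  1199 bases is discarded; 1200 is kept.
* **Internal window**: clustering identities are computed inside a
  contiguous window (default 900 columns, roughly the V3–V7 region of the
  bacterial model coordinates) to avoid artifacts from terminal gaps on
  partially assembled genes.  "The internal columns present in all
  sequences" is under-specified on arbitrary inputs, so the window is
  operationalized as the one maximizing the *minimum* per-sequence non-gap
  count, ties broken towards the smallest start column; a fixed start can
  be configured instead.
* **Gap content**: a sequence with more than `max_gaps` (default 40) gap
  characters inside the window is discarded; exactly 40 is kept.  All gap
  characters in the window count, terminal or internal — the distinction is
  not recoverable from the alignment alone.

`.` gap characters and `U` residues are normalized on input ( to `-` and `T`);
a Stockholm reader derives the match-column mask from the `#=GC RF` line so
covariance-model insert columns can be projected away with
`drop_insert_columns()`.

## Pairwise identity and greedy clustering

Identity between two aligned sequences inside the window is

> 100 × (columns where both carry the same residue) / (columns where at
> least one carries a residue),

with dual-gap columns excluded entirely and residue-vs-gap counted as a
mismatch.  This is a deliberate, reproducible replacement for the banded
aligner inside usearch, whose exact scoring is not public; the window
restriction already serves the same purpose (ignore terminal gaps) as the
original tool's settings.

Greedy centroid clustering visits sequences by decreasing ungapped length
(ties: ascending id, C locale) and assigns each to the *first* centroid — in
centroid-creation order — reaching the threshold, else founds a new cluster.
The scan is deterministic by construction and is verified against a naive
re-implementation of the same definition on hundreds of random instances.

The census uses two linked levels: 97% OTUs (species-like), then 85%
clustering of the 97% centroids (order-level), giving every OTU exactly one
85% cluster.  Coarse clusters with a single underlying *sequence* are
removed (their OTUs are flagged unplaced); a config switch interprets the
singleton rule per OTU instead, since "one single sequence" admits both
readings.

**Novelty** is assigned by jointly reclustering pipeline and reference
(amplicon-database) sequences at 97%: an OTU whose representative co-clusters
with a reference is `mg_and_silva`; any OTU containing a genome-source
member is `genome_backed` (precedence over the reference match); all others
are `mg_only`.  Matching is by representative membership (an `any_member`
mode exists); reference-only joint clusters are discarded and counted.

## Chimera screening

Planted and real chimeras are screened with a transparent two-parent model
rather than a re-implementation of UCHIME's h-score.  For a query and an
ordered parent pair, every breakpoint on a `stride`-column grid (default 10,
endpoints included) splits the window; the model identity pools matched and
scored columns of query-vs-left-parent before the breakpoint with
query-vs-right-parent after it.  The verdict is `chimeric` iff the best
model beats the best *single* parent by at least `d_min` (default 2.0
percentage points) and both parent-side identities reach `s_min` (default
90%).  Including the endpoint breakpoints makes the model at least as good
as the best single parent, so the reported divergence is never negative.

Candidate parents come from a chunked k-mer search (k = 8, top 4): the
query window is split into four chunks, references are scored per chunk by
shared distinct k-mers, the best reference of *each chunk* is always
retained, and remaining slots are filled by the best chunk-maximum scores.
Per-chunk retention matters: a recombinant query shares only half its
window with each parent, and a full-window ranking lets near-relatives of
one side crowd out the other side entirely.  Genome-source sequences serve
as the clean training set.

On simulated communities with 10% planted chimeras (parents from distinct
phyla, breakpoints in the middle third of the window), the screen reaches
recall above 0.9 at zero observed false positives over 20 seeds; the
residual misses are chimeras whose parent OTU happens to contain no
genome-source reference within the 90% side-identity floor, which no
reference-based screen can recover.

## Trees, bootstraps, and rogue taxa

Distances are Jukes–Cantor corrected window identities,
`d = -(3/4) ln(1 - (4/3) p)`, with the mismatch proportion capped at 0.70
(saturation warning) since the correction diverges at 0.75.  Trees are
neighbor joining (via `ape`); negative NJ branch lengths are clamped to zero
with the deficit moved to a sibling branch, then floored at zero.
Bootstrapping resamples window columns with replacement.  On distances that
are exactly additive on a tree, NJ provably recovers the topology, which the
tests verify for 4–8 leaves against exhaustive topology enumeration.

Bipartitions are canonicalized as the split side not containing the
lexicographically smallest leaf; majority-rule (> 50%, strict) consensus
topologies are assembled from the strict-majority splits (which are
automatically pairwise compatible and laminar after canonicalization), and
supports are percentages of replicates containing each split.  A 50/50
conflict therefore collapses to a polytomy.

**Rogue removal.**  A rogue taxon is a leaf whose position varies across
replicates, degrading the consensus.  A first design — scoring a candidate
leaf by the *count* of strict-majority splits gained after pruning it —
turns out to be incapable of detecting even a textbook rogue: if a single
leaf X is regrafted across otherwise identical replicates, every backbone
split appears in each replicate as exactly one of its two X-augmented
versions, and since the two versions' frequencies sum to the replicate
count, exactly one of them always holds a strict majority.  The full-tree
resolved count therefore stays at its maximum and pruning can only shrink
it.  The implemented criterion scores the *consensus support sum* instead —
the sum of support fractions over strict-majority splits, the quantity that
RogueNaRok-style criteria behind RAxML's rogue options optimize.  Pruning a
rogue re-concentrates support (score rises toward the pruned maximum);
pruning a stable leaf deletes one fully supported split (score falls by
about one).  Per round, all leaves with positive improvement are pruned;
iteration stops when a round finds fewer than `stop_when_fewer_than`
(default 5) rogues — the stopping rule reads "until fewer than five rogues
per round", with the final round's rogues still pruned — or after
`max_rounds`.  Pruning never proceeds below four leaves.

Rooting uses an outgroup: the stem edge of the smallest clade containing all
outgroup leaves, or, for a non-monophyletic outgroup, the edge maximizing
Jaccard overlap between leaf side and outgroup set (with a warning).  Leaves
on pendant branches longer than 10× the median are flagged advisorily.

**Phylum assignment** walks each unlabeled leaf rootward to the smallest
clade containing a labeled leaf and assigns that phylum iff all labels in
the clade agree and the clade's bootstrap support is at least `support_min`
(default 50, the conventional display threshold; absent support fails).  In
the pipeline, labels come from 85% clusters containing genome-source
sequences with known taxonomy.

## Census statistics

* **Phylogenetic diversity** is the Faith-style sum of all branch lengths.
* **PD increase** per phylum builds two NJ trees from 97% OTU
  representatives — previously known OTUs (not `mg_only`) versus all — and
  reports `100 × (pd_all − pd_known) / pd_known`.  Phyla with fewer than 5
  known OTUs are skipped (mirroring the usual inclusion rule for such
  tables), and at least 3 representatives are required per tree.
* **Richness** counts 97% OTUs (total and per novelty category) and 85%
  clusters per phylum.
* **Environment tallies** count each OTU at most once per environment in
  which any member occurs; empty labels count as `unknown`, and a
  configurable environment (e.g. `engineered`) can be dropped.

## Primer mismatch prediction

Primers are IUPAC strings scored against ungapped member sequences; reverse
primers are matched as reverse complements with the 3′ window tracked
accordingly.  Penalties default to 0.4 per non-3′ mismatch, 1.0 per 3′
mismatch, 1.0 per non-3′ gap and 3.0 per 3′ gap, with a 5-base 3′ window —
the documented convention of the standard primer-evaluation tool, and fully
configurable since the weights are a convention, not a law.

The binding site is the full-primer alignment (free target ends) minimizing
the *weighted score itself*.  An earlier design selected the site by unit
edit cost and evaluated the weighted score there, but that contradicts the
natural oracle (minimum score over all concrete expansions of the
degenerate primer): a variant may reach a lower weighted score at a site
with a higher unit cost.  With a single additive objective, the
degenerate-as-match dynamic program provably equals the expansion minimum —
at any fixed alignment each primer position independently picks its best
base, so the positionwise optimum assembles into one concrete variant — and
the acceptance tests verify this equality on random primers.

Per 85% cluster, all member sequences are scored; the cluster is predicted
*missed* by the primer set iff either primer's mean weighted score is
strictly greater than 1 (a mean of exactly 1.0 does not flag).  The
standard deviation is the population SD (n divisor; a sample-SD switch
exists), and `mismatch_score` reports the maximum of the two primer means.

## The synthetic-community generator

The generator emulates the *structure* a census pipeline must resolve, not
rRNA biology.  A uniform-random global ancestor (default 1534 match
columns) spawns one root per phylum at `between_phylum_divergence` (default
0.15 substitutions/site); per-phylum coalescent guide trees carry OTU
ancestors, rescaled so the mean pairwise leaf-to-leaf path equals
`2 × between_otu_divergence`, with half of that separation carried by
private terminal stems so that every OTU pair is separated by at least
`between_otu_divergence` (defaults: 0.065, keeping the closest OTU pairs
below ~94% identity, safely apart from the 97% threshold); OTU members
diverge by `within_otu_divergence` (default 0.003, ≈ 99.4% within-OTU
identity).  Evolution is independent-site Jukes–Cantor with no indels, so
alignment coordinates stay exact and the closed-form JC expectation serves
as a test oracle.  Artifacts are planted post hoc on disjoint random
subsets: chimeras (clean parents from distinct phyla, breakpoints uniform
in columns 300–600), truncations (terminal masking to below 1200 bases),
gap-riddled sequences (~90 evenly spaced gaps, so any 900-column window
holds well over 40), and optional rogue mosaics (alternating 150-column
blocks from several phylum roots, which gives a sequence no consistent
phylogenetic position).  Sources are drawn per sequence from `source_mix`;
genome-source sequences carry their true phylum as known taxonomy; each OTU
gets a home environment with an `env_spread` chance per metagenome member
of a second environment (exercising the once-per-environment tally rule);
outgroup sequences share a long stem (80% of `outgroup_divergence`) so
rooting is well-defined.

What the generator does **not** emulate: secondary-structure–aware
evolution, rate heterogeneity across sites, indels and intron-like
insertions (truncation/gap artifacts are masks, not indels), realistic
abundance distributions, or sequencing error.  Passing tests therefore
demonstrate that the *procedure* is correct under controlled conditions,
not that any particular biological dataset will cluster cleanly.

Chimeras and rogue mosaics have `NA` true OTU and phylum in the truth
table — they belong to no true lineage; every emitted sequence appears in
every truth map exactly once, and artifact flags are mutually exclusive.

## Problem sizes and determinism

All randomness flows through explicit seeds; a fixed seed yields a
bit-identical dataset, bootstrap series and census.  The test suite runs
communities of 48–200 sequences (20 seeds for clustering recovery and
chimera screening), 50 NJ consistency trials, 20 planted-rogue simulations
with 50 replicates of 12-leaf trees, and one 500-sequence end-to-end census
(5 phyla × 20 OTUs × 5 sequences) with 50 bootstrap replicates — sizes
chosen so the full suite exercises every stage in about a minute while
leaving clustering and tree stages far from their asymptotic regime.

## Known limitations

* Identity is defined on the given alignment; badly aligned inputs degrade
  everything downstream, and no realignment is attempted.
* NJ with JC correction is a deliberate simplification; for publication
  trees users should export representatives and run an external ML tool,
  then feed the tree back through the rogue/assignment/PD stages.
* The chimera screen is reference-based only; novel-lineage chimeras with
  no genome-backed relatives evade it (and de novo abundance-based
  detection is out of scope).
* The primer weights are a tool convention; conclusions about "missed"
  clades inherit that convention.
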