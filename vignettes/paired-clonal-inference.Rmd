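---
title: "Paired clonal family inference: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired clonal family inference: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairclone)
```

# The problem

B cell receptors consist of a heavy and a light chain, each produced by
somatic V(D)J rearrangement and subsequently diversified by somatic
hypermutation (SHM).  Grouping a repertoire's sequences into *clonal
families* — the descendants of single rearrangement events — is a first
step of most repertoire analyses.  Single-chain clustering is limited by
*collisions*: distinct rearrangement events whose naive (unmutated
ancestor) sequences are practically indistinguishable.  Collisions are
rampant in the light chain, whose junctional diversity is orders of
magnitude below the heavy chain's.

Droplet-based single-cell sequencing attaches a shared barcode to the
heavy and light chain of each cell.  Because heavy and light germline
choices are (very nearly) uncorrelated, two collided light families
almost always have easily distinguishable heavy partners — so pairing
information can repair exactly the errors single-chain clustering cannot
avoid.  `pairclone` implements this refinement, two methods for fixing
imperfect pairing information, and the simulator and metrics needed to
benchmark all of it without any external data.

# The inference stack

## Per-sequence annotation

Sequences are aligned ungapped against every germline V and J allele;
deletion lengths are chosen by match score (matches minus mismatches),
with ties resolved toward the larger deletion so germline is never
extended over the junction on 50/50 evidence.  The J search is
constrained to the suffix left over by the chosen V, so the two germline
segments cannot overlap.  The naive sequence takes germline bases where
aligned and observed bases in the non-templated junction; CDR3 bounds
come from the conserved anchor codons.  D calls (heavy only) are
best-effort — an end-trimmed maximum-scoring segment with mismatches
costed double — and are not used by clustering.  No indels are modelled:
the simulator introduces none, so annotation is a fixed-length
comparison throughout.

## Cluster annotation and the subcluster scheme

A cluster's annotation is the per-position majority vote over its
members' naive reconstructions, aligned at the CDR3 start — a star-tree
consensus.  Votes tie toward the germline base of the consensus V/J
call where it covers the position; inside the non-templated junction,
ties fall to the base backed by the most underlying sequences, then to
the alphabetically first base.

The star assumption fails on imbalanced trees (large variance in
root-to-tip distances), where sublineages share many mutations.  The
*subcluster annotation* scheme exploits the fact that, zoomed in far
enough, every tree looks like a star tree: the ordered member list is
split into contiguous blocks of at most `n_s` sequences (default 3; a
cluster of 10 splits 3/3/2/2), each block is annotated, the blocks are
replaced by their inferred naives, and the procedure iterates to a
single block.  Because cluster order is the agglomeration merge order,
similar sequences share blocks, and block consensus naives progressively
strip sublineage-private mutations.  Each block naive carries the number
of sequences it summarizes as a vote *weight used only for ties*: this
keeps one-block-one-vote semantics (the point of the scheme) while
letting, e.g., a 27-sequence block beat a 23-sequence block when two
blocks disagree head-on.  On caterpillar trees with 50 leaves at 15%
SHM this roughly halves the naive inference error relative to the flat
star consensus; on star trees the two coincide.

## Single-chain clustering

`naive_hamming_partition()` first collapses sequences with identical
inferred naives, then hierarchically agglomerates within CDR3-length
classes: the closest pair of clusters at normalized naive Hamming
distance below `d_0` (default 0.05) merges, and the merged cluster is
re-annotated.  Two engineering devices keep this linear-ish in practice:
*key translation* (clusters larger than `n_t = 15` are represented by a
random subsample during agglomeration, with final annotations recomputed
on full clusters) and the *large/small shortcut* (when one parent is at
least 4 times larger, its annotation is reused unchanged).  Distance
ties break toward the lexicographically smallest pair of cluster leader
ids, making the partition independent of input row order.
`vj_cdr3_partition()` provides the classical baseline: group by V gene,
J gene and CDR3 length, then single-linkage on CDR3 at 0.8 identity.

Clusters of different naive lengths within a CDR3-length class are
compared anchored at the CDR3 start, over the overlapping flank length
only — alignment of unequal-length naives has no canonical definition,
and anchoring at the one structurally fixed landmark is the least
arbitrary choice.

With `threshold_mode = "shm_scaled"`, `d_0` widens to
`d_0 * (1 + 2 * mean SHM)`: highly mutated samples spread inferred
naives of one family further apart, so a fixed threshold oversplits
them.  The default stays fixed at 0.05.

## Paired refinement

`joint_partition()` resolves the two single-chain partitions over *pair
identifiers* (one per cell).  For each cluster of one chain, the
overlapping opposite-chain clusters are grouped by CDR3 length
(inferred CDR3 length is essentially always right, so disagreement is
decisive), and within a group, clusters whose naives differ by more than
`d_0` are put on each other's *split lists*; everything not forbidden by
a split list merges greedily.  The resolved clusters are folded into the
growing final partition by removing overlaps from the larger cluster of
the first conflicting pair (ties remove from the incoming cluster —
this makes the operation a fixed point on agreeing partitions, hence
the idempotence property) and cutting subsequent overlaps out as their
own clusters.  The net effect only ever splits single-chain clusters:
similarity in the other chain is never treated as evidence to merge.

## Fixing imperfect pair info

*Pair cleaning* (`clean_pair_info()`): overloaded droplets give each
sequence several candidate partners.  Correct pair info is shared among
clone-mates, spurious co-droplet partners are not; so for each
single-chain cluster (largest first), candidate opposite-chain families
are ranked by member-candidate links ("votes"), and each multi-candidate
sequence takes the candidate from the top family.  Tied candidates from
one family are a random pick (they likely stem from one molecule); ties
across families discard the sequence's pair info.  Every fixed pair is
removed from all other candidate lists, which progressively
disambiguates the rest of its droplet.  Votes are recomputed at each
cluster visit against the current lists; a stripped sequence is also
removed from other candidates' lists so the output pairing stays
symmetric.

Sequences left unpaired are noted with their nearest (observed-sequence
Hamming) paired family member, excluded from paired clustering, and
afterwards attached to that neighbour's final family
(`attach_unpaired()`) — nearby sequences share sublineages, so they
piggy-back on the refinement of sequences that do have pair info.

*Approximate bulk pairing* (`bulk_pair()`): in a merged single-cell +
bulk sample, every unpaired sequence in a cluster that contains at
least one paired sequence receives the partner of its nearest paired
cluster-mate.  This pairs bulk sequences with the correct (or at least
a similar) opposite-chain family, though usually not the correct
sequence — by construction the exactly-correct fraction equals the
single-cell fraction of the sample.

# The simulator

Each sample starts from a synthetic germline set: per locus and region,
the configured number of genes (defaults: IgH 42 V / 18 D / 6 J, IgK
11 V / 3 J, IgL 11 V / 2 J) with one or two alleles per gene.  The mean
alleles per gene `n_a` (IgH V 1.33, D and J 1.2, light 1.1) converts to
the single-allele probability via `p_1 = f / (1 + f)`,
`f = (n_a - 2)/(1 - n_a)` — algebraically `p_1 = 2 - n_a`.  Allele
prevalences come from integer pseudo-counts drawn uniformly in
`[1, 1/r_m]` (rounded down) and normalized, bounding any pairwise
prevalence ratio below by roughly `r_m` (default 0.1).  Allele sequences
are synthesized: random nucleotides with fixed region lengths (V 300,
D 20, J 50), conserved CDR3 anchor codons, and 1–3 point differences
between alleles of a gene.  This preserves exactly the structure the
inference consumes — gene/allele identity, prevalence, anchoring —
without any database download.

Each event draws a family size, V/(D)/J alleles by prevalence, geometric
deletion and insertion lengths per boundary (heavy means 3–4 nt, light
2 nt — light junctions are deliberately information-poor), and uniform
insertion bases.  Deletions are capped so anchors survive (rejection
with bounded retries); the caps truncate the geometric tail slightly.
One tree per event is shared by the heavy and light chain — pairing is
biologically uncorrelated by construction.  Trees are birth–death
(speciation 1, extinction 0.5) conditioned on tip count via
`ape::rphylo` — an exact conditioned sampler, preferred over
simulate-and-reject since only tip count, imbalance and branch-length
heterogeneity matter downstream; `star` and `caterpillar` (exponential
branch lengths) models serve the annotation benchmarks, and arbitrary
newick can be supplied.

Mutation follows JC69 with four discrete gamma rate categories (shape
0.35, configurable — a stand-in for externally inferred values, as the
shape itself is not critical to clustering difficulty).  Site categories
are drawn once per family; the branch scale is then calibrated by
root-finding against the *realized* site-rate composition so the
expected leaf-to-naive Hamming fraction equals `shm_mean` exactly, which
keeps the empirical SHM fraction within ±1% of target at 1000 leaves.
The star tree's root branch is deliberately short (0.1 of a tip branch):
mutations above the MRCA are perfectly correlated across leaves and
would otherwise dominate the variance of that average.  `shm_mean` must
stay below 0.7 because Hamming fractions saturate at 0.75 under JC69.

Family sizes: `fixed(k)`, `geometric(mean)`, or `datalike` — 70%
singletons with a geometric tail on sizes ≥ 2.  The default tail
parameter 0.3 gives a mean family size of 2, i.e. roughly 12,000 heavy
plus light sequences from 3,000 events, matching the scale of real
droplet datasets the benchmarks emulate.  Real repertoires have heavier
tails (power-law-like); with the geometric tail, families of ≥ 10 cells
are present but families of ≥ 30 are rare, which matters for
bulk-pairing benchmarks (a family with no single-cell member can never
be paired) — see the limitations below.

Cells go to droplets (fixed occupancy or truncated Poisson); each
record's raw pair info lists *all* other sequences in its droplet, both
chains, matching how droplet data is actually delivered.  A configured
fraction of cells is emitted as bulk (droplet and pair info stripped),
and each chain read can drop out independently.

# Performance metrics

Per-sequence precision (fraction of a sequence's cluster that is truly
clonal) and sensitivity (fraction of its true family recovered), each
averaged over sequences; F1 is the harmonic mean of the two averages —
not the average of per-sequence F1s.  Pair fixes are classified per
sequence (heavy and light both counted) as exactly correct, correct
family, similar family, mispaired or unpaired.  *Similar* captures
wrong-family partners that arise from collisions: the focal sequence's
event and the partner's event have true naives within 3 nucleotides
(absolute) on the focal sequence's own chain, so the focal sequence
could stand in for a member of the partner's own family and the pairing
is likely still functional.  The synthetic neighbour partition instead
uses a *normalized* 3% threshold — the two conventions serve different
purposes and are kept distinct.  Two synthetic error partitions
(`synth_singleton()`, `synth_neighbor()`) provide intuitive context:
known error modes applied to the truth.

# Benchmark scales and what the tests show

The packaged checks run, per replicate, 3,000 events (≈ 12,000
sequences) for the pair-cleaning and bulk-pairing benchmarks and 1,000
events for the paired-refinement comparison, three replicates each —
sizes at which every relevant effect (light-chain collisions, droplet
ambiguity, family-size dependence) is well expressed while a replicate
completes in about two minutes on one core.

Passing them shows the algorithms behave as designed *under the
simulator's assumptions*: uncorrelated pairing, no SHM indels, no
allelic inclusion (exactly one heavy and one light per cell), synthetic
germline sets, and a geometric family-size tail.  Real data adds
correlated pairing (small but nonzero), indels, doublet chains,
sequencing error and database mismatch, none of which these tests
exercise.  Two consequences worth flagging: light-chain collision rates
in synthetic germline sets track the configured locus diversity rather
than any particular species; and bulk-pairing coverage of large
families is sensitive to the family-size tail — under the geometric
tail, several percent of sequences in families of ≥ 10 cells sit in
families with no single-cell member at bulk fraction 0.8 and stay
unpaired, where data-derived, heavier-tailed size distributions would
make such families vanishingly rare; mispairs into families 4–17
nucleotides away (merged by the 5% clustering threshold but beyond the
3-nucleotide similarity cut) add another point or two of loss.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; TSVs are tab-separated,
  unquoted, with semicolon-separated id lists.
* All randomized steps (subsampling, tie draws, simulation) consume the
  R RNG; `run_pipeline(seed =)` pins every stage, and identical
  configurations reproduce byte-identical outputs.
* Agglomeration distance ties break on cluster leader ids; annotation
  score ties break toward earlier alleles (lexicographic) and larger
  deletions; consensus ties toward germline, then vote weight, then
  base order.
* Empty inputs (no sequences at a locus, empty partitions, clusters with
  no paired members) pass through rather than error; sequences whose
  annotation fails the match-fraction floor (0.55) are excluded from
  clustering but reported in the partition's `failed` field.
* Clusters produced by paired resolution can mix CDR3 lengths (the
  merge of opposite-chain clusters is not constrained by this chain's
  junctions); where a single cluster-level annotation is needed, the
  modal CDR3-length class is annotated.

# Known limitations

No SHM indels, no VDDJ rearrangement, no allelic inclusion, no
data-mimicking ("parameter-matched") simulation mode, no
likelihood-based agglomeration — the naive-Hamming distance with a
single threshold stands in for the full HMM framework, and the
iterative clean-and-recluster loop that would likely improve pair
cleaning further is deliberately out of scope.
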