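# pairclone

Clonal family inference for B cell receptor (BCR) repertoires with
heavy/light chain pairing information.

Grouping BCR sequences into clonal families — the descendants of single
V(D)J rearrangement events — is the first step of most repertoire
analyses.  Single-chain clustering is fundamentally limited by
*collisions*: distinct rearrangement events with practically
indistinguishable naive (unmutated ancestor) sequences, which are
pervasive in the low-diversity light chain.  Single-cell droplet data
tells us which heavy chain pairs with which light chain; because the two
chains rearrange independently, collided light families almost always
have distinguishable heavy partners, so pairing information can repair
exactly the errors single-chain clustering cannot avoid.

`pairclone` provides:

* **Single-chain partitioning** by hierarchical agglomeration on
  inferred naive sequences within CDR3-length classes (threshold
  `d_0 = 0.05` normalized Hamming distance), with key-translation
  subsampling and a large/small merge shortcut for speed, plus the
  classical *VJ CDR3 0.8* single-linkage baseline.
* **Paired refinement** (`joint_partition()`): resolves the heavy and
  light partitions into one joint partition over cells, splitting
  clusters that the opposite chain confidently separates (by CDR3
  length, or by naive distance above `d_0`) and never merging on
  opposite-chain similarity.
* **Pair-info cleaning** (`clean_pair_info()`): disambiguates multiple
  candidate partners from overloaded droplets by clonal-family voting —
  the correct partner's family is shared among clone-mates, spurious
  co-droplet partners are not.
* **Approximate bulk pairing** (`bulk_pair()`): transfers pair info from
  a matched single-cell sample to bulk sequences through shared clonal
  families.
* **A from-scratch paired repertoire simulator**
  (`simulate_paired_repertoire()`): synthetic germline sets with allele
  prevalences, V(D)J rearrangement, birth–death/star/caterpillar trees
  shared between the two chains, JC69 + discrete-gamma somatic
  hypermutation, droplet assignment, dropout and bulk splits — with
  full ground truth.
* **Evaluation metrics** (`partition_scores()`, `pairing_scores()`):
  per-sequence precision/sensitivity/F1 against truth, pair-fix
  classification (exact / correct family / similar family / mispaired /
  unpaired), and synthetic error partitions for context.

## Worked example

Simulate 300 clonal families (geometric sizes, mean 3; 10% SHM), then
run the full workflow — annotation, single-chain partitions, pair
cleaning, paired refinement, evaluation:

```r
library(pairclone)

cfg <- sim_config(n_events = 300,
                  family_size_model = list(model = "geometric", mean = 3),
                  shm_mean = 0.10)
res <- run_pipeline(cfg, seed = 42)

round(rbind(single_light = res$evaluation$single_light,
            joint_light  = res$evaluation$joint_light,
            single_heavy = res$evaluation$single_heavy,
            joint_heavy  = res$evaluation$joint_heavy), 4)
#>              precision sensitivity     f1
#> single_light    0.8070           1 0.8932
#> joint_light     1.0000           1 1.0000
#> single_heavy    0.9836           1 0.9917
#> joint_heavy     1.0000           1 1.0000

res$joint$pairs
#> <clonal_partition> paired: 300 clusters over 921 sequences
#>   sizes: 26 13 12 12 11 10 10 10 10 10...
```

The single-chain light partition merges collided families (precision
0.81: roughly a fifth of each cluster is unrelated); the heavy chain is
nearly clean.  Refinement with pairing information recovers the true
300-family partition exactly on both chains.

Sequence records travel as AIRR-style TSV (`read_airr()` /
`write_airr()`), germline sets as FASTA plus an anchor side-car
(`write_germline_set()`), truth trees as newick.  A thin command-line
front end lives at `inst/scripts/pairclone`
(`pairclone simulate | annotate | partition | run-all`).

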