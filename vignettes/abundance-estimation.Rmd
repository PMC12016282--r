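---
title: "Bayesian reestimation of taxonomic abundance from k-mer LCA classifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian reestimation of taxonomic abundance from k-mer LCA classifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brackenlite)
```

## The problem

K-mer LCA classifiers (Kraken and its descendants) label each sequencing
read with the lowest common ancestor (LCA) of every genome that contains
the read's k-mers. This is the correct per-read answer, but it is a poor
abundance estimate: many bacterial species are nearly identical (the
*M. tuberculosis* / *M. bovis* pair shares well over 99.9% of its
sequence), so for such species most reads carry no species-specific
k-mer and get "stranded" at the genus, at an intermediate species-group
node, or higher. Counting only species-level assignments can
underestimate such species by an order of magnitude.

`brackenlite` converts a classification report into abundance estimates
at a chosen rank by moving reads across the level boundary in both
directions:

* reads at strain/leaf nodes (and unranked nodes below the level) are
  summed into their target-level ancestor, and
* reads stranded at nodes above the level are pushed down
  probabilistically to the detected target-level taxa of that node's
  subtree.

## The model

For a distributing node $G_j$ and a genome $S_i$ beneath it, the
probability that a read classified at $G_j$ belongs to $S_i$ is, by
Bayes' theorem,

$$P(S_i \mid G_j) = \frac{P(G_j \mid S_i)\, P(S_i)}{P(G_j)},$$

with $P(G_j) = 1$ because we condition on the read having been classified
at $G_j$. The two remaining ingredients are estimated as follows.

**Read-destination probabilities $P(G_j \mid S_i)$** come from
*self-classification* of the reference database: every window of length
$r$ (a pseudo-read) of every genome is classified against the k-mer
index built from those same genomes. Because each k-mer of a database
genome is assigned somewhere on the path from the genome's taxid to the
root, the deepest assigned node in the window is exactly the
classification a weighted root-to-leaf-path classifier would produce.
For a genome of length $L_i$ this yields $L_i - r + 1$ assignments, and

$$P(G_j \mid S_i) = \frac{N_{G_j}(S_i)}{L_i - r + 1},$$

where $N_{G_j}(S_i)$ counts the windows of $S_i$ landing on node $G_j$.
The *unique fraction*

$$U_{S_i} = \frac{N_{S_i}}{L_i - r + 1}$$

is the proportion of windows classified to the genome's own node. These
quantities depend only on the database and $r$, so they are computed once
(`build_distribution()`), written to a distribution file, and reused for
any sample.

**Priors $P(S_i)$** are estimated from the sample itself. If the
classifier assigned $K_{S_i}$ reads directly to $S_i$, and only a
fraction $U_{S_i}$ of reads from $S_i$ can be so assigned, the genome
likely contributed

$$\hat K_{S_i} = \frac{K_{S_i}}{U_{S_i}}$$

reads in total (1,000 direct reads at $U = 0.25$ imply 4,000 reads).
The prior is the genome's share among the candidate genomes of the
distributing node's subtree:

$$P(S_i) = \frac{\hat K_{S_i}}{\sum_a \hat K_{S_a}}.$$

Each distributing node's direct reads are then split in proportion to
$P(G_j \mid S_i)\,P(S_i)$, per-genome allocations are combined per
species, and the final estimate per taxon is its rolled-up classifier
count plus everything allocated to it.

## Tunable parameters

* `k` (default 31, bases): k-mer length of the index. Longer k-mers are
  more often unique to one genome; shorter ones are more sensitive.
* `r` (default 75, bases): pseudo-read window length, matched to the
  sample's read length. Estimates degrade only mildly when sample read
  length differs; `estimate_abundance()` warns and proceeds on a
  mismatch, and re-running `build_distribution()` at the matching `r` is
  always available.
* `threshold` (default 10, reads): minimum rolled-up read count for a
  taxon to be treated as present. This is the false-positive guard; taxa
  below it are excluded from redistribution and their reads reported as
  unallocated. The threshold is applied *after* strain roll-up, so a
  species seen as 4 species-level plus 7 strain-level reads counts 11.
* `level` (default `"species"`): the target rank; any rank from domain
  to strain works, and `"root"` collapses the report to one row.

## Design choices in corners the math leaves open

* **Ties in read classification.** When two root-to-leaf paths carry
  equal k-mer weight, the read is assigned to the LCA of the tied
  deepest nodes (the behaviour of the published k-mer classifiers).
* **Normalization over detected taxa.** Allocation shares at a node are
  renormalized over the *detected* genomes of its subtree; read
  conservation is the governing contract. A node whose subtree holds no
  detected taxon keeps its reads as explicit `unallocated_reads`; they
  are never dropped and never leak into other subtrees.
* **Priors per distributing node.** $P(S_i)$ is normalized over the
  candidate genomes of each distributing node's own subtree, which
  reduces to per-genus priors for genus nodes and generalizes naturally
  to family and above.
* **$U_{S_i} = 0$.** A genome with no unique windows cannot anchor
  $\hat K = K/U$; if it nevertheless has direct reads, $\hat K = K$ is
  used with a warning (the only alternative is division by zero).
* **Multiple genomes per species.** Allocation runs at genome
  granularity and is summed per species. Species-level direct reads are
  apportioned among the species' genomes proportionally to their
  strain-derived totals when strain reads exist, otherwise to their
  unique window counts.
* **Windows and strands.** Windows are slid on the given strand only;
  strand symmetry comes from canonical k-mers (each k-mer keyed by the
  lexicographic minimum of itself and its reverse complement). Windows
  never span contig boundaries, and any window position whose k-mer
  overlaps an `N` contributes no k-mer; a window with no usable k-mer at
  all is counted at the root.
* **Arithmetic.** Allocations are carried in full precision; within each
  node the last allocation absorbs the floating-point remainder so
  per-node conservation is exact. Estimates are rounded half-to-even to
  integers only when written.

## A worked example

```{r toy}
tree <- load_taxonomy(c("1 | 1 | root |", "2 | 1 | genus |",
                        "3 | 2 | species |", "4 | 2 | species |"))
gA <- genome_record(3, "AAACC")
gB <- genome_record(4, "AAAGG")
idx <- build_kmer_index(list(gA, gB), k = 3, tree)
dist <- build_distribution(list(gA, gB), idx, tree, r = 3)
dist$per_genome[["3"]]
```

The k-mer `AAA` occurs in both genomes, so it maps to the genus and one
of genome A's three windows classifies there: $P(G\mid A) = 1/3$,
$U_A = 2/3$. Given a report with stranded genus reads, the estimator
pushes them back down:

```{r toy-estimate}
rep <- kraken_report(c(`3` = 100, `4` = 50, `2` = 90), tree)
estimate_abundance(rep, dist, tree,
                   estimation_config(threshold = 10, read_length = 3))
```

## What the simulator emulates, and what it does not

`mock_community_spec()` / `make_community()` build a seeded community of
nine species in six genera (one genus holding four species, mirroring
published skin mock communities), mixed in equal proportions, with one
sister pair sharing 99.9% of its sequence beneath a species-group node.
Sister divergence is scattered single-base substitution sites rather
than one contiguous divergent block: that is how real near-identical
species pairs differ, and it is also the regime that stresses the
estimator realistically, because each differing base rescues only the
~r windows covering it (at 99.9% identity this leaves a unique fraction
of roughly $(1-0.999)\times r \approx 0.06$, not $0.001$).

Reads are single-end, uniformly positioned, with i.i.d. per-base
substitution errors to a uniformly chosen different base. The simulator
does **not** model indels, quality-value-driven error profiles, GC or
library-preparation bias, paired reads, or genomes absent from the
database. Passing tests on these fixtures therefore demonstrate the
correctness of the redistribution arithmetic and the classifier
semantics, not robustness to every artefact of real sequencing data.

Default problem sizes are chosen to exercise the estimator meaningfully
on a desk machine: 50 kb genomes, $10^5$ reads of 75 bp at k = 31 for
the full community (about half a minute end to end), and 2–8 kb genomes
for the unit fixtures. With $10^5$ equal-proportion reads, each sister
species keeps roughly 600 uniquely assignable reads, enough to estimate
its prior to a few percent — which is what bounds the accuracy of the
split of the stranded reads between sisters.

## Known limitations

* The index is an exact in-memory hash of canonical k-mers; it is
  faithful to the classification semantics but makes no attempt at the
  memory engineering (minimizers, compacted databases) real classifiers
  need at RefSeq scale.
* A species present in the sample but absent from the database can never
  be estimated (its reads land on relatives or go unclassified), and a
  genome present in the taxonomy but missing from the distribution file
  cannot receive redistributed reads (the estimator warns).
* Redistribution can only repartition reads among *detected* taxa; if
  the classifier's report conflates two sisters entirely (neither passes
  the detection threshold alone), their joint abundance is preserved but
  the split between them is unresolvable.
* Estimates for a species are only as good as its unique fraction: the
  sampling error of the prior scales like $1/\sqrt{K_{S_i}}$, so species
  with very small $U$ and low coverage carry proportionally noisy
  estimates.
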