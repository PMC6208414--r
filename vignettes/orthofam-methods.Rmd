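---
title: "orthofam: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthofam: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, the
numerical conventions, the places where the design was genuinely open and
what we chose, and what the validation on synthetic data does and does not
demonstrate.

## The analysis in one paragraph

Given one predicted proteome per genome, `orthofam` clusters all genes
into ortholog groups (gene families) by Markov clustering of a weighted
gene similarity graph, summarizes family presence and size across taxa in
a family × taxon count matrix, partitions families into core /
clade-specific / clade-diversified / species-expanded / species-specific
sets relative to a declared focal clade, tests families for
lineage-specific expansion while conditioning on total gene content,
builds an alignment-free whole-proteome phylogeny from k-mer frequency
profiles, and tests gene sets for GO term enrichment against the genome
universe.

## Similarity graph

Two interchangeable sources feed the clustering:

* **Ingested alignment hits** (12-column tabular format). Hits with
  E-value above the cutoff (default `1e-5`, the conventional threshold
  for orthology-pipeline BLAST searches) are dropped, self-hits are
  dropped, the edge weight is `-log10(E)` with E floored at `1e-200` so
  weights stay finite, and reciprocal hits are symmetrized by taking the
  maximum weight. Symmetrization by max (rather than mean) follows common
  MCL-pipeline practice; the choice matters little because reciprocal
  E-values are usually within an order of magnitude.
* **Internal alignment-free scorer.** The Jaccard index of the two genes'
  sets of distinct amino-acid 4-mers, with an edge kept when it reaches
  `min_score = 0.2`. For random length-150 sequences over 20 letters the
  expected 4-mer overlap is ≈ 150²/20⁴ ≈ 0.14 shared 4-mers, so unrelated
  genes essentially never reach 0.2, while homologs with up to ≈ 25%
  per-site divergence retain Jaccard ≈ (1−d)⁴/(2−(1−d)⁴) ≥ 0.2. Both `k`
  and `min_score` are exposed. Within-taxon edges are included — paralogs
  must co-cluster for family size statistics to make sense.

Isolated genes are retained as graph nodes so that singleton families
survive clustering. Residues outside the 20 standard letters are mapped to
`X` on input and any k-mer window containing `X` is skipped, keeping the
k-mer space at 20 letters.

## Markov clustering

The MCL iteration is implemented directly on a sparse column-stochastic
matrix: expansion (matrix squaring), inflation (entrywise power, default
2.0, then column renormalization), pruning of entries below `1e-5` with
renormalization, until the maximum entrywise change falls below `1e-8` or
100 iterations. Choices the MCL literature leaves open, fixed here:

* **Self-loops** are set to each node's maximum incident edge weight
  (1 for isolated nodes). Loops are required for convergence; max-weight
  loops are the common pipeline choice and behave better than unit loops
  when edge weights are far from 1 (e.g. `-log10 E` weights of 200).
* **Cluster read-out.** Clusters are the connected components of the
  nonzero structure of the limit matrix. This both reads attractor
  systems and *merges overlapping attractors*, so the result is always a
  partition (asserted on every run). The alternative — assigning an
  overlap node to its heaviest attractor — was rejected as numerically
  unstable. A consequence worth knowing: in exactly symmetric graphs
  (e.g. a bridge node equidistant from two cliques) the overlap is exact
  and the merge rule unions the two clusters; breaking the tie requires
  asymmetry in the data, not in the algorithm.
* **Inflation 2.0** is the default granularity, exposed in the
  configuration. Higher inflation gives finer clusters; on the default
  synthetic dataset the family count is monotone non-decreasing in
  inflation (a tested property).

A dense-matrix reference implementation of the same iteration (numpy,
`inst/oracle/mcl_reference.py`) exists purely as an independent
cross-check in the test suite; the R implementation never calls it.

## Family counts and gene sets

Presence means count ≥ 1 everywhere: Venn regions, core membership and
specificity all count families, not gene copies. The five sets are:
core (present in every focal-clade taxon); clade-specific (core and
absent from every other taxon, comparison clade and outgroups alike);
clade-diversified and species-expanded (from the tests below);
focal-species-specific *genes* (members of families containing no other
taxon, focal singletons included — a gene set, because the natural unit of
"no orthologs in any other genome" is the gene; a family-level summary is
also reported). The partition invariant clade-specific ⊆ core is asserted.

The shared-gene-content dendrogram uses
d(A,B) = 1 − shared / min(|A|,|B|), the gene-content phylogeny convention
in which a nested proteome is at distance 0 from its superset; `mean` is
available as an alternative denominator. UPGMA (average linkage) is used
because the display is a rooted dendrogram; the tree should be read as a
similarity summary, not a phylogeny. Family-size histograms use
exponential binning with intervals open on the left — (0,1], (1,3],
(3,7], … — so bin *i* covers sizes 2^(i−1) … 2^i − 1.

## Expansion statistics

Two one-directional tests, both conditioning on total gene content by
treating each taxon's family count as a binomial draw from its proteome:

* **Clade diversification**: a binomial GLM with a single two-level group
  factor, realized exactly as a grouped-binomial likelihood-ratio test —
  null, one shared proportion; alternative, pooled focal and comparison
  proportions; statistic 2(ℓ₁−ℓ₀) ~ χ²₁; the log-likelihood uses the
  binomial kernel with 0·log 0 = 0. For a two-level factor this is
  identical inference to an iteratively fitted regression with no fitting
  machinery to call. A pooled one-sided Fisher variant is available
  (`method = "fisher"`) because both test names circulate for this
  contrast in the comparative literature; the LRT is the default.
  Outgroups are excluded; all-zero families are skipped, degenerate
  all-zero input returns p = 1 with direction 0.
* **Species expansion**: for every family shared by ≥ 2 focal taxa and
  every ordered pair of focal taxa possessing it, a one-sided Fisher
  exact test (hypergeometric upper tail, computed by `phyper`) on
  [[cₓ, Tₓ−cₓ],[c_y, T_y−c_y]] with T the proteome totals. Pairs
  involving a taxon that lacks the family are not tested — a zero count
  against a positive one is trivially "larger" and would only dilute the
  FDR pool.

BH-FDR is applied within one test family per contrast type: once across
all clade tests, and once jointly across *all* pairwise tests (pooling is
the more conservative choice for the pairwise sweep, whose per-family
tests are strongly dependent). Significance is q < 0.01 with positive
direction. A family is declared expanded in a species only when
significant against **every** other focal taxon possessing it
(`rule = "all"`); the permissive any-pair rule is a configuration switch.
Proteome totals (not clustered-gene totals) are the denominators — that is
what "accounting for differences in total gene content" means here.

## Alignment-free phylogeny

Feature frequency profiles count all overlapping amino-acid 8-mers per
proteome (windows never span protein boundaries). Length 8 over 20
letters is sparse — ~2.5 × 10¹⁰ possible features — so profiles are hash
maps, never dense vectors. Divergence is the Jensen–Shannon divergence in
bits over the union of observed features, which lies in [0, 1] and is 0
iff the frequency vectors coincide; the raw JSD (not its square root) is
the default distance, with the square-root metric available.

Neighbor joining is the canonical Saitou–Nei algorithm with the
Studier–Keppler Q-criterion, with two conventions fixed for determinism:
ties in Q are broken by the lowest pair of taxon indices, and negative
branch lengths are clamped to zero with the deficit moved to the sister
branch so the joined pair's distance is preserved. On additive matrices
the reconstruction is exact (tested to 10⁻⁹ against distances regenerated
from random trees, and against the stock `ape::nj`).

Bootstrap support resamples the union feature set with replacement at its
own cardinality — the standard profile (column) bootstrap; each
pseudoreplicate's reweighted counts give a JSD matrix and an NJ tree, and
each internal bipartition of the point tree is supported by the
percentage of pseudoreplicate trees containing it. 100 pseudoreplicates
is the default. A block bootstrap over sequence positions is not
attempted; with only "resample the features" as the established recipe,
the column bootstrap is the defensible choice.

## GO enrichment

Classic hypergeometric enrichment: universe restricted to genes with ≥ 1
annotation (so reported universes match the annotated fractions one
quotes for each set), observed k per term versus expectation n·K/N,
upper-tail p by `phyper`, zero-observed terms omitted, rows sorted by p.
Raw p-values are the primary output — the convention for this table
format — with a clearly labelled BH column alongside. The true-path rule
is applied first when a parent table (minimal OBO: `id:`/`is_a:` only,
obsolete terms dropped, cycles rejected) is supplied. topGO-style
decorrelation algorithms (weight01 and friends) are deliberately not
reproduced: they are properties of that tool, not of the hypergeometric
model, which is why published topGO p-values are generally not
bit-reproducible by any classic implementation.

## The synthetic generator

The generator is the package's source of ground truth, not a fixture: it
evolves `n_families` families along a known species tree. Per branch of
length *t* (substitutions/site), each gene copy survives with probability
exp(−λ_loss·t) and, if it survives, duplicates at most once with
probability 1 − exp(−λ_dup·t); a lost copy's would-be duplicate dies with
it. Planted expansions multiply a family's copy number by `fold` on the
stem branch of a named taxon or clade, so the new copies are independent
lineages early enough to diverge, yet late enough to stay clusterable.
Sequences are i.i.d.-uniform at the root (geometric lengths around 150
aa, minimum 30), mutate i.i.d. per site with probability s·t per branch
(default s = 0.15) to a uniformly chosen different residue, and child
copies mutate independently from their parent-node sequence — same-branch
duplicate siblings therefore diverge over that branch. GO annotations are
Bernoulli: background terms at a base frequency (default 0.05), planted
terms at `frequency_in` inside the target families and `frequency_out`
elsewhere. Gene ids are `<taxon>_g<serial>` and never encode the family.

Default study design: 8 taxa — a 4-taxon focal clade, a 2-taxon
comparison clade, 2 outgroups — with branch lengths giving at most ≈ 10%
per-site divergence across the deepest split, 200 families, λ_dup = 0.3
and λ_loss = 0.2 per unit branch length. These are modest, realistic
rates for protein-coding family turnover at this divergence scale and
give count matrices in which most families are present in most taxa. The
`root_copies` parameter (default 1) sets the ancestral copy number per
family, so expansion-recovery experiments can use baseline family sizes
of 10 as their starting condition.

What the generator does *not* emulate — and therefore what passing
recovery tests do **not** demonstrate about real data: rate heterogeneity
among sites and lineages (no substitution matrix; every exchange equally
likely), indels, domain shuffling, horizontal transfer, codon-level
effects, assembly and annotation artifacts, and fragmented gene models.
Real proteomes violate all of these; the synthetic results validate the
*machinery* (graph, clustering, tests, trees, enrichment), not the
biological error rates one would see on real assemblies.

## Determinism and problem sizes

All randomness flows from explicit integer seeds: the generator derives
per-stage seeds (counts, sequences, annotations) from its single seed,
and the pipeline gives the FFP bootstrap its own substream, so a rerun
with the same configuration is byte-identical (a tested property, file by
file). JSON reports contain no timestamps; timings go to a log file.

The validation suite uses desk-scale problem sizes chosen to make every
property measurable in seconds: 200-family / 8-taxon datasets for
clustering recovery, 20 × 1000 families for null calibration of the
expansion tests, 20 × 10 planted 5-fold expansions at baseline size 10
for sensitivity, 100 random additive 6-taxon matrices for NJ exactness,
and 100 bootstrap pseudoreplicates on 4-taxon simulations for FFP
recovery. These sizes are the package's own validation design; all of
them scale up linearly in the obvious ways if heavier checks are wanted.

## Known limitations

* MCL is dense in the worst case and the implementation targets
  desk-scale graphs (up to a few tens of thousands of genes); it is not
  an out-of-core or regularized MCL.
* The internal k-mer scorer is a similarity heuristic, not an alignment;
  for distant homologs (< ~50% identity) BLAST-derived graphs remain the
  better input, and the package consumes them natively.
* The decontamination filter reproduces a fixed published rule
  (E < 10⁻²⁰ **and** bitscore > 1000, strict inequalities, any qualifying
  hit); it is a screening convention, not a classifier.
* Bootstrap supports are supports of the *profile* resampling scheme;
  they quantify feature-sampling variance, not model adequacy.
* The grouped-binomial LRT relies on the χ²₁ asymptotics; for families
  with very few genes the Fisher variants are the safer tool (and the
  pairwise test is exact by construction).
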