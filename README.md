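# orthofam

Comparative gene-family analysis across whole genomes, in R.

When several related genomes are available as predicted proteomes, a
standard set of questions follows: which gene families are shared by every
member of a focal clade (the *core* genome)? Which of those are found
nowhere else (*clade-specific* families)? Which families are significantly
*larger* in the focal clade than in its sister lineages, or in one species
than in its congeners (*lineage-specific expansions*)? And what does
whole-proteome signal say about the phylogeny of the genomes themselves?
`orthofam` implements this entire analysis as a reusable, tested pipeline,
aimed at comparative genomicists working with a handful to a few dozen
proteomes (the motivating use case is multi-genome comparisons within a
clade such as the scleractinian corals and their anthozoan relatives).

## What it computes

1. **Ortholog groups (gene families).** A weighted gene similarity graph —
   either from an internal alignment-free k-mer Jaccard scorer or from
   ingested BLAST tabular hits (E-value cutoff 10⁻⁵, edge weight
   −log₁₀ E) — is clustered with the Markov Cluster algorithm (MCL):
   alternating expansion (matrix squaring) and inflation (entrywise power
   *r*, default 2.0, with column renormalization) of a column-stochastic
   matrix until convergence; clusters are the attractor systems of the
   limit matrix, singletons included.
2. **Gene-set partition.** From the family × taxon count matrix **C**,
   with a declared focal clade *F*, comparison clade and outgroups:
   core = { f : C[f,g] ≥ 1 ∀ g ∈ F }; clade-specific = core families with
   zero members outside *F*; focal-species-specific genes = genes whose
   family contains no other taxon. Venn region counts, exponential
   family-size binning (intervals (0,1], (1,3], (3,7], …) and a UPGMA
   dendrogram on shared-gene-content distance
   d(A,B) = 1 − shared/min(|A|,|B|) summarize the matrix.
3. **Expansion statistics.** Clade diversification per family by a
   grouped-binomial likelihood-ratio test (the two-level binomial GLM in
   closed form: 2(ℓ₁−ℓ₀) ~ χ²₁, pooled MLE proportions per group);
   species-level expansion by one-sided Fisher's exact tests on
   [[cₓ, Tₓ−cₓ],[c_y, T_y−c_y]] for every ordered focal pair, conditioning
   on total gene content T. Benjamini–Hochberg FDR across each test family,
   significance at q < 0.01, one-directional ("larger") calls only.
4. **Alignment-free phylogeny.** Length-8 amino-acid feature frequency
   profiles (FFP) per proteome, pairwise Jensen–Shannon divergence
   JSD(P,Q) = H(M) − (H(P)+H(Q))/2 in bits, Saitou–Nei neighbor joining,
   and feature bootstrap (100 pseudoreplicates) for internal-node support.
5. **GO enrichment.** Classic hypergeometric upper-tail enrichment of any
   gene set against the annotated genome universe, with true-path-rule
   annotation propagation, reporting Observed / Expected / p (raw p
   primary, BH q labelled alongside).
6. **Synthetic proteomes with planted truth.** A generator that evolves
   gene families along a known species tree (per-copy birth/death per
   branch, i.i.d. per-site substitution), plants lineage-specific
   expansions and GO enrichment, and emits FASTA/TSV plus the full ground
   truth — so clustering, tests, phylogeny and enrichment can all be
   validated by parameter recovery.

## Worked example

```r
library(orthofam)

## 8 taxa (focal clade F1-F4, comparison C1-C2, outgroups O1-O2),
## 60 families; families 1-5 start at 10 ancestral copies and family 1 is
## expanded 5-fold on the F1 stem branch.
cfg <- sim_config(n_families = 60, seed = 42,
                  planted_expansions = list(list(family = 1, taxa = "F1",
                                                 fold = 5)),
                  root_copies = c(rep(10L, 5), rep(1L, 55)))
sim <- simulate_proteomes(cfg)
proteins <- sim$proteins

graph  <- build_graph_internal(proteins)     # k = 4, min Jaccard 0.2
groups <- mcl(graph)                         # inflation 2.0
groups
#> ortholog_groups: 60 families over 955 genes; sizes 6-133 (inflation 2.00, 14 iterations)
cluster_quality(groups, sim$truth)           # adjusted Rand index vs truth
#> [1] 1

fcm <- build_count_matrix(groups, setNames(proteins$taxon_id,
                                           proteins$gene_id))
gr  <- default_grouping()
cd  <- test_clade_diversified(fcm, gr)       # binomial LRT, BH q < 0.01
se  <- test_species_expansion(fcm, gr)       # pairwise Fisher, all-pairs
part <- classify_gene_sets(fcm, gr, cd, se, groups)
length(part$core)                            # families in all of F1-F4
#> [1] 55
core_gene_fraction(fcm, part, "F1")          # fraction of F1 genes in core
#> [1] 0.982
expanded_families(se)$F1                     # the planted expansion, found
#> [1] "OG00001"

profiles <- lapply(split(proteins, proteins$taxon_id), ffp_profile, l = 8)
tree <- bootstrap_tree(profiles, B = 100, seed = 43)
write_newick(tree)
#> ((F3:...,F4:...)100:...,((C1:...,C2:...)100:...,(O1:...,O2:...)100:...)100:...,(F1:...,F2:...)100:...);
```

The clustering recovers the 60 planted families exactly (ARI = 1); 55 of
60 families survive birth/death in all four focal taxa and make up 98% of
F1's genes; the single planted 5-fold expansion is the only family called
expanded in any species; and the FFP tree recovers the true
((F1,F2),(F3,F4)) / (C1,C2) / (O1,O2) structure with 100% bootstrap
support at every node.

The same analysis runs end to end from one configuration with
`run_pipeline()` (or the CLI dispatcher in `inst/cli/orthofam.R`, which
exposes `simulate | graph | cluster | classify | expand | phylo | enrich |
all` as subcommands), writing every stage's TSV/newick output and a JSON
report.

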