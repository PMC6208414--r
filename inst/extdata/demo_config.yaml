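# Demo pipeline configuration: synthetic 8-taxon dataset with one planted
# 5-fold expansion in F1 and one planted enriched GO term.
# Run:  Rscript inst/cli/orthofam.R all --config demo_config.yaml --outdir demo_out
seed: 42
simulate:
  n_families: 60
  seed: 42
  root_copies: [10, 10, 10, 10, 10, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
                1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
                1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
                1, 1]
  planted_expansions:
    - family: 1
      taxa: F1
      fold: 5
  planted_go:
    - term: "GO:9000001"
      families: [1, 2, 3, 4, 5]
      frequency_in: 0.8
      frequency_out: 0.05
grouping:
  focal_clade: [F1, F2, F3, F4]
  comparison_clade: [C1, C2]
  outgroups: [O1, O2]
  focal_species: F1
similarity:
  source: internal
  k: 4
  min_score: 0.2
mcl:
  inflation: 2.0
expansion:
  q_threshold: 0.01
  clade_method: binomial
  pairwise_rule: all
ffp:
  l: 8
  B: 100
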