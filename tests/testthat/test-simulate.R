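test_that("zero rates and no planting give exactly one copy everywhere", {
  cfg <- sim_config(n_families = 25, duplication_rate = 0, loss_rate = 0,
                    seed = 11)
  sim <- simulate_family_counts(cfg)
  expect_true(all(sim$counts == 1L))
})

test_that("planted single-taxon expansion multiplies the stem copy number", {
  cfg <- sim_config(n_families = 10, duplication_rate = 0, loss_rate = 0,
                    planted_expansions = list(
                      list(family = 3, taxa = "F2", fold = 5)),
                    seed = 2)
  sim <- simulate_family_counts(cfg)
  expect_equal(sim$counts["fam0003", "F2"], 5L)
  expect_true(all(sim$counts["fam0003", colnames(sim$counts) != "F2"] == 1L))
  expect_true(all(sim$counts[rownames(sim$counts) != "fam0003", ] == 1L))
})

test_that("clade-level planting hits the stem branch of the clade only", {
  cfg <- sim_config(n_families = 6, duplication_rate = 0, loss_rate = 0,
                    planted_expansions = list(
                      list(family = 1, taxa = c("F1", "F2", "F3", "F4"),
                           fold = 3)),
                    seed = 2)
  sim <- simulate_family_counts(cfg)
  expect_true(all(sim$counts["fam0001", c("F1", "F2", "F3", "F4")] == 3L))
  expect_true(all(sim$counts["fam0001", c("C1", "C2", "O1", "O2")] == 1L))
})

test_that("planting on an unknown taxon is a config error", {
  expect_error(sim_config(planted_expansions = list(
    list(family = 1, taxa = "NOPE", fold = 5))), "unknown taxa")
  expect_error(sim_config(planted_expansions = list(
    list(family = 1, taxa = "F1", fold = 1))), "fold")
})

test_that("loss-only simulation matches the closed-form survival rate", {
  # single tip at path length 0.5: P(survive) = exp(-loss * 0.5)
  cfg <- sim_config(species_tree = "(A:0.2,B:0.5);", n_families = 10000,
                    duplication_rate = 0, loss_rate = 1.2, seed = 31)
  sim <- simulate_family_counts(cfg)
  p_true <- exp(-1.2 * 0.5)
  frac <- mean(sim$counts[, "B"])
  se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(frac - p_true), 3 * se)
})

test_that("sequence counts agree with the count matrix and ids hide family", {
  cfg <- sim_config(n_families = 30, seed = 5)
  sim <- simulate_family_counts(cfg)
  sq <- simulate_sequences(sim)
  expect_equal(nrow(sq$proteins), sum(sim$counts))
  tab <- table(sq$proteins$taxon_id)
  expect_equal(as.integer(tab[colnames(sim$counts)]),
               unname(colSums(sim$counts)))
  expect_true(all(grepl("^[A-Z][0-9]_g[0-9]+$", sq$proteins$gene_id)))
  expect_false(any(grepl("fam", sq$proteins$gene_id)))
  # truth covers every emitted gene exactly once
  expect_setequal(names(sq$truth$gene_to_family), sq$proteins$gene_id)
  expect_equal(unname(colSums(sq$truth$family_counts$counts)),
               as.integer(tab[colnames(sq$truth$family_counts$counts)]))
})

test_that("near-zero substitution keeps family members identical", {
  cfg <- sim_config(n_families = 8, duplication_rate = 0.4, loss_rate = 0,
                    substitution_prob_per_unit = 1e-9, seed = 9)
  sq <- simulate_sequences(simulate_family_counts(cfg))
  by_fam <- split(sq$proteins$sequence, sq$truth$gene_to_family[
    sq$proteins$gene_id])
  expect_true(all(vapply(by_fam, function(s) length(unique(s)) == 1L,
                         TRUE)))
})

test_that("distinct families share essentially no 4-mers", {
  cfg <- sim_config(n_families = 40, duplication_rate = 0, loss_rate = 0,
                    family_length_mean = 100, seed = 13)
  sq <- simulate_sequences(simulate_family_counts(cfg))
  one_per_fam <- sq$proteins[sq$proteins$taxon_id == "F1", ]
  set.seed(1)
  pairs <- t(combn(nrow(one_per_fam), 2))
  pairs <- pairs[sample(nrow(pairs), 100), ]
  jac <- apply(pairs, 1, function(pr)
    kmer_jaccard(one_per_fam$sequence[pr[1]], one_per_fam$sequence[pr[2]]))
  expect_lt(mean(jac), 1e-2)
})

test_that("the generator is byte-deterministic given a seed", {
  cfg <- sim_config(n_families = 12, seed = 77,
                    planted_go = list(list(term = "GO:9000001",
                                           families = 1:2,
                                           frequency_in = 0.9,
                                           frequency_out = 0.05)))
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  simulate_proteomes(cfg, outdir = d1)
  simulate_proteomes(cfg, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("GO planting controls annotation frequency inside the target set", {
  cfg <- sim_config(n_families = 100, duplication_rate = 0, loss_rate = 0,
                    go_terms = 0, seed = 21,
                    planted_go = list(list(term = "GO:9000001",
                                           families = 1:25,
                                           frequency_in = 0.8,
                                           frequency_out = 0.05)))
  out <- simulate_proteomes(cfg)
  target <- sprintf("fam%04d", 1:25)
  inside <- names(out$truth$gene_to_family)[
    out$truth$gene_to_family %in% target]
  has_term <- vapply(out$annotations$gene_to_terms[inside],
                     function(t) "GO:9000001" %in% t, TRUE)
  # 25 families x 8 taxa = 200 genes in the set; binomial 99% interval
  k <- sum(has_term); n <- length(inside)
  expect_gt(k, qbinom(0.005, n, 0.8))
  expect_lt(k, qbinom(0.995, n, 0.8))
  # extreme frequencies annotate exactly the target genes
  cfg2 <- sim_config(n_families = 20, duplication_rate = 0, loss_rate = 0,
                     go_terms = 0, seed = 22,
                     planted_go = list(list(term = "GO:9000001",
                                            families = 1:5,
                                            frequency_in = 1,
                                            frequency_out = 0)))
  out2 <- simulate_proteomes(cfg2)
  tgt2 <- sprintf("fam%04d", 1:5)
  with_term <- names(Filter(function(t) "GO:9000001" %in% t,
                            out2$annotations$gene_to_terms))
  expect_setequal(with_term, names(out2$truth$gene_to_family)[
    out2$truth$gene_to_family %in% tgt2])
})
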