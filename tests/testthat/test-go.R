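test_that("annotation propagation closes term sets under ancestry", {
  parents <- list(`GO:t` = "GO:s", `GO:s` = "GO:r")
  ann <- go_annotations(list(g1 = "GO:t", g2 = "GO:s", g3 = character()),
                        parents)
  prop <- propagate_annotations(ann)
  expect_setequal(prop$gene_to_terms$g1, c("GO:t", "GO:s", "GO:r"))
  expect_setequal(prop$gene_to_terms$g2, c("GO:s", "GO:r"))
  expect_length(prop$gene_to_terms$g3, 0)
  # idempotent; no parent map is a no-op
  expect_equal(lapply(propagate_annotations(prop)$gene_to_terms, sort),
               lapply(prop$gene_to_terms, sort))
  plain <- go_annotations(list(g1 = "GO:t"))
  expect_identical(propagate_annotations(plain)$gene_to_terms,
                   plain$gene_to_terms)
  expect_error(go_annotations(list(), list(`GO:a` = "GO:b", `GO:b` = "GO:a")),
               "[Cc]ycle")
})

test_that("enrichment matches the hand-enumerated hypergeometric case", {
  # N = 10, K = 4, n = 5, k = 3: expected 2.0, p = 66/252
  universe <- sprintf("u%02d", 1:10)
  g2t <- stats::setNames(rep(list(character()), 10), universe)
  for (g in universe[1:4]) g2t[[g]] <- "GO:K"
  for (g in universe) g2t[[g]] <- c(g2t[[g]], "GO:ALL")
  ann <- go_annotations(g2t)
  set <- universe[c(1, 2, 3, 5, 6)]  # 3 of the 4 carriers
  rows <- enrich(set, universe, ann)
  k_row <- rows[rows$term == "GO:K", ]
  expect_equal(k_row$observed, 3L)
  expect_equal(k_row$expected, 2.0)
  expect_equal(k_row$p_value, 66 / 252, tolerance = 1e-12)
  expect_equal(k_row$p_value, brute_hyper_upper(3, 4, 10, 5),
               tolerance = 1e-12)
  # a term annotating the whole universe has p = 1 and expected = n
  all_row <- rows[rows$term == "GO:ALL", ]
  expect_equal(all_row$p_value, 1)
  expect_equal(all_row$expected, 5)
  expect_error(enrich(c(set, "zz"), universe, ann), "subset")
})

test_that("enrichment p-values match enumeration on random small universes", {
  set.seed(27)
  for (i in 1:20) {
    N <- sample(10:30, 1)
    universe <- sprintf("g%03d", seq_len(N))
    K <- sample(1:N, 1)
    carriers <- sample(universe, K)
    g2t <- stats::setNames(lapply(universe, function(g)
      if (g %in% carriers) "GO:X" else "GO:BG"), universe)
    ann <- go_annotations(g2t)
    n <- sample(2:N, 1)
    set <- sample(universe, n)
    rows <- enrich(set, universe, ann)
    k <- sum(set %in% carriers)
    if (k > 0) {
      expect_equal(rows$p_value[rows$term == "GO:X"],
                   brute_hyper_upper(k, K, N, n), tolerance = 1e-12)
      expect_equal(rows$observed[rows$term == "GO:X"], k)
    } else {
      expect_false("GO:X" %in% rows$term)  # zero-observed rows omitted
    }
  }
})

test_that("the universe is restricted to annotated genes", {
  g2t <- list(g1 = "GO:A", g2 = "GO:A", g3 = character())
  ann <- go_annotations(g2t)
  rows <- enrich(c("g1", "g3"), c("g1", "g2", "g3", "g4"), ann)
  # N = 2 annotated universe genes, n = 1 annotated set gene
  expect_equal(rows$expected[rows$term == "GO:A"], 1)
})

test_that("a planted term ranks first under simulated enrichment", {
  cfg <- sim_config(n_families = 100, duplication_rate = 0, loss_rate = 0,
                    go_terms = 30, seed = 55,
                    planted_go = list(list(term = "GO:9000001",
                                           families = 1:10,
                                           frequency_in = 0.8,
                                           frequency_out = 0.05)))
  out <- simulate_proteomes(cfg)
  genes <- names(out$truth$gene_to_family)
  target <- sprintf("fam%04d", 1:10)
  set <- genes[out$truth$gene_to_family %in% target]
  rows <- enrich(set, genes, out$annotations)
  expect_equal(rows$term[1], "GO:9000001")
  expect_lt(rows$p_value[1], 1e-10)
})

test_that("null annotations yield non-anticonservative uniform-ish p-values", {
  # same frequency inside and outside: no signal, so small p-values are rare
  set.seed(71)
  pvals <- numeric(0)
  for (s in 1:5) {
    cfg <- sim_config(n_families = 60, duplication_rate = 0, loss_rate = 0,
                      go_terms = 25, base_go_frequency = 0.2, seed = 500 + s)
    out <- simulate_proteomes(cfg)
    genes <- names(out$truth$gene_to_family)
    set <- genes[out$truth$gene_to_family %in% sprintf("fam%04d", 1:15)]
    rows <- enrich(set, genes, out$annotations)
    pvals <- c(pvals, rows$p_value)
  }
  expect_gte(mean(pvals), 0.4)           # super-uniform or uniform
  expect_lte(mean(pvals < 0.05), 0.06)   # no excess of small p
})
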