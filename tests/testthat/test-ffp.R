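test_that("profiles count overlapping windows within proteins only", {
  p1 <- ffp_profile(data.frame(sequence = "ACDEFGHI"), l = 8)
  expect_equal(unname(p1$counts), 1L)
  expect_equal(p1$total, 1L)
  p2 <- ffp_profile(data.frame(sequence = "AAAAA"), l = 2)
  expect_equal(p2$counts[["AA"]], 4L)
  p3 <- ffp_profile(data.frame(sequence = c("ACD", "CDE")), l = 3)
  expect_equal(sort(names(p3$counts)), c("ACD", "CDE"))
  expect_equal(p3$total, 2L)  # no window spans the protein boundary
  expect_error(ffp_profile(data.frame(sequence = "ACD"), l = 8),
               "No countable window")
  # X-containing windows are skipped
  px <- ffp_profile(data.frame(sequence = "ACXDE"), l = 2)
  expect_setequal(names(px$counts), c("AC", "DE"))
})

test_that("profile totals and content are invariant to protein order", {
  cfg <- ffp_sim_config(seed = 19, n_families = 20)
  sq <- simulate_sequences(simulate_family_counts(cfg))
  prot <- sq$proteins[sq$proteins$taxon_id == "A", ]
  p1 <- ffp_profile(prot, l = 8)
  p2 <- ffp_profile(prot[rev(seq_len(nrow(prot))), ], l = 8)
  expect_equal(p1$counts[sort(names(p1$counts))],
               p2$counts[sort(names(p2$counts))])
  expect_equal(p1$total,
               sum(pmax(nchar(prot$sequence) - 8 + 1, 0)))
})

test_that("JSD matches the entropy formula and its bounds", {
  mk <- function(counts) structure(list(taxon_id = "t", l = 1L,
                                        counts = counts,
                                        total = sum(counts)),
                                   class = "ffp_profile")
  pa <- mk(c(A = 2L))            # frequencies (1, 0)
  pb <- mk(c(A = 1L, C = 1L))    # frequencies (0.5, 0.5)
  # frozen from direct evaluation: H((0.75,0.25)) - (0 + 1)/2
  expect_equal(jsd(pa, pb), 0.311278124459133, tolerance = 1e-12)
  expect_equal(jsd(pa, pa), 0)
  expect_equal(jsd(mk(c(A = 3L)), mk(c(C = 5L))), 1)  # disjoint support
  expect_equal(jsd(pa, pb), jsd(pb, pa))
  expect_equal(jsd(pa, pb, take_sqrt = TRUE), sqrt(jsd(pa, pb)))
  expect_error(jsd(pa, ffp_profile(data.frame(sequence = "ACDE"), l = 2)),
               "different feature lengths")
})

test_that("neighbor joining reconstructs the hand-solved additive case", {
  D <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D)
  # split AB|CD with internal branch 1, leaf branches 1,2,3,4
  expect_equal(sort(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)] - D,
                    decreasing = TRUE)[1], 0, tolerance = 1e-12)
  key <- orthofam:::bipartition_keys(tr)
  expect_true("C|D" %in% key[!is.na(key)])
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining is exact on random additive matrices", {
  set.seed(77)
  for (i in 1:25) {
    ref <- ape::rtree(6)
    D <- ape::cophenetic.phylo(ref)
    tr <- nj_tree(D)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)] -
                        D)), 1e-9)
  }
})

test_that("nj_tree agrees with the stock NJ implementation on additive input", {
  set.seed(5)
  for (i in 1:5) {
    ref <- ape::rtree(7)
    D <- ape::cophenetic.phylo(ref)
    ours <- nj_tree(D)
    stock <- ape::nj(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ours),
                                           ape::unroot(stock))), 0)
  }
})

test_that("bootstrap supports identify forced and recovered splits", {
  cfg <- ffp_sim_config(seed = 3)
  sq <- simulate_sequences(simulate_family_counts(cfg))
  profs <- lapply(split(sq$proteins, sq$proteins$taxon_id), ffp_profile,
                  l = 8)
  tr <- bootstrap_tree(profs, B = 50, seed = 10)
  sup <- attr(tr, "supports")
  expect_true(all(sup >= 0 & sup <= 100))
  # the true cherry C|D (equivalently A|B side) must be recovered strongly
  expect_true(any(sup >= 90))
  # B = 1 gives all-or-nothing supports
  tr1 <- bootstrap_tree(profs, B = 1, seed = 10)
  expect_true(all(attr(tr1, "supports") %in% c(0, 100)))
  expect_error(bootstrap_tree(profs, B = 0), "B must be")
})

test_that("duplicated proteomes force a 100-support cherry", {
  cfg <- ffp_sim_config(seed = 8, n_families = 15)
  sq <- simulate_sequences(simulate_family_counts(cfg))
  byt <- split(sq$proteins, sq$proteins$taxon_id)
  profs <- list(A = ffp_profile(byt$A, taxon_id = "A"),
                A2 = ffp_profile(byt$A, taxon_id = "A2"),
                C = ffp_profile(byt$C, taxon_id = "C"),
                D = ffp_profile(byt$D, taxon_id = "D"))
  tr <- bootstrap_tree(profs, B = 25, seed = 4)
  sup <- attr(tr, "supports")
  cherry <- sup[names(sup) %in% c("A2|A", "A|A2", "C|D")]
  expect_true(any(cherry == 100))
})
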