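test_that("one-sided Fisher p matches exhaustive enumeration", {
  # hand case: [[2,3],[1,4]] -> (C(5,2)C(5,1) + C(5,3)C(5,0)) / C(10,3)
  expect_equal(fisher_exact_one_sided(2, 3, 1, 4), 0.5)
  expect_equal(brute_fisher_upper(2, 3, 1, 4), 0.5)
  expect_equal(fisher_exact_one_sided(0, 10, 0, 7), 1)
  expect_gt(fisher_exact_one_sided(5, 95, 5, 95), 0.5)
  expect_error(fisher_exact_one_sided(-1, 1, 1, 1), "non-negative")
  # randomized sweep over tables with margins <= 60
  set.seed(14)
  for (i in 1:200) {
    a <- sample(0:30, 1); b <- sample(0:30, 1)
    c <- sample(0:30, 1); d <- sample(0:30, 1)
    expect_equal(fisher_exact_one_sided(a, b, c, d),
                 brute_fisher_upper(a, b, c, d), tolerance = 1e-12,
                 label = sprintf("table [[%d,%d],[%d,%d]]", a, b, c, d))
  }
  # cross-check against the stock implementation on a few tables
  for (tb in list(c(8, 2, 3, 9), c(1, 20, 5, 12), c(10, 0, 0, 10))) {
    expect_equal(fisher_exact_one_sided(tb[1], tb[2], tb[3], tb[4]),
                 stats::fisher.test(matrix(tb, 2, byrow = TRUE),
                                    alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("grouped-binomial LRT matches the numeric-optimization oracle", {
  r <- binomial_lrt(c(20, 22, 2, 1), rep(10000, 4),
                    c("focal", "focal", "comparison", "comparison"))
  # frozen from direct maximization of both likelihoods (optimize, tol 1e-14)
  expect_equal(r$statistic, 40.3776116712, tolerance = 1e-8)
  expect_equal(r$p_value, 2.09326087481e-10, tolerance = 1e-6)
  expect_equal(r$direction, 1)
})

test_that("LRT degenerate and null cases behave", {
  r0 <- binomial_lrt(c(5, 5), c(1000, 1000), c("focal", "comparison"))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  rz <- binomial_lrt(c(0, 0), c(100, 100), c("focal", "comparison"))
  expect_equal(rz$p_value, 1)
  expect_equal(rz$direction, 0)
  rneg <- binomial_lrt(c(1, 30), c(1000, 1000), c("focal", "comparison"))
  expect_equal(rneg$direction, -1)
  # p decreases as counts and totals scale up at fixed proportions
  p1 <- binomial_lrt(c(6, 2), c(100, 100), c("focal", "comparison"))$p_value
  p2 <- binomial_lrt(c(60, 20), c(1000, 1000),
                     c("focal", "comparison"))$p_value
  expect_lt(p2, p1)
})

test_that("BH step-up matches the hand formula and is order-invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(6)
  p <- runif(50)
  # hand step-up: q_(i) = min_{j>=i} p_(j) * m / j
  o <- order(p)
  m <- length(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q_hand <- numeric(m); q_hand[o] <- pmin(1, q_sorted)
  expect_equal(bh_fdr(p), q_hand, tolerance = 1e-12)
  perm <- sample(m)
  expect_equal(bh_fdr(p[perm]), q_hand[perm], tolerance = 1e-12)
  expect_true(all(diff(bh_fdr(p)[o]) >= -1e-12))
})

test_that("clade diversification test flags only positive-direction families", {
  counts <- rbind(flat = c(1, 1, 1, 1, 1, 1),
                  up = c(30, 28, 25, 27, 1, 1),
                  down = c(1, 1, 1, 1, 30, 30),
                  outonly = c(0, 0, 0, 0, 0, 0))
  colnames(counts) <- c("F1", "F2", "F3", "F4", "C1", "C2")
  counts <- cbind(counts, O1 = c(1, 1, 1, 5), O2 = c(1, 1, 1, 2))
  totals <- stats::setNames(rep(2000L, 8), colnames(counts))
  fcm <- family_count_matrix_from_counts(counts, totals)
  gr <- default_grouping()
  res <- test_clade_diversified(fcm, gr)
  expect_false("outonly" %in% res$family_id)  # outgroup-only family skipped
  expect_true(res$significant[res$family_id == "up"])
  expect_false(res$significant[res$family_id == "down"])  # wrong direction
  expect_equal(res$direction[res$family_id == "down"], -1)
  expect_false(res$significant[res$family_id == "flat"])
  # the Fisher variant agrees on the clear-cut calls
  resf <- test_clade_diversified(fcm, gr, method = "fisher")
  expect_true(resf$significant[resf$family_id == "up"])
  expect_false(resf$significant[resf$family_id == "down"])
})

test_that("pairwise expansion testing follows the shared-family and all-pairs rules", {
  counts <- rbind(big1 = c(75, 5, 5, 5), even = c(5, 5, 5, 5),
                  pair = c(40, 2, 0, 0), solo = c(9, 0, 0, 0))
  colnames(counts) <- c("F1", "F2", "F3", "F4")
  totals <- stats::setNames(rep(3000L, 4), colnames(counts))
  fcm <- family_count_matrix_from_counts(counts, totals)
  gr <- taxon_grouping(focal_clade = colnames(counts),
                       comparison_clade = character(0) ,
                       focal_species = "F1")
  expect_error(test_clade_diversified(fcm, gr), "empty")
  res <- test_species_expansion(fcm, gr)
  expect_false("solo" %in% res$family_id)  # not shared by >= 2 taxa
  expect_equal(sum(res$family_id == "pair"), 2)  # only the possessing pair
  exp_fam <- expanded_families(res)
  expect_true("big1" %in% exp_fam$F1)
  expect_true("pair" %in% exp_fam$F1)
  expect_false(any(vapply(exp_fam[c("F2", "F3", "F4")],
                          function(x) "even" %in% x, TRUE)))
  expect_false("even" %in% exp_fam$F1)
})

test_that("planted 5-fold expansions are recovered and nulls stay quiet", {
  cfg <- sim_config(n_families = 60, seed = 41, root_copies = 10,
                    planted_expansions = list(
                      list(family = 7, taxa = "F3", fold = 5)))
  sim <- simulate_family_counts(cfg)
  fcm <- family_count_matrix_from_counts(sim$counts)
  res <- test_species_expansion(fcm, default_grouping())
  exp_fam <- expanded_families(res)
  expect_true("fam0007" %in% exp_fam$F3)
  expect_false("fam0007" %in% unlist(exp_fam[c("F1", "F2", "F4")]))
})
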