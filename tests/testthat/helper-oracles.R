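# Independent brute-force oracles used across the suite. These enumerate
# probabilities from first principles (binomial coefficients) and never
# call the implementation paths they check.

# one-sided Fisher p for [[a,b],[c,d]] by exhaustive enumeration over all
# tables with the observed margins
brute_fisher_upper <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(r1 + r2, c1)
  sum(probs[xs >= a])
}

# hypergeometric upper tail P(X >= k) for a term with K carriers among N
# universe genes and a set of size n, by enumeration
brute_hyper_upper <- function(k, K, N, n) {
  xs <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(probs[xs >= k])
}

# adjusted Rand index straight from the contingency-table formula
brute_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- si * sj / n2
  mx <- (si + sj) / 2
  if (mx == expected) return(0)
  (sij - expected) / (mx - expected)
}

# run the dense numpy reference MCL on a similarity graph; returns the
# partition as a sorted list of sorted member vectors
run_reference_mcl <- function(graph, inflation = 2, max_iter = 100,
                              prune_below = 1e-5, tol = 1e-8) {
  script <- system.file("oracle", "mcl_reference.py", package = "orthofam")
  stopifnot(nzchar(script))
  abc <- tempfile(fileext = ".abc")
  nodes <- tempfile(fileext = ".txt")
  write_abc(graph, abc)
  writeLines(graph$nodes$gene_id, nodes)
  out <- system2("python", c(script, abc, nodes, format(inflation),
                             format(max_iter), format(prune_below),
                             format(tol)), stdout = TRUE)
  unlink(c(abc, nodes))
  lapply(strsplit(out, "\t", fixed = TRUE), sort)
}

partition_as_sets <- function(groups) {
  fams <- lapply(groups$families, sort)
  fams <- unname(fams)
  fams[order(vapply(fams, `[`, "", 1))]
}

# random edge-weighted graph on n nodes for clustering cross-validation
random_graph <- function(n, p_edge = 0.15, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p_edge
  edges <- data.frame(from = ids[pairs[keep, 1]], to = ids[pairs[keep, 2]],
                      weight = round(runif(sum(keep), 0.1, 1), 3))
  orthofam:::new_similarity_graph(
    data.frame(gene_id = ids, taxon_id = "T", stringsAsFactors = FALSE),
    edges)
}

# graph made of disjoint cliques with unit weights
clique_graph <- function(sizes) {
  ids <- unlist(lapply(seq_along(sizes), function(i)
    sprintf("c%d_%02d", i, seq_len(sizes[i]))))
  edges <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    members <- sprintf("c%d_%02d", i, seq_len(sizes[i]))
    if (length(members) < 2) return(NULL)
    pr <- t(combn(members, 2))
    data.frame(from = pr[, 1], to = pr[, 2], weight = 1)
  }))
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  orthofam:::new_similarity_graph(
    data.frame(gene_id = ids, taxon_id = "T", stringsAsFactors = FALSE),
    edges)
}
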