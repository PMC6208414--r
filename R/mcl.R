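#' Markov clustering of a gene similarity graph into ortholog groups
#'
#' Implements the MCL algorithm on the weighted similarity graph. A
#' column-stochastic matrix is built from the edge weights with self-loops
#' (loop weight = maximum incident edge weight; 1 for isolated nodes), then
#' expansion (matrix squaring) and inflation (entrywise power `inflation`,
#' column renormalization) alternate, pruning entries below `prune_below`
#' and renormalizing, until the maximum entrywise change drops below `tol`
#' or `max_iter` iterations. Clusters are read from the limit matrix as
#' attractor systems: connected components of the nonzero structure, which
#' also merges overlapping attractors so the result is always a partition.
#' Isolated nodes become singleton families.
#'
#' @param graph a `similarity_graph`.
#' @param inflation inflation exponent, must be > 1 (default 2.0); higher
#'   values give finer clusters.
#' @param max_iter maximum number of expansion/inflation rounds.
#' @param prune_below entries below this value are removed each round.
#' @param tol convergence threshold on the maximum entrywise change.
#' @return object of class `ortholog_groups`: list with `families` (named
#'   list family_id -> character vector of gene ids, a partition of the
#'   nodes, ordered by decreasing size) and `provenance` (parameters used).
#' @export
mcl <- function(graph, inflation = 2.0, max_iter = 100, prune_below = 1e-5,
                tol = 1e-8) {
  stopifnot(inherits(graph, "similarity_graph"))
  if (inflation <= 1) stop("inflation must be > 1")
  ids <- graph$nodes$gene_id
  n <- length(ids)
  e <- graph$edges
  i <- match(e$from, ids); j <- match(e$to, ids)
  # symmetric adjacency with self-loops
  loop <- rep(1, n)
  if (nrow(e)) {
    mx <- tapply(c(e$weight, e$weight), c(i, j), max)
    loop[as.integer(names(mx))] <- pmax(1e-300, as.numeric(mx))
  }
  M <- Matrix::sparseMatrix(i = c(i, j, seq_len(n)), j = c(j, i, seq_len(n)),
                            x = c(e$weight, e$weight, loop),
                            dims = c(n, n))
  M <- normalize_cols(M)
  for (iter in seq_len(max_iter)) {
    prev <- M
    M <- M %*% M                               # expansion
    M@x <- M@x^inflation                       # inflation
    M <- normalize_cols(M)
    M <- Matrix::drop0(M * (M >= prune_below)) # prune, then renormalize
    M <- normalize_cols(M)
    if (max(abs(M - prev)) < tol) break
  }
  tri <- Matrix::summary(M)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tri$i, to = tri$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership
  comp <- comp[as.character(seq_len(n))]
  fams <- split(ids, comp)
  # stable ids: order by decreasing size, ties by smallest member id
  first <- vapply(fams, function(x) min(x), "")
  ord <- order(-lengths(fams), first)
  fams <- fams[ord]
  names(fams) <- sprintf("OG%05d", seq_along(fams))
  res <- structure(list(families = fams,
                        provenance = list(inflation = inflation,
                                          max_iter = max_iter,
                                          prune_below = prune_below,
                                          tol = tol, iterations = iter)),
                   class = "ortholog_groups")
  assert_partition(res, ids)
  res
}

normalize_cols <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

assert_partition <- function(groups, ids) {
  all_members <- unlist(groups$families, use.names = FALSE)
  if (anyDuplicated(all_members) || length(all_members) != length(ids) ||
      !setequal(all_members, ids)) {
    stop("Internal error: clustering result is not a partition of the nodes")
  }
  invisible(TRUE)
}

#' @export
print.ortholog_groups <- function(x, ...) {
  sz <- lengths(x$families)
  cat("ortholog_groups:", length(sz), "families over", sum(sz), "genes;",
      "sizes", paste(range(sz), collapse = "-"),
      sprintf("(inflation %.2f, %d iterations)\n",
              x$provenance$inflation, x$provenance$iterations))
  invisible(x)
}

#' Gene-to-family lookup from an ortholog group set
#'
#' @param groups an `ortholog_groups` object.
#' @return named character vector, gene id -> family id.
#' @export
gene_families <- function(groups) {
  stopifnot(inherits(groups, "ortholog_groups"))
  fam <- rep(names(groups$families), lengths(groups$families))
  stats::setNames(fam, unlist(groups$families, use.names = FALSE))
}

#' Write ortholog groups as a three-column TSV
#'
#' One row per gene: `family_id`, `taxon`, `gene_id` — the shape consumed by
#' the family-analysis stage.
#'
#' @param groups an `ortholog_groups` object.
#' @param gene_taxon named vector gene id -> taxon id.
#' @param path output path.
#' @export
write_families <- function(groups, gene_taxon, path) {
  g2f <- gene_families(groups)
  df <- data.frame(family_id = unname(g2f),
                   taxon = unname(gene_taxon[names(g2f)]),
                   gene_id = names(g2f), stringsAsFactors = FALSE)
  df <- df[order(df$family_id, df$gene_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Adjusted Rand index of a clustering against the simulated truth
#'
#' @param groups an `ortholog_groups` object.
#' @param truth a `synthetic_truth` object (or any named gene -> label
#'   vector).
#' @return the adjusted Rand index in \[-1, 1\]; 1 means identical
#'   partitions, 0 is the chance level.
#' @export
cluster_quality <- function(groups, truth) {
  g2f <- gene_families(groups)
  true_lab <- if (inherits(truth, "synthetic_truth")) truth$gene_to_family
  else truth
  if (!setequal(names(g2f), names(true_lab))) {
    stop("Clustering and truth cover different gene universes")
  }
  genes <- names(true_lab)
  mclust::adjustedRandIndex(unname(g2f[genes]), unname(true_lab[genes]))
}
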