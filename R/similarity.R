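# all overlapping k-mers of one sequence; windows containing X are skipped
seq_kmers <- function(sequence, k, unique_only = TRUE) {
  n <- nchar(sequence)
  if (n < k) return(character())
  km <- substring(sequence, 1:(n - k + 1), k:n)
  km <- km[!grepl("X", km, fixed = TRUE)]
  if (unique_only) unique(km) else km
}

#' k-mer Jaccard similarity of two protein sequences
#'
#' Jaccard index of the two sets of distinct k-mers; k-mers containing `X`
#' are skipped. An alignment-free similarity score used to weight edges of
#' the gene similarity graph.
#'
#' @param a,b amino-acid sequences (strings), each of length >= `k`.
#' @param k k-mer length (default 4).
#' @return similarity in \[0, 1\].
#' @export
kmer_jaccard <- function(a, b, k = 4) {
  if (nchar(a) < k || nchar(b) < k) {
    stop("Sequences must be at least k = ", k, " residues long")
  }
  ka <- seq_kmers(a, k)
  kb <- seq_kmers(b, k)
  un <- length(union(ka, kb))
  if (un == 0L) return(0)
  length(intersect(ka, kb)) / un
}

new_similarity_graph <- function(nodes, edges) {
  stopifnot(all(c("gene_id", "taxon_id") %in% names(nodes)),
            all(c("from", "to", "weight") %in% names(edges)))
  if (nrow(edges)) {
    stopifnot(all(edges$weight > 0), !any(edges$from == edges$to))
    # canonical orientation + dedupe so the graph is simple and undirected
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    key <- paste(a, b, sep = "\r")
    keep <- !duplicated(key)
    edges <- data.frame(from = a[keep], to = b[keep],
                        weight = edges$weight[keep],
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity_graph:", nrow(x$nodes), "genes (",
      length(unique(x$nodes$taxon_id)), "taxa ),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Build a gene similarity graph with the internal k-mer scorer
#'
#' Connects every pair of genes (within and across taxa; within-taxon edges
#' are needed so paralogs co-cluster) whose k-mer Jaccard similarity reaches
#' `min_score`; the similarity is the edge weight. Genes without edges are
#' retained as isolated nodes so singleton families survive clustering.
#'
#' @param proteomes data.frame with columns `gene_id`, `taxon_id`,
#'   `sequence` (e.g. from [read_fasta()] or [simulate_proteomes()]), or a
#'   list of such data.frames.
#' @param k k-mer length (default 4).
#' @param min_score minimum Jaccard similarity for an edge (default 0.2).
#' @return a `similarity_graph`.
#' @export
build_graph_internal <- function(proteomes, k = 4, min_score = 0.2) {
  if (is.data.frame(proteomes)) prot <- proteomes
  else prot <- do.call(rbind, lapply(proteomes, function(p)
    p[, c("gene_id", "taxon_id", "sequence")]))
  if (anyDuplicated(prot$gene_id)) stop("Duplicate gene ids across proteomes")
  n <- nrow(prot)
  kml <- lapply(prot$sequence, seq_kmers, k = k)
  sizes <- lengths(kml)
  all_km <- unlist(kml, use.names = FALSE)
  edges <- data.frame(from = character(), to = character(), weight = numeric())
  if (length(all_km)) {
    kid <- match(all_km, unique(all_km))
    gid <- rep.int(seq_len(n), sizes)
    X <- Matrix::sparseMatrix(i = gid, j = kid, x = 1,
                              dims = c(n, max(kid)))
    inter <- Matrix::tcrossprod(X)
    tri <- Matrix::summary(inter)
    tri <- tri[tri$i < tri$j, , drop = FALSE]
    if (nrow(tri)) {
      un <- sizes[tri$i] + sizes[tri$j] - tri$x
      jac <- ifelse(un > 0, tri$x / un, 0)
      keep <- jac >= min_score & jac > 0
      edges <- data.frame(from = prot$gene_id[tri$i[keep]],
                          to = prot$gene_id[tri$j[keep]],
                          weight = jac[keep], stringsAsFactors = FALSE)
    }
  }
  new_similarity_graph(
    data.frame(gene_id = prot$gene_id, taxon_id = prot$taxon_id,
               stringsAsFactors = FALSE),
    edges)
}

#' Build a gene similarity graph from tabular alignment hits
#'
#' Self-hits are dropped, hits with E-value above `evalue_cutoff` are
#' dropped, edge weight is `-log10(max(evalue, 1e-200))`, and reciprocal
#' hits are symmetrized by taking the maximum weight.
#'
#' @param hits data.frame from [read_blast_tab()].
#' @param evalue_cutoff maximum E-value for an edge (default 1e-5).
#' @param nodes optional data.frame (`gene_id`, `taxon_id`) fixing the node
#'   universe, so genes without qualifying hits stay as isolated nodes.
#'   Defaults to the ids seen in `hits` (taxon `NA`).
#' @return a `similarity_graph`.
#' @export
build_graph_from_hits <- function(hits, evalue_cutoff = 1e-5, nodes = NULL) {
  keep <- hits$query_id != hits$subject_id & hits$evalue <= evalue_cutoff
  h <- hits[keep, , drop = FALSE]
  w <- -log10(pmax(h$evalue, 1e-200))
  a <- pmin(h$query_id, h$subject_id)
  b <- pmax(h$query_id, h$subject_id)
  key <- paste(a, b, sep = "\r")
  wmax <- tapply(w, key, max)
  ab <- do.call(rbind, strsplit(names(wmax), "\r", fixed = TRUE))
  edges <- if (length(wmax)) {
    data.frame(from = ab[, 1], to = ab[, 2], weight = as.numeric(wmax),
               stringsAsFactors = FALSE)
  } else data.frame(from = character(), to = character(), weight = numeric())
  if (is.null(nodes)) {
    ids <- sort(unique(c(hits$query_id, hits$subject_id)))
    nodes <- data.frame(gene_id = ids, taxon_id = NA_character_,
                        stringsAsFactors = FALSE)
  }
  missing <- setdiff(unique(c(edges$from, edges$to)), nodes$gene_id)
  if (length(missing)) stop("Hits reference genes outside the node set: ",
                            paste(utils::head(missing), collapse = ", "))
  new_similarity_graph(nodes, edges)
}

#' Write a similarity graph in 3-column ABC format
#'
#' The `gene_a<TAB>gene_b<TAB>weight` dialect consumed by standard MCL
#' implementations, enabling cross-validation against them. Isolated nodes
#' are omitted by the format.
#'
#' @param graph a `similarity_graph`.
#' @param path output path.
#' @export
write_abc <- function(graph, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(graph$edges)) {
    writeLines(sprintf("%s\t%s\t%.10g", graph$edges$from, graph$edges$to,
                       graph$edges$weight), con, sep = "\n")
  }
  invisible(path)
}
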