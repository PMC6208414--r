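#' Propagate GO annotations to ancestor terms (true-path rule)
#'
#' Closes every gene's term set under the `is_a` ancestry so that a gene
#' annotated to a term is annotated to all the term's ancestors. Idempotent;
#' annotations without a parent map are returned unchanged.
#'
#' @param annotations a [go_annotations()] object.
#' @return a [go_annotations()] object with closed term sets.
#' @export
propagate_annotations <- function(annotations) {
  stopifnot(inherits(annotations, "go_annotations"))
  parents <- annotations$term_parents
  if (is.null(parents)) return(annotations)
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(tm) {
    hit <- get0(tm, envir = anc_cache, ifnotfound = NULL)
    if (!is.null(hit)) return(hit)
    ps <- parents[[tm]]
    res <- if (is.null(ps) || !length(ps)) character() else {
      unique(c(ps, unlist(lapply(ps, ancestors), use.names = FALSE)))
    }
    assign(tm, res, envir = anc_cache)
    res
  }
  g2t <- lapply(annotations$gene_to_terms, function(terms) {
    unique(c(terms, unlist(lapply(terms, ancestors), use.names = FALSE)))
  })
  go_annotations(g2t, parents)
}

#' Hypergeometric GO term enrichment of a gene set
#'
#' Classic one-sided hypergeometric (Fisher) enrichment of a gene set
#' against the whole-genome universe. The universe is restricted to genes
#' carrying at least one annotation. For each term annotating at least one
#' universe gene, with `N` annotated universe genes, `K` of them carrying
#' the term, and `n` annotated genes in the set, the observed count `k` is
#' compared to its expectation `n*K/N` and the upper-tail probability
#' `P(X >= k)` is reported. Terms observed zero times in the set are
#' omitted; rows are sorted by p ascending. Raw p-values are the primary
#' output; a BH-adjusted column is added for convenience, clearly labelled.
#'
#' @param set_genes character vector of gene ids (subset of the universe).
#' @param universe_genes character vector of gene ids.
#' @param annotations a [go_annotations()] object (run
#'   [propagate_annotations()] first if ancestor counting is wanted).
#' @return data.frame with columns `term`, `observed`, `expected`,
#'   `p_value`, `q_value_bh`, sorted by `p_value`.
#' @export
enrich <- function(set_genes, universe_genes, annotations) {
  stopifnot(inherits(annotations, "go_annotations"))
  set_genes <- unique(set_genes)
  universe_genes <- unique(universe_genes)
  if (!all(set_genes %in% universe_genes)) {
    stop("set_genes must be a subset of universe_genes")
  }
  g2t <- annotations$gene_to_terms
  annotated <- universe_genes[universe_genes %in% names(g2t) &
                                lengths(g2t[universe_genes]) > 0]
  N <- length(annotated)
  set_ann <- intersect(set_genes, annotated)
  n <- length(set_ann)
  if (N == 0L) {
    return(data.frame(term = character(), observed = integer(),
                      expected = numeric(), p_value = numeric(),
                      q_value_bh = numeric(), stringsAsFactors = FALSE))
  }
  uni_terms <- unlist(g2t[annotated], use.names = FALSE)
  K <- table(uni_terms)
  set_terms <- unlist(g2t[set_ann], use.names = FALSE)
  k <- table(set_terms)
  terms <- names(k)  # only terms observed in the set are reported
  Kv <- as.integer(K[terms])
  kv <- as.integer(k[terms])
  p <- stats::phyper(kv - 1, Kv, N - Kv, n, lower.tail = FALSE)
  out <- data.frame(term = terms, observed = kv,
                    expected = n * Kv / N, p_value = p,
                    q_value_bh = bh_fdr(p), stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV (Observed/Expected/p schema)
#'
#' @param rows data.frame from [enrich()].
#' @param path output path.
#' @param term_names optional named vector term -> human-readable name.
#' @export
write_enrichment <- function(rows, path, term_names = NULL) {
  out <- data.frame(`GO Accession` = rows$term,
                    `Term Name` = if (is.null(term_names)) "" else
                      unname(term_names[rows$term]),
                    Observed = rows$observed, Expected = rows$expected,
                    p = rows$p_value, q = rows$q_value_bh,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
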