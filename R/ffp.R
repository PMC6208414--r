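#' Feature frequency profile of a proteome
#'
#' Counts all overlapping amino-acid l-mers across the proteins of one
#' proteome (windows never cross protein boundaries; l-mers containing `X`
#' are skipped). Profiles are stored sparsely as named counts: the length-8
#' feature space over 20 letters is far too large for dense vectors.
#'
#' @param proteome data.frame with a `sequence` column (e.g. from
#'   [read_fasta()]), or a character vector of sequences.
#' @param l feature length (default 8).
#' @param taxon_id taxon label for the profile (taken from the data.frame
#'   when present).
#' @return object of class `ffp_profile`: `taxon_id`, `l`, `counts`
#'   (named integer vector), `total`.
#' @export
ffp_profile <- function(proteome, l = 8, taxon_id = NULL) {
  if (is.data.frame(proteome)) {
    seqs <- proteome$sequence
    if (is.null(taxon_id) && "taxon_id" %in% names(proteome)) {
      taxon_id <- proteome$taxon_id[1]
    }
  } else {
    seqs <- as.character(proteome)
  }
  km <- unlist(lapply(seqs, seq_kmers, k = l, unique_only = FALSE),
               use.names = FALSE)
  if (!length(km)) {
    stop("No countable window: no sequence of length >= ", l,
         " without X in every window")
  }
  tb <- table(km)
  counts <- stats::setNames(as.integer(tb), names(tb))
  structure(list(taxon_id = if (is.null(taxon_id)) NA_character_ else taxon_id,
                 l = as.integer(l), counts = counts,
                 total = sum(counts)),
            class = "ffp_profile")
}

#' @export
print.ffp_profile <- function(x, ...) {
  cat("ffp_profile:", x$taxon_id, "- l =", x$l, ",",
      length(x$counts), "distinct features,", x$total, "total\n")
  invisible(x)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence between two feature frequency profiles
#'
#' Profiles are normalized to frequency vectors over the union of their
#' features; `JSD(P,Q) = H(M) - (H(P) + H(Q))/2` with `M = (P+Q)/2` and
#' entropies in bits, so the value lies in \[0, 1\] and is 0 exactly for
#' identical frequency vectors.
#'
#' @param p,q `ffp_profile` objects with the same `l`.
#' @param take_sqrt return the square root (a metric) instead of the raw
#'   divergence; default `FALSE`.
#' @return divergence in \[0, 1\].
#' @export
jsd <- function(p, q, take_sqrt = FALSE) {
  stopifnot(inherits(p, "ffp_profile"), inherits(q, "ffp_profile"))
  if (p$l != q$l) stop("Profiles have different feature lengths")
  feats <- union(names(p$counts), names(q$counts))
  fp <- numeric(length(feats)); fq <- numeric(length(feats))
  fp[match(names(p$counts), feats)] <- p$counts / p$total
  fq[match(names(q$counts), feats)] <- q$counts / q$total
  v <- entropy_bits((fp + fq) / 2) - (entropy_bits(fp) + entropy_bits(fq)) / 2
  v <- min(1, max(0, v))
  if (take_sqrt) sqrt(v) else v
}

#' Pairwise Jensen-Shannon divergence matrix of proteome profiles
#'
#' @param profiles list of `ffp_profile` objects (same `l`); names default
#'   to the profiles' taxon ids.
#' @param take_sqrt see [jsd()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
jsd_matrix <- function(profiles, take_sqrt = FALSE) {
  taxa <- names(profiles)
  if (is.null(taxa)) {
    taxa <- vapply(profiles, function(p) p$taxon_id, "")
    names(profiles) <- taxa
  }
  if (anyDuplicated(taxa)) stop("Duplicate taxon labels in profiles")
  n <- length(profiles)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  if (n < 2) return(D)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- jsd(profiles[[i]], profiles[[j]],
                              take_sqrt = take_sqrt)
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining with the Studier-Keppler Q
#' criterion. Ties in Q are broken deterministically by the lowest pair of
#' taxon indices; negative branch lengths are clamped to 0 with the deficit
#' transferred to the sister branch (their sum, the joined pair's distance,
#' is preserved). Exact on additive distance matrices. The result is
#' unrooted (the basal node is a trifurcation).
#'
#' @param D symmetric numeric matrix with labelled rows/columns (or a
#'   `dist`), >= 3 taxa.
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("Neighbor joining needs at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) stop("Distance matrix must have taxon labels")
  stopifnot(isSymmetric(unname(D)), all(is.finite(D)), all(diag(D) == 0))
  sub <- labels  # newick fragment per active node
  d <- D
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { li <- 0; lj <- d[i, j] }
    if (lj < 0) { lj <- 0; li <- d[i, j] }
    new_sub <- sprintf("(%s:%.15g,%s:%.15g)", sub[i], li, sub[j], lj)
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    sub <- c(sub[keep], new_sub)
    d <- d2
  }
  v1 <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  v2 <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  v3 <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 sub[1], v1, sub[2], v2, sub[3], v3)
  ape::read.tree(text = nwk)
}

# non-trivial bipartition keys of an (unrooted) tree, canonicalized so the
# side not containing the alphabetically first taxon is reported
bipartition_keys <- function(tree, all_taxa = sort(tree$tip.label)) {
  ref <- all_taxa[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    set <- labs[idx]
    if (ref %in% set) set <- setdiff(all_taxa, set)
    if (length(set) < 2L || length(set) > length(all_taxa) - 2L) {
      return(NA_character_)
    }
    paste(sort(set), collapse = "|")
  }, "")
  keys
}

#' Alignment-free phylogeny with feature bootstrap support
#'
#' Builds the point-estimate neighbor-joining tree from the Jensen-Shannon
#' divergence matrix of the profiles, then resamples the union feature set
#' with replacement (keeping its cardinality) `B` times; each
#' pseudoreplicate's resampled counts yield a JSD matrix and an NJ tree.
#' The support of each internal bipartition of the point tree is the
#' percentage of pseudoreplicate trees containing it, attached as internal
#' node labels.
#'
#' @param profiles list of `ffp_profile` objects (>= 3 taxa; >= 4 for
#'   non-trivial supports).
#' @param B number of bootstrap pseudoreplicates (default 100).
#' @param seed optional integer seed for the resampling.
#' @param take_sqrt see [jsd()].
#' @return the point-estimate `ape::phylo` tree; internal node labels hold
#'   the supports (root label empty), and `attr(tree, "supports")` maps
#'   bipartition keys to support percentages.
#' @export
bootstrap_tree <- function(profiles, B = 100, seed = NULL,
                           take_sqrt = FALSE) {
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  taxa <- names(profiles)
  if (is.null(taxa)) {
    taxa <- vapply(profiles, function(p) p$taxon_id, "")
    names(profiles) <- taxa
  }
  point <- nj_tree(jsd_matrix(profiles, take_sqrt = take_sqrt))

  feats <- sort(unique(unlist(lapply(profiles, function(p) names(p$counts)),
                              use.names = FALSE)))
  M <- length(feats)
  C <- matrix(0, nrow = M, ncol = length(taxa),
              dimnames = list(NULL, taxa))
  for (t in seq_along(profiles)) {
    p <- profiles[[t]]
    C[match(names(p$counts), feats), t] <- p$counts
  }
  all_sorted <- sort(taxa)
  hits <- new.env(parent = emptyenv())
  for (b in seq_len(B)) {
    w <- tabulate(sample.int(M, M, replace = TRUE), nbins = M)
    Cb <- C * w
    tot <- colSums(Cb)
    if (any(tot == 0)) next  # degenerate resample carries no information
    Fb <- sweep(Cb, 2, tot, "/")
    nt <- length(taxa)
    Hb <- apply(Fb, 2, entropy_bits)
    Db <- matrix(0, nt, nt, dimnames = list(taxa, taxa))
    for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
      v <- entropy_bits((Fb[, i] + Fb[, j]) / 2) - (Hb[i] + Hb[j]) / 2
      v <- min(1, max(0, v))
      Db[i, j] <- Db[j, i] <- if (take_sqrt) sqrt(v) else v
    }
    for (k in bipartition_keys(nj_tree(Db), all_sorted)) {
      if (!is.na(k)) {
        assign(k, get0(k, envir = hits, ifnotfound = 0L) + 1L, envir = hits)
      }
    }
  }
  keys <- bipartition_keys(point, all_sorted)
  support <- vapply(keys, function(k) {
    if (is.na(k)) NA_real_
    else 100 * get0(k, envir = hits, ifnotfound = 0L) / B
  }, 0)
  point$node.label <- ifelse(is.na(support), "",
                             sprintf("%d", round(support)))
  sp <- support[!is.na(support)]
  names(sp) <- keys[!is.na(keys)]
  attr(point, "supports") <- sp
  point
}

#' Write a distance matrix as a labelled square TSV
#'
#' @param D symmetric matrix with dimnames.
#' @param path output path.
#' @export
write_distance_matrix <- function(D, path) {
  utils::write.table(as.data.frame(D), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
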