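#' Taxon grouping for comparative contrasts
#'
#' Declares which taxa form the focal clade (e.g. the scleractinian corals
#' in a coral comparative study), the comparison clade (the remaining
#' anthozoans), the outgroups, and which focal taxon is the focal species.
#'
#' @param focal_clade,comparison_clade,outgroups disjoint character vectors
#'   of taxon ids (outgroups may be empty).
#' @param focal_species a single taxon, member of `focal_clade`.
#' @return object of class `taxon_grouping`.
#' @export
taxon_grouping <- function(focal_clade, comparison_clade,
                           outgroups = character(), focal_species) {
  sets <- list(focal_clade, comparison_clade, outgroups)
  all_taxa <- unlist(sets)
  if (anyDuplicated(all_taxa)) stop("Grouping sets must be disjoint")
  if (!focal_species %in% focal_clade) {
    stop("focal_species must belong to the focal clade")
  }
  structure(list(focal_clade = focal_clade,
                 comparison_clade = comparison_clade,
                 outgroups = outgroups, focal_species = focal_species),
            class = "taxon_grouping")
}

#' Build the family-by-taxon count matrix from ortholog groups
#'
#' @param groups an `ortholog_groups` object.
#' @param gene_taxon named vector gene id -> taxon id covering every
#'   clustered gene; its full length per taxon gives the proteome totals.
#' @return object of class `family_count_matrix`: integer matrix `counts`
#'   (families x taxa) and `taxon_totals` (total genes per proteome).
#' @export
build_count_matrix <- function(groups, gene_taxon) {
  g2f <- gene_families(groups)
  if (any(!names(g2f) %in% names(gene_taxon))) {
    missing <- setdiff(names(g2f), names(gene_taxon))
    stop("Genes with unknown taxon: ", paste(utils::head(missing), collapse = ", "))
  }
  taxa <- sort(unique(unname(gene_taxon)))
  fam <- factor(unname(g2f), levels = names(groups$families))
  tax <- factor(unname(gene_taxon[names(g2f)]), levels = taxa)
  counts <- table(fam, tax)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(rownames(counts), colnames(counts)))
  totals <- table(factor(unname(gene_taxon), levels = taxa))
  family_count_matrix_from_counts(counts, totals)
}

#' Construct a family count matrix from a counts table
#'
#' @param counts integer matrix, families x taxa, with dimnames.
#' @param taxon_totals per-taxon total gene counts (named, or a table);
#'   defaults to the column sums (i.e. every gene clustered).
#' @return a `family_count_matrix`.
#' @export
family_count_matrix_from_counts <- function(counts, taxon_totals = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(dimnames(counts)) || is.null(rownames(counts))) {
    stop("counts must have family and taxon dimnames")
  }
  if (any(counts < 0)) stop("Family counts must be non-negative")
  if (is.null(taxon_totals)) taxon_totals <- colSums(counts)
  tt <- as.integer(taxon_totals)
  names(tt) <- names(taxon_totals)
  tt <- tt[colnames(counts)]
  if (any(is.na(tt))) stop("taxon_totals must cover every matrix taxon")
  if (any(colSums(counts) > tt)) {
    stop("Clustered gene counts exceed proteome totals")
  }
  structure(list(counts = counts, taxon_totals = tt),
            class = "family_count_matrix")
}

#' @export
print.family_count_matrix <- function(x, ...) {
  cat("family_count_matrix:", nrow(x$counts), "families x",
      ncol(x$counts), "taxa;", sum(x$taxon_totals), "genes total\n")
  invisible(x)
}

presence <- function(fcm, taxa) fcm$counts[, taxa, drop = FALSE] >= 1L

#' Partition gene families into comparative gene sets
#'
#' Applies the five gene-set definitions used in multi-genome gene-content
#' comparisons: (1) core = families present in every focal-clade taxon;
#' (2) clade-specific = core families absent from every non-focal taxon
#' (comparison clade and outgroups alike); (3) clade-diversified = families
#' significantly larger in the focal clade (from [test_clade_diversified()]);
#' (4) species-expanded = families significantly larger in one focal species
#' than the others (from [test_species_expansion()]); (5) focal-specific =
#' genes of the focal species whose family contains genes from no other
#' taxon, focal-species singletons included.
#'
#' @param fcm a `family_count_matrix`.
#' @param grouping a [taxon_grouping()].
#' @param diversified optional result of [test_clade_diversified()].
#' @param expanded optional result of [test_species_expansion()].
#' @param groups optional `ortholog_groups`; needed to list the
#'   focal-specific genes (family-level summary is always produced).
#' @return object of class `gene_set_partition` with elements `core`,
#'   `clade_specific`, `clade_diversified` (family id vectors),
#'   `species_expanded` (list taxon -> family ids), `focal_specific_families`
#'   and `focal_specific` (gene ids; `NULL` when `groups` is absent).
#' @export
classify_gene_sets <- function(fcm, grouping, diversified = NULL,
                               expanded = NULL, groups = NULL) {
  stopifnot(inherits(fcm, "family_count_matrix"),
            inherits(grouping, "taxon_grouping"))
  all_g <- c(grouping$focal_clade, grouping$comparison_clade,
             grouping$outgroups)
  absent <- setdiff(all_g, colnames(fcm$counts))
  if (length(absent)) {
    stop("Grouping taxa absent from matrix: ", paste(absent, collapse = ", "))
  }
  fams <- rownames(fcm$counts)
  core <- fams[rowSums(presence(fcm, grouping$focal_clade)) ==
                 length(grouping$focal_clade)]
  others <- setdiff(colnames(fcm$counts), grouping$focal_clade)
  clade_specific <- if (length(others)) {
    core[rowSums(presence(fcm, others)[core, , drop = FALSE]) == 0L]
  } else core
  clade_div <- if (!is.null(diversified)) {
    unique(diversified$family_id[diversified$significant])
  } else character()
  sp_exp <- if (!is.null(expanded)) {
    expanded_families(expanded)
  } else stats::setNames(rep(list(character()), length(grouping$focal_clade)),
                         grouping$focal_clade)
  fs <- grouping$focal_species
  other_taxa <- setdiff(colnames(fcm$counts), fs)
  focal_only <- fams[fcm$counts[, fs] >= 1L &
                       rowSums(presence(fcm, other_taxa)) == 0L]
  focal_genes <- NULL
  if (!is.null(groups)) {
    focal_genes <- sort(unlist(groups$families[focal_only], use.names = FALSE))
  }
  part <- structure(list(core = core, clade_specific = clade_specific,
                         clade_diversified = clade_div,
                         species_expanded = sp_exp,
                         focal_specific_families = focal_only,
                         focal_specific = focal_genes),
                    class = "gene_set_partition")
  stopifnot(all(part$clade_specific %in% part$core))
  part
}

#' Fraction of a proteome belonging to core families
#'
#' @param fcm a `family_count_matrix`.
#' @param partition a `gene_set_partition`.
#' @param taxon taxon id.
#' @return fraction in \[0, 1\]: core-family gene count over the proteome
#'   total.
#' @export
core_gene_fraction <- function(fcm, partition, taxon) {
  if (!taxon %in% colnames(fcm$counts)) stop("Unknown taxon: ", taxon)
  sum(fcm$counts[partition$core, taxon]) / fcm$taxon_totals[[taxon]]
}

#' Venn region counts of family presence across up to four taxa
#'
#' Each family present in at least one of the chosen taxa is assigned to
#' exactly one presence region (presence = count >= 1); region counts sum to
#' that family total.
#'
#' @param fcm a `family_count_matrix`.
#' @param taxa ordered character vector of 2 to 4 taxa.
#' @return named integer vector; region names join taxa with `&`
#'   (e.g. `"A"`, `"A&B"`).
#' @export
venn_counts <- function(fcm, taxa) {
  if (length(taxa) > 4L) stop("venn_counts supports at most 4 taxa")
  if (length(taxa) < 2L) stop("venn_counts needs at least 2 taxa")
  if (!all(taxa %in% colnames(fcm$counts))) stop("Unknown taxa in venn_counts")
  pres <- presence(fcm, taxa)
  keep <- rowSums(pres) > 0L
  pres <- pres[keep, , drop = FALSE]
  region_names <- apply(expand_regions(taxa), 1, function(r)
    paste(taxa[r], collapse = "&"))
  pattern <- apply(pres, 1, function(r) paste(taxa[r], collapse = "&"))
  out <- stats::setNames(integer(length(region_names)), region_names)
  tb <- table(pattern)
  out[names(tb)] <- as.integer(tb)
  out
}

expand_regions <- function(taxa) {
  m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(taxa))))
  m <- m[rowSums(m) > 0L, , drop = FALSE]
  m[order(rowSums(m), apply(m, 1, function(r) min(which(r)))), , drop = FALSE]
}

#' Exponentially binned family-size histogram
#'
#' Bins family sizes into intervals open on the left: the first interval
#' holds size 1, the second sizes 2-3, the third sizes 4-7, and so on
#' (interval i covers sizes `2^(i-1)` to `2^i - 1`). Trailing empty
#' intervals are trimmed.
#'
#' @param sizes positive integer family sizes.
#' @return data.frame with columns `interval` (label like `"(1,3]"`),
#'   `lower`, `upper` (the open/closed endpoints) and `count`.
#' @export
exponential_bins <- function(sizes) {
  if (length(sizes) == 0L) {
    return(data.frame(interval = character(), lower = numeric(),
                      upper = numeric(), count = integer()))
  }
  if (any(sizes < 1)) stop("Family sizes must be >= 1")
  idx <- floor(log2(sizes)) + 1L
  nb <- max(idx)
  count <- tabulate(idx, nbins = nb)
  upper <- 2^seq_len(nb) - 1
  lower <- c(0, utils::head(upper, -1))
  data.frame(interval = sprintf("(%d,%d]", as.integer(lower),
                                as.integer(upper)),
             lower = lower, upper = upper, count = count)
}

#' Dendrogram of taxa based on shared gene content
#'
#' Pairwise distance `d(A,B) = 1 - |families present in both| /
#' min(|families in A|, |families in B|)` (or `mean` of the two set sizes
#' via `denominator`), clustered by average linkage (UPGMA), giving a
#' rooted ultrametric dendrogram.
#'
#' @param fcm a `family_count_matrix`.
#' @param taxa taxa to include (default all; at least 3).
#' @param denominator `"min"` (default) or `"mean"`.
#' @return a rooted `ape::phylo` dendrogram.
#' @export
gene_content_dendrogram <- function(fcm, taxa = colnames(fcm$counts),
                                    denominator = c("min", "mean")) {
  denominator <- match.arg(denominator)
  if (length(taxa) < 3L) stop("Dendrogram needs at least 3 taxa")
  pres <- presence(fcm, taxa)
  sizes <- colSums(pres)
  if (any(sizes == 0L)) {
    stop("Taxon with zero families: ",
         paste(taxa[sizes == 0L], collapse = ", "))
  }
  shared <- crossprod(pres * 1L)
  denom <- outer(sizes, sizes, if (denominator == "min") pmin
                 else function(a, b) (a + b) / 2)
  D <- 1 - shared / denom
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ape::as.phylo(hc)
}
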