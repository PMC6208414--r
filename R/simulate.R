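#' Simulation configuration for synthetic proteomes
#'
#' Defines the conditions under which multi-taxon proteomes are generated:
#' a species tree with branch lengths (substitutions/site), gene-family
#' birth/death rates, planted lineage-specific expansions and planted GO
#' enrichment. The defaults describe an 8-taxon study design with a 4-taxon
#' focal clade, a 2-taxon comparison clade and 2 outgroups, mirroring the
#' focal/comparison/outgroup structure of multi-genome gene-content studies.
#'
#' @param species_tree newick string with branch lengths.
#' @param n_families number of ancestral gene families.
#' @param family_length_mean mean ancestral protein length in amino acids
#'   (lengths are geometric around this mean with a 30 aa minimum).
#' @param duplication_rate,loss_rate per-copy, per-unit-branch-length event
#'   rates; along a branch of length `t` each copy duplicates with
#'   probability `1 - exp(-duplication_rate * t)` and is lost with
#'   probability `1 - exp(-loss_rate * t)`.
#' @param planted_expansions list of `list(family = <int>, taxa = <chr>,
#'   fold = <int >= 2>)`; on the stem branch of the named taxon (or the
#'   clade's most recent common ancestor) the family's copy number is
#'   multiplied by `fold`.
#' @param substitution_prob_per_unit per-site substitution probability per
#'   unit branch length, in (0, 1).
#' @param go_terms number of background GO terms.
#' @param base_go_frequency probability that a background term annotates any
#'   given gene.
#' @param planted_go list of `list(term = <chr>, families = <int>,
#'   frequency_in = <num>, frequency_out = <num>)`.
#' @param root_copies ancestral copy number per family at the root (scalar
#'   or vector of length `n_families`); default 1.
#' @param seed integer seed; all generator randomness derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(species_tree = default_species_tree(),
                       n_families = 200,
                       family_length_mean = 150,
                       duplication_rate = 0.3,
                       loss_rate = 0.2,
                       planted_expansions = list(),
                       substitution_prob_per_unit = 0.15,
                       go_terms = 50,
                       base_go_frequency = 0.05,
                       planted_go = list(),
                       root_copies = 1,
                       seed = 1) {
  stopifnot(n_families >= 1, family_length_mean >= 30,
            duplication_rate >= 0, loss_rate >= 0,
            substitution_prob_per_unit > 0, substitution_prob_per_unit < 1,
            go_terms >= 0, base_go_frequency >= 0, base_go_frequency <= 1,
            all(root_copies >= 1))
  tree <- ape::read.tree(text = species_tree)
  if (is.null(tree)) stop("Could not parse species tree newick")
  if (is.null(tree$edge.length)) stop("Species tree must have branch lengths")
  for (pe in planted_expansions) {
    if (is.null(pe$fold) || pe$fold < 2) stop("Planted expansion fold must be >= 2")
    if (is.null(pe$family) || pe$family < 1 || pe$family > n_families) {
      stop("Planted expansion names an unknown family")
    }
    unknown <- setdiff(pe$taxa, tree$tip.label)
    if (length(unknown)) {
      stop("Planted expansion names unknown taxa: ",
           paste(unknown, collapse = ", "))
    }
  }
  for (pg in planted_go) {
    fr <- c(pg$frequency_in, pg$frequency_out)
    if (any(fr < 0 | fr > 1)) stop("Planted GO frequencies must be in [0,1]")
    if (is.null(pg$term)) stop("Planted GO entry needs a term id")
  }
  if (!length(root_copies) %in% c(1L, n_families)) {
    stop("root_copies must be scalar or length n_families")
  }
  structure(list(species_tree = species_tree, n_families = as.integer(n_families),
                 family_length_mean = family_length_mean,
                 duplication_rate = duplication_rate, loss_rate = loss_rate,
                 planted_expansions = planted_expansions,
                 substitution_prob_per_unit = substitution_prob_per_unit,
                 go_terms = as.integer(go_terms),
                 base_go_frequency = base_go_frequency,
                 planted_go = planted_go,
                 root_copies = as.integer(rep(root_copies,
                                              length.out = n_families)),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default 8-taxon species tree
#'
#' Four focal taxa (F1-F4), two comparison taxa (C1, C2) and two outgroups
#' (O1, O2); branch lengths in substitutions per site.
#' @return newick string.
#' @export
default_species_tree <- function() {
  paste0("((((F1:0.08,F2:0.08):0.06,(F3:0.08,F4:0.08):0.06):0.10,",
         "(C1:0.12,C2:0.12):0.12):0.08,(O1:0.25,O2:0.25):0.07);")
}

#' Default taxon grouping matching [default_species_tree()]
#' @return a `taxon_grouping` object.
#' @export
default_grouping <- function() {
  taxon_grouping(focal_clade = c("F1", "F2", "F3", "F4"),
                 comparison_clade = c("C1", "C2"),
                 outgroups = c("O1", "O2"),
                 focal_species = "F1")
}

# edges of a phylo in parent-before-child (preorder) order
preorder_edges <- function(tree) {
  ord <- rev(ape::postorder(tree))
  cbind(tree$edge[ord, , drop = FALSE], tree$edge.length[ord])
}

# child node index of the stem branch of a taxon set (tip or MRCA)
stem_node <- function(tree, taxa) {
  taxa <- as.character(taxa)
  if (length(taxa) == 1L) {
    return(match(taxa, tree$tip.label))
  }
  ape::getMRCA(tree, taxa)
}

#' Simulate gene-family copy numbers along a species tree
#'
#' Every family starts with `root_copies` copies at the root. Along each
#' branch of length `t` each copy is lost with probability
#' `1 - exp(-loss_rate * t)` and, if it survives, duplicates (at most once
#' per branch) with probability `1 - exp(-duplication_rate * t)`. Planted
#' expansions multiply the family's copy number by `fold` on the stem branch
#' of the named taxon or clade; the extra copies are independent lineages
#' from that point on, so they diverge once sequences are simulated.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_counts`: the per-family, per-taxon copy
#'   number matrix plus the internal copy genealogy consumed by
#'   [simulate_sequences()].
#' @export
simulate_family_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- ape::read.tree(text = config$species_tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nf <- config$n_families

  planted_at <- integer(0)
  planted <- config$planted_expansions
  if (length(planted)) {
    planted_at <- vapply(planted, function(pe) stem_node(tree, pe$taxa), 0L)
  }

  # copy genealogy, appended branch by branch
  cp_parent <- integer(0); cp_node <- integer(0); cp_family <- integer(0)
  n_root <- sum(config$root_copies)
  cp_parent <- rep(0L, n_root)
  cp_node <- rep(root, n_root)
  cp_family <- rep(seq_len(nf), times = config$root_copies)

  at_node <- vector("list", max(tree$edge))  # copy ids currently at each node
  at_node[[root]] <- seq_len(n_root)

  edges <- preorder_edges(tree)
  for (e in seq_len(nrow(edges))) {
    pnode <- edges[e, 1]; cnode <- edges[e, 2]; t <- edges[e, 3]
    ids <- at_node[[pnode]]
    if (!length(ids)) { at_node[[cnode]] <- integer(0); next }
    fam <- cp_family[ids]
    surv <- stats::runif(length(ids)) < exp(-config$loss_rate * t)
    dup <- stats::runif(length(ids)) < (1 - exp(-config$duplication_rate * t))
    par <- c(ids[surv], ids[surv & dup])
    if (length(planted_at)) {
      hit <- which(planted_at == cnode)
      for (h in hit) {
        k <- planted[[h]]$fold
        f <- planted[[h]]$family
        sel <- cp_family[par] == f
        if (any(sel)) {
          par <- c(par[!sel], rep(par[sel], each = k))
        }
      }
    }
    if (length(par)) {
      new_ids <- length(cp_parent) + seq_along(par)
      cp_parent <- c(cp_parent, par)
      cp_node <- c(cp_node, rep(cnode, length(par)))
      cp_family <- c(cp_family, cp_family[par])
      at_node[[cnode]] <- new_ids
    } else {
      at_node[[cnode]] <- integer(0)
    }
  }

  counts <- matrix(0L, nrow = nf, ncol = ntip,
                   dimnames = list(family_ids(nf), tree$tip.label))
  for (tip in seq_len(ntip)) {
    ids <- at_node[[tip]]
    if (length(ids)) {
      tb <- tabulate(cp_family[ids], nbins = nf)
      counts[, tip] <- tb
    }
  }
  structure(list(counts = counts,
                 copies = data.frame(id = seq_along(cp_parent),
                                     parent = cp_parent, node = cp_node,
                                     family = cp_family),
                 at_node = at_node, tree = tree, config = config),
            class = "sim_counts")
}

family_ids <- function(n) sprintf("fam%04d", seq_len(n))

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate protein sequences for a gene-family genealogy
#'
#' Each family receives an i.i.d.-uniform ancestral sequence whose length is
#' geometric around `family_length_mean` (minimum 30 aa). Along each branch
#' of length `t`, every copy's sequence undergoes i.i.d. per-site
#' substitution with probability `substitution_prob_per_unit * t` (capped at
#' 1) to a uniformly chosen different residue. Gene ids are
#' `<taxon>_g<serial>` and never encode the family.
#'
#' @param sim a `sim_counts` object from [simulate_family_counts()].
#' @param config the generating [sim_config()] (defaults to the one stored
#'   in `sim`).
#' @return list with `proteins` (data.frame `gene_id`, `taxon_id`,
#'   `sequence`) and `truth` (class `synthetic_truth`: `gene_to_family`
#'   named vector, `family_counts` [family_count_matrix()], planted lists,
#'   seed).
#' @export
simulate_sequences <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "sim_counts"))
  set.seed(config$seed + 1L)
  tree <- sim$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nf <- config$n_families

  len_p <- 1 / (config$family_length_mean - 30 + 1)
  root_len <- 30L + stats::rgeom(nf, len_p)
  root_seq <- lapply(root_len, function(L) sample.int(20L, L, replace = TRUE))

  # branch length leading into each node
  in_len <- numeric(max(tree$edge))
  in_len[tree$edge[, 2]] <- tree$edge.length

  s <- config$substitution_prob_per_unit
  cp <- sim$copies
  seqs <- vector("list", nrow(cp))
  for (i in seq_len(nrow(cp))) {
    if (cp$node[i] == root) {
      seqs[[i]] <- root_seq[[cp$family[i]]]
    } else {
      parent_seq <- seqs[[cp$parent[i]]]
      p_site <- min(1, s * in_len[cp$node[i]])
      mut <- which(stats::runif(length(parent_seq)) < p_site)
      sq <- parent_seq
      if (length(mut)) {
        shift <- sample.int(19L, length(mut), replace = TRUE)
        sq[mut] <- ((sq[mut] - 1L + shift) %% 20L) + 1L
      }
      seqs[[i]] <- sq
    }
  }

  gene_id <- character(0); taxon_id <- character(0)
  sequence <- character(0); fam_of_gene <- character(0)
  fids <- family_ids(nf)
  for (tip in seq_len(ntip)) {
    ids <- sim$at_node[[tip]]
    if (!length(ids)) next
    taxon <- tree$tip.label[tip]
    gid <- sprintf("%s_g%04d", taxon, seq_along(ids))
    gene_id <- c(gene_id, gid)
    taxon_id <- c(taxon_id, rep(taxon, length(ids)))
    sequence <- c(sequence,
                  vapply(ids, function(i) paste(AA20[seqs[[i]]], collapse = ""),
                         ""))
    fam_of_gene <- c(fam_of_gene, fids[cp$family[ids]])
  }
  proteins <- data.frame(gene_id = gene_id, taxon_id = taxon_id,
                         sequence = sequence, stringsAsFactors = FALSE)
  gene_to_family <- stats::setNames(fam_of_gene, gene_id)
  fcm <- family_count_matrix_from_counts(sim$counts,
                                         table(factor(taxon_id,
                                                      levels = tree$tip.label)))
  truth <- structure(list(gene_to_family = gene_to_family,
                          family_counts = fcm,
                          planted_expansions = config$planted_expansions,
                          planted_go = config$planted_go,
                          seed = config$seed),
                     class = "synthetic_truth")
  list(proteins = proteins, truth = truth)
}

#' Assign GO annotations with planted enrichment
#'
#' Background terms annotate every gene independently with
#' `base_go_frequency`; each planted `(term, family set)` pair annotates
#' genes of the target families with `frequency_in` and all other genes with
#' `frequency_out` (replacing the base frequency for that term).
#'
#' @param truth `synthetic_truth` from [simulate_sequences()].
#' @param config the generating [sim_config()].
#' @return a [go_annotations()] object covering every gene.
#' @export
assign_go_annotations <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(config$seed + 2L)
  genes <- names(truth$gene_to_family)
  ng <- length(genes)
  g2t <- stats::setNames(rep(list(character()), ng), genes)
  planted_terms <- vapply(config$planted_go, function(pg) pg$term, "")
  if (config$go_terms > 0) {
    bg <- sprintf("GO:%07d", seq_len(config$go_terms))
    bg <- setdiff(bg, planted_terms)
    for (tm in bg) {
      hit <- stats::runif(ng) < config$base_go_frequency
      for (i in which(hit)) g2t[[i]] <- c(g2t[[i]], tm)
    }
  }
  fids <- family_ids(config$n_families)
  for (pg in config$planted_go) {
    target <- fids[pg$families]
    inside <- truth$gene_to_family %in% target
    p <- ifelse(inside, pg$frequency_in, pg$frequency_out)
    hit <- stats::runif(ng) < p
    for (i in which(hit)) g2t[[i]] <- c(g2t[[i]], pg$term)
  }
  go_annotations(g2t)
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_family_counts()], [simulate_sequences()] and
#' [assign_go_annotations()] under one configuration, optionally writing the
#' per-taxon FASTA files, truth tables, id2go TSV and a JSON echo of the
#' resolved configuration.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory.
#' @return list with `proteins`, `truth`, `annotations`, `counts` (the
#'   `sim_counts` object) and `config`.
#' @export
simulate_proteomes <- function(config = sim_config(), outdir = NULL) {
  sim <- simulate_family_counts(config)
  sq <- simulate_sequences(sim, config)
  ann <- assign_go_annotations(sq$truth, config)
  out <- list(proteins = sq$proteins, truth = sq$truth, annotations = ann,
              counts = sim, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (taxon in unique(sq$proteins$taxon_id)) {
      write_fasta(sq$proteins[sq$proteins$taxon_id == taxon, ],
                  file.path(outdir, paste0(taxon, ".faa")))
    }
    g2f <- data.frame(gene_id = names(sq$truth$gene_to_family),
                      family_id = unname(sq$truth$gene_to_family))
    utils::write.table(g2f, file.path(outdir, "gene_to_family.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(sim$counts),
                       file.path(outdir, "family_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE)
    write_id2go(ann, file.path(outdir, "id2go.tsv"))
    cfg <- config
    class(cfg) <- NULL
    jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
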