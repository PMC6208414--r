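#' Default pipeline configuration
#'
#' Every stage constant quoted from the underlying comparative protocol
#' surfaces here with its standard value as default: similarity E-value
#' cutoff 1e-5, expansion FDR threshold q < 0.01, FFP feature length 8 and
#' 100 bootstrap pseudoreplicates. By default the pipeline starts from the
#' synthetic generator (see [sim_config()]); set `proteomes` to named FASTA
#' paths to analyse real data instead.
#'
#' @param seed root seed; each stage draws from a named substream derived
#'   from it.
#' @param outdir output directory.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1, outdir = "orthofam_out") {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = list(n_families = 150, seed = as.integer(seed)),
    proteomes = NULL,                   # named FASTA paths (alternative)
    grouping = list(focal_clade = c("F1", "F2", "F3", "F4"),
                    comparison_clade = c("C1", "C2"),
                    outgroups = c("O1", "O2"), focal_species = "F1"),
    similarity = list(source = "internal", k = 4, min_score = 0.2,
                      hits_path = NULL, evalue_cutoff = 1e-5),
    mcl = list(inflation = 2.0, max_iter = 100, prune_below = 1e-5,
               tol = 1e-8),
    expansion = list(q_threshold = 0.01, clade_method = "binomial",
                     pairwise_rule = "all"),
    ffp = list(l = 8, B = 100),
    enrichment = list(id2go = NULL, obo = NULL),
    dendrogram = list(denominator = "min")
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(seed = user$seed %||% 1,
                                 outdir = user$outdir %||% "orthofam_out")
  modify_list_deep(cfg, user)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

modify_list_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Run the full comparative gene-family pipeline
#'
#' Executes simulate (optional) -> similarity graph -> MCL ortholog groups
#' -> family count matrix -> expansion tests -> gene-set partition ->
#' Venn / size bins / gene-content dendrogram -> FFP bootstrap phylogeny ->
#' GO enrichment, writing every stage's TSV/newick output plus a
#' machine-readable JSON report. Deterministic given the configured seed
#' (stage timings go to a log file, never into the report). On a stage
#' failure, partial outputs are retained and the `MANIFEST` marks the run
#' incomplete with the failing stage.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   YAML path.
#' @return the report, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(outdir, "MANIFEST")
  logfile <- file.path(outdir, "orthofam.log")
  cat("", file = manifest)
  cat("", file = logfile)
  done <- character()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      cat(sprintf("status: FAILED at stage %s: %s\n", name,
                  conditionMessage(e)),
          sprintf("completed: %s\n", paste(done, collapse = ", ")),
          file = manifest, sep = "")
      stop("Pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    cat(sprintf("stage %-12s %8.2fs\n", name,
                proc.time()[["elapsed"]] - t0),
        file = logfile, append = TRUE)
    done <<- c(done, name)
    res
  }
  cfg_echo <- config
  jsonlite::write_json(cfg_echo, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  truth <- NULL
  annotations <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      sc <- do.call(sim_config, config$simulate)
      simulate_proteomes(sc, outdir = file.path(outdir, "simulate"))
    })
    proteins <- sim$proteins
    truth <- sim$truth
    annotations <- sim$annotations
  } else {
    proteins <- stage("read", {
      do.call(rbind, lapply(names(config$proteomes), function(tx)
        read_fasta(config$proteomes[[tx]], taxon_id = tx)[,
          c("gene_id", "taxon_id", "sequence")]))
    })
  }
  if (!is.null(config$enrichment$id2go)) {
    parents <- if (!is.null(config$enrichment$obo)) {
      read_obo_lite(config$enrichment$obo)
    } else NULL
    annotations <- read_id2go(config$enrichment$id2go, parents)
  }

  grouping <- do.call(taxon_grouping, config$grouping)
  gene_taxon <- stats::setNames(proteins$taxon_id, proteins$gene_id)

  graph <- stage("graph", {
    if (identical(config$similarity$source, "hits")) {
      hits <- read_blast_tab(config$similarity$hits_path)
      build_graph_from_hits(hits, config$similarity$evalue_cutoff,
                            nodes = data.frame(gene_id = proteins$gene_id,
                                               taxon_id = proteins$taxon_id))
    } else {
      build_graph_internal(proteins, k = config$similarity$k,
                           min_score = config$similarity$min_score)
    }
  })
  write_abc(graph, file.path(outdir, "graph.abc.tsv"))

  groups <- stage("cluster", {
    do.call(mcl, c(list(graph = graph), config$mcl))
  })
  write_families(groups, gene_taxon, file.path(outdir, "families.tsv"))

  fcm <- stage("matrix", build_count_matrix(groups, gene_taxon))
  utils::write.table(as.data.frame(fcm$counts),
                     file.path(outdir, "family_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE)

  diversified <- stage("expand_clade", {
    test_clade_diversified(fcm, grouping,
                           q_threshold = config$expansion$q_threshold,
                           method = config$expansion$clade_method)
  })
  write_expansion_results(diversified,
                          file.path(outdir, "clade_diversified.tsv"))
  pairwise <- stage("expand_pairs", {
    test_species_expansion(fcm, grouping,
                           q_threshold = config$expansion$q_threshold,
                           rule = config$expansion$pairwise_rule)
  })
  write_expansion_results(pairwise,
                          file.path(outdir, "species_expansion.tsv"))

  partition <- stage("classify", {
    classify_gene_sets(fcm, grouping, diversified, pairwise, groups)
  })
  write_partition(partition, file.path(outdir, "gene_sets.tsv"))

  venn_taxa <- utils::head(grouping$focal_clade, 4)
  venn <- stage("venn", venn_counts(fcm, venn_taxa))
  utils::write.table(data.frame(region = names(venn), families = venn),
                     file.path(outdir, "venn.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bins <- stage("bins", {
    out <- list()
    for (tx in grouping$focal_clade) {
      sz <- fcm$counts[fcm$counts[, tx] >= 1L, tx]
      out[[tx]] <- exponential_bins(sz)
      utils::write.table(out[[tx]],
                         file.path(outdir, sprintf("bins_%s.tsv", tx)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
  })
  dendro_taxa <- if (length(grouping$focal_clade) >= 3) {
    grouping$focal_clade
  } else colnames(fcm$counts)
  dendro <- stage("dendrogram", {
    gene_content_dendrogram(fcm, dendro_taxa,
                            denominator = config$dendrogram$denominator)
  })
  write_newick(dendro, file.path(outdir, "gene_content_dendrogram.nwk"))

  tree <- stage("phylo", {
    profiles <- lapply(split(proteins, proteins$taxon_id), ffp_profile,
                       l = config$ffp$l)
    D <- jsd_matrix(profiles)
    write_distance_matrix(D, file.path(outdir, "ffp_distances.tsv"))
    bootstrap_tree(profiles, B = config$ffp$B,
                   seed = config$seed + 1000L)
  })
  write_newick(tree, file.path(outdir, "ffp_tree.nwk"))

  enrichment <- stage("enrich", {
    out <- list()
    if (!is.null(annotations)) {
      ann <- propagate_annotations(annotations)
      universe <- proteins$gene_id[proteins$taxon_id ==
                                     grouping$focal_species]
      g2f <- gene_families(groups)
      sets <- list(
        core = universe[g2f[universe] %in% partition$core],
        clade_specific = universe[g2f[universe] %in% partition$clade_specific],
        clade_diversified = universe[g2f[universe] %in%
                                       partition$clade_diversified],
        focal_specific = intersect(universe, partition$focal_specific))
      for (nm in names(sets)) {
        if (length(sets[[nm]])) {
          out[[nm]] <- enrich(sets[[nm]], universe, ann)
          write_enrichment(out[[nm]],
                           file.path(outdir, sprintf("enrichment_%s.tsv", nm)))
        }
      }
    }
    out
  })

  report <- list(
    seed = config$seed,
    n_genes = nrow(proteins),
    n_taxa = length(unique(proteins$taxon_id)),
    n_edges = nrow(graph$edges),
    n_families = length(groups$families),
    largest_family = max(lengths(groups$families)),
    set_sizes = list(core = length(partition$core),
                     clade_specific = length(partition$clade_specific),
                     clade_diversified = length(partition$clade_diversified),
                     focal_specific_families =
                       length(partition$focal_specific_families),
                     focal_specific_genes =
                       length(partition$focal_specific %||% character())),
    core_gene_fraction = core_gene_fraction(fcm, partition,
                                            grouping$focal_species),
    expanded_per_taxon = lapply(expanded_families(pairwise), length),
    venn = as.list(venn),
    ffp_tree = write_newick(tree),
    gene_content_dendrogram = write_newick(dendro),
    clustering_ari = if (!is.null(truth)) cluster_quality(groups, truth)
    else NULL,
    enrichment_top = lapply(enrichment, function(e)
      as.list(e[1, c("term", "observed", "expected", "p_value")]))
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cat("status: COMPLETE\n",
      sprintf("completed: %s\n", paste(done, collapse = ", ")),
      file = manifest, sep = "")
  invisible(report)
}

#' Write a gene-set partition as a two-column TSV
#'
#' @param partition a `gene_set_partition`.
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  set_df <- function(nm, ids) {
    if (!length(ids)) return(NULL)
    data.frame(set_name = nm, id = ids, stringsAsFactors = FALSE)
  }
  pieces <- c(list(set_df("core", partition$core),
                   set_df("clade_specific", partition$clade_specific),
                   set_df("clade_diversified", partition$clade_diversified)),
              lapply(names(partition$species_expanded), function(tx)
                set_df(paste0("expanded_", tx),
                       partition$species_expanded[[tx]])),
              list(set_df("focal_specific_family",
                          partition$focal_specific_families),
                   set_df("focal_specific_gene", partition$focal_specific)))
  pieces <- Filter(Negate(is.null), pieces)
  rows <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(set_name = character(), id = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
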