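# Shared fixtures built in code at test time.

# hand-built 6-taxon, 8-family count matrix with a fully hand-derived
# gene-set partition (see test-family.R / acceptance)
toy_matrix <- function() {
  taxa <- c("F1", "F2", "F3", "F4", "C1", "O1")
  counts <- rbind(
    famA = c(2, 1, 1, 1, 1, 1),  # everywhere -> core only
    famB = c(1, 1, 1, 1, 0, 0),  # focal only -> core + clade-specific
    famC = c(1, 1, 2, 1, 0, 1),  # focal + outgroup -> core only
    famD = c(1, 1, 1, 0, 0, 0),  # missing one focal -> not core
    famE = c(3, 0, 0, 0, 0, 0),  # focal species only -> focal-specific
    famF = c(0, 0, 0, 0, 1, 1),  # outside focal clade entirely
    famG = c(1, 2, 1, 1, 1, 0),  # focal + comparison -> core only
    famH = c(0, 2, 0, 0, 0, 0))  # one non-focal-species taxon
  colnames(counts) <- taxa
  family_count_matrix_from_counts(counts)
}

toy_grouping <- function() {
  taxon_grouping(focal_clade = c("F1", "F2", "F3", "F4"),
                 comparison_clade = "C1", outgroups = "O1",
                 focal_species = "F1")
}

# tiny ortholog group set consistent with toy_matrix(); gene ids encode
# taxon and serial only
toy_groups <- function() {
  fcm <- toy_matrix()
  fams <- list()
  serial <- stats::setNames(rep(0L, ncol(fcm$counts)),
                            colnames(fcm$counts))
  for (f in rownames(fcm$counts)) {
    members <- character()
    for (tx in colnames(fcm$counts)) {
      k <- fcm$counts[f, tx]
      if (k > 0) {
        members <- c(members, sprintf("%s_g%02d", tx, serial[[tx]] + seq_len(k)))
        serial[[tx]] <- serial[[tx]] + k
      }
    }
    fams[[f]] <- members
  }
  structure(list(families = fams, provenance = list()),
            class = "ortholog_groups")
}

toy_gene_taxon <- function() {
  g <- unlist(toy_groups()$families, use.names = FALSE)
  stats::setNames(sub("_g\\d+$", "", g), g)
}

# 4-taxon simulation used by the FFP tests: two well-separated cherries
ffp_sim_config <- function(seed = 3, n_families = 60) {
  sim_config(species_tree = "((A:0.15,B:0.15):0.1,(C:0.15,D:0.15):0.1);",
             n_families = n_families, seed = seed)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
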