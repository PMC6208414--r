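#' Read a protein FASTA file
#'
#' Reads one proteome from a FASTA file. The header token before the first
#' whitespace becomes the gene identifier; the remainder is kept as a
#' description but is never used downstream. Sequences are upper-cased and
#' any residue outside the 20 standard amino-acid letters is mapped to `X`
#' (so ambiguity codes B, Z, J, U, O and stop/gap characters all become `X`;
#' k-mer based stages later skip X-containing windows).
#'
#' @param path Path to a FASTA file.
#' @param taxon_id Taxon label attached to every record (default `NA`).
#' @return A data.frame with columns `gene_id`, `taxon_id`, `sequence`,
#'   `description`, one row per FASTA entry in file order.
#' @export
read_fasta <- function(path, taxon_id = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(gene_id = character(), taxon_id = character(),
                      sequence = character(), description = character(),
                      stringsAsFactors = FALSE))
  }
  ss <- Biostrings::readAAStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) {
    stop("Malformed FASTA header (empty id) at entry ",
         which(ids == "")[1], " of ", path)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("Duplicate gene ids in ", path, ": ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0L)) {
    stop("Empty sequence for entry '", ids[which(nchar(seqs) == 0L)[1]],
         "' in ", path)
  }
  seqs <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "X", seqs)
  data.frame(gene_id = ids, taxon_id = taxon_id, sequence = seqs,
             description = desc, stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param proteins data.frame with columns `gene_id` and `sequence`.
#' @param path Output path (UTF-8, LF line endings).
#' @export
write_fasta <- function(proteins, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(">", proteins$gene_id, "\n", proteins$sequence),
             con, sep = "\n")
  invisible(path)
}

#' Read tabular alignment hits (12-column BLAST outfmt 6 dialect)
#'
#' Columns 1, 2, 3, 11, 12 are interpreted as query id, subject id, percent
#' identity, E-value and bitscore; any extra columns are ignored.
#'
#' @param path Path to a tab-separated hits file with at least 12 columns.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("Hits file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), evalue = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  }
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) {
    stop("Expected >= 12 tab-separated columns, found ", ncol(tab),
         " in ", path)
  }
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad)) {
      stop("Non-numeric ", what, " '", x[bad[1]], "' at row ", bad[1],
           " of ", path)
    }
    v
  }
  out <- data.frame(query_id = tab[[1]], subject_id = tab[[2]],
                    percent_identity = num(tab[[3]], "percent identity"),
                    evalue = num(tab[[11]], "evalue"),
                    bitscore = num(tab[[12]], "bitscore"),
                    stringsAsFactors = FALSE)
  if (any(out$evalue < 0) || any(out$bitscore < 0)) {
    stop("Negative evalue or bitscore in ", path)
  }
  out
}

#' Flag putative contaminant scaffolds from alignment hits
#'
#' A query (scaffold) is removed when it has at least one hit with
#' E-value strictly below `evalue_max` and bitscore strictly above
#' `bitscore_min`; such hits against contaminant databases mark sequences as
#' non-target in origin. Queries without any qualifying hit are kept.
#'
#' @param hits data.frame as returned by [read_blast_tab()].
#' @param evalue_max E-value threshold (default `1e-20`; strict `<`).
#' @param bitscore_min Bitscore threshold (default `1000`; strict `>`).
#' @param all_queries Optional character vector of every scaffold screened,
#'   so scaffolds with no hits at all are reported as kept. Defaults to the
#'   queries seen in `hits`.
#' @return list with character vectors `kept` and `removed`
#'   (disjoint; their union covers `all_queries`).
#' @export
filter_contaminant_scaffolds <- function(hits, evalue_max = 1e-20,
                                         bitscore_min = 1000,
                                         all_queries = NULL) {
  if (is.null(all_queries)) all_queries <- unique(hits$query_id)
  all_queries <- unique(as.character(all_queries))
  if (nrow(hits) == 0L) {
    return(list(kept = all_queries, removed = character()))
  }
  bad <- hits$evalue < evalue_max & hits$bitscore > bitscore_min
  removed <- sort(unique(hits$query_id[bad]))
  removed <- intersect(all_queries, removed)
  list(kept = setdiff(all_queries, removed), removed = removed)
}

#' Construct a gene-to-GO annotation map
#'
#' @param gene_to_terms named list, gene id -> character vector of GO ids.
#' @param term_parents optional named list, term -> character vector of
#'   parent terms (`is_a`); must be acyclic and never self-parenting.
#' @return object of class `go_annotations`.
#' @export
go_annotations <- function(gene_to_terms, term_parents = NULL) {
  stopifnot(is.list(gene_to_terms))
  gene_to_terms <- lapply(gene_to_terms, function(x) unique(as.character(x)))
  if (!is.null(term_parents)) {
    term_parents <- lapply(term_parents, as.character)
    for (tm in names(term_parents)) {
      if (tm %in% term_parents[[tm]]) stop("Term is its own parent: ", tm)
    }
    check_acyclic(term_parents)
  }
  structure(list(gene_to_terms = gene_to_terms, term_parents = term_parents),
            class = "go_annotations")
}

# topological check of a term -> parents list; stops on a cycle
check_acyclic <- function(parents) {
  state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  visit <- function(tm) {
    s <- get0(tm, envir = state, ifnotfound = 0L)
    if (s == 1L) stop("Cycle in GO parent graph at term: ", tm)
    if (s == 2L) return(invisible())
    assign(tm, 1L, envir = state)
    for (p in parents[[tm]]) if (!is.null(parents[[p]])) visit(p)
    assign(tm, 2L, envir = state)
  }
  for (tm in names(parents)) visit(tm)
  invisible(TRUE)
}

#' Read a two-column gene-to-GO TSV (id2go format)
#'
#' Each line is `gene_id<TAB>GO:A,GO:B,...`; a gene line with an empty second
#' field yields a gene with no terms.
#'
#' @param path Path to the TSV.
#' @param term_parents optional parent map to attach (see [go_annotations()]).
#' @return `go_annotations` object.
#' @export
read_id2go <- function(path, term_parents = NULL) {
  if (!file.exists(path)) stop("id2go file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  g2t <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 1L || !nzchar(parts[1])) {
      stop("Malformed id2go line ", i, " in ", path)
    }
    terms <- if (length(parts) >= 2L && nzchar(parts[2])) {
      trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    } else character()
    g2t[[parts[1]]] <- unique(terms[nzchar(terms)])
  }
  go_annotations(g2t, term_parents)
}

#' Write a gene-to-GO map as a two-column TSV
#'
#' @param annotations `go_annotations` object.
#' @param path Output path.
#' @export
write_id2go <- function(annotations, path) {
  g2t <- annotations$gene_to_terms
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(names(g2t), "\t",
                    vapply(g2t, paste, "", collapse = ",")), con, sep = "\n")
  invisible(path)
}

#' Read a minimal OBO ontology file
#'
#' Parses only `[Term]` stanzas and their `id:`, `is_a:` and `is_obsolete:`
#' lines; obsolete terms are dropped. Full OBO semantics (relationships,
#' intersections, subsets) are deliberately out of scope.
#'
#' @param path Path to the OBO file.
#' @return named list term -> character vector of parents (acyclic).
#' @export
read_obo_lite <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  parents <- list()
  cur <- NULL
  cur_parents <- character()
  obsolete <- FALSE
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) parents[[cur]] <<- unique(cur_parents)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- NULL; cur_parents <- character(); obsolete <- FALSE
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush()
      cur <- NULL; in_term <- FALSE
    } else if (in_term && grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^is_a:", ln)) {
      p <- trimws(sub("^is_a:", "", ln))
      p <- trimws(sub("!.*$", "", p))  # strip trailing name comment
      cur_parents <- c(cur_parents, p)
    } else if (in_term && grepl("^is_obsolete:\\s*true", ln)) {
      obsolete <- TRUE
    }
  }
  flush()
  for (tm in names(parents)) {
    if (tm %in% parents[[tm]]) stop("Term is its own parent: ", tm)
  }
  check_acyclic(parents)
  parents
}

#' Write a tree as a newick string or file
#'
#' @param tree an `ape::phylo` object (bootstrap supports, when present, are
#'   carried as internal node labels).
#' @param path optional output path; when `NULL` the newick string is
#'   returned instead.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n")
  invisible(path)
}

#' Read a newick tree
#'
#' @param path path to a newick file, or a literal newick string when
#'   `text = TRUE`.
#' @param text interpret `path` as the newick string itself.
#' @return an `ape::phylo` object.
#' @export
read_newick <- function(path, text = FALSE) {
  if (text) ape::read.tree(text = path) else ape::read.tree(path)
}
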