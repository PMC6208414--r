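#' One-sided Fisher's exact test (upper tail) for a 2x2 table
#'
#' For the table `[[a, b], [c, d]]` with row 1 = (family gene count, other
#' genes) in taxon 1 and row 2 the same in taxon 2, returns the one-sided
#' hypergeometric upper-tail probability `P(X >= a)` with all margins fixed
#' — the probability that taxon 1's proportion is at least as extreme as
#' observed ("taxon 1 proportion larger"). Vectorized over cells.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return p-value(s) in \[0, 1\].
#' @export
fisher_exact_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("Cell counts must be non-negative")
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

# binomial log-likelihood kernel with 0*log(0) = 0
binom_kernel <- function(counts, totals, p) {
  t1 <- ifelse(counts > 0, counts * log(p), 0)
  t2 <- ifelse(totals - counts > 0, (totals - counts) * log(1 - p), 0)
  sum(t1 + t2)
}

#' Grouped-binomial likelihood-ratio test for clade diversification
#'
#' Realizes a binomial GLM with a single two-level group factor as a
#' likelihood-ratio test on grouped binomial data — identical inference,
#' no fitting machinery. Null model: one shared proportion for all taxa;
#' alternative: separate pooled proportions for the focal and comparison
#' groups (each the pooled MLE count/total). The statistic
#' `2 * (loglik_alt - loglik_null)` is referred to a chi-squared
#' distribution with 1 degree of freedom; the sign of
#' `p_hat_focal - p_hat_comparison` gives the direction.
#'
#' @param counts per-taxon family gene counts.
#' @param totals per-taxon total gene counts (same length, all > 0).
#' @param groups character vector (`"focal"` / `"comparison"`) aligned with
#'   `counts`.
#' @return list with `statistic`, `p_value`, `direction` (+1 focal larger,
#'   -1 smaller, 0 degenerate).
#' @export
binomial_lrt <- function(counts, totals, groups) {
  stopifnot(length(counts) == length(totals),
            length(groups) == length(counts), all(totals > 0),
            all(counts >= 0), all(counts <= totals))
  groups <- as.character(groups)
  if (!all(groups %in% c("focal", "comparison")) ||
      !all(c("focal", "comparison") %in% groups)) {
    stop("groups must contain both 'focal' and 'comparison'")
  }
  if (all(counts == 0)) {
    return(list(statistic = 0, p_value = 1, direction = 0))
  }
  f <- groups == "focal"
  p_f <- sum(counts[f]) / sum(totals[f])
  p_c <- sum(counts[!f]) / sum(totals[!f])
  p_0 <- sum(counts) / sum(totals)
  ll_alt <- binom_kernel(counts[f], totals[f], p_f) +
    binom_kernel(counts[!f], totals[!f], p_c)
  ll_null <- binom_kernel(counts, totals, p_0)
  stat <- max(0, 2 * (ll_alt - ll_null))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       direction = sign(p_f - p_c))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order (ties share identical q).
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Test every family for diversification in the focal clade
#'
#' Per family, a [binomial_lrt()] (default) or pooled one-sided Fisher test
#' of the family's gene proportion in the focal clade against the
#' comparison clade, conditioning on total gene content; outgroups are
#' excluded from the contrast. Families with zero genes in both groups are
#' skipped. BH-FDR is applied across all tested families, and a family is
#' significant when `q < q_threshold` with a positive direction (focal
#' larger) — both definitions of diversification say "larger", so the test
#' is one-directional.
#'
#' @param fcm a `family_count_matrix`.
#' @param grouping a [taxon_grouping()] (its comparison clade must be
#'   non-empty).
#' @param q_threshold FDR threshold (default 0.01).
#' @param method `"binomial"` (grouped-binomial LRT, default) or `"fisher"`
#'   (one-sided Fisher on pooled group counts).
#' @return data.frame with columns `family_id`, `contrast`, `statistic`,
#'   `p_value`, `q_value`, `direction`, `significant`.
#' @export
test_clade_diversified <- function(fcm, grouping, q_threshold = 0.01,
                                   method = c("binomial", "fisher")) {
  method <- match.arg(method)
  stopifnot(inherits(fcm, "family_count_matrix"),
            inherits(grouping, "taxon_grouping"))
  if (length(grouping$comparison_clade) == 0L) {
    stop("Comparison clade is empty")
  }
  taxa <- c(grouping$focal_clade, grouping$comparison_clade)
  if (!all(taxa %in% colnames(fcm$counts))) {
    stop("Grouping taxa absent from matrix")
  }
  cm <- fcm$counts[, taxa, drop = FALSE]
  tested <- rownames(cm)[rowSums(cm) > 0L]
  groups <- ifelse(taxa %in% grouping$focal_clade, "focal", "comparison")
  totals <- fcm$taxon_totals[taxa]
  contrast <- paste0(paste(grouping$focal_clade, collapse = "+"), ">",
                     paste(grouping$comparison_clade, collapse = "+"))
  n <- length(tested)
  stat <- numeric(n); p <- numeric(n); dir <- numeric(n)
  f <- groups == "focal"
  for (i in seq_len(n)) {
    cts <- cm[tested[i], ]
    if (method == "binomial") {
      r <- binomial_lrt(cts, totals, groups)
      stat[i] <- r$statistic; p[i] <- r$p_value; dir[i] <- r$direction
    } else {
      a <- sum(cts[f]); cc <- sum(cts[!f])
      tf <- sum(totals[f]); tc <- sum(totals[!f])
      p[i] <- fisher_exact_one_sided(a, tf - a, cc, tc - cc)
      stat[i] <- a
      dir[i] <- sign(a / tf - cc / tc)
    }
  }
  q <- bh_fdr(p)
  data.frame(family_id = tested, contrast = contrast, statistic = stat,
             p_value = p, q_value = q, direction = dir,
             significant = q < q_threshold & dir > 0,
             stringsAsFactors = FALSE)
}

#' Pairwise species-expansion tests among the focal clade
#'
#' For every family shared by at least two focal taxa and every ordered
#' pair (X, Y) of focal taxa possessing it, a one-sided Fisher exact test
#' of `[[count_X, total_X - count_X], [count_Y, total_Y - count_Y]]`
#' ("X proportion larger"), accounting for differences in total gene
#' content through the proteome totals. BH-FDR is applied jointly across
#' all pairwise tests. Under the default `rule = "all"`, a family is
#' declared expanded in X when it is significant against every other focal
#' taxon that possesses it; `rule = "any"` requires a single significant
#' pair.
#'
#' @param fcm a `family_count_matrix`.
#' @param grouping a [taxon_grouping()] with >= 2 focal taxa.
#' @param q_threshold FDR threshold (default 0.01).
#' @param rule `"all"` (default) or `"any"`.
#' @return data.frame (one row per family x ordered pair) with columns
#'   `family_id`, `contrast`, `taxon`, `other`, `count_taxon`,
#'   `count_other`, `statistic`, `p_value`, `q_value`, `direction`,
#'   `significant`; attributes carry the rule, threshold and focal taxa for
#'   [expanded_families()].
#' @export
test_species_expansion <- function(fcm, grouping, q_threshold = 0.01,
                                   rule = c("all", "any")) {
  rule <- match.arg(rule)
  stopifnot(inherits(fcm, "family_count_matrix"))
  focal <- grouping$focal_clade
  if (length(focal) < 2L) stop("Need >= 2 focal taxa")
  if (!all(focal %in% colnames(fcm$counts))) {
    stop("Focal taxa absent from matrix")
  }
  cm <- fcm$counts[, focal, drop = FALSE]
  pres <- cm >= 1L
  shared <- rowSums(pres) >= 2L
  # one vectorized block per ordered focal pair; a family enters a pair's
  # block only when both taxa possess it
  rows <- list()
  for (x in focal) for (y in setdiff(focal, x)) {
    sel <- shared & pres[, x] & pres[, y]
    if (!any(sel)) next
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = rownames(cm)[sel], taxon = x, other = y,
      count_taxon = cm[sel, x], count_other = cm[sel, y],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    res <- data.frame(family_id = character(), contrast = character(),
                      taxon = character(), other = character(),
                      count_taxon = integer(), count_other = integer(),
                      statistic = numeric(), p_value = numeric(),
                      q_value = numeric(), direction = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, rows)
    tx <- fcm$taxon_totals[res$taxon]
    ty <- fcm$taxon_totals[res$other]
    res$statistic <- res$count_taxon
    res$p_value <- fisher_exact_one_sided(res$count_taxon,
                                          tx - res$count_taxon,
                                          res$count_other,
                                          ty - res$count_other)
    res$q_value <- bh_fdr(res$p_value)
    res$direction <- sign(res$count_taxon / tx - res$count_other / ty)
    res$significant <- res$q_value < q_threshold
    res$contrast <- paste0(res$taxon, ">", res$other)
    res <- res[order(res$family_id, res$taxon, res$other),
               c("family_id", "contrast", "taxon", "other", "count_taxon",
                 "count_other", "statistic", "p_value", "q_value",
                 "direction", "significant")]
    rownames(res) <- NULL
  }
  attr(res, "rule") <- rule
  attr(res, "q_threshold") <- q_threshold
  attr(res, "focal_clade") <- focal
  res
}

#' Families declared expanded per focal taxon
#'
#' Aggregates the pairwise test table from [test_species_expansion()] under
#' its declared rule (`"all"`: significant versus every other focal taxon
#' possessing the family; `"any"`: versus at least one).
#'
#' @param results output of [test_species_expansion()].
#' @return named list, taxon -> character vector of family ids.
#' @export
expanded_families <- function(results) {
  rule <- attr(results, "rule")
  focal <- attr(results, "focal_clade")
  if (is.null(rule) || is.null(focal)) {
    stop("results must come from test_species_expansion()")
  }
  out <- stats::setNames(rep(list(character()), length(focal)), focal)
  if (!nrow(results)) return(out)
  key <- paste(results$family_id, results$taxon, sep = "\r")
  agg <- if (rule == "all") {
    tapply(results$significant, key, all)
  } else {
    tapply(results$significant, key, any)
  }
  hits <- names(agg)[agg]
  if (length(hits)) {
    parts <- do.call(rbind, strsplit(hits, "\r", fixed = TRUE))
    for (tx in unique(parts[, 2])) {
      out[[tx]] <- sort(parts[parts[, 2] == tx, 1])
    }
  }
  out
}

#' Write expansion test results as TSV
#'
#' @param results data.frame from [test_clade_diversified()] or
#'   [test_species_expansion()].
#' @param path output path.
#' @export
write_expansion_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
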