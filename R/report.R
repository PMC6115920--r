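## Summary statistics in the layout of published genome-wide NLR surveys,
## and the homology-hit filter.

#' Published sunflower NLR census values
#'
#' The printed counts of the genome-wide NBS-LRR survey of the sunflower
#' (XRQ, assembly r1.2) proteome, used as inputs for summary arithmetic:
#' subgroup counts, group totals, proteome size, cluster statistics and
#' per-group exon means.
#'
#' @return Nested list of the printed counts.
#' @export
sunflower_census <- function() {
  subgroup_counts <- c(CNL = 90, CN = 5, CNNL = 4, CNN = 1,
                       RNL = 10, RN = 1, RCNL = 2,
                       TNL = 52, TN = 21, TNNL = 0, TTNL = 1, TNLTNL = 1,
                       CTNL = 1, CTN = 1,
                       N = 29, NL = 125, NN = 2, NNL = 6)
  list(
    proteome_size = 52243,
    subgroup_counts = subgroup_counts,
    group_counts = c(CNL = 100, TNL = 77, RNL = 13, NL = 162),
    total_nbs = 352,
    n_chromosomes = 17,
    n_clusters = 75,
    n_clustered_genes = 200,
    chr13_clusters = 25,
    chr13_clustered_genes = 73,
    exon_means = c(CNL = 2.7, TNL = 6.1, RNL = 6.2, NL = 2.9),
    clade_kaks = c(CNL = 0.68, TNL = 0.89, RNL = 0.31),
    nl_kinase2 = c(DDVW = 83, DDVD = 18)
  )
}

#' Half-up rounding
#'
#' Rounds halves away from zero (36.5 -> 37), the convention used for the
#' printed "~37%"-style percentages, unlike [round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## group of a subgroup code by the T > R > C dominance rule
subgroup_group <- function(code) {
  if (grepl("T", code)) "TNL"
  else if (grepl("R", code)) "RNL"
  else if (grepl("C", code)) "CNL"
  else "NL"
}

#' Assemble the survey summary report
#'
#' Counts are exact; `pct_of_proteome` and `cnl_tnl_ratio` are stored
#' unrounded (presentation rounds to 2 and 1 decimals). Percentages in the
#' printed-style rendering use half-up rounding; `print()` annotates the
#' convention.
#'
#' @param records Classified records from [classify_proteins()].
#' @param proteome_size Total number of proteins surveyed.
#' @param cluster_stats Optional result of [cluster_summary()].
#' @param exon_stats Optional result of [exon_statistics()].
#' @return Object of class `nlr_summary`.
#' @export
nlr_summary_report <- function(records, proteome_size,
                               cluster_stats = NULL, exon_stats = NULL) {
  if (proteome_size <= 0) stop("proteome_size must be positive")
  total <- nrow(records)
  groups <- c("CNL", "TNL", "RNL", "NL")
  group_counts <- vapply(groups, function(g) sum(records$group == g),
                         numeric(1))
  subgroup_counts <- vapply(SUBGROUP_CODES, function(s) {
    sum(records$subgroup == s)
  }, numeric(1))
  n_unclassified <- sum(records$subgroup == "unclassified_architecture")
  kin <- table(records$group,
               ifelse(is.na(records$kinase2), "absent", records$kinase2))
  structure(list(
    total_nbs = total,
    group_counts = group_counts,
    subgroup_counts = subgroup_counts,
    n_unclassified = n_unclassified,
    proteome_size = proteome_size,
    pct_of_proteome = 100 * total / proteome_size,
    cnl_tnl_ratio = if (group_counts[["TNL"]] > 0)
      group_counts[["CNL"]] / group_counts[["TNL"]] else NA_real_,
    kinase2_tally = kin,
    nl_subtype_counts = c(
      N_CC = sum(records$nl_subtype == "N_CC", na.rm = TRUE),
      N_TIR = sum(records$nl_subtype == "N_TIR", na.rm = TRUE),
      unassigned = sum(records$nl_subtype == "unassigned", na.rm = TRUE)),
    cluster_stats = cluster_stats,
    exon_stats = exon_stats
  ), class = "nlr_summary")
}

#' @export
print.nlr_summary <- function(x, ...) {
  cat("NLR survey summary\n")
  cat(sprintf("  %d NBS-encoding proteins of %d surveyed (%.2f%%)\n",
              x$total_nbs, x$proteome_size, x$pct_of_proteome))
  cat("  groups: ",
      paste(sprintf("%s=%d", names(x$group_counts), x$group_counts),
            collapse = ", "), "\n", sep = "")
  if (!is.na(x$cnl_tnl_ratio)) {
    cat(sprintf("  CNL:TNL ratio %.1f:1\n", x$cnl_tnl_ratio))
  }
  nz <- x$subgroup_counts[x$subgroup_counts > 0]
  cat("  subgroups: ",
      paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n", sep = "")
  if (x$n_unclassified > 0) {
    cat("  unclassified architectures:", x$n_unclassified, "\n")
  }
  cat("  NL subtypes: ",
      paste(sprintf("%s=%d", names(x$nl_subtype_counts),
                    x$nl_subtype_counts), collapse = ", "), "\n", sep = "")
  if (!is.null(x$cluster_stats)) {
    cs <- x$cluster_stats
    cat(sprintf(paste0("  clusters: %d (%d genes, %.1f genes/cluster, ",
                       "%.1f clusters/chromosome, %.0f%% clustered)\n"),
                cs$n_clusters, cs$n_clustered_genes, cs$genes_per_cluster,
                cs$clusters_per_chromosome, round(cs$pct_clustered)))
  }
  if (!is.null(x$exon_stats)) {
    es <- x$exon_stats
    cat("  exons/gene: ",
        paste(sprintf("%s %.1f (%d-%d)", es$group, es$mean, es$min, es$max),
              collapse = ", "), "\n", sep = "")
  }
  cat("  (percentages half-up rounded at presentation)\n")
  invisible(x)
}

#' Filter tabular homology hits
#'
#' Keeps rows with `evalue < max_evalue` AND `pct_identity > min_identity`
#' (both strict) and flags the best hit per query (highest identity, ties
#' by lowest E-value). Malformed rows (non-numeric identity or E-value)
#' are skipped with a message. The filter is idempotent.
#'
#' @param hits Data.frame with columns `query`, `subject`, `pct_identity`,
#'   `evalue`.
#' @param max_evalue E-value bound (strict).
#' @param min_identity Percent-identity bound (strict).
#' @return Filtered data.frame with an added logical `best` column.
#' @export
filter_homology_hits <- function(hits, max_evalue = 0.01,
                                 min_identity = 50.0) {
  need <- c("query", "subject", "pct_identity", "evalue")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("homology table missing column(s): ",
                         paste(miss, collapse = ", "))
  pid <- suppressWarnings(as.numeric(hits$pct_identity))
  ev <- suppressWarnings(as.numeric(hits$evalue))
  malformed <- is.na(pid) | is.na(ev)
  if (any(malformed)) {
    message(sum(malformed), " malformed homology row(s) skipped")
  }
  keep <- !malformed & ev < max_evalue & pid > min_identity
  out <- hits[keep, need, drop = FALSE]
  out$pct_identity <- pid[keep]
  out$evalue <- ev[keep]
  out <- out[order(out$query, -out$pct_identity, out$evalue), , drop = FALSE]
  out$best <- !duplicated(out$query)
  rownames(out) <- NULL
  out
}
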