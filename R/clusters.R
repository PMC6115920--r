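## Physical NBS gene-cluster calling on chromosomes and exon statistics.

#' Cluster-calling criteria
#'
#' Two adjacent NBS genes are linked when their intergenic gap is strictly
#' below `max_gap_bp` (default 200 kb) and at most `max_intervening`
#' (default 8) annotated non-NBS genes lie between them.
#'
#' @param max_gap_bp Maximum gap in bp (strict).
#' @param max_intervening Maximum intervening non-NBS gene count
#'   (inclusive).
#' @export
cluster_criteria <- function(max_gap_bp = 200000L, max_intervening = 8L) {
  stopifnot(max_gap_bp >= 0, max_intervening >= 0)
  list(max_gap_bp = as.integer(max_gap_bp),
       max_intervening = as.integer(max_intervening))
}

#' Call physical NBS gene clusters
#'
#' Per chromosome, consecutive NBS genes (in start order) are linked iff
#' the gap between them is `< max_gap_bp` AND the number of annotated
#' non-NBS genes strictly between them is `<= max_intervening`. Connected
#' runs of two or more linked NBS genes form clusters; singletons are not
#' clusters. The gap is `start(next NBS) - end(previous NBS)` (negatives
#' clamped to 0), or start-to-start with `anchor = "start"`.
#'
#' @param loci Gene loci data.frame (see [read_gff3()]) with `is_nbs` set
#'   for every row.
#' @param criteria From [cluster_criteria()].
#' @param anchor `"gap"` (intergenic, default) or `"start"`.
#' @return List with `clusters` (data.frame `cluster_id`, `chrom`, `start`,
#'   `end`, `n_members`, `members` comma-separated) and `membership`
#'   (named vector gene_id -> cluster_id).
#' @export
call_clusters <- function(loci, criteria = cluster_criteria(),
                          anchor = c("gap", "start")) {
  anchor <- match.arg(anchor)
  if (anyNA(loci$is_nbs)) stop("is_nbs must be set for every locus")
  if (anyDuplicated(loci$gene_id)) {
    stop("duplicate gene id(s): ",
         paste(unique(loci$gene_id[duplicated(loci$gene_id)]),
               collapse = ", "))
  }
  loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
  clusters <- list()
  membership <- character(0)
  cid <- 0L
  for (chrom in unique(loci$chrom)) {
    d <- loci[loci$chrom == chrom, , drop = FALSE]
    nbs <- which(d$is_nbs)
    if (length(nbs) < 2L) next
    linked <- logical(length(nbs) - 1L)
    for (k in seq_len(length(nbs) - 1L)) {
      i <- nbs[k]; j <- nbs[k + 1L]
      gap <- if (anchor == "gap") max(0L, d$start[j] - d$end[i])
             else max(0L, d$start[j] - d$start[i])
      interv <- sum(!d$is_nbs[seq_len(nrow(d)) > i & seq_len(nrow(d)) < j])
      linked[k] <- (gap < criteria$max_gap_bp) &&
        (interv <= criteria$max_intervening)
    }
    r <- rle(linked)
    pos <- 1L
    for (u in seq_along(r$lengths)) {
      if (r$values[u]) {
        members <- nbs[pos:(pos + r$lengths[u])]
        cid <- cid + 1L
        id <- sprintf("%s_cluster_%d", chrom, cid)
        clusters[[id]] <- data.frame(
          cluster_id = id, chrom = chrom,
          start = d$start[members[1L]], end = d$end[members[length(members)]],
          n_members = length(members),
          members = paste(d$gene_id[members], collapse = ","),
          stringsAsFactors = FALSE)
        membership <- c(membership,
                        stats::setNames(rep(id, length(members)),
                                        d$gene_id[members]))
      }
      pos <- pos + r$lengths[u]
    }
  }
  cl <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(cluster_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), n_members = integer(0),
               members = character(0), stringsAsFactors = FALSE)
  rownames(cl) <- NULL
  list(clusters = cl, membership = membership)
}

#' Summarize called clusters
#'
#' Ratios are left unrounded; round only at presentation (1 decimal).
#' Unplaced scaffolds are handled through the `n_chromosomes` denominator:
#' genes on scaffolds still cluster, but per-chromosome averages divide by
#' the chromosome count only.
#'
#' @param called Result of [call_clusters()].
#' @param loci Loci with `is_nbs` set (total NBS gene denominator).
#' @param n_chromosomes Number of chromosomes (default 17).
#' @return List `n_clusters`, `n_clustered_genes`, `genes_per_cluster`,
#'   `clusters_per_chromosome`, `pct_clustered`, `per_chrom` (data.frame),
#'   `degenerate` flag (TRUE when there are no clusters).
#' @export
cluster_summary <- function(called, loci, n_chromosomes = 17L) {
  cl <- called$clusters
  n_clusters <- nrow(cl)
  n_genes <- length(called$membership)
  total_nbs <- sum(loci$is_nbs, na.rm = TRUE)
  degenerate <- n_clusters == 0L
  per_chrom <- if (n_clusters) {
    agg <- stats::aggregate(cbind(n_clusters = 1, n_genes = cl$n_members),
                            by = list(chrom = cl$chrom), FUN = sum)
    agg
  } else {
    data.frame(chrom = character(0), n_clusters = numeric(0),
               n_genes = numeric(0))
  }
  list(
    n_clusters = n_clusters,
    n_clustered_genes = n_genes,
    genes_per_cluster = if (degenerate) 0 else n_genes / n_clusters,
    clusters_per_chromosome = n_clusters / n_chromosomes,
    pct_clustered = if (total_nbs == 0L) 0 else 100 * n_genes / total_nbs,
    per_chrom = per_chrom,
    degenerate = degenerate
  )
}

#' Per-group exon statistics
#'
#' @param loci Loci with `exon_count` populated.
#' @param records Classified records (see [classify_proteins()]); matched
#'   to loci by `protein_id == gene_id`.
#' @return Data.frame `group`, `n`, `min`, `max`, `mean` (mean unrounded);
#'   groups with no members are absent.
#' @export
exon_statistics <- function(loci, records) {
  m <- merge(records[, c("protein_id", "group")],
             loci[, c("gene_id", "exon_count")],
             by.x = "protein_id", by.y = "gene_id")
  if (nrow(m) == 0L) {
    return(data.frame(group = character(0), n = integer(0), min = integer(0),
                      max = integer(0), mean = numeric(0)))
  }
  out <- do.call(rbind, lapply(split(m$exon_count, m$group), function(v) {
    data.frame(n = length(v), min = min(v), max = max(v), mean = mean(v))
  }))
  out <- data.frame(group = rownames(out), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(match(out$group, c("CNL", "TNL", "RNL", "NL"))), , drop = FALSE]
}

#' Write clusters as a BED-like table
#'
#' Spans use BED convention: 0-based half-open (`start - 1`, `end`).
#'
#' @param called Result of [call_clusters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_bed <- function(called, path) {
  cl <- called$clusters
  utils::write.table(
    data.frame(chrom = cl$chrom, start = cl$start - 1L, end = cl$end,
               cluster_id = cl$cluster_id, n_members = cl$n_members,
               members = cl$members),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
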