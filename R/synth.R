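## Synthetic proteomes, genomes, codon alignments and expression matrices
## with planted ground truth, for end-to-end validation of the pipeline.

## linker alphabet excludes L (no accidental LxxLxxLxx), D (no accidental
## Kinase-2 DD dyad) and W
LINKER_ALPHABET <- setdiff(AA20, c("L", "D", "W"))

CC_BLOCK <- strrep("LEALEGK", 6L)   # ideal heptad repeat, 42 aa
LRR_UNIT <- "LAALAALAA"             # one LxxLxxLxx signature

## per-group LRR signature count ranges of the published survey
LRR_RANGES <- list(CNL = c(2L, 22L), RNL = c(1L, 8L),
                   TNL = c(2L, 26L), NL = c(2L, 30L))

## default subgroup census (the published sunflower column), total 352
DEFAULT_SUBGROUP_COUNTS <- c(CNL = 90L, CN = 5L, CNNL = 4L, CNN = 1L,
                             RNL = 10L, RN = 1L, RCNL = 2L,
                             TNL = 52L, TN = 21L, TNNL = 0L, TTNL = 1L,
                             TNLTNL = 1L, CTNL = 1L, CTN = 1L,
                             N = 29L, NL = 125L, NN = 2L, NNL = 6L)

DEFAULT_EXON_MEANS <- c(CNL = 2.7, TNL = 6.1, RNL = 6.2, NL = 2.9)

rand_res <- function(n, alphabet = LINKER_ALPHABET) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## sample() without the length-1 surprise
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

#' Blueprint for a synthetic NLR genome
#'
#' Fixes the gene census (subgroup counts, default: the published sunflower
#' census, total 352), the cluster plan (default: 75 clusters holding 200
#' genes, in sizes of 2 and 3, about one third on chromosome 13, none on
#' chromosomes 5 and 12), exon-count laws per group (shifted Poisson with
#' the published means) and the chromosome assignment of every gene. All
#' randomness is governed by `seed`.
#'
#' @param scale Single scale factor applied to gene and cluster counts.
#' @param seed Integer seed.
#' @param n_chromosomes Number of chromosomes (default 17).
#' @param subgroup_counts Named integer vector over the 18 subgroup codes.
#' @param n_clusters,n_clustered_genes Cluster plan (defaults 75 and 200,
#'   scaled); sizes of 2 and 3 are derived to match both.
#' @param exon_means Per-group exon-count means.
#' @param n_unplaced Genes placed on unanchored scaffolds (default 4).
#' @return List with the per-gene table (`genes`) and the parameters.
#' @export
genome_blueprint <- function(scale = 1, seed = 42L, n_chromosomes = 17L,
                             subgroup_counts = NULL,
                             n_clusters = NULL, n_clustered_genes = NULL,
                             exon_means = DEFAULT_EXON_MEANS,
                             n_unplaced = 4L) {
  set.seed(seed)
  if (is.null(subgroup_counts)) {
    subgroup_counts <- DEFAULT_SUBGROUP_COUNTS
    if (scale != 1) {
      subgroup_counts <- pmax(round(subgroup_counts * scale),
                              as.integer(subgroup_counts > 0))
      ## keep singleton oddities out of tiny blueprints
      if (scale < 0.2) {
        rare <- c("CNN", "TNNL", "TTNL", "TNLTNL", "CTNL", "CTN", "RCNL",
                  "RN", "NN")
        subgroup_counts[rare] <- 0L
      }
    }
  }
  subgroup_counts <- subgroup_counts[subgroup_counts > 0]
  n_genes <- sum(subgroup_counts)
  if (is.null(n_clusters)) n_clusters <- max(2L, round(75 * scale))
  if (is.null(n_clustered_genes)) {
    n_clustered_genes <- max(2L * n_clusters, round(200 * scale))
  }
  n_unplaced <- min(n_unplaced, max(0L, n_genes - n_clustered_genes))
  if (n_clustered_genes > n_genes - n_unplaced) {
    stop("cluster plan needs more genes than the census provides")
  }
  ## cluster sizes in {2, 3}: n3 triples and the rest pairs
  n3 <- n_clustered_genes - 2L * n_clusters
  if (n3 < 0L || n3 > n_clusters) {
    stop("cluster plan not realisable with sizes 2 and 3")
  }
  sizes <- c(rep(3L, n3), rep(2L, n_clusters - n3))
  ## chromosome plan: ~1/3 of clusters on chr13, none on chr5/chr12
  chrom_names <- sprintf("HanSynChr%02d", seq_len(n_chromosomes))
  no_cluster <- intersect(c("HanSynChr05", "HanSynChr12"), chrom_names)
  hot <- if (n_chromosomes >= 13L) "HanSynChr13" else chrom_names[1L]
  others <- setdiff(chrom_names, c(no_cluster, hot))
  n_hot <- round(n_clusters / 3)
  cluster_chrom <- c(rep(hot, n_hot),
                     rep_len(others, n_clusters - n_hot))
  ## assemble gene table
  subgroup <- rep(names(subgroup_counts), subgroup_counts)
  group <- vapply(subgroup, subgroup_group, character(1))
  perm <- sample.int(n_genes)
  subgroup <- subgroup[perm]
  group <- group[perm]
  cluster_id <- rep(NA_character_, n_genes)
  chrom <- rep(NA_character_, n_genes)
  idx <- 1L
  for (k in seq_len(n_clusters)) {
    members <- idx:(idx + sizes[k] - 1L)
    cluster_id[members] <- sprintf("planted_cluster_%03d", k)
    chrom[members] <- cluster_chrom[k]
    idx <- idx + sizes[k]
  }
  if (n_unplaced > 0L) {
    unpl <- idx:(idx + n_unplaced - 1L)
    chrom[unpl] <- sprintf("HanSynChr00c%04d", seq_len(n_unplaced))
    idx <- idx + n_unplaced
  }
  if (idx <= n_genes) {
    chrom[idx:n_genes] <- rep_len(sample(chrom_names), n_genes - idx + 1L)
  }
  exon_count <- vapply(group, function(g) {
    1L + stats::rpois(1L, exon_means[[g]] - 1)
  }, integer(1))
  genes <- data.frame(subgroup = subgroup, group = group, chrom = chrom,
                      cluster_id = cluster_id, exon_count = exon_count,
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom), , drop = FALSE]
  genes$gene_id <- sprintf("%sg%04d", genes$chrom,
                           stats::ave(seq_len(n_genes), genes$chrom,
                                      FUN = seq_along) * 10L)
  rownames(genes) <- NULL
  list(genes = genes[, c("gene_id", "group", "subgroup", "chrom",
                         "cluster_id", "exon_count")],
       n_chromosomes = n_chromosomes, chrom_names = chrom_names,
       n_clusters = n_clusters, n_clustered_genes = n_clustered_genes,
       exon_means = exon_means, seed = seed, scale = scale)
}

## build one synthetic protein for a subgroup code; returns sequence,
## domain rows and planted signature metadata
build_synthetic_protein <- function(id, code, lrr_total, kinase2) {
  units <- strsplit(code, "", fixed = TRUE)[[1]]
  n_lrr_blocks <- sum(units == "L")
  lrr_per_block <- integer(0)
  if (n_lrr_blocks > 0L) {
    lrr_per_block <- rep(lrr_total %/% n_lrr_blocks, n_lrr_blocks)
    extra <- lrr_total %% n_lrr_blocks
    if (extra > 0L) {
      lrr_per_block[seq_len(extra)] <- lrr_per_block[seq_len(extra)] + 1L
    }
  }
  seq_parts <- character(0)
  rows <- list()
  pos <- 0L
  first_nbs <- TRUE
  lrr_block_i <- 0L
  add <- function(s) {
    seq_parts <<- c(seq_parts, s)
    pos <<- pos + nchar(s)
  }
  add(rand_res(sample(6:12, 1L)))
  for (u in units) {
    if (u == "C") {
      start <- pos + 1L
      add(CC_BLOCK)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, accession = "COILS", start = start, end = pos,
        score = 1, stringsAsFactors = FALSE)
    } else if (u == "T") {
      start <- pos + 1L
      add(rand_res(60L))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, accession = "PF01582", start = start, end = pos,
        score = 50, stringsAsFactors = FALSE)
    } else if (u == "R") {
      start <- pos + 1L
      add(rand_res(50L))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, accession = "PF05659", start = start, end = pos,
        score = 50, stringsAsFactors = FALSE)
    } else if (u == "N") {
      start <- pos + 1L
      if (first_nbs) {
        add(rand_res(8L))
        add("GAMSGKTT")                          # P-loop
        add(rand_res(sample(6:10, 1L)))
        if (!is.na(kinase2)) add(paste0("VL", kinase2))   # Kinase-2
        add(rand_res(sample(6:10, 1L)))
        add(if (startsWith(code, "T") || grepl("T", code)) "TTRD" else "TSR")
        add(rand_res(sample(6:10, 1L)))
        add("GLPLA")                             # GLPL
        add(rand_res(sample(6:10, 1L)))
        add("MHDL")                              # MHDL
        add(rand_res(8L))
        first_nbs <- FALSE
      } else {
        add(rand_res(70L))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, accession = "PF00931", start = start, end = pos,
        score = 80, stringsAsFactors = FALSE)
    } else if (u == "L") {
      lrr_block_i <- lrr_block_i + 1L
      add(strrep(LRR_UNIT, lrr_per_block[lrr_block_i]))
    }
    add(rand_res(sample(6:12, 1L)))
  }
  list(seq = paste(seq_parts, collapse = ""),
       rows = do.call(rbind, rows))
}

#' Generate a synthetic proteome with planted architectures
#'
#' Each protein is a concatenation of unit blocks following its planted
#' subgroup code: an ideal heptad CC repeat, random TIR/RPW8 blocks, an
#' NBS block embedding the curated P-loop / Kinase-2 (with the planted
#' DDVW/DDVD/other signature) / RNBS-B / GLPL / MHDL patterns, and LRR
#' blocks with an exact planted number of LxxLxxLxx units, joined by
#' random linkers free of L, D and W. A matching domain-hit table is
#' emitted. One plain TNL protein carries a Kelch block (PF01344).
#'
#' @param blueprint From [genome_blueprint()].
#' @param seed Integer seed (defaults to the blueprint's).
#' @return List `proteins` (named character), `domains` (hit data.frame)
#'   and `truth` (planted subgroup, LRR count, Kinase-2 signature, NL
#'   subtype per protein).
#' @export
gen_proteome <- function(blueprint, seed = blueprint$seed) {
  set.seed(seed + 1L)
  genes <- blueprint$genes
  n <- nrow(genes)
  ## planted Kinase-2 signatures: CC-lineage groups get DDVW (one RNL gene
  ## carries the DDVR variant), TIR-lineage DDVD; NL genes follow the
  ## published 83:18:61 DDVW/DDVD/absent proportions
  kinase2 <- character(n)
  for (i in seq_len(n)) {
    kinase2[i] <- switch(genes$group[i],
      CNL = "DDVW", RNL = "DDVW", TNL = "DDVD",
      NL = sample(c("DDVW", "DDVD", NA_character_), 1L,
                  prob = c(83, 18, 61) / 162))
  }
  rnl_idx <- which(genes$group == "RNL")
  if (length(rnl_idx) > 1L) kinase2[rnl_idx[1L]] <- "DDVR"
  lrr_total <- integer(n)
  proteins <- character(n)
  dom <- vector("list", n)
  kelch_done <- FALSE
  for (i in seq_len(n)) {
    code <- genes$subgroup[i]
    rng <- LRR_RANGES[[genes$group[i]]]
    has_l <- grepl("L", code, fixed = TRUE)
    lrr_total[i] <- if (has_l) {
      resample(seq(max(rng[1L], sum(strsplit(code, "")[[1]] == "L")),
                   rng[2L]), 1L)
    } else 0L
    p <- build_synthetic_protein(genes$gene_id[i], code, lrr_total[i],
                                 kinase2[i])
    if (!kelch_done && code == "TNL") {
      start <- nchar(p$seq) + 1L
      kb <- rand_res(45L)
      p$seq <- paste0(p$seq, kb)
      p$rows <- rbind(p$rows, data.frame(
        protein_id = genes$gene_id[i], accession = "PF01344",
        start = start, end = start + nchar(kb) - 1L, score = 30,
        stringsAsFactors = FALSE))
      kelch_done <- TRUE
    }
    proteins[i] <- p$seq
    dom[[i]] <- p$rows
  }
  names(proteins) <- genes$gene_id
  domains <- do.call(rbind, dom)
  domains$kind <- unname(PFAM_KIND_MAP[domains$accession])
  rownames(domains) <- NULL
  truth <- data.frame(
    protein_id = genes$gene_id, group = genes$group,
    subgroup = genes$subgroup, lrr_count = lrr_total, kinase2 = kinase2,
    nl_subtype = ifelse(genes$group != "NL", NA_character_,
                        ifelse(is.na(kinase2), "unassigned",
                               ifelse(kinase2 == "DDVW", "N_CC",
                                      ifelse(kinase2 == "DDVD", "N_TIR",
                                             "unassigned")))),
    stringsAsFactors = FALSE)
  list(proteins = proteins,
       domains = domains[, c("protein_id", "kind", "accession", "start",
                             "end", "score")],
       truth = truth)
}

#' Generate a synthetic genome annotation with planted clusters
#'
#' Planted clusters satisfy both linkage criteria with margin (gaps drawn
#' inside `intra_gap_range`, at most `intra_intervening_max` filler genes
#' between members); separate NBS entities are isolated by
#' `separation_gap` bp and `separation_intervening` fillers, violating
#' both criteria. Planted exon counts are emitted as exon features.
#'
#' @param blueprint From [genome_blueprint()].
#' @param seed Integer seed (defaults to the blueprint's).
#' @param intra_gap_range Range (bp) for intra-cluster gaps; give two equal
#'   values for an exact boundary probe.
#' @param intra_intervening_max Max filler genes between cluster members.
#' @param separation_gap Gap (bp) isolating consecutive NBS entities.
#' @param separation_intervening Filler genes in each separation gap.
#' @param gene_length,filler_length Body lengths (bp).
#' @return List `loci` (data.frame as [read_gff3()], `is_nbs` set) and
#'   `truth` (planted cluster id and exon count per NBS gene).
#' @export
gen_genome <- function(blueprint, seed = blueprint$seed,
                       intra_gap_range = c(20000L, 120000L),
                       intra_intervening_max = 3L,
                       separation_gap = 300000L,
                       separation_intervening = 10L,
                       gene_length = 3000L, filler_length = 2000L) {
  set.seed(seed + 2L)
  genes <- blueprint$genes
  loci <- list()
  filler_n <- 0L
  place_fillers <- function(chrom, from, to, m) {
    if (m <= 0L) return(NULL)
    slots <- round(seq(from, to - filler_length, length.out = m + 2L))
    slots <- slots[2:(m + 1L)]
    out <- lapply(seq_len(m), function(j) {
      filler_n <<- filler_n + 1L
      data.frame(gene_id = sprintf("%s_filler%05d", chrom, filler_n),
                 chrom = chrom, start = slots[j],
                 end = slots[j] + filler_length - 1L, strand = "+",
                 is_nbs = FALSE, exon_count = 1L, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  for (chrom in unique(genes$chrom)) {
    d <- genes[genes$chrom == chrom, , drop = FALSE]
    ## entities: clusters (kept together) then singletons, shuffled
    ents <- c(split(seq_len(nrow(d)), d$cluster_id),
              as.list(which(is.na(d$cluster_id))))
    ents <- ents[sample.int(length(ents))]
    cur <- 10000L
    first <- TRUE
    for (ent in ents) {
      if (!first) {
        loci[[length(loci) + 1L]] <-
          place_fillers(chrom, cur, cur + separation_gap,
                        separation_intervening)
        cur <- cur + separation_gap
      }
      first <- FALSE
      for (m in seq_along(ent)) {
        i <- ent[m]
        if (m > 1L) {
          ## measured gap is start(next) - end(prev); cur sits at end + 1
          gap <- resample(seq(intra_gap_range[1L], intra_gap_range[2L]), 1L)
          nf <- resample(0:intra_intervening_max, 1L)
          loci[[length(loci) + 1L]] <-
            place_fillers(chrom, cur, cur + gap - 1L, nf)
          cur <- cur + gap - 1L
        }
        loci[[length(loci) + 1L]] <- data.frame(
          gene_id = d$gene_id[i], chrom = chrom, start = cur,
          end = cur + gene_length - 1L, strand = sample(c("+", "-"), 1L),
          is_nbs = TRUE, exon_count = d$exon_count[i],
          stringsAsFactors = FALSE)
        cur <- cur + gene_length
      }
    }
  }
  loci <- do.call(rbind, loci)
  loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  truth <- genes[, c("gene_id", "chrom", "cluster_id", "exon_count")]
  list(loci = loci, truth = truth)
}

## sense-codon machinery for the divergence simulator
sense_codons <- function() {
  all <- apply(expand.grid(NT4, NT4, NT4), 1L, paste, collapse = "")
  all[vapply(all, is_sense_codon, logical(1))]
}

codon_neighbors <- function(codon) {
  nt <- strsplit(codon, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (alt in setdiff(NT4, nt[pos])) {
      mut <- nt
      mut[pos] <- alt
      out <- c(out, paste(mut, collapse = ""))
    }
  }
  out
}

#' Generate codon alignments with controlled divergence
#'
#' Each pair consists of a random sense-codon ancestor and a derived copy
#' carrying single-nucleotide substitutions at distinct codons: the number
#' of synonymous changes targets the proportion implied by `ks_target`
#' under Jukes-Cantor, and the nonsynonymous count the proportion implied
#' by `omega * ks_target`, so the expected Ka/Ks of a pair is `omega`.
#'
#' @param n_pairs Number of pairs.
#' @param n_codons Codons per sequence.
#' @param omega Target Ka/Ks.
#' @param ks_target Target Ks.
#' @param seed Integer seed.
#' @return List `pairs` (data.frame `id_a`, `id_b`), `sequences` (named
#'   character, in-frame), `truth` (planted substitution counts per pair).
#' @export
gen_codon_pairs <- function(n_pairs = 50L, n_codons = 300L, omega = 0.3,
                            ks_target = 0.3, seed = 1L) {
  set.seed(seed + 3L)
  sense <- sense_codons()
  syn_nb <- lapply(sense, function(cd) {
    nb <- codon_neighbors(cd)
    nb[vapply(nb, is_sense_codon, logical(1)) & codon_aa(nb) == codon_aa(cd)]
  })
  non_nb <- lapply(sense, function(cd) {
    nb <- codon_neighbors(cd)
    nb[vapply(nb, is_sense_codon, logical(1)) & codon_aa(nb) != codon_aa(cd)]
  })
  names(syn_nb) <- names(non_nb) <- sense
  pS <- 0.75 * (1 - exp(-4 * ks_target / 3))
  pN <- 0.75 * (1 - exp(-4 * omega * ks_target / 3))
  seqs <- character(0)
  pairs <- list()
  truth <- list()
  for (p in seq_len(n_pairs)) {
    anc <- sample(sense, n_codons, replace = TRUE)
    st <- vapply(anc, function(cd) count_sites_cached(cd)[["s"]], numeric(1))
    S <- sum(st)
    N <- 3 * n_codons - S
    n_syn <- round(pS * S)
    n_non <- round(pN * N)
    der <- anc
    syn_ok <- which(lengths(syn_nb[anc]) > 0L)
    syn_at <- resample(syn_ok, min(n_syn, length(syn_ok)))
    for (i in syn_at) {
      der[i] <- resample(syn_nb[[anc[i]]], 1L)
    }
    non_at <- resample(setdiff(seq_len(n_codons), syn_at), n_non)
    for (i in non_at) {
      der[i] <- resample(non_nb[[anc[i]]], 1L)
    }
    id_a <- sprintf("pair%03d_a", p)
    id_b <- sprintf("pair%03d_b", p)
    seqs[id_a] <- paste(anc, collapse = "")
    seqs[id_b] <- paste(der, collapse = "")
    pairs[[p]] <- data.frame(id_a = id_a, id_b = id_b,
                             stringsAsFactors = FALSE)
    truth[[p]] <- data.frame(id_a = id_a, id_b = id_b,
                             n_syn = length(syn_at), n_non = n_non,
                             omega = omega, ks_target = ks_target,
                             stringsAsFactors = FALSE)
  }
  list(pairs = do.call(rbind, pairs), sequences = seqs,
       truth = do.call(rbind, truth))
}

DEFAULT_TISSUES <- c("bract", "corolla", "leaves", "ligule", "ovary",
                     "pollen", "seed", "stamen", "stem")

#' Generate a tissue expression matrix with planted level classes
#'
#' Three planted expression-level classes with log-normal noise around the
#' class means; default class sizes follow the published 13/15/43 split
#' over 71 genes (scaled proportionally for other `n_genes`).
#'
#' @param n_genes Number of genes.
#' @param tissues Tissue names (default: the 9 surveyed tissues).
#' @param class_means Mean expression of the three classes, descending.
#' @param class_sizes Genes per class; `NULL` scales the 13/15/43 split.
#' @param sdlog Log-normal noise.
#' @param seed Integer seed.
#' @return List `mat` (genes x tissues), `truth` (planted class label per
#'   gene) and `degenerate` (TRUE when class means are not distinct).
#' @export
gen_expression <- function(n_genes = 71L, tissues = DEFAULT_TISSUES,
                           class_means = c(50, 8, 0.4),
                           class_sizes = NULL, sdlog = 0.3, seed = 1L) {
  set.seed(seed + 4L)
  if (is.null(class_sizes)) {
    class_sizes <- round(n_genes * c(13, 15, 43) / 71)
    class_sizes[3L] <- n_genes - sum(class_sizes[1:2])
  }
  stopifnot(sum(class_sizes) == n_genes, length(class_means) == 3L)
  cls <- rep(EXPRESSION_LEVEL_LABELS, class_sizes)
  mu <- rep(class_means, class_sizes)
  mat <- matrix(stats::rlnorm(n_genes * length(tissues),
                              meanlog = rep(log(mu), length(tissues)),
                              sdlog = sdlog),
                nrow = n_genes, ncol = length(tissues),
                dimnames = list(sprintf("gene%03d", seq_len(n_genes)),
                                tissues))
  list(mat = mat,
       truth = stats::setNames(cls, rownames(mat)),
       degenerate = anyDuplicated(class_means) > 0L)
}
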