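## End-to-end orchestration: identify -> classify -> cluster -> evolve ->
## express -> report, driven by a config list or YAML file.

#' Default pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Root seed; per-stage seeds are derived from it.
#' @return Config list with the documented threshold defaults.
#' @export
default_pipeline_config <- function(outdir = tempfile("nlrscan_"),
                                    seed = 1L) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    inputs = list(proteins = NULL, gff3 = NULL, domain_table = NULL,
                  cds = NULL, clades = NULL, expression = NULL,
                  rx_cc_list = NULL),
    thresholds = list(
      cc_threshold = 0.4,
      nls_cutoff = 0.5,
      cluster = list(max_gap_bp = 200000L, max_intervening = 8L),
      homology = list(max_evalue = 0.01, min_identity = 50)
    ),
    options = list(use_builtin_scanners = FALSE, n_chromosomes = 17L,
                   kmeans_k = 3L, stages = NULL)
  )
}

validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  th <- config$thresholds
  if (th$cc_threshold < 0 || th$cc_threshold > 1) {
    stop("cc_threshold must lie in [0, 1]")
  }
  if (th$nls_cutoff < 0 || th$nls_cutoff > 1) {
    stop("nls_cutoff must lie in [0, 1]")
  }
  stages <- config$options$stages
  if (is.null(stages)) {
    stages <- c("identify", "classify", "cluster",
                if (!is.null(config$inputs$cds)) "kaks",
                if (!is.null(config$inputs$expression)) "express",
                "report")
  }
  if ("kaks" %in% stages && is.null(config$inputs$cds)) {
    stop("config error: stage 'kaks' enabled but inputs$cds is missing")
  }
  if ("kaks" %in% stages && is.null(config$inputs$clades)) {
    stop("config error: stage 'kaks' enabled but inputs$clades is missing")
  }
  for (f in c("proteins", "gff3")) {
    if (is.null(config$inputs[[f]])) {
      stop("config error: inputs$", f, " is required")
    }
  }
  for (f in Filter(Negate(is.null), config$inputs)) {
    if (!file.exists(f)) stop("config error: input not found: ", f)
  }
  config$options$stages <- stages
  config
}

## infer an NBS domain hit from the motif scan: the span of the NB-ARC
## motifs when at least two of them are present
scan_nbs_region <- function(seq, protein_id) {
  mh <- scan_known_motifs(seq, protein_id = protein_id)
  core <- mh[mh$motif %in% c("P-loop", "Kinase-2", "GLPL", "MHDL"), ,
             drop = FALSE]
  if (length(unique(core$motif)) < 2L) return(NULL)
  data.frame(protein_id = protein_id, kind = "NBS", accession = "PF00931",
             start = min(core$start),
             end = max(core$start + nchar(core$matched) - 1L),
             score = nrow(core), stringsAsFactors = FALSE)
}

## add a CC hit from the coiled-coil scanner when the segment starts before
## the first NBS hit (N-terminal evidence only); used only when the domain
## table carries no CC evidence at all, so two CC callers are never mixed
augment_cc_hits <- function(seqs, hits, threshold) {
  extra <- list()
  for (id in names(seqs)) {
    h <- hits[hits$protein_id == id, , drop = FALSE]
    if (any(h$kind == "CC") || !any(h$kind == "NBS")) next
    cc <- suppressWarnings(call_cc(seqs[[id]], threshold = threshold,
                                   protein_id = id))
    if (is.null(cc)) next
    first_nbs <- min(h$start[h$kind == "NBS"])
    if (cc$start < first_nbs) {
      extra[[id]] <- data.frame(protein_id = id, kind = "CC",
                                accession = "COILS", start = cc$start,
                                end = cc$end, score = cc$support,
                                stringsAsFactors = FALSE)
    }
  }
  if (length(extra)) rbind(hits, do.call(rbind, extra)) else hits
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stages run in order identify, classify, cluster, kaks (when CDS and
#' clade inputs are configured), express (when an expression matrix is
#' configured), report; every stage's outputs are written to `outdir`
#' before the next starts, and a manifest records package version, seeds
#' and input digests. All randomness derives from the root seed.
#'
#' @param config Config list (see [default_pipeline_config()]) or path to
#'   a YAML file with the same structure.
#' @return List with the summary report and the paths of all outputs.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$options$stages
  paths <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## identify: sequences, domain evidence, CC and NLS signals
  seqs <- read_fasta(config$inputs$proteins, alphabet = "protein")
  hits <- NULL
  nls_ids <- character(0)
  run_stage("identify", function() {
    if (!is.null(config$inputs$domain_table)) {
      hits <<- read_domain_table(config$inputs$domain_table)
    } else if (isTRUE(config$options$use_builtin_scanners)) {
      hits <<- do.call(rbind, Filter(Negate(is.null),
        lapply(names(seqs), function(id) scan_nbs_region(seqs[[id]], id))))
      if (is.null(hits)) stop("built-in scanners found no NBS region")
    } else {
      stop("no domain_table input and use_builtin_scanners is FALSE")
    }
    if (!any(hits$kind == "CC")) {
      hits <<- augment_cc_hits(seqs, hits, config$thresholds$cc_threshold)
    }
    nls <- lapply(names(seqs), function(id) {
      nls_decode(seqs[[id]], mode = "posterior",
                 cutoff = config$thresholds$nls_cutoff,
                 protein_id = id)$calls
    })
    nls <- do.call(rbind, nls)
    nls_ids <<- unique(nls$protein_id)
    paths$domains <<- write_tsv(hits, file.path(outdir, "domains.tsv"))
    paths$nls <<- write_tsv(nls, file.path(outdir, "nls_calls.tsv"))
  })

  ## classify
  rx_ids <- if (!is.null(config$inputs$rx_cc_list)) {
    readLines(config$inputs$rx_cc_list)
  } else character(0)
  cls <- NULL
  run_stage("classify", function() {
    cls <<- classify_proteins(seqs, hits, nls_ids = nls_ids,
                              rx_cc_ids = rx_ids)
    paths$records <<- write_tsv(cls$records,
                                file.path(outdir, "records.tsv"))
    paths$excluded <<- write_tsv(cls$excluded,
                                 file.path(outdir, "excluded.tsv"))
  })

  ## cluster + exon structure
  loci <- NULL; csum <- NULL; estats <- NULL
  run_stage("cluster", function() {
    loci <<- read_gff3(config$inputs$gff3)
    loci$is_nbs <<- loci$gene_id %in% cls$records$protein_id
    crit <- cluster_criteria(config$thresholds$cluster$max_gap_bp,
                             config$thresholds$cluster$max_intervening)
    called <- call_clusters(loci, crit)
    csum <<- cluster_summary(called, loci,
                             n_chromosomes = config$options$n_chromosomes)
    estats <<- exon_statistics(loci, cls$records)
    paths$clusters <<- write_cluster_bed(called,
                                         file.path(outdir, "clusters.bed"))
    paths$exon_stats <<- write_tsv(estats,
                                   file.path(outdir, "exon_stats.tsv"))
  })

  ## molecular evolution (optional)
  kaks <- NULL
  if ("kaks" %in% stages) {
    run_stage("kaks", function() {
      cds <- read_fasta(config$inputs$cds, alphabet = "nucleotide")
      cl <- utils::read.delim(config$inputs$clades,
                              stringsAsFactors = FALSE)
      clades <- stats::setNames(cl$clade, cl$gene_id)
      kaks <<- kaks_pairs_table(cds, clades)
      paths$kaks <<- write_tsv(kaks, file.path(outdir, "kaks.tsv"))
    })
  }

  ## expression (optional)
  expr <- NULL
  if ("express" %in% stages) {
    run_stage("express", function() {
      mat <- read_expression(config$inputs$expression)
      norm <- normalize_expression(mat)
      fit <- kmeans_cluster(norm, k = config$options$kmeans_k,
                            seed = config$seed + 10L)
      lab <- if (config$options$kmeans_k == 3L) {
        classify_expression_levels(fit)$labels
      } else rep(NA_character_, length(fit$cluster))
      expr <<- data.frame(gene_id = names(fit$cluster),
                          cluster = unname(fit$cluster),
                          level = unname(lab), stringsAsFactors = FALSE)
      paths$expression <<- write_tsv(
        expr, file.path(outdir, "expression_assignments.tsv"))
    })
  }

  ## report + manifest
  report <- NULL
  run_stage("report", function() {
    report <<- nlr_summary_report(cls$records, proteome_size = length(seqs),
                                  cluster_stats = csum, exon_stats = estats)
    rep_json <- list(
      total_nbs = report$total_nbs,
      group_counts = as.list(report$group_counts),
      subgroup_counts = as.list(report$subgroup_counts),
      pct_of_proteome = report$pct_of_proteome,
      cnl_tnl_ratio = report$cnl_tnl_ratio,
      cluster = csum[c("n_clusters", "n_clustered_genes",
                       "genes_per_cluster", "clusters_per_chromosome",
                       "pct_clustered")]
    )
    paths$report <<- file.path(outdir, "report.json")
    jsonlite::write_json(rep_json, paths$report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    ins <- Filter(Negate(is.null), config$inputs)
    manifest <- list(
      package = "nlrscan",
      version = as.character(utils::packageVersion("nlrscan")),
      seed = config$seed,
      stages = stages,
      inputs = lapply(ins, function(f) {
        list(path = f, md5 = unname(tools::md5sum(f)))
      })
    )
    paths$manifest <<- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE)
  })

  invisible(list(report = report, records = cls$records,
                 cluster_summary = csum, exon_stats = estats, kaks = kaks,
                 expression = expr, paths = paths))
}
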