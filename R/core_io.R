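#' @keywords internal
"_PACKAGE"

## Shared alphabets. Proteins use the 20 canonical residues plus X (unknown);
## nucleotide sequences use ACGT plus N.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA20, "X")
NT_ALPHABET <- c("A", "C", "G", "T", "N")

## Pfam-style accession -> domain kind. CC and LRR rows may come from the
## built-in scanners rather than an external domain database.
PFAM_KIND_MAP <- c(PF01582 = "TIR", PF00931 = "NBS", PF05659 = "RPW8",
                   PF01344 = "KELCH", CC = "CC", COILS = "CC", LRR = "LRR")

DOMAIN_KINDS <- c("TIR", "NBS", "RPW8", "CC", "LRR", "KELCH")

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased, line folding is undone, and every residue is
#' checked against the declared alphabet (20 amino acids plus X, or ACGTN).
#' Record ids are the first whitespace-delimited token of each header and
#' must be unique within the file.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- if (alphabet == "protein") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  ok <- if (alphabet == "protein") AA_ALPHABET else NT_ALPHABET
  bad <- vapply(seqs, function(s) {
    ch <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    length(setdiff(ch, ok)) > 0L
  }, logical(1))
  if (any(bad)) {
    stop("sequence(s) with characters outside the ", alphabet, " alphabet: ",
         paste(ids[bad], collapse = ", "))
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read gene loci from a GFF3 annotation
#'
#' Builds one row per `gene` feature. `exon_count` is the exon count of the
#' gene's primary transcript, defined as the mRNA with the most exons (ties
#' broken by file order); genes without an mRNA child get 0. Coordinates are
#' 1-based inclusive, as in GFF3. Rows are sorted by (chrom, start).
#'
#' @param path Path to a GFF3 file with gene/mRNA/exon features linked by
#'   `ID`/`Parent` attributes.
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `is_nbs` (all `NA`; set by the caller), `exon_count`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- gr$Parent   # CharacterList
  genes <- which(typ == "gene")
  mrnas <- which(typ %in% c("mRNA", "transcript"))
  exons <- which(typ == "exon")
  if (length(genes) == 0L) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), is_nbs = logical(0),
                      exon_count = integer(0), stringsAsFactors = FALSE))
  }
  mrna_parent <- vapply(parents[mrnas], function(p) p[1], character(1))
  mrna_ids <- ids[mrnas]
  ## exon -> mRNA (an exon shared by several transcripts counts for each)
  exon_parents <- parents[exons]
  ep <- unlist(exon_parents, use.names = FALSE)
  unresolved <- setdiff(unique(ep), mrna_ids)
  if (length(unresolved)) {
    bad <- exons[vapply(exon_parents,
                        function(p) any(p %in% unresolved), logical(1))]
    desc <- paste0(as.character(GenomicRanges::seqnames(gr))[bad], ":",
                   GenomicRanges::start(gr)[bad], "-",
                   GenomicRanges::end(gr)[bad],
                   " Parent=", vapply(exon_parents[match(bad, exons)],
                                      paste, character(1), collapse = ","))
    stop("exon feature(s) with unresolvable Parent:\n  ",
         paste(desc, collapse = "\n  "))
  }
  exon_per_mrna <- table(factor(ep, levels = mrna_ids))
  ## primary transcript = max-exon mRNA; mrnas are in file order so which.max
  ## breaks ties by file order
  gene_ids <- ids[genes]
  exon_count <- vapply(gene_ids, function(g) {
    k <- which(mrna_parent == g)
    if (length(k) == 0L) return(0L)
    as.integer(max(exon_per_mrna[mrna_ids[k]]))
  }, integer(1))
  strand <- as.character(BiocGenerics::strand(gr))[genes]
  strand[strand == "*"] <- "."
  out <- data.frame(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(gr))[genes],
    start = GenomicRanges::start(gr)[genes],
    end = GenomicRanges::end(gr)[genes],
    strand = strand,
    is_nbs = NA,
    exon_count = exon_count,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$gene_id)) {
    stop("duplicate gene id(s): ",
         paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene loci as GFF3
#'
#' Emits gene, mRNA and exon features; `exon_count` exons are tiled across
#' the gene body so that [read_gff3()] round-trips `gene_id`, `chrom`,
#' `start`, `end`, `strand` and `exon_count`.
#'
#' @param loci Data.frame as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(loci))) {
    g <- loci[i, ]
    st <- if (g$strand %in% c("+", "-")) g$strand else "."
    writeLines(sprintf("%s\tnlrscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start, g$end, st, g$gene_id), con)
    if (g$exon_count >= 1L) {
      mid <- paste0(g$gene_id, ".1")
      writeLines(sprintf("%s\tnlrscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         g$chrom, g$start, g$end, st, mid, g$gene_id), con)
      bounds <- round(seq(g$start, g$end + 1L, length.out = g$exon_count + 1L))
      for (e in seq_len(g$exon_count)) {
        writeLines(sprintf(
          "%s\tnlrscan\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
          g$chrom, bounds[e], bounds[e + 1L] - 1L, st, mid, e, mid), con)
      }
    }
  }
  invisible(path)
}

#' Read a tab-separated domain-hit table
#'
#' Expected columns: `protein_id`, `accession`, `start`, `end`, `score`.
#' Accessions are mapped to domain kinds via the fixed Pfam table
#' (PF01582 = TIR, PF00931 = NBS, PF05659 = RPW8, PF01344 = KELCH; CC/COILS
#' and LRR are accepted for scanner-derived rows). Coordinates are 1-based
#' inclusive residue positions.
#'
#' @param path Path to the TSV (header row required).
#' @param unknown_map Optional named character vector mapping additional
#'   accessions to kinds.
#' @param on_unknown `"error"` or `"drop"` for unmapped accessions.
#' @return Data.frame with columns `protein_id`, `kind`, `accession`,
#'   `start`, `end`, `score`.
#' @export
read_domain_table <- function(path, unknown_map = NULL,
                              on_unknown = c("error", "drop")) {
  on_unknown <- match.arg(on_unknown)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "accession", "start", "end", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("domain table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(df$start > df$end)
  if (length(bad)) {
    stop("domain table row(s) with start > end: row ",
         paste(bad, collapse = ", "))
  }
  map <- c(PFAM_KIND_MAP, unknown_map)
  kind <- unname(map[df$accession])
  if (anyNA(kind)) {
    unk <- unique(df$accession[is.na(kind)])
    if (on_unknown == "error") {
      stop("unknown accession(s): ", paste(unk, collapse = ", "),
           "; supply unknown_map or on_unknown = \"drop\"")
    }
    df <- df[!is.na(kind), , drop = FALSE]
    kind <- kind[!is.na(kind)]
  }
  data.frame(protein_id = df$protein_id, kind = kind,
             accession = df$accession,
             start = as.integer(df$start), end = as.integer(df$end),
             score = as.numeric(df$score), stringsAsFactors = FALSE)
}

#' Write a domain-hit table
#' @param hits Data.frame as from [read_domain_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(hits, path) {
  utils::write.table(hits[, c("protein_id", "accession", "start", "end",
                              "score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
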