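## Shared fixture builders. All fixtures are generated in code; seeds are
## fixed by the caller.

AA20_FIX <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, alphabet = AA20_FIX) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## sequences of length L with a motif planted at a random position
planted_motif_seqs <- function(n_seq, L, motif, seed) {
  set.seed(seed)
  w <- nchar(motif)
  out <- vapply(seq_len(n_seq), function(i) {
    pos <- sample.int(L - w + 1L, 1L)
    s <- random_protein(L)
    paste0(substr(s, 1, pos - 1L), motif, substr(s, pos + w, L))
  }, character(1))
  stats::setNames(out, sprintf("seq%03d", seq_len(n_seq)))
}

## minimal loci table builder
make_loci <- function(start, end, is_nbs, chrom = "chr1",
                      exon_count = 1L) {
  n <- length(start)
  data.frame(
    gene_id = sprintf("%s_g%03d", chrom, seq_len(n)),
    chrom = chrom, start = start, end = end, strand = "+",
    is_nbs = is_nbs, exon_count = rep_len(exon_count, n),
    stringsAsFactors = FALSE)
}

## random toy genome for the cluster oracle: <= max_genes genes on 1-2
## chromosomes with random NBS flags and spacings spanning the criteria
random_toy_genome <- function(max_genes = 50L) {
  n_chrom <- sample(1:2, 1L)
  out <- lapply(seq_len(n_chrom), function(ci) {
    n <- sample(2:max_genes, 1L)
    gaps <- sample(c(1000L, 50000L, 150000L, 199999L, 200000L, 250000L),
                   n, replace = TRUE)
    len <- 2000L
    start <- cumsum(c(10000L, gaps[-1L] + len))
    make_loci(start, start + len - 1L,
              is_nbs = sample(c(TRUE, FALSE), n, replace = TRUE,
                              prob = c(0.5, 0.5)),
              chrom = paste0("toy", ci))
  })
  loci <- do.call(rbind, out)
  loci$gene_id <- sprintf("g%04d", seq_len(nrow(loci)))
  loci
}

## tiny two-state HMM with distinct, hand-picked parameters (valid rows)
toy_hmm <- function() {
  emit_bg <- rep(1 / 20, 20)
  emit_sig <- rep(0.3 / 18, 20)
  emit_sig[c(9, 15)] <- 0.35   # K and R enriched
  list(init = c(0.8, 0.2),
       trans = matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE),
       emit = matrix(c(emit_bg, emit_sig), 2, byrow = TRUE,
                     dimnames = list(NULL, AA20_FIX)))
}
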