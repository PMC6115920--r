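test_that("FASTA reading folds lines, upper-cases and preserves order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "mk", "vl", ">b desc text", "MKV"), f)
  seqs <- read_fasta(f)
  expect_identical(names(seqs), c("a", "b"))
  expect_identical(unname(seqs), c("MKVL", "MKV"))
})

test_that("FASTA duplicate ids error and empty files warn", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "MKV", ">a", "MML"), f)
  expect_error(read_fasta(f), "duplicate.*a")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f2)
  expect_warning(res <- read_fasta(f2), "empty")
  expect_length(res, 0L)
})

test_that("FASTA round-trips ids and residues", {
  set.seed(11)
  seqs <- stats::setNames(
    vapply(1:20, function(i) random_protein(sample(30:200, 1)),
           character(1)),
    sprintf("prot%02d", 1:20))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f, width = 60)
  expect_identical(read_fasta(f), seqs)
})

test_that("alphabet violations are rejected", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "MKV*"), f)
  expect_error(read_fasta(f), "alphabet")
})

test_that("GFF3 exon counts use the max-exon primary transcript", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\t.\tgene\t100\t500\t.\t+\t.\tID=g1",
    "chr1\t.\tmRNA\t100\t500\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\t.\texon\t100\t200\t.\t+\t.\tID=e1;Parent=m1",
    "chr1\t.\texon\t250\t300\t.\t+\t.\tID=e2;Parent=m1",
    "chr1\t.\tmRNA\t100\t500\t.\t+\t.\tID=m2;Parent=g1",
    paste0("chr1\t.\texon\t", c(100, 150, 250, 350, 450),
           "\t", c(120, 180, 300, 400, 500),
           "\t.\t+\t.\tID=e", 3:7, ";Parent=m2"),
    "chr0\t.\tgene\t10\t90\t.\t-\t.\tID=g0",
    "chr0\t.\tmRNA\t10\t90\t.\t-\t.\tID=m0;Parent=g0",
    "chr0\t.\texon\t10\t50\t.\t-\t.\tID=e0;Parent=m0",
    "chr0\t.\texon\t60\t90\t.\t-\t.\tID=e0b;Parent=m0",
    "chr0\t.\texon\t55\t58\t.\t-\t.\tID=e0c;Parent=m0"
  ), f)
  loci <- read_gff3(f)
  ## sorted chromosome-major
  expect_identical(loci$gene_id, c("g0", "g1"))
  expect_identical(loci$exon_count, c(3L, 5L))
  expect_identical(loci$strand, c("-", "+"))
})

test_that("GFF3 exon with unresolvable Parent errors with context", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\t.\tgene\t100\t500\t.\t+\t.\tID=g1",
    "chr1\t.\tmRNA\t100\t500\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\t.\texon\t100\t200\t.\t+\t.\tID=e1;Parent=ghost"
  ), f)
  expect_error(read_gff3(f), "unresolvable Parent.*ghost")
})

test_that("gene loci round-trip through GFF3", {
  loci <- make_loci(start = c(100L, 9000L, 30000L),
                    end = c(2000L, 12000L, 33000L),
                    is_nbs = c(TRUE, FALSE, TRUE),
                    exon_count = c(3L, 1L, 7L))
  loci$strand <- c("+", "-", "+")
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(loci, f)
  back <- read_gff3(f)
  cols <- c("gene_id", "chrom", "start", "end", "strand", "exon_count")
  expect_equal(back[, cols], loci[, cols], ignore_attr = TRUE)
})

test_that("domain table maps Pfam accessions to kinds", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\taccession\tstart\tend\tscore",
               "p1\tPF00931\t200\t480\t1e-30",
               "p1\tPF01582\t5\t150\t1e-10",
               "p2\tPF05659\t3\t60\t2",
               "p2\tPF01344\t100\t140\t2"), f)
  hits <- read_domain_table(f)
  expect_identical(hits$kind, c("NBS", "TIR", "RPW8", "KELCH"))
  expect_identical(hits$start[1], 200L)
})

test_that("domain table rejects inverted coordinates and unknowns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\taccession\tstart\tend\tscore",
               "p1\tPF00931\t480\t200\t1"), f)
  expect_error(read_domain_table(f), "start > end")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\taccession\tstart\tend\tscore",
               "p1\tPF99999\t1\t10\t1"), f2)
  expect_error(read_domain_table(f2), "unknown accession")
  expect_identical(nrow(read_domain_table(f2, on_unknown = "drop")), 0L)
  mapped <- read_domain_table(f2, unknown_map = c(PF99999 = "LRR"))
  expect_identical(mapped$kind, "LRR")
})
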