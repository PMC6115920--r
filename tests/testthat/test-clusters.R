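test_that("two NBS genes link under both criteria", {
  ## gap 150 kb with 3 intervening non-NBS genes -> one cluster of 2
  nbs1_end <- 3100L
  fillers <- nbs1_end + c(10000L, 20000L, 30000L)
  nbs2_start <- nbs1_end + 150000L
  loci <- make_loci(start = c(100L, fillers, nbs2_start),
                    end = c(nbs1_end, fillers + 500L, nbs2_start + 3000L),
                    is_nbs = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  called <- call_clusters(loci)
  expect_identical(nrow(called$clusters), 1L)
  expect_identical(called$clusters$n_members, 2L)
})

test_that("criterion boundaries are strict for gap, inclusive for count", {
  two <- function(gap, n_int) {
    end1 <- 3100L
    start2 <- end1 + gap
    fillers <- if (n_int > 0) {
      round(seq(end1 + 100, start2 - 700, length.out = n_int))
    } else numeric(0)
    make_loci(start = c(100L, fillers, start2),
              end = c(end1, fillers + 500, start2 + 3000L),
              is_nbs = c(TRUE, rep(FALSE, n_int), TRUE))
  }
  expect_identical(nrow(call_clusters(two(199999L, 8L))$clusters), 1L)
  expect_identical(nrow(call_clusters(two(200000L, 0L))$clusters), 0L)
  expect_identical(nrow(call_clusters(two(250000L, 0L))$clusters), 0L)
  expect_identical(nrow(call_clusters(two(100000L, 9L))$clusters), 0L)
  expect_identical(nrow(call_clusters(two(100000L, 8L))$clusters), 1L)
})

test_that("cluster calling equals the brute-force oracle on toy genomes", {
  set.seed(61)
  for (i in 1:200) {
    loci <- random_toy_genome()
    called <- call_clusters(loci)
    got <- if (length(called$membership)) {
      lapply(split(names(called$membership), called$membership), sort)
    } else list()
    got <- unname(got[order(vapply(got, paste, character(1),
                                   collapse = ","))])
    want <- oracle_clusters(loci)
    expect_identical(got, want)
  }
})

test_that("clusters are invariant under coordinate translation", {
  set.seed(62)
  loci <- random_toy_genome()
  base <- call_clusters(loci)
  shifted <- loci
  shifted$start <- shifted$start + 1000000L
  shifted$end <- shifted$end + 1000000L
  expect_identical(call_clusters(shifted)$membership, base$membership)
})

test_that("tightening either criterion never adds clustered genes", {
  set.seed(63)
  for (i in 1:20) {
    loci <- random_toy_genome()
    n_base <- length(call_clusters(loci)$membership)
    for (crit in list(cluster_criteria(max_gap_bp = 100000L),
                      cluster_criteria(max_intervening = 3L),
                      cluster_criteria(100000L, 3L))) {
      expect_lte(length(call_clusters(loci, crit)$membership), n_base)
    }
  }
})

test_that("no gene belongs to two clusters and duplicates are rejected", {
  set.seed(64)
  loci <- random_toy_genome()
  called <- call_clusters(loci)
  expect_false(anyDuplicated(names(called$membership)) > 0)
  dup <- rbind(loci, loci[1, ])
  expect_error(call_clusters(dup), "duplicate")
})

test_that("cluster summaries reproduce the ratio arithmetic", {
  ## shape of the published census: 200 genes in 75 clusters of 352 total
  called <- list(clusters = data.frame(
    cluster_id = sprintf("c%d", 1:75), chrom = "chr1", start = 1L,
    end = 2L, n_members = c(rep(3L, 50), rep(2L, 25)), members = ""),
    membership = stats::setNames(rep("c", 200), sprintf("g%d", 1:200)))
  loci <- make_loci(start = seq_len(352) * 10L, end = seq_len(352) * 10L + 5L,
                    is_nbs = TRUE)
  cs <- cluster_summary(called, loci, n_chromosomes = 17)
  expect_equal(round(cs$genes_per_cluster, 1), 2.7)
  expect_equal(round(cs$clusters_per_chromosome, 1), 4.4)
  expect_equal(round(cs$pct_clustered), 57)
})

test_that("an empty cluster set yields zero ratios with the flag", {
  loci <- make_loci(start = c(1L, 500000L), end = c(100L, 500100L),
                    is_nbs = c(TRUE, TRUE))
  cs <- cluster_summary(call_clusters(loci), loci)
  expect_true(cs$degenerate)
  expect_identical(cs$genes_per_cluster, 0)
  expect_identical(cs$pct_clustered, 0)
})

test_that("exon statistics aggregate per group", {
  loci <- make_loci(start = c(1L, 100L, 200L, 300L),
                    end = c(50L, 150L, 250L, 350L), is_nbs = TRUE,
                    exon_count = c(1L, 4L, 6L, 6L))
  loci$gene_id <- c("a", "b", "c", "d")
  rec <- data.frame(protein_id = c("a", "b", "c", "d"),
                    group = c("CNL", "CNL", "TNL", "TNL"))
  es <- exon_statistics(loci, rec)
  expect_equal(es$mean[es$group == "CNL"], 2.5)
  expect_identical(es$min[es$group == "TNL"], 6L)
  empty <- exon_statistics(loci[0, ], rec[0, ])
  expect_identical(nrow(empty), 0L)
})
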