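test_that("ZOOPS EM recovers a planted motif on a small fixture", {
  seqs <- planted_motif_seqs(25, 60, "GMGGLGKTT", seed = 21)
  mods <- discover_zoops_motifs(seqs, nmotifs = 1, minw = 6, maxw = 12,
                                seed = 2, n_restarts = 6)
  expect_identical(mods[[1]]$consensus, "GMGGLGKTT")
  expect_true(all(diff(mods[[1]]$loglik) >= -1e-6))
  expect_true(all(abs(rowSums(mods[[1]]$ppm) - 1) < 1e-9))
  expect_true(all(mods[[1]]$ppm > 0))
})

test_that("identical sequences give identically aligned occurrences", {
  seqs <- stats::setNames(rep(paste(rep(AA20_FIX, 3), collapse = ""), 10),
                          paste0("i", 1:10))
  mods <- discover_zoops_motifs(seqs, nmotifs = 1, minw = 6, maxw = 8,
                                seed = 1, n_restarts = 3)
  occ <- mods[[1]]$occurrences
  expect_identical(nrow(occ), 10L)
  expect_length(unique(occ$start), 1L)
})

test_that("fixing the occurrence prior at 1 degenerates ZOOPS to OOPS", {
  seqs <- planted_motif_seqs(20, 60, "GMGGLGKTT", seed = 22)
  mods <- discover_zoops_motifs(seqs, nmotifs = 1, minw = 9, maxw = 9,
                                seed = 3, n_restarts = 5,
                                gamma = 1 - 1e-9, trim_ic = 0)
  ## OOPS: exactly one occurrence per sequence
  expect_identical(nrow(mods[[1]]$occurrences), length(seqs))
  expect_equal(mods[[1]]$zoops_gamma, 1 - 1e-9)
})

test_that("the maxsize guard and short-input errors fire", {
  seqs <- stats::setNames(c(strrep("A", 60), strrep("C", 60)), c("a", "b"))
  expect_error(discover_zoops_motifs(seqs, maxsize = 100), "maxsize")
  short <- stats::setNames(c("AC", "CA"), c("a", "b"))
  expect_error(discover_zoops_motifs(short, minw = 6), "shorter than minw")
  expect_error(discover_zoops_motifs(seqs["a"]), "at least 2")
})

test_that("motif scanning matches a brute-force per-offset oracle", {
  set.seed(31)
  catalog <- default_motif_catalog()
  for (rep in 1:20) {
    seq <- random_protein(sample(50:200, 1))
    ## spike in real motif content half the time
    if (rep %% 2 == 0) {
      seq <- paste0(substr(seq, 1, 20), "VLDDVW", "TSR", "GLPLA",
                    substr(seq, 30, nchar(seq)))
    }
    hits <- scan_known_motifs(seq, catalog)
    for (nm in names(catalog)) {
      got <- hits[hits$motif == nm, c("start", "matched")]
      want <- oracle_scan_pattern(seq, catalog[[nm]])
      if (is.null(want)) {
        expect_identical(nrow(got), 0L)
      } else {
        expect_equal(got$start, want$start)
        expect_identical(got$matched, want$matched)
      }
    }
  }
})

test_that("scan hits shift with prepended flanking residues", {
  seq <- paste0(random_protein(40), "VLDDVWN", random_protein(40))
  h1 <- scan_known_motifs(seq)
  flank <- strrep("G", 10)   # G is inert for the Kinase-2 pattern
  h2 <- scan_known_motifs(paste0(flank, seq))
  k1 <- h1[h1$motif == "Kinase-2", ]
  k2 <- h2[h2$motif == "Kinase-2", ]
  expect_identical(k2$start, k1$start + 10L)
  expect_identical(k2$matched, k1$matched)
})

test_that("empty catalog yields an empty hit table", {
  out <- scan_known_motifs("MKVLDDVWN", list())
  expect_identical(nrow(out), 0L)
})

test_that("Kinase-2 signatures are extracted from the DD dyad", {
  cases <- list(
    list(seq = paste0("AAAA", "VLDDVWDK", "AAAA"), want = "DDVW"),
    list(seq = paste0("AAAA", "VLDDVDNE", "AAAA"), want = "DDVD"),
    list(seq = paste0("AAAA", "VLDDVRKE", "AAAA"), want = "DDVR"))
  for (cs in cases) {
    hits <- scan_known_motifs(cs$seq)
    sig <- extract_signatures(cs$seq, hits)
    expect_identical(sig$kinase2, cs$want)
  }
})

test_that("missing Kinase-2 hits give an absent signature", {
  seq <- strrep("A", 30)
  sig <- extract_signatures(seq, scan_known_motifs(seq))
  expect_identical(sig$kinase2, NA_character_)
  expect_identical(sig$rnbsb, NA_character_)
})

test_that("RNBS-B signatures distinguish CC and TIR lineages", {
  s1 <- paste0(strrep("A", 10), "TSR", strrep("A", 10))
  s2 <- paste0(strrep("A", 10), "TTRD", strrep("A", 10))
  expect_identical(extract_signatures(s1, scan_known_motifs(s1))$rnbsb,
                   "TSR")
  expect_identical(extract_signatures(s2, scan_known_motifs(s2))$rnbsb,
                   "TTRD")
})
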