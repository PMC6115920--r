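test_that("LxxLxxLxx counting is greedy and non-overlapping", {
  expect_identical(count_lrr_signatures("LAALAALAA"), 1L)
  expect_identical(count_lrr_signatures("LAALAALAALAALAALAA"), 2L)
  expect_identical(count_lrr_signatures("AAAA"), 0L)
  expect_identical(count_lrr_signatures(strrep("LAALAALAA", 5)), 5L)
  ## overlapping candidates resolve left-to-right
  expect_identical(count_lrr_signatures("LLAALAALAALAA"), 1L)
  expect_identical(lrr_signature_positions("AALAALAALAA"), 3L)
})

test_that("architectures order merged hits by start", {
  h <- data.frame(protein_id = "p", kind = c("CC", "NBS"),
                  start = c(5L, 200L), end = c(40L, 480L), score = 1)
  a <- build_architecture("p", h, 12L)
  expect_identical(a$letters, "CN")
  expect_true(a$has_lrr)
  h2 <- data.frame(protein_id = "p", kind = c("TIR", "NBS", "NBS"),
                   start = c(10L, 220L, 600L), end = c(170L, 500L, 880L),
                   score = 1)
  expect_identical(build_architecture("p", h2, 4L)$letters, "TNN")
})

test_that("overlapping same-kind hits merge to their interval union", {
  set.seed(51)
  for (i in 1:50) {
    n <- sample(1:6, 1)
    st <- sample(1:400, n)
    en <- st + sample(20:150, n, replace = TRUE)
    h <- data.frame(protein_id = "p", kind = "NBS", start = st, end = en,
                    score = 1)
    a <- build_architecture("p", h, 0L)
    ## oracle: union via position cover
    cover <- rep(FALSE, max(en))
    for (k in seq_len(n)) cover[st[k]:en[k]] <- TRUE
    n_blocks <- sum(diff(c(FALSE, cover)) == 1)
    expect_identical(nchar(a$letters), n_blocks)
    expect_identical(unique(strsplit(a$letters, "")[[1]]), "N")
  }
})

test_that("classification follows the letter-code table", {
  mk <- function(letters, lrr) {
    kinds <- c(C = "CC", T = "TIR", R = "RPW8", N = "NBS")
    ls <- strsplit(letters, "")[[1]]
    h <- data.frame(protein_id = "p", kind = unname(kinds[ls]),
                    start = seq_along(ls) * 100L,
                    end = seq_along(ls) * 100L + 50L, score = 1)
    classify_architecture(build_architecture("p", h, lrr))
  }
  expect_identical(mk("CN", 3L), list(group = "CNL", subgroup = "CNL",
                                      letters = "CN"))
  expect_identical(mk("TN", 0L)$subgroup, "TN")
  expect_identical(mk("TN", 0L)$group, "TNL")
  expect_identical(mk("RCN", 2L), list(group = "RNL", subgroup = "RCNL",
                                       letters = "RCN"))
  expect_identical(mk("CTN", 1L), list(group = "TNL", subgroup = "CTNL",
                                       letters = "CTN"))
  expect_identical(mk("N", 0L), list(group = "NL", subgroup = "N",
                                     letters = "N"))
  expect_identical(mk("NN", 5L)$subgroup, "NNL")
  expect_identical(mk("RN", 0L)$subgroup, "RN")
  ## an architecture outside the table is surfaced, not silently dropped
  expect_identical(mk("CCN", 0L)$subgroup, "unclassified_architecture")
})

test_that("proteins without an NBS domain are rejected by classification", {
  h <- data.frame(protein_id = "p", kind = "TIR", start = 1L, end = 100L,
                  score = 1)
  a <- build_architecture("p", h, 0L)
  expect_error(classify_architecture(a), "no NBS domain")
})

test_that("TNLTNL needs LRR blocks after each unit", {
  h <- data.frame(protein_id = "p", kind = c("TIR", "NBS", "TIR", "NBS"),
                  start = c(1L, 100L, 400L, 500L),
                  end = c(80L, 300L, 480L, 700L), score = 1)
  a <- build_architecture("p", h, 4L)
  ## LRR between the units (at 320) and after the second (at 720)
  expect_identical(classify_architecture(a, c(320L, 720L))$subgroup,
                   "TNLTNL")
  ## LRR only after the tail: the doubled code does not apply
  expect_identical(classify_architecture(a, 720L)$subgroup,
                   "unclassified_architecture")
})

test_that("NL subtyping follows the Kinase-2 signature", {
  expect_identical(subtype_nl("NL", "DDVW"), "N_CC")
  expect_identical(subtype_nl("NL", "DDVD"), "N_TIR")
  expect_identical(subtype_nl("NL", NA_character_), "unassigned")
  expect_identical(subtype_nl("NL", "DDVR"), "unassigned")
  expect_error(subtype_nl("CNL", "DDVW"), "NL")
})

test_that("every NBS protein maps to exactly one group and subgroup", {
  bp <- genome_blueprint(scale = 0.15, seed = 13)
  pr <- gen_proteome(bp)
  cls <- classify_proteins(pr$proteins, pr$domains)
  rec <- cls$records
  expect_identical(nrow(rec) + nrow(cls$excluded),
                   length(unique(pr$domains$protein_id)))
  expect_false(any(is.na(rec$group)))
  expect_false(any(is.na(rec$subgroup)))
  ## group totals equal the sum of their subgroup totals
  for (g in unique(rec$group)) {
    expect_identical(sum(rec$group == g),
                     sum(rec$group == g & nzchar(rec$subgroup)))
  }
  ## subgroup letter content is consistent with the group dominance rule
  real <- rec[rec$subgroup != "unclassified_architecture", ]
  expect_true(all(ifelse(grepl("T", real$subgroup), real$group == "TNL",
                  ifelse(grepl("R", real$subgroup), real$group == "RNL",
                  ifelse(grepl("C", real$subgroup), real$group == "CNL",
                         real$group == "NL")))))
})
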