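## Pairwise Ka/Ks by the Nei-Gojobori (1986) method: fractional synonymous
## and nonsynonymous site counts, equal-weight averaging over minimal
## mutational pathways, and Jukes-Cantor correction.

NT4 <- c("A", "C", "G", "T")

codon_aa <- local({
  tab <- NULL
  function(codon) {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    unname(tab[codon])
  }
})

is_sense_codon <- function(codon) {
  !is.na(codon_aa(codon)) && codon_aa(codon) != "*"
}

#' Synonymous and nonsynonymous site counts of one codon
#'
#' Each of the 9 single-nucleotide mutations of the codon contributes 1/3
#' of a synonymous site at its position when it yields a synonymous sense
#' codon; mutations to stop codons count as nonsynonymous. `n = 3 - s`.
#'
#' @param codon A sense codon (3-letter ACGT string).
#' @return Named numeric vector `c(n = ..., s = ...)`.
#' @export
count_sites <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    stop("not an ACGT codon: ", codon)
  }
  if (!is_sense_codon(codon)) stop("stop codon has no site counts: ", codon)
  aa <- codon_aa(codon)
  nt <- strsplit(codon, "", fixed = TRUE)[[1]]
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(NT4, nt[pos])) {
      mut <- nt
      mut[pos] <- alt
      mcodon <- paste(mut, collapse = "")
      if (is_sense_codon(mcodon) && codon_aa(mcodon) == aa) s <- s + 1 / 3
    }
  }
  c(n = 3 - s, s = s)
}

## permutations of 1..k (k <= 3)
perms_upto3 <- function(k) {
  switch(k,
         list(1L),
         list(c(1L, 2L), c(2L, 1L)),
         list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

## nd/sd for one codon pair, averaged over minimal mutational pathways;
## pathways through stop codons are excluded unless every pathway passes
## through one (then a step to or from a stop counts as nonsynonymous)
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(nd = 0, sd = 0))
  n1 <- strsplit(c1, "", fixed = TRUE)[[1]]
  n2 <- strsplit(c2, "", fixed = TRUE)[[1]]
  diff_pos <- which(n1 != n2)
  paths <- perms_upto3(length(diff_pos))
  res <- lapply(paths, function(ord) {
    cur <- n1
    nd <- 0; sd <- 0; through_stop <- FALSE
    for (p in diff_pos[ord]) {
      nxt <- cur
      nxt[p] <- n2[p]
      a1 <- codon_aa(paste(cur, collapse = ""))
      a2 <- codon_aa(paste(nxt, collapse = ""))
      if (a1 == "*" || a2 == "*") {
        through_stop <- TRUE
        nd <- nd + 1
      } else if (a1 == a2) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    list(nd = nd, sd = sd, through_stop = through_stop)
  })
  ok <- !vapply(res, `[[`, logical(1), "through_stop")
  use <- if (any(ok)) res[ok] else res
  c(nd = mean(vapply(use, `[[`, numeric(1), "nd")),
    sd = mean(vapply(use, `[[`, numeric(1), "sd")))
}

## memoized views of the per-codon quantities (61 sense codons, 61^2 pairs)
.kaks_cache <- new.env(parent = emptyenv())

count_sites_cached <- function(codon) {
  v <- .kaks_cache[[codon]]
  if (is.null(v)) {
    v <- count_sites(codon)
    .kaks_cache[[codon]] <- v
  }
  v
}

codon_pair_diffs_cached <- function(c1, c2) {
  key <- paste0(c1, c2)
  v <- .kaks_cache[[key]]
  if (is.null(v)) {
    v <- codon_pair_diffs(c1, c2)
    .kaks_cache[[key]] <- v
  }
  v
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  if (p == 0) return(0)   # avoid IEEE negative zero
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Ka and Ks by Nei-Gojobori with Jukes-Cantor correction
#'
#' Site counts are averaged over the two sequences; codons containing
#' non-ACGT characters or coding a stop in either sequence are excluded
#' pairwise. Multi-nucleotide codon differences are averaged over all
#' minimal mutational pathways, excluding pathways through stop codons
#' unless all pass through one. `Ka = -(3/4) log(1 - (4/3) pN)` and
#' likewise for Ks; a proportion at or above 0.75 leaves the corrected
#' value undefined (`NA`) with the `saturated` flag set.
#'
#' @param seq_a,seq_b Equal-length in-frame gap-free coding sequences.
#' @param id_a,id_b Ids recorded in the result.
#' @return Object of class `kaks_result`: `N_sites`, `S_sites`, `Nd`,
#'   `Sd`, `pN`, `pS`, `Ka`, `Ks`, `ratio` (`NA` when `Ks` is 0 or
#'   undefined), `n_codons_used`, `n_codons_skipped`, `saturated`.
#' @export
pairwise_kaks <- function(seq_a, seq_b, id_a = "a", id_b = "b") {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences differ in length")
  if (nchar(seq_a) %% 3L != 0L) stop("alignment length not divisible by 3")
  nc <- nchar(seq_a) / 3L
  starts <- 3L * seq_len(nc) - 2L
  ca <- substring(seq_a, starts, starts + 2L)
  cb <- substring(seq_b, starts, starts + 2L)
  usable <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb) &
    vapply(ca, is_sense_codon, logical(1)) &
    vapply(cb, is_sense_codon, logical(1))
  if (!any(usable)) stop("no comparable codons between ", id_a, " and ", id_b)
  Na <- 0; Sa <- 0; Nb <- 0; Sb <- 0; Nd <- 0; Sd <- 0
  for (i in which(usable)) {
    sa <- count_sites_cached(ca[i]); sb <- count_sites_cached(cb[i])
    Na <- Na + sa["n"]; Sa <- Sa + sa["s"]
    Nb <- Nb + sb["n"]; Sb <- Sb + sb["s"]
    d <- codon_pair_diffs_cached(ca[i], cb[i])
    Nd <- Nd + d["nd"]; Sd <- Sd + d["sd"]
  }
  N <- (Na + Nb) / 2
  S <- (Sa + Sb) / 2
  pN <- Nd / N
  pS <- Sd / S
  Ka <- jc_correct(pN)
  Ks <- jc_correct(pS)
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  structure(list(
    id_a = id_a, id_b = id_b,
    N_sites = unname(N), S_sites = unname(S),
    Nd = unname(Nd), Sd = unname(Sd),
    pN = unname(pN), pS = unname(pS),
    Ka = unname(Ka), Ks = unname(Ks), ratio = ratio,
    n_codons_used = sum(usable), n_codons_skipped = sum(!usable),
    saturated = (pN >= 0.75) || (pS >= 0.75)
  ), class = "kaks_result")
}

#' Average Ka/Ks ratio over a clade's pairs
#'
#' Arithmetic mean of the defined ratios; pairs with an undefined ratio
#' (Ks of 0 or a saturated proportion) are excluded and counted.
#'
#' @param results List of `kaks_result` objects for all within-clade pairs.
#' @return List `mean_ratio`, `n_used`, `n_excluded`.
#' @export
clade_average <- function(results) {
  ratios <- vapply(results, function(r) r$ratio, numeric(1))
  ok <- !is.na(ratios)
  if (!any(ok)) stop("all pairs have undefined Ka/Ks ratios")
  list(mean_ratio = mean(ratios[ok]), n_used = sum(ok),
       n_excluded = sum(!ok))
}

#' Ka/Ks over all within-clade pairs of a CDS set
#'
#' @param cds Named character vector of equal-frame coding sequences (the
#'   members of one clade, pre-aligned and gap-free).
#' @param clades Named character vector gene_id -> clade label; pairs are
#'   formed within each clade.
#' @return Data.frame with one row per pair and all intermediate
#'   quantities.
#' @export
kaks_pairs_table <- function(cds, clades) {
  stopifnot(!is.null(names(cds)), !is.null(names(clades)))
  rows <- list()
  for (cl in unique(clades)) {
    ids <- intersect(names(cds), names(clades)[clades == cl])
    if (length(ids) < 2L) next
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        r <- pairwise_kaks(cds[[ids[i]]], cds[[ids[j]]], ids[i], ids[j])
        rows[[length(rows) + 1L]] <- data.frame(
          clade = cl, id_a = r$id_a, id_b = r$id_b,
          N_sites = r$N_sites, S_sites = r$S_sites, Nd = r$Nd, Sd = r$Sd,
          pN = r$pN, pS = r$pS, Ka = r$Ka, Ks = r$Ks, ratio = r$ratio,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(clade = character(0), id_a = character(0),
                      id_b = character(0), N_sites = numeric(0),
                      S_sites = numeric(0), Nd = numeric(0), Sd = numeric(0),
                      pN = numeric(0), pS = numeric(0), Ka = numeric(0),
                      Ks = numeric(0), ratio = numeric(0)))
  }
  do.call(rbind, rows)
}
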