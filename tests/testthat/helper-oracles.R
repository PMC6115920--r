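## Independent brute-force oracles. These deliberately share no code with
## the package implementation.

## --- cluster-calling oracle -------------------------------------------
## explicit pair-linkage test between every pair of consecutive NBS genes
oracle_clusters <- function(loci, max_gap = 200000L, max_int = 8L) {
  loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
  groups <- list()
  for (ch in unique(loci$chrom)) {
    d <- loci[loci$chrom == ch, , drop = FALSE]
    nbs_rows <- which(d$is_nbs)
    if (length(nbs_rows) < 2L) next
    comp <- seq_along(nbs_rows)   # connected components over NBS genes
    for (k in seq_len(length(nbs_rows) - 1L)) {
      a <- nbs_rows[k]
      b <- nbs_rows[k + 1L]
      gap <- d$start[b] - d$end[a]
      if (gap < 0) gap <- 0
      n_between <- 0L
      for (r in seq_len(nrow(d))) {
        if (r > a && r < b && !d$is_nbs[r]) n_between <- n_between + 1L
      }
      if (gap < max_gap && n_between <= max_int) {
        comp[comp == comp[k + 1L]] <- comp[k]
      }
    }
    for (cc in unique(comp)) {
      ids <- d$gene_id[nbs_rows[comp == cc]]
      if (length(ids) >= 2L) groups[[length(groups) + 1L]] <- sort(ids)
    }
  }
  groups[order(vapply(groups, paste, character(1), collapse = ","))]
}

## --- Nei-Gojobori oracle ----------------------------------------------
## literal re-derivation: explicit mutant enumeration for sites, explicit
## path recursion for differences, no shared helpers
oracle_ng86 <- function(sa, sb) {
  code <- Biostrings::GENETIC_CODE
  translate1 <- function(cd) unname(code[cd])
  nts <- c("A", "C", "G", "T")
  site_s <- function(cd) {
    ref_aa <- translate1(cd)
    tot <- 0
    for (p in 1:3) {
      for (b in nts) {
        if (b == substr(cd, p, p)) next
        mut <- cd
        substr(mut, p, p) <- b
        if (!is.na(translate1(mut)) && translate1(mut) != "*" &&
            translate1(mut) == ref_aa) {
          tot <- tot + 1 / 3
        }
      }
    }
    tot
  }
  path_steps <- function(from, to) {
    ## returns list of (nd, sd, stop_seen) over every orderings
    ps <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (length(ps) == 0L) return(list(c(0, 0, 0)))
    out <- list()
    for (p in ps) {
      step <- from
      substr(step, p, p) <- substr(to, p, p)
      a1 <- translate1(from)
      a2 <- translate1(step)
      stopped <- as.numeric(a1 == "*" || a2 == "*")
      this_nd <- as.numeric(stopped == 1 || a1 != a2)
      this_sd <- as.numeric(stopped == 0 && a1 == a2)
      for (rest in path_steps(step, to)) {
        out[[length(out) + 1L]] <- c(this_nd + rest[1], this_sd + rest[2],
                                     max(stopped, rest[3]))
      }
    }
    out
  }
  n_cod <- nchar(sa) / 3
  N <- 0; S <- 0; Nd <- 0; Sd <- 0
  for (i in seq_len(n_cod)) {
    ca <- substr(sa, 3 * i - 2, 3 * i)
    cb <- substr(sb, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (translate1(ca) == "*" || translate1(cb) == "*") next
    ssa <- site_s(ca); ssb <- site_s(cb)
    S <- S + (ssa + ssb) / 2
    N <- N + (3 - ssa + 3 - ssb) / 2
    paths <- path_steps(ca, cb)
    clean <- Filter(function(v) v[3] == 0, paths)
    use <- if (length(clean)) clean else paths
    Nd <- Nd + mean(vapply(use, `[`, numeric(1), 1))
    Sd <- Sd + mean(vapply(use, `[`, numeric(1), 2))
  }
  pn <- Nd / N
  ps_ <- Sd / S
  jc <- function(p) if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pn, pS = ps_,
       Ka = jc(pn), Ks = jc(ps_))
}

## --- HMM oracles -------------------------------------------------------
## joint log-probability of one state path (states coded 1/2)
oracle_path_logprob <- function(seq, hmm, path) {
  idx <- match(strsplit(seq, "")[[1]], AA20_FIX)
  lp <- log(hmm$init[path[1]]) + log(hmm$emit[path[1], idx[1]])
  for (t in seq_along(idx)[-1]) {
    lp <- lp + log(hmm$trans[path[t - 1], path[t]]) +
      log(hmm$emit[path[t], idx[t]])
  }
  lp
}

## exhaustive enumeration of all 2^L paths
oracle_viterbi <- function(seq, hmm) {
  L <- nchar(seq)
  grid <- as.matrix(expand.grid(rep(list(1:2), L)))
  lps <- apply(grid, 1, function(p) oracle_path_logprob(seq, hmm, p))
  list(path = unname(grid[which.max(lps), ]),
       loglik = max(lps),
       total = log(sum(exp(lps - max(lps)))) + max(lps))
}

## --- motif-scan oracle -------------------------------------------------
## try the pattern anchored at every single offset, then pick
## non-overlapping hits best-score-first (score = match length)
oracle_scan_pattern <- function(seq, pattern) {
  L <- nchar(seq)
  cand <- NULL
  for (i in seq_len(L)) {
    m <- regmatches(substr(seq, i, L),
                    regexpr(paste0("^(", pattern, ")"), substr(seq, i, L),
                            perl = TRUE))
    if (length(m)) {
      cand <- rbind(cand, data.frame(start = i, matched = m,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(cand)) return(cand)
  cand <- cand[order(-nchar(cand$matched), cand$start), , drop = FALSE]
  used <- rep(FALSE, L)
  keep <- c()
  for (r in seq_len(nrow(cand))) {
    span <- cand$start[r]:(cand$start[r] + nchar(cand$matched[r]) - 1L)
    if (!any(used[span])) {
      keep <- c(keep, r)
      used[span] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}
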