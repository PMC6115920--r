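## Motif discovery (ZOOPS expectation-maximization) and scanning of the
## short conserved NLR motifs: P-loop, Kinase-2, RNBS A-D, GLPL, MHDL.

#' Default curated motif patterns
#'
#' Regex-style patterns for the conserved NB-ARC motifs, used by
#' [scan_known_motifs()] when no fitted motif models are supplied. The
#' RNBS-B entry is the signature region itself, so the matched string is the
#' signature (TSR in CC-lineage proteins, TTRD in TIR-lineage ones).
#'
#' @return Named list of patterns.
#' @export
default_motif_catalog <- function() {
  list(
    `P-loop`   = "G[GAV].{2}G[KR][TS]T",
    `Kinase-2` = "[LIVMF]{2}DD[VIML][WDR]",
    `RNBS-B`   = "TTRD|TSR",
    GLPL       = "G[LIVM]PL[AG]",
    MHDL       = "[MQ]HD[LV]"
  )
}

## residues -> integer codes 1..20 (X and anything else -> NA)
aa_index <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], AA20)
}

## motif-vs-background log-odds of every width-w window of integer-coded x;
## NA where the window touches an unknown or masked residue
window_log_odds <- function(x, logodds_mat, masked = NULL) {
  w <- nrow(logodds_mat)
  n <- length(x) - w + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (t in seq_len(w)) {
    s <- s + logodds_mat[t, x[t:(t + n - 1L)]]
  }
  if (!is.null(masked) && any(masked)) {
    bad <- which(masked)
    for (j in bad) {
      lo <- max(1L, j - w + 1L)
      hi <- min(n, j)
      if (lo <= hi) s[lo:hi] <- NA_real_
    }
  }
  s
}

log_sum_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

## Single ZOOPS EM run at fixed width w. xs: list of integer-coded
## sequences; masks: list of logical vectors (TRUE = unavailable).
## Returns ppm, gamma, loglik trace and per-sequence occurrence posteriors.
zoops_em_run <- function(xs, masks, w, ppm0, background, gamma0,
                         pseudocount, tol, max_iter, fix_gamma = FALSE) {
  nseq <- length(xs)
  logbg <- log(background)
  ppm <- ppm0
  gamma <- gamma0
  trace <- numeric(0)
  z_list <- vector("list", nseq)
  bg_const <- vapply(xs, function(x) sum(logbg[x[!is.na(x)]]), numeric(1))
  onehot <- lapply(xs, function(x) {
    H <- matrix(0, nrow = length(x), ncol = 20L)
    ok <- which(!is.na(x))
    H[cbind(ok, x[ok])] <- 1
    H
  })
  for (iter in seq_len(max_iter)) {
    lom <- log(ppm) - matrix(logbg, nrow = w, ncol = 20L, byrow = TRUE)
    counts <- matrix(pseudocount, nrow = w, ncol = 20L)
    gamma_sum <- 0
    n_contrib <- 0L
    ll <- 0
    for (i in seq_len(nseq)) {
      x <- xs[[i]]
      lam <- window_log_odds(x, lom, masks[[i]])
      J <- which(!is.na(lam))
      if (length(J) == 0L) {
        ll <- ll + bg_const[i]
        z_list[[i]] <- numeric(0)
        next
      }
      n_contrib <- n_contrib + 1L
      lv <- log(gamma) - log(length(J)) + lam[J]
      lz <- log_sum_exp(c(log1p(-gamma), lv))
      ll <- ll + bg_const[i] + lz
      z <- exp(lv - lz)
      z_list[[i]] <- stats::setNames(z, J)
      gamma_sum <- gamma_sum + sum(z)
      H <- onehot[[i]]
      for (t in seq_len(w)) {
        counts[t, ] <- counts[t, ] +
          crossprod(z, H[J + t - 1L, , drop = FALSE])[1L, ]
      }
    }
    trace <- c(trace, ll)
    if (iter > 1L &&
        (ll - trace[iter - 1L]) < tol * (abs(trace[iter - 1L]) + 1)) {
      break
    }
    ppm <- counts / rowSums(counts)
    if (!fix_gamma && n_contrib > 0L) {
      gamma <- min(max(gamma_sum / n_contrib, 1e-4), 1 - 1e-4)
    }
  }
  list(ppm = ppm, gamma = gamma, loglik = trace, z = z_list)
}

## seed a ppm from one window of the data (0.5 mass on the observed residue)
seed_ppm <- function(xs, masks, w) {
  ok <- which(vapply(seq_along(xs), function(i) {
    lam <- window_log_odds(xs[[i]], matrix(0, w, 20L), masks[[i]])
    any(!is.na(lam))
  }, logical(1)))
  if (length(ok) == 0L) return(NULL)
  i <- ok[sample.int(length(ok), 1L)]
  lam <- window_log_odds(xs[[i]], matrix(0, w, 20L), masks[[i]])
  j <- sample(which(!is.na(lam)), 1L)
  win <- xs[[i]][j:(j + w - 1L)]
  ppm <- matrix(0.5 / 19, nrow = w, ncol = 20L)
  for (t in seq_len(w)) {
    if (is.na(win[t])) ppm[t, ] <- 1 / 20 else ppm[t, win[t]] <- 0.5
  }
  ppm
}

#' Discover motifs by ZOOPS expectation-maximization
#'
#' Iteratively fits one "zero-or-one occurrence per sequence" motif by EM
#' (E-step: per-sequence posterior over start positions plus an absent state
#' weighted by the occurrence prior gamma; M-step: pseudocounted position
#' probability matrix and gamma update), masks the best occurrences, and
#' repeats. Motif width is selected over `minw:maxw` by a BIC-penalized
#' log-likelihood; each candidate width is explored with `n_restarts` short
#' seeded runs and the best is refined to convergence. The per-motif EM
#' log-likelihood trace is non-decreasing.
#'
#' @param seqs Named character vector of protein sequences.
#' @param nmotifs Number of motifs to extract.
#' @param minw,maxw Width range searched.
#' @param seed Integer seed for restart initialization.
#' @param n_restarts Seeded restarts per width.
#' @param gamma Fixed occurrence prior; `NULL` (default) learns it. Setting
#'   `gamma = 1` with `fix_gamma` semantics degenerates ZOOPS to OOPS.
#' @param pseudocount Dirichlet pseudocount for the PPM.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap for the refinement run.
#' @param maxsize Guard on total dataset residues.
#' @param trim_ic Information-content threshold (bits) below which edge
#'   columns of the refined motif are trimmed (down to `minw`); the motif
#'   is then re-fit at the trimmed width. Set to 0 to disable.
#' @return List of motif models; each has `name`, `width`, `ppm`,
#'   `background`, `zoops_gamma`, `loglik` (trace), `consensus` and an
#'   `occurrences` data.frame.
#' @export
discover_zoops_motifs <- function(seqs, nmotifs = 20L, minw = 6L, maxw = 25L,
                                  seed = 1L, n_restarts = 10L, gamma = NULL,
                                  pseudocount = 0.1, tol = 1e-6,
                                  max_iter = 200L, maxsize = 100000L,
                                  trim_ic = 1) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (sum(nchar(seqs)) > maxsize) {
    stop("dataset has ", sum(nchar(seqs)), " residues, exceeding maxsize = ",
         maxsize)
  }
  if (all(nchar(seqs) < minw)) stop("all sequences shorter than minw")
  set.seed(seed)
  xs <- lapply(seqs, aa_index)
  masks <- lapply(xs, function(x) rep(FALSE, length(x)))
  known <- unlist(xs, use.names = FALSE)
  known <- known[!is.na(known)]
  background <- (tabulate(known, 20L) + 1) / (length(known) + 20)
  fix_gamma <- !is.null(gamma)
  gamma0 <- if (fix_gamma) gamma else 0.5
  models <- list()
  for (k in seq_len(nmotifs)) {
    best <- NULL
    for (w in seq(minw, maxw)) {
      for (r in seq_len(n_restarts)) {
        ppm0 <- seed_ppm(xs, masks, w)
        if (is.null(ppm0)) next
        fit <- zoops_em_run(xs, masks, w, ppm0, background, gamma0,
                            pseudocount, tol = 1e-3, max_iter = 8L,
                            fix_gamma = fix_gamma)
        ll <- fit$loglik[length(fit$loglik)]
        score <- ll - 0.5 * (19 * w) * log(length(xs))
        if (is.null(best) || score > best$score) {
          best <- list(w = w, fit = fit, score = score)
        }
      }
    }
    if (is.null(best)) break
    w <- best$w
    fit <- zoops_em_run(xs, masks, w, best$fit$ppm, background,
                        best$fit$gamma, pseudocount, tol, max_iter,
                        fix_gamma = fix_gamma)
    ## trim uninformative edge columns and re-fit at the trimmed width
    if (trim_ic > 0) {
      ic <- rowSums(fit$ppm * log2(sweep(fit$ppm, 2L, background, "/")))
      lo <- 1L; hi <- w
      while (hi - lo + 1L > minw && ic[lo] < trim_ic) lo <- lo + 1L
      while (hi - lo + 1L > minw && ic[hi] < trim_ic) hi <- hi - 1L
      if (lo > 1L || hi < w) {
        w <- hi - lo + 1L
        fit <- zoops_em_run(xs, masks, w,
                            fit$ppm[lo:hi, , drop = FALSE], background,
                            fit$gamma, pseudocount, tol, max_iter,
                            fix_gamma = fix_gamma)
      }
    }
    ## occurrences: best window where the presence posterior exceeds 1/2
    occ <- do.call(rbind, lapply(seq_along(xs), function(i) {
      z <- fit$z[[i]]
      if (length(z) == 0L || sum(z) <= 0.5) return(NULL)
      j <- as.integer(names(z)[which.max(z)])
      data.frame(protein_id = names(seqs)[i], start = j,
                 matched = substr(seqs[[i]], j, j + w - 1L),
                 posterior = max(z), stringsAsFactors = FALSE)
    }))
    if (is.null(occ)) {
      occ <- data.frame(protein_id = character(0), start = integer(0),
                        matched = character(0), posterior = numeric(0))
    }
    ppm <- fit$ppm
    colnames(ppm) <- AA20
    model <- structure(list(
      name = paste0("motif_", k), width = w, ppm = ppm,
      background = stats::setNames(background, AA20),
      zoops_gamma = fit$gamma, loglik = fit$loglik,
      consensus = paste(AA20[apply(ppm, 1L, which.max)], collapse = ""),
      occurrences = occ, threshold = 0
    ), class = "nlr_motif_model")
    models[[k]] <- model
    ## a motif with no confident occurrence means nothing is left to mask
    if (nrow(occ) == 0L) break
    for (i in seq_len(nrow(occ))) {
      s <- match(occ$protein_id[i], names(seqs))
      masks[[s]][occ$start[i]:(occ$start[i] + w - 1L)] <- TRUE
    }
  }
  models
}

## all (possibly overlapping) regex occurrences via a zero-width lookahead
regex_occurrences <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=(", pattern, "))"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), matched = character(0)))
  }
  starts <- as.integer(m)
  lens <- attr(m, "capture.length")[, 1L]
  data.frame(start = starts,
             matched = substring(seq, starts, starts + lens - 1L),
             stringsAsFactors = FALSE)
}

## greedy non-overlapping selection by descending score, ties by leftmost
greedy_select <- function(cand) {
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(-cand$log_odds, cand$start), , drop = FALSE]
  taken <- logical(0)
  keep <- integer(0)
  occupied <- integer(0)
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:(cand$start[i] + nchar(cand$matched[i]) - 1L)
    if (!any(span %in% occupied)) {
      keep <- c(keep, i)
      occupied <- c(occupied, span)
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Scan a sequence for known motifs
#'
#' Catalog entries are either regex-style patterns (see
#' [default_motif_catalog()]) or fitted motif models from
#' [discover_zoops_motifs()]. For each motif, all non-overlapping
#' best-scoring occurrences above the per-motif threshold are reported,
#' resolved greedily by descending log-odds with ties to the leftmost
#' start. Pattern hits score by match length; model hits by PPM log-odds.
#'
#' @param seq A single protein sequence (character scalar).
#' @param catalog Named list of patterns and/or motif models.
#' @param protein_id Id recorded in the output.
#' @return Data.frame `protein_id`, `motif`, `start`, `matched`,
#'   `log_odds`, sorted by start.
#' @export
scan_known_motifs <- function(seq, catalog = default_motif_catalog(),
                              protein_id = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  out <- list()
  for (nm in names(catalog)) {
    entry <- catalog[[nm]]
    if (is.character(entry)) {
      occ <- regex_occurrences(seq, entry)
      if (nrow(occ) == 0L) next
      cand <- data.frame(motif = nm, start = occ$start, matched = occ$matched,
                         log_odds = nchar(occ$matched),
                         stringsAsFactors = FALSE)
    } else {
      w <- entry$width
      x <- aa_index(seq)
      if (length(x) < w) next
      lom <- log(entry$ppm) -
        matrix(log(entry$background), nrow = w, ncol = 20L, byrow = TRUE)
      lam <- window_log_odds(x, lom)
      thr <- if (is.null(entry$threshold)) 0 else entry$threshold
      J <- which(!is.na(lam) & lam >= thr)
      if (length(J) == 0L) next
      cand <- data.frame(motif = nm, start = J,
                         matched = substring(seq, J, J + w - 1L),
                         log_odds = lam[J], stringsAsFactors = FALSE)
    }
    sel <- greedy_select(cand)
    if (nrow(sel)) out[[nm]] <- sel
  }
  if (length(out) == 0L) {
    return(data.frame(protein_id = character(0), motif = character(0),
                      start = integer(0), matched = character(0),
                      log_odds = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- data.frame(protein_id = protein_id, res, stringsAsFactors = FALSE)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract Kinase-2 and RNBS-B signature residues
#'
#' The Kinase-2 signature is the 4 residues starting at the first D of the
#' DD dyad inside the Kinase-2 hit (DDVW marks CC-lineage, DDVD TIR-lineage
#' proteins); the RNBS-B signature is the matched residues of the RNBS-B
#' catalog entry. Fields are `NA` when the corresponding hit is missing.
#'
#' @param seq The protein sequence the hits refer to.
#' @param hits Data.frame from [scan_known_motifs()].
#' @return List with character fields `kinase2` and `rnbsb`.
#' @export
extract_signatures <- function(seq, hits) {
  kin <- hits[hits$motif == "Kinase-2", , drop = FALSE]
  kinase2 <- NA_character_
  if (nrow(kin)) {
    m <- kin$matched[1L]
    p <- regexpr("DD", m, fixed = TRUE)
    if (p < 0L) {
      warning("Kinase-2 hit without a DD dyad: ", m)
    } else {
      abs_pos <- kin$start[1L] + as.integer(p) - 1L
      sig <- substr(seq, abs_pos, abs_pos + 3L)
      if (nchar(sig) == 4L) kinase2 <- sig else
        warning("Kinase-2 DD dyad too close to the protein end")
    }
  }
  rb <- hits[hits$motif == "RNBS-B", , drop = FALSE]
  rnbsb <- if (nrow(rb)) rb$matched[1L] else NA_character_
  list(kinase2 = kinase2, rnbsb = rnbsb)
}
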