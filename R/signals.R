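## Coiled-coil propensity scoring by heptad-register scan, and nuclear
## localization signal (NLS) detection with a two-state HMM decoded by
## Viterbi or by forward-backward posteriors.

CC_HYDROPHOBIC <- c("L", "I", "V", "M", "F", "A")
CC_POLAR <- c("E", "K", "Q", "R", "D", "N", "S", "T", "H")

#' Per-residue coiled-coil probability profile
#'
#' Slides a window over the sequence and, for each of the 7 heptad register
#' phases, scores the core a/d positions (+1 for a hydrophobic residue,
#' -1 otherwise) and the flanking e/g positions (+1/2 for a polar residue,
#' -1/2 otherwise); the best phase score, normalised to \[-1, 1\], is
#' mapped through a logistic to (0, 1). The mismatch penalties keep
#' register-free sequence far below the ideal repeat: with the default
#' calibration an ideal heptad scores above 0.9 and random or poly-P
#' sequence below 0.1. Window scores are assigned to the window's center
#' residue; edges take the nearest window value.
#'
#' @param seq Protein sequence (character scalar).
#' @param window Window length; a multiple of 7 (default 21, three
#'   heptads: 6 a/d and 6 e/g scored positions).
#' @param slope,midpoint Logistic calibration on the normalised score.
#' @return Numeric vector of length `nchar(seq)` in \[0, 1\].
#' @export
cc_probability_profile <- function(seq, window = 21L, slope = 8,
                                   midpoint = 0.55) {
  stopifnot(window %% 7L == 0L)
  L <- nchar(seq)
  if (L < window) {
    warning("sequence shorter than the coiled-coil window; all-zero profile")
    return(numeric(L))
  }
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  hyd <- ifelse(ch %in% CC_HYDROPHOBIC, 1, -1)
  pol <- ifelse(ch %in% CC_POLAR, 0.5, -0.5)
  nwin <- L - window + 1L
  smax <- window / 7L * 3L   # per-window max: heptads x (2 x 1 + 2 x 1/2)
  best <- rep(-Inf, nwin)
  for (phase in 0:6) {
    reg <- (seq_len(L) - 1L + phase) %% 7L   # 0=a .. 6=g
    contrib <- hyd * (reg == 0L | reg == 3L) + pol * (reg == 4L | reg == 6L)
    cs <- c(0, cumsum(contrib))
    sc <- (cs[(window + 1L):(L + 1L)] - cs[seq_len(nwin)]) / smax
    best <- pmax(best, sc)
  }
  p <- stats::plogis(slope * (best - midpoint))
  centers <- seq_len(nwin) + (window - 1L) %/% 2L
  prof <- numeric(L)
  prof[centers] <- p
  prof[seq_len(centers[1L] - 1L)] <- p[1L]
  if (centers[nwin] < L) prof[(centers[nwin] + 1L):L] <- p[nwin]
  prof
}

#' Call a coiled-coil segment
#'
#' Returns the maximal (longest, ties to the first) run of residues whose
#' coiled-coil probability is at or above `threshold`, or `NULL` when no
#' residue qualifies. Runs shorter than `min_length` are rejected: a
#' coiled coil must sustain its register over at least one full window,
#' which suppresses isolated high-scoring windows in non-coiled sequence.
#'
#' @param seq Protein sequence.
#' @param threshold Probability threshold (default 0.4, the lower end of
#'   the accepted probability window).
#' @param min_length Minimum run length of a reportable segment.
#' @param protein_id Id recorded in the call.
#' @param ... Passed to [cc_probability_profile()].
#' @return A list (`protein_id`, `kind = "CC"`, `start`, `end`, `support`)
#'   or `NULL`.
#' @export
call_cc <- function(seq, threshold = 0.4, min_length = 21L,
                    protein_id = "seq", ...) {
  prof <- cc_probability_profile(seq, ...)
  ok <- prof >= threshold
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_length)
  if (length(runs) == 0L) return(NULL)
  pick <- runs[which.max(r$lengths[runs])]
  s <- starts[pick]; e <- ends[pick]
  list(protein_id = protein_id, kind = "CC", start = s, end = e,
       support = max(prof[s:e]))
}

#' Default two-state NLS model
#'
#' A static background/signal HMM over amino acids: the signal state is
#' enriched for lysine and arginine (emission 0.38 each, remaining mass
#' uniform), the background state is uniform; entering the signal state is
#' rare (0.005) and leaving it moderately fast (0.10). All parameters are
#' overridable by supplying a different model to [nls_decode()].
#'
#' @return List with `init` (length 2), `trans` (2x2) and `emit` (2x20)
#'   row-stochastic components, states ordered (background, signal).
#' @export
default_nls_hmm <- function() {
  emit_bg <- rep(1 / 20, 20L)
  emit_sig <- rep((1 - 2 * 0.38) / 18, 20L)
  emit_sig[match(c("K", "R"), AA20)] <- 0.38
  hmm <- list(
    init = c(background = 0.95, signal = 0.05),
    trans = matrix(c(0.995, 0.005, 0.10, 0.90), nrow = 2L, byrow = TRUE,
                   dimnames = list(c("background", "signal"),
                                   c("background", "signal"))),
    emit = matrix(c(emit_bg, emit_sig), nrow = 2L, byrow = TRUE,
                  dimnames = list(c("background", "signal"), AA20))
  )
  validate_hmm(hmm)
  hmm
}

validate_hmm <- function(hmm) {
  stopifnot(length(hmm$init) == 2L, all(dim(hmm$trans) == 2L),
            nrow(hmm$emit) == 2L, ncol(hmm$emit) == 20L)
  if (any(hmm$init <= 0) || any(hmm$trans <= 0) || any(hmm$emit <= 0)) {
    stop("HMM parameters must all be positive")
  }
  sums <- c(sum(hmm$init), rowSums(hmm$trans), rowSums(hmm$emit))
  if (any(abs(sums - 1) > 1e-9)) {
    stop("HMM probability rows must sum to 1")
  }
  invisible(TRUE)
}

## per-residue log emission matrix (2 x L); unknown residues emit the
## state's mean emission (uninformative)
hmm_log_emissions <- function(seq, hmm) {
  x <- aa_index(seq)
  le <- log(hmm$emit)
  out <- rbind(le[1L, x], le[2L, x])
  if (anyNA(x)) {
    out[1L, is.na(x)] <- log(mean(hmm$emit[1L, ]))
    out[2L, is.na(x)] <- log(mean(hmm$emit[2L, ]))
  }
  out
}

#' Decode nuclear localization signals with a two-state HMM
#'
#' `mode = "viterbi"` reports maximal runs of the signal state on the
#' maximum-probability state path; `mode = "posterior"` computes the
#' forward-backward per-residue posterior of the signal state and reports
#' maximal runs at or above `cutoff`. All arithmetic is in log space.
#'
#' @param seq Protein sequence.
#' @param hmm Model as from [default_nls_hmm()].
#' @param mode `"posterior"` or `"viterbi"`.
#' @param cutoff Posterior cutoff (default 0.5).
#' @param protein_id Id recorded in the calls.
#' @return List with `calls` (data.frame `protein_id`, `kind`, `start`,
#'   `end`, `support`), `posterior` (signal-state posterior vector),
#'   `path` (Viterbi state vector, 1 = background, 2 = signal),
#'   `loglik_forward` and `loglik_backward`.
#' @export
nls_decode <- function(seq, hmm = default_nls_hmm(),
                       mode = c("posterior", "viterbi"), cutoff = 0.5,
                       protein_id = "seq") {
  mode <- match.arg(mode)
  validate_hmm(hmm)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L == 0L) stop("empty sequence")
  le <- hmm_log_emissions(seq, hmm)
  li <- log(hmm$init)
  lt <- log(hmm$trans)

  ## forward
  fwd <- matrix(-Inf, 2L, L)
  fwd[, 1L] <- li + le[, 1L]
  for (t in seq_len(L - 1L)) {
    for (s in 1:2) {
      fwd[s, t + 1L] <- log_sum_exp(fwd[, t] + lt[, s]) + le[s, t + 1L]
    }
  }
  ll_f <- log_sum_exp(fwd[, L])

  ## backward
  bwd <- matrix(0, 2L, L)
  for (t in rev(seq_len(L - 1L))) {
    for (s in 1:2) {
      bwd[s, t] <- log_sum_exp(lt[s, ] + le[, t + 1L] + bwd[, t + 1L])
    }
  }
  ll_b <- log_sum_exp(li + le[, 1L] + bwd[, 1L])

  post <- exp(fwd + bwd - ll_f)
  post <- sweep(post, 2L, colSums(post), "/")   # guard rounding
  posterior <- post[2L, ]

  ## viterbi
  vit <- matrix(-Inf, 2L, L)
  ptr <- matrix(0L, 2L, L)
  vit[, 1L] <- li + le[, 1L]
  for (t in seq_len(L - 1L)) {
    for (s in 1:2) {
      cand <- vit[, t] + lt[, s]
      ptr[s, t + 1L] <- which.max(cand)
      vit[s, t + 1L] <- cand[ptr[s, t + 1L]] + le[s, t + 1L]
    }
  }
  path <- integer(L)
  path[L] <- which.max(vit[, L])
  for (t in rev(seq_len(L - 1L))) path[t] <- ptr[path[t + 1L], t + 1L]

  in_signal <- if (mode == "viterbi") path == 2L else posterior >= cutoff
  calls <- NULL
  if (any(in_signal)) {
    r <- rle(in_signal)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sig <- which(r$values)
    calls <- data.frame(
      protein_id = protein_id, kind = "NLS",
      start = starts[sig], end = ends[sig],
      support = vapply(sig, function(k) {
        max(posterior[starts[k]:ends[k]])
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  } else {
    calls <- data.frame(protein_id = character(0), kind = character(0),
                        start = integer(0), end = integer(0),
                        support = numeric(0), stringsAsFactors = FALSE)
  }
  list(calls = calls, posterior = posterior, path = path,
       loglik_forward = ll_f, loglik_backward = ll_b)
}
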