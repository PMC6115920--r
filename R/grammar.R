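## Ordered domain architectures and the CNL/TNL/RNL/NL letter-code
## classification grammar.

LRR_SIGNATURE <- "L..L..L.."

## the 18 recognised subgroup letter codes
SUBGROUP_CODES <- c("CNL", "CN", "CNNL", "CNN",
                    "RNL", "RN", "RCNL",
                    "TNL", "TN", "TNNL", "TTNL", "TNLTNL", "CTNL", "CTN",
                    "N", "NL", "NN", "NNL")

#' Count LxxLxxLxx leucine-rich-repeat signatures
#'
#' Greedy left-to-right non-overlapping matches of the 9-residue pattern
#' L-x-x-L-x-x-L-x-x (L literal leucine, x any residue).
#'
#' @param seq Protein sequence.
#' @return Nonnegative integer count.
#' @export
count_lrr_signatures <- function(seq) {
  m <- gregexpr(LRR_SIGNATURE, toupper(seq))[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Start positions of the greedy LxxLxxLxx matches
#' @inheritParams count_lrr_signatures
#' @return Integer vector (possibly empty) of 1-based start positions.
#' @export
lrr_signature_positions <- function(seq) {
  m <- gregexpr(LRR_SIGNATURE, toupper(seq))[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

## union-merge overlapping/touching intervals of one kind
merge_intervals <- function(df) {
  df <- df[order(df$start, df$end), , drop = FALSE]
  out <- df[1L, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1L]) {
    j <- nrow(out)
    if (df$start[i] <= out$end[j]) {
      out$end[j] <- max(out$end[j], df$end[i])
    } else {
      out <- rbind(out, df[i, , drop = FALSE])
    }
  }
  out
}

#' Build a protein's ordered domain architecture
#'
#' Overlapping hits of the same kind are merged (interval union) and the
#' merged TIR/NBS/RPW8/CC hits, sorted by start, are lettered T/N/R/C.
#' LRR and KELCH hits do not contribute letters: LRR content is carried by
#' `lrr_count` (from [count_lrr_signatures()]) and Kelch by `has_kelch`.
#'
#' @param protein_id Protein id; all `hits` must refer to it.
#' @param hits Data.frame of domain hits (columns `protein_id`, `kind`,
#'   `start`, `end`).
#' @param lrr_count Number of LxxLxxLxx signatures in the protein.
#' @return An object of class `nlr_architecture`: `protein_id`, `letters`,
#'   `intervals` (merged, with `letter`), `has_lrr`, `lrr_count`,
#'   `has_kelch`.
#' @export
build_architecture <- function(protein_id, hits, lrr_count = 0L) {
  if (nrow(hits) && !all(hits$protein_id == protein_id)) {
    stop("hits refer to a different protein than ", protein_id)
  }
  letter_map <- c(TIR = "T", NBS = "N", RPW8 = "R", CC = "C")
  core <- hits[hits$kind %in% names(letter_map), , drop = FALSE]
  merged <- NULL
  if (nrow(core)) {
    merged <- do.call(rbind, lapply(split(core, core$kind), function(d) {
      m <- merge_intervals(d[, c("start", "end"), drop = FALSE])
      data.frame(kind = d$kind[1L], m, stringsAsFactors = FALSE)
    }))
    merged <- merged[order(merged$start, merged$end), , drop = FALSE]
    merged$letter <- unname(letter_map[merged$kind])
    rownames(merged) <- NULL
  } else {
    merged <- data.frame(kind = character(0), start = integer(0),
                         end = integer(0), letter = character(0),
                         stringsAsFactors = FALSE)
  }
  structure(list(
    protein_id = protein_id,
    letters = paste(merged$letter, collapse = ""),
    intervals = merged,
    has_lrr = lrr_count >= 1L,
    lrr_count = as.integer(lrr_count),
    has_kelch = any(hits$kind == "KELCH")
  ), class = "nlr_architecture")
}

## decide the TNLTNL code: needs an LRR signature block between the two
## T..N units and after the last (unit-level placement of 'L')
tnltnl_code <- function(arch, lrr_starts) {
  iv <- arch$intervals
  t_idx <- which(iv$letter == "T")
  n_idx <- which(iv$letter == "N")
  if (is.null(lrr_starts)) return("TNLTNL")   # positions unavailable
  mid_lo <- iv$end[n_idx[1L]]
  mid_hi <- iv$start[t_idx[2L]]
  between <- any(lrr_starts > mid_lo & lrr_starts < mid_hi)
  after <- any(lrr_starts > iv$end[n_idx[2L]])
  if (between && after) "TNLTNL" else paste0(arch$letters, "L")
}

#' Classify an architecture into group and subgroup
#'
#' Group follows the dominance order T > R > C (TIR presence puts a protein
#' in the TNL group even with a CC domain, as for CTNL/CTN; RPW8 presence
#' without TIR gives RNL, including RCNL); proteins with none of the three
#' N-terminal domains are NL. The subgroup code is the letter string with
#' "L" appended when LRR signatures are present, matched against the 18
#' recognised codes; for the doubled TNTN architecture the "L" is placed at
#' the unit level (TNLTNL) when LRR positions confirm a repeat block after
#' each unit. Codes outside the table are reported as
#' `"unclassified_architecture"`.
#'
#' @param arch `nlr_architecture` from [build_architecture()].
#' @param lrr_starts Optional LxxLxxLxx start positions (only consulted for
#'   the TNTN doubled architecture).
#' @return List `group`, `subgroup`, `letters`.
#' @export
classify_architecture <- function(arch, lrr_starts = NULL) {
  letters <- arch$letters
  if (!grepl("N", letters, fixed = TRUE)) {
    stop("no NBS domain in architecture of ", arch$protein_id)
  }
  group <- if (grepl("T", letters, fixed = TRUE)) "TNL"
  else if (grepl("R", letters, fixed = TRUE)) "RNL"
  else if (grepl("C", letters, fixed = TRUE)) "CNL"
  else "NL"
  code <- if (letters == "TNTN" && arch$has_lrr) {
    tnltnl_code(arch, lrr_starts)
  } else if (arch$has_lrr) {
    paste0(letters, "L")
  } else {
    letters
  }
  if (!code %in% SUBGROUP_CODES) {
    return(list(group = group, subgroup = "unclassified_architecture",
                letters = letters))
  }
  list(group = group, subgroup = code, letters = letters)
}

#' Subtype an NL gene by its Kinase-2 signature
#'
#' NL proteins carrying the CC-lineage DDVW signature are subtyped N_CC,
#' those with the TIR-lineage DDVD are N_TIR; anything else (including a
#' missing Kinase-2 hit) is unassigned.
#'
#' @param group Group of the record; must be `"NL"`.
#' @param kinase2 Kinase-2 signature 4-mer or `NA`.
#' @return `"N_CC"`, `"N_TIR"` or `"unassigned"`.
#' @export
subtype_nl <- function(group, kinase2) {
  if (!identical(group, "NL")) {
    stop("NL subtyping applies only to NL-group records, got ", group)
  }
  if (identical(kinase2, "DDVW")) "N_CC"
  else if (identical(kinase2, "DDVD")) "N_TIR"
  else "unassigned"
}

#' Classify a set of proteins from sequences and domain evidence
#'
#' For every protein with at least one domain hit: counts LRR signatures,
#' builds the architecture, classifies it, scans for Kinase-2/RNBS-B
#' signatures, and subtypes NL-group proteins. Proteins without an NBS
#' domain hit are excluded with reason `"no NBS domain"`.
#'
#' @param seqs Named character vector of protein sequences.
#' @param hits Domain-hit data.frame (see [read_domain_table()]).
#' @param nls_ids Optional character vector of protein ids with an NLS call.
#' @param rx_cc_ids Optional character vector of protein ids flagged as
#'   carrying an Rx-like CC domain (input metadata, not computed).
#' @param catalog Motif catalog for signature extraction.
#' @return List with `records` (one row per classified protein) and
#'   `excluded` (protein_id, reason).
#' @export
classify_proteins <- function(seqs, hits, nls_ids = character(0),
                              rx_cc_ids = character(0),
                              catalog = default_motif_catalog()) {
  ids <- intersect(names(seqs), unique(hits$protein_id))
  skipped <- setdiff(unique(hits$protein_id), names(seqs))
  records <- list()
  excluded <- list()
  for (id in ids) {
    seq <- seqs[[id]]
    h <- hits[hits$protein_id == id, , drop = FALSE]
    lrr <- count_lrr_signatures(seq)
    arch <- build_architecture(id, h, lrr)
    if (!grepl("N", arch$letters, fixed = TRUE)) {
      excluded[[id]] <- data.frame(protein_id = id, reason = "no NBS domain",
                                   stringsAsFactors = FALSE)
      next
    }
    cls <- classify_architecture(arch, lrr_signature_positions(seq))
    mh <- scan_known_motifs(seq, catalog, protein_id = id)
    sig <- extract_signatures(seq, mh)
    records[[id]] <- data.frame(
      protein_id = id, group = cls$group, subgroup = cls$subgroup,
      letters = cls$letters, lrr_count = lrr,
      kinase2 = sig$kinase2, rnbsb = sig$rnbsb,
      nl_subtype = if (cls$group == "NL") subtype_nl("NL", sig$kinase2)
                   else NA_character_,
      has_nls = id %in% nls_ids,
      has_kelch = arch$has_kelch,
      has_cc_rx_like = id %in% rx_cc_ids,
      stringsAsFactors = FALSE
    )
  }
  for (id in skipped) {
    excluded[[id]] <- data.frame(protein_id = id, reason = "no sequence",
                                 stringsAsFactors = FALSE)
  }
  rec <- if (length(records)) do.call(rbind, records) else
    data.frame(protein_id = character(0), group = character(0),
               subgroup = character(0), letters = character(0),
               lrr_count = integer(0), kinase2 = character(0),
               rnbsb = character(0), nl_subtype = character(0),
               has_nls = logical(0), has_kelch = logical(0),
               has_cc_rx_like = logical(0), stringsAsFactors = FALSE)
  exc <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(protein_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  rownames(rec) <- rownames(exc) <- NULL
  list(records = rec, excluded = exc)
}
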