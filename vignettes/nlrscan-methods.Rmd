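---
title: "Methods: NLR identification, classification and molecular evolution"
author: "nlrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NLR identification, classification and molecular evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlrscan)
```

This vignette documents the models behind each stage of the package, the
tunable parameters and their defaults, the numerical choices, what the
synthetic-data generator does and does not emulate, and the design
decisions that were genuinely open.

## 1. Domain architectures and the classification grammar

A protein enters classification once it has at least one NBS (NB-ARC,
PF00931) domain hit; proteins without one are excluded and reported with
the reason, mirroring the usual survey filtering step. Domain evidence
can come from an external table (InterProScan-style, reduced to
`protein_id, accession, start, end, score`) or from the built-in
scanners; hits of the same kind whose intervals overlap are merged to
their union before lettering, so tandem NB-ARC repeats with fragmented
hits collapse to a single `N`.

The letter string over {C, T, R, N}, ordered by hit start, plus a
trailing `L` when the protein carries at least one `LxxLxxLxx` signature,
is matched against the 18 recognised subgroup codes (CNL, CN, CNNL, CNN,
RNL, RN, RCNL, TNL, TN, TNNL, TTNL, TNLTNL, CTNL, CTN, N, NL, NN, NNL).
Group membership follows the dominance order **T > R > C**: the published
group memberships of every mixed code (CTNL and CTN in the TNL group,
RCNL in the RNL group) are reproduced by this single rule, which the
package adopts as the general definition since the literature assigns
mixed architectures by example rather than by rule. Codes outside the
table are reported as `unclassified_architecture` with the raw letter
string — surfacing, rather than resolving, the ambiguity inherent in
signature-based coding (surveys themselves report a handful of genes with
LRR signatures but no trailing-L code).

Two placement subtleties:

* The trailing `L` is presence-based for simple architectures (one
  `LxxLxxLxx` anywhere suffices), because published subgroup codes are
  assigned on presence alone. Only the doubled `TNTN` architecture needs
  unit-level placement: `TNLTNL` is assigned when signature positions
  confirm an LRR block between the two T–N units *and* after the last;
  otherwise the architecture is surfaced as unclassified.
* LRR counting is greedy left-to-right over the 9-residue pattern
  `L..L..L..`, non-overlapping — the convention that makes counts
  reproducible and order-independent.

NL-group genes are subtyped by the Kinase-2 signature: the four residues
starting at the first D of the DD dyad inside the Kinase-2 motif hit.
`DDVW` marks the CC lineage (N_CC), `DDVD` the TIR lineage (N_TIR);
anything else, or a missing hit, is `unassigned`.

## 2. Motif discovery and scanning

`discover_zoops_motifs()` implements ZOOPS (zero-or-one occurrence per
sequence) expectation-maximization. Per sequence, the E-step computes a
posterior over all window start positions plus an absent state weighted
by the occurrence prior `gamma`; the M-step re-estimates a pseudocounted
position probability matrix (pseudocount 0.1) and `gamma`. The
log-likelihood trace is non-decreasing, which the tests assert. Fixing
`gamma = 1` recovers OOPS (exactly one occurrence per sequence).

Width selection is two-stage: short seeded EM runs (`n_restarts` per
width, default 10) across `minw:maxw` (defaults 6 and 25; the published
parameter set quotes the same bounds, with the 100,000-residue dataset
cap enforced as a guard), scored by a BIC-penalized log-likelihood
(`19 w log n` parameters); the winner is refined to convergence
(relative tolerance 1e-6, 200-iteration cap), then edge columns with
information content below 1 bit are trimmed and the motif re-fit at the
trimmed width. The trimming step matters: a wide window that has locked
onto a shorter conserved core still attains high likelihood through its
noisy flanks, and the penalized likelihood alone is an unreliable width
arbiter at these dataset sizes; column information content separates the
core (> 4 bits per conserved column on a clean fixture) from flanks
(about 0.3 bits) by an order of magnitude.

Scanning uses either fitted matrices or the curated default patterns
(P-loop `G[GAV].{2}G[KR][TS]T`, Kinase-2 `[LIVMF]{2}DD[VIML][WDR]`,
RNBS-B `TTRD|TSR`, GLPL `G[LIVM]PL[AG]`, MHDL `[MQ]HD[LV]`). Published
surveys rely on discovered motifs and print only the signature residues,
so these patterns are this package's own declarations, config-overridable
through the catalog argument. The RNBS-B entry is deliberately the
signature region itself, so the extracted signature equals the matched
string. Hits are resolved non-overlapping per motif, greedily by
descending score with ties to the leftmost start — a deterministic rule.

## 3. Coiled-coil and nuclear-localization signals

The coiled-coil scorer is a declared simplification of profile-HMM
servers (whose trained emission models are not reproduced here): for each
window (21 residues = three heptads) and each of the 7 register phases,
core a/d positions score +1 for a hydrophobic residue (LIVMFA) and −1
otherwise, flank e/g positions +1/2 for a polar residue and −1/2
otherwise; the best phase score, normalised to [−1, 1], passes through a
logistic (slope 8, midpoint 0.55). The penalties are what make the score
informative: a pure "fraction matched" score over 12 binary positions
saturates on random sequence. Calibration targets, fixed before any
pipeline integration: an ideal heptad repeat (`LEALEGK`)ₙ scores > 0.9,
register-free sequence (poly-P, random) < 0.1. A CC segment is called as
the longest run of residues at or above the 0.4 threshold (the lower end
of the accepted probability window), with a minimum run length of one
full window (21) so isolated high-scoring windows in non-coiled sequence
do not call; in the pipeline, scanner-derived CC evidence is accepted
only when the segment starts before the first NBS hit (N-terminal
verification) and only when the domain table carries no CC rows at all,
so two different CC callers are never mixed.

NLS detection uses a two-state (background/signal) HMM. The default
parameterization — init (0.95, 0.05), background→signal 0.005,
signal→background 0.10, signal emissions K = R = 0.38 with the remaining
mass uniform, uniform background emissions — is a declared stand-in for
trained static models whose parameters are not published; everything is
overridable. Decoding offers the Viterbi path and forward–backward
posteriors (segments = maximal runs at or above the 0.5 cutoff). All
recursions run in log space; forward and backward total log-likelihoods
agree to 1e-9 and per-residue posteriors are normalised, both asserted
against exhaustive path enumeration on short sequences in the tests.

## 4. Gene clusters and exon structure

Clusters follow the two-criterion rule: adjacent NBS genes (in start
order per chromosome) are linked iff the intergenic gap
(`start(next) − end(prev)`, negatives clamped to 0) is **strictly** below
200 kb *and* the count of annotated non-NBS genes strictly between them
is **at most** 8. The criteria combine with AND; "distance" is read as
the intergenic gap (the originating protocols do not fix the anchor), and
a start-to-start anchor is available as a config switch. Linked runs of
≥ 2 genes are clusters; singletons are not. Per-chromosome averages
divide by the chromosome count (default 17); genes on unplaced scaffolds
still cluster but do not add chromosomes to the denominator. Tightening
either criterion can only shrink the clustered-gene set (property-tested),
and the implementation is checked against a brute-force pair-linkage
oracle on 200 random toy genomes.

Exon counts come from the GFF3 gene/mRNA/exon hierarchy; the primary
transcript is the mRNA with the most exons (ties by file order), a
declared choice since annotation-based surveys rarely state which
transcript they count.

## 5. Ka/Ks by Nei–Gojobori

The method is the classic NG86 with equal-pathway weighting, the standard
genetic code, and Jukes–Cantor correction — the estimator behind the
"Nei–Gojobori" output of the usual CDS-analysis programs (the survey
literature typically names only the program, so the method identification
is a declared decision). Per codon, each of the 9 single-nucleotide
mutations contributes 1/3 of a synonymous site when it yields a
synonymous sense codon; mutations to stops are nonsynonymous. Sites are
averaged over the two sequences; codons with non-ACGT characters or a
stop in either sequence are excluded pairwise. Multi-nucleotide codon
differences average over all minimal mutational pathways, excluding
pathways through stop codons unless every pathway crosses one. A
proportion at or above 3/4 leaves the corrected distance undefined
(`saturated` flag); a Ks of 0 leaves the ratio undefined, and clade
averages pool the defined ratios while reporting the exclusion count.
Clade averages are computed over all unordered within-clade pairs, with
clade membership supplied as input (phylogeny reconstruction is out of
scope).

## 6. Expression normalization and clustering

Size factors are the median-of-ratios estimator: per tissue, the median
over reference genes (those positive in every tissue) of the ratio to
the gene's geometric mean. One property worth stating precisely: a
global rescale of the matrix leaves the factors **unchanged** (the
gene-wise geometric means absorb it), so normalized values scale with
the input — the estimator removes *relative* depth differences between
tissues, not absolute scale. The tests pin this behaviour and cross-check
the factors against the reference implementation in DESeq2.

K-means is Lloyd's algorithm with Euclidean distance, a 1000-iteration
cap (the cap, not a restart count — matching the common GUI semantics of
"1000 iterations"), seeded initialization on k distinct genes, and
empty clusters re-seeded to the point farthest from its assigned
centroid. Rows are sorted by gene id before seeding so results depend
only on the seed and data, never on row order. For k = 3 the clusters
are ranked by mean centroid magnitude and labelled moderate-to-minimal,
minimal-to-basal, basal-to-none.

## 7. The synthetic-data generator

`genome_blueprint()` fixes the study conditions once: the default census
is the published sunflower column (352 genes: 100 CNL, 77 TNL, 13 RNL,
162 NL over 18 subgroup codes), 17 chromosomes plus 4 unplaced-scaffold
genes, 75 planted clusters holding 200 genes in sizes 2 and 3 with about
one third on chromosome 13 and none on chromosomes 5 and 12, and
per-group exon-count laws (shifted Poisson with means 2.7/6.1/6.2/2.9).
A single `scale` factor shrinks everything proportionally for fast
tests; below scale 0.2 the singleton subgroup codes are dropped rather
than inflated.

`gen_proteome()` concatenates unit blocks per subgroup code — an ideal
heptad CC repeat, random TIR/RPW8 blocks backed by domain-table rows, an
NBS block embedding the curated motifs with the planted Kinase-2
signature (DDVW for CC-lineage groups, DDVD for TNL, the published
83:18:61 DDVW/DDVD/absent proportions for NL, one RNL carrying the DDVR
variant), and LRR blocks with an exact planted signature count — joined
by random linkers that exclude L, D and W so no accidental LRR or
Kinase-2 signal can arise. `gen_genome()` places clusters so both
criteria hold with margin and isolates everything else by 300 kb gaps
with 10 intervening fillers (violating both criteria); boundary-probe
arguments allow exact gaps of 199,999/200,000 bp. `gen_codon_pairs()`
plants one substitution per mutated codon, with synonymous and
nonsynonymous counts targeting the proportions implied by `ks_target`
and `omega * ks_target` under Jukes–Cantor, so a simulated clade's mean
Ka/Ks recovers `omega`. `gen_expression()` plants three log-normal
expression-level classes (default 13/15/43 genes over 9 tissues, means
50/8/0.4, sdlog 0.3).

What the generator does **not** emulate: realistic residue and codon
composition, domain-hit noise (fragmented, overlapping or missing hits
beyond the planted structure), annotation errors in the GFF3,
transition/transversion bias, rate variation among sites, and
count-distributed (negative-binomial) expression noise. Passing the
closure tests therefore demonstrates correctness of the algorithms under
clean evidence, not robustness of the upstream scanners to real-data
noise; the scanners' behaviour on adversarial sequence is tested
separately (calibration controls, false-call measurements).

## 8. Problem sizes and numerical choices

The test suite and acceptance script run the classifier closure at the
full 352-gene census, the cluster oracle on 200 random toy genomes of up
to 50 genes, the Ka/Ks oracle on 100 random 300-codon pairs (equality to
an independent literal implementation at 1e-9) plus three 50-pair
simulated clades, exhaustive HMM path enumeration up to length 12, and
one 50-sequence motif-recovery fixture — sizes chosen so the whole suite
completes in about a minute on one core while still exercising every
boundary the criteria define. Coordinates are 1-based inclusive
end-to-end (GFF3 and domain-table convention); any half-open arithmetic
is local to an operation (the BED-like cluster export). Strand is
carried but ignored by classification and clustering, whose criteria are
strand-agnostic.

## 9. Known limitations

* The CC and NLS scorers are declared simplifications; their absolute
  probabilities are calibrated, not trained, and should not be compared
  numerically against profile-HMM server outputs.
* The Rx-like CC flag on CNL records is input metadata (it requires a
  similarity search against a reference protein, out of scope), and
  TX-class (TIR without NBS) genes are excluded by design.
* Ka/Ks assumes gap-free in-frame alignments; alignment construction is
  the caller's responsibility.
* Clade Ka/Ks averages depend on the (unstated, in the survey
  literature) choice of pair set; this package averages all within-clade
  pairs and reports exclusion counts, so its averages are comparable
  between runs but not necessarily to other tools' sliding-window
  variants.
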