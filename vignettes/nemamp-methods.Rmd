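---
title: "Methods: mining nematode antimicrobial peptide repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining nematode antimicrobial peptide repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemamp)
```

## The problem

Nematode genomes encode five known groups of antimicrobial peptides (AMPs):
Cecropins, Diapausins, CSαβ defensin-fold peptides, Nemapores (saposin-like
peptides) and glycine-rich secreted peptides (GRSPs). Each group is defined
by different evidence: Cecropins purely by sequence similarity to known
family members, Diapausins/CSαβ/Nemapores by conserved cysteine arrays, and
GRSPs by precursor architecture (a signal peptide, a short precursor, and a
glycine-rich mature region). `nemamp` implements a homology-search pipeline
over predicted proteomes that applies these group-specific acceptance rules,
expands queries iteratively to convergence, derives mature peptides, and
summarizes repertoires and life-stage expression.

Because real pan-phylum proteome collections are large external downloads
and several published steps depend on external neural-network predictors,
the package is validated end-to-end on synthetic proteomes with planted
ground truth. The synthetic generator is first-class, tested code: it
defines the study conditions under which the pipeline's sensitivity and
false discovery rate are measured.

## Profile search and E-values

Each seed set (curated family queries plus their multiple alignment) is
compiled into a lightweight profile: match states are alignment columns with
gap fraction below 0.5; emissions are observed counts with a Laplace
pseudocount of 1, expressed as log2-odds against Robinson–Robinson
background frequencies; insertions and deletions carry a fixed linear
penalty of 2 bits per residue/state. Scoring is Smith–Waterman-style local
dynamic programming over match states, so scores are in bits and a sequence
of only `X` residues scores 0 (an `X` can never be scored as a match).

E-values are calibrated per profile by the method of moments: 200
composition-preserving shuffled decoys of length 150 are drawn from the
database, their score mean and standard deviation determine Gumbel
parameters (λ = π/(σ√6), μ = m − γ/λ), and
E(s) = K·db_size·exp(−λs) with K = exp(λμ)/150. E is therefore strictly
decreasing in the score and linear in database size. Intake gates follow the
study design: E < 0.01 for Cecropin, Diapausin, CSαβ and Nemapore;
E ≤ 10 for the low-complexity GRSPs, whose authenticity is instead enforced
by the architectural gate below.

Pairwise search (iterative expansion, the GRSP reciprocal check, and the
similarity edge-list export) uses exhaustive Smith–Waterman with BLOSUM62
and affine gaps (open 11, extend 1; a gap of length k costs 11 + k). No
seeding heuristics are used — at desk scale exhaustive DP is affordable and
exactly testable against a naive full-matrix oracle. Tie-breaking is fully
specified: the best cell is the highest score with ties to the smallest
(row, column); hit rankings sort by E-value, then bits, then id.

One numerical choice deserves emphasis: before a candidate is used as a
pairwise query, its predicted signal peptide is masked. Sec signal peptides
are near-degenerate hydrophobic runs; left unmasked they dominate local
alignments between unrelated secreted precursors and let query expansion
snowball across families. Masking restricts expansion similarity to the
mature region, which carries the family signal.

## Cysteine-array motifs

Motif arrays are *data*, not code: `inst/extdata/motifs.json` holds, for
each array, the cysteine count, the allowed residue ranges between
consecutive cysteines, and the putative disulfide connectivity (metadata
only; matching uses positions and spacing). Exact published spacer ranges
for these families are not recoverable from text sources, so the shipped
defaults were derived at design time alongside the synthetic seed sets, with
one hard requirement verified symbolically: no array can be embedded, via
any subset of another array's cysteines (with merged gaps), inside an
instance of a different array. That makes CSαβ subgroup classification
(MND, TID, Macin, Drosomycin, and the rearranged six-cysteine MND variant)
unambiguous by construction on family-true sequences; when a sequence does
match more than one array, the classifier reports `ambiguous` and never
tie-breaks silently. Every pipeline report records the motif file's MD5
checksum so results are auditable against the arrays used.

Matching is leftmost-greedy and non-overlapping: among all valid cysteine
tuples the scanner takes the one with the smallest first position (ties:
smallest span, then lexicographic), then resumes after its last cysteine.
This matches how discrete domains and tandem motifs are counted per gene
(e.g. two complete Diapausin arrays in one precursor, or seven tandem
Saposin B domains in a multi-domain Nemapore). An `X` inside a spacer window
is tolerated; an `X` at a cysteine position voids the match, because the
cysteine identity cannot be confirmed. The matcher is verified against a
brute-force enumerator over all increasing cysteine tuples on hundreds of
random sequences.

The Macin call requires exactly ten cysteines (the arrangement observed in
nematodes), not the eight-to-twelve seen in other invertebrates; the array
file is editable if a user wants the looser definition.

## Maturation rules

External neural-network predictors for signal peptides and propeptide
cleavage are deliberately not reimplemented. Instead the package ships
rule-based defaults so the pipeline is self-contained, plus TSV adapters
that override the heuristics with real predictor output wherever provided;
candidate tables record the resulting calls.

The signal-peptide heuristic requires, within the first 35 residues: an
n-region with at least one K/R in the first five residues; an h-region —
a window of at least seven residues with mean Kyte–Doolittle hydropathy
≥ 1.6, extended greedily; and the first small-residue cleavage triplet
`[AGSTC]-X-[AGST]` ending at or after the h-region. Furin propeptide sites
are all occurrences of `R-X-[KR]-R`, cleaving after the final R. Mature
peptides remove the signal peptide and then the region up to the last furin
site preceding the group motif. A candidate without a predicted signal
peptide is retained for reporting with `complete = FALSE`, and is excluded
from mature-peptide composition statistics.

GRSP authenticity applies four gates: precursor ≤ 200 amino acids (the
length bound applies to the full precursor), a predicted signal peptide,
mature glycine content strictly greater than 17% — computed after
signal-peptide removal only, since propeptides are rarely annotated in these
families — and a reciprocal check: the candidate, aligned against a labelled
reference database, must return a known GRSP within its top five hits
(ranked by E, then bits, then id). The strict `> 17` boundary follows the
normative rule rather than the descriptive 17–74% family range; the upper
bound is not enforced.

## The synthetic study

`generate_study()` emits per-genome proteome FASTA, species metadata, a
ground-truth table, a domain-annotation table and a life-stage TPM matrix,
all deterministic given one master seed (per-genome streams are derived at
fixed offsets). The default corpus — 6 genomes × (500 decoys + 10 planted
AMPs per group), 10% substitution rate on seed-derived regions — is the
condition under which recovery statistics are quoted; it is small enough for
routine testing and large enough to estimate sensitivity and FDR on 300
planted positives against 3000 decoys.

Planted sequences are composed as: canonical signal peptide (M + basic
n-region + hydrophobic h-region, A-X-A cleavage, with A excluded from the
h-region so the cleavage site is unambiguous), optionally a furin-terminated
pro-region, then a group-defining mature region. Cecropins are
BLOSUM62-conditional mutated copies of a seed mature region, since the group
is accepted on similarity alone and planted members must remain in the
similarity basin. For the cysteine-array groups the array spacings are drawn
uniformly within the configured ranges, and the non-cysteine scaffold is a
seed-derived, mutated background rather than uniform random residues: family
members share scaffold composition beyond their cysteines, and a planted
"member" with a random scaffold would not be a member of the family in any
detectable sense. GRSP matures draw a glycine fraction from U(0.20, 0.60)
laid down as glycine blocks interleaved with hydrophilic spacer tokens,
mirroring the repeat structure of real glycine-rich families; residues that
would create spurious hydrophobic h-regions or cysteine arrays are excluded
from the relevant pools.

Four hard-decoy classes each violate exactly one acceptance rule:
glycine-rich but 250 aa long; glycine-rich without a signal peptide; a
Saposin B domain plus an annotated extra domain; and a Diapausin-like
sequence with one cysteine spacer at range-max + 3. This localization is
verified by running the rule checkers on every generated hard decoy —
a failing class pinpoints the rule whose implementation drifted. The TPM
table gives an exact fraction (default 0.86) of planted genes at least one
stage ≥ 2 TPM, by counting rather than sampling, so the pooled expressed
fraction is reproducible.

What the generator does *not* emulate: real clade-specific abundance
distributions, nucleotide-level gene models, assembly artifacts beyond an
optional signal-peptide truncation flag, and realistic cross-family sequence
entanglement. Passing recovery tests on this corpus therefore demonstrates
that the pipeline's rules, gates and bookkeeping behave as specified — not
that the same sensitivity would be obtained on real proteomes.

## Repertoire and expression statistics

Per-genome tallies count complete and incomplete candidates; relative
abundance is 100 × AMP genes / protein-coding genes. Group summaries report
mean ± SEM (sample sd, n − 1); a single-genome group reports SEM 0 with an
explicit n = 1 flag rather than being dropped. Statistics are computed per
genome; a species-collapse is left to the caller via the metadata.

Normality is assessed with a Lilliefors-corrected one-sample
Kolmogorov–Smirnov test: because mean and sd are estimated from the data,
p-values come from a seeded Monte-Carlo null (10⁴ replicates by default,
cached per sample size) rather than the plain KS distribution. Group
comparisons use the Kruskal–Wallis test (tie-corrected H via
`stats::kruskal.test`, chi-square p on k − 1 df) followed by Dunn z-tests
on pooled mean ranks. The Dunn adjustment defaults to Bonferroni — the
convention of the statistics software family this mirrors — configurable to
Šidák or none, and the chosen flavour is recorded in the result object.

Expression calls use an inclusive threshold: a gene is expressed iff some
life stage reaches ≥ 2 TPM, so 2.00 is expressed and 1.99 is not (where the
sources disagree between "≥ 2" and "> 2", the normative methods wording is
adopted and the discrepancy noted here). Heatmap matrices are
log2(TPM + 1), row-standardized with the sample sd; constant rows are set to
z = 0 and flagged, never dropped. Row order comes from average-linkage
agglomerative clustering on Euclidean distances of the z rows via
`stats::hclust`, which is deterministic for a fixed input; the package
relies on that determinism rather than re-implementing the merge loop with a
bespoke tie-break, and exports the merge table and heights alongside the
leaf order.

## Other design choices

* **Coordinates.** All coordinates, internal and serialized, are 1-based
  inclusive — the natural convention in R and the one biologists read;
  serialized motif spans print as `start-end`.
* **Ambiguity codes.** `U`, `B` and `Z` are mapped to `X` on read with a
  warning; sequences are uppercased and a terminal `*` stop is stripped.
* **"High peptide similarity."** For Cecropins the acceptance operationalizes
  manual similarity assessment as E-gate plus profile coverage ≥ 60%; the
  threshold is a config default and flagged as an interpretation in the run
  report (config echo).
* **Cross-group candidates.** A protein accepted by two groups is reported
  once per group with a `cross_group` flag, never silently deduplicated.
* **GRSP subgroups.** GRSPs carry one pooled label; reference subgroup
  models overlap too much for reliable subgroup assignment.
* **Orthology and layout.** Ortholog assignment and 2-D cluster layouts are
  out of scope; the package exports the all-vs-all candidate E-value edge
  list for external clustering tools.

## Validation problem sizes

The shipped test suite exercises: oracle equivalence of the motif matcher on
500 random sequences (≤ 120 aa, ≤ 20 cysteines) and of the aligner on 100
random pairs (≤ 40 aa, exact integer equality); full-pipeline recovery on
the default corpus (seed 7) and two alternate seeds, requiring pooled
sensitivity ≥ 0.90 and FDR ≤ 0.10; rule-localized rejection of all 240
generated hard decoys; an eight-case GRSP gate fixture with three designed
accepts; Kruskal–Wallis type-I error over 2000 null simulations (3 × 15)
within [0.04, 0.06]; and the expression boundary and row-standardization
identities. These sizes were chosen so the whole suite runs comfortably on a
single CPU while keeping Monte-Carlo standard errors well inside the
asserted bands.

## Known limitations

The profile scorer is a match-state-only approximation, not a full HMM with
learned transition probabilities; its E-values are moment-fit Gumbel
calibrations, adequate for gating at desk scale but not interchangeable with
HMMER or BLAST E-values. The rule-based signal-peptide heuristic is
co-designed with the generator's canonical signal peptides and will be
cruder on real sequences — the adapter mechanism exists precisely so real
predictor output can replace it. Sensitivity on weakly glycine-rich GRSPs is
limited by the compositional nature of their similarity signal; the
reciprocal gate controls the corresponding false-positive risk, at some cost
in recall (visible in the per-group recovery numbers on the synthetic
corpus).
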