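---
title: "Detecting RiPP recognition elements with profile HMMs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting RiPP recognition elements with profile HMMs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrescan)
```

## The problem

Ribosomally synthesized and posttranslationally modified peptides (RiPPs)
are made from a short precursor peptide whose N-terminal leader region is
bound by biosynthetic enzymes during maturation. In most prokaryotic RiPP
classes that binding is carried out by a small PqqD-like domain, the RiPP
recognition element (RRE): roughly 90 residues folding into three
α-helices and a three-stranded β-sheet, occurring either as a discrete
protein (<100 residues) or fused into a larger enzyme. Because the RRE is
the closest thing to a class-independent genetic handle on RiPP
biosynthetic gene clusters (BGCs), detecting it reliably — despite very
low sequence identity across classes — turns genome mining for new RiPP
chemistry into a tractable sequence-analysis problem.

`rrescan` implements that detection task end to end: class-specific
*precision* scanning with a library of profile hidden Markov models
(pHMMs), a two-stage *exploratory* pipeline for divergent RREs, the
model-building and validation machinery (identity clustering, sequence
similarity networks, seed selection), a regulator filter for the dominant
structural false-positive class (helix-turn-helix DNA-binding domains),
in-silico domain excision, and genomic co-occurrence rules that turn
per-protein hits into BGC-level judgments. A deterministic
synthetic-fixture generator makes the whole pipeline testable without any
external database.

## The scoring model

A model is a profile HMM over match, insert and delete states: per-position
match emission distributions $e_j(a)$ over the 20 canonical amino acids,
seven transition probabilities per position
($M{\to}M, M{\to}I, M{\to}D, I{\to}M, I{\to}I, D{\to}M, D{\to}D$), and a
background $f(a)$ (uniform $1/20$ by default, replaceable in
`rre_config()`). Scoring is *local*: begin enters any match state with
probability $1/M$, exit after any match state is free, and flanking
residues are scored only under the null. A path scores

$$ S = \log_2 \frac{1}{M} + \sum_{\text{matches}} \log_2 \frac{e_j(x_i)}{f(x_i)}
      + \sum_{\text{transitions}} \log_2 t $$

and the reported **bit score** is the maximum over all local paths
(Viterbi), computed in C++. A forward (log-sum-exp) score over the same
path space is provided and is always at least the Viterbi score, but
thresholding uses Viterbi only: it is deterministic and directly checkable
against explicit path enumeration, which the test suite does exhaustively
for every model with up to 4 match states against every sequence of
length up to 6 over a 3-letter reduced alphabet.

Two architectural choices are deliberately simple and documented rather
than inherited from any external tool. Insert states emit the background
(0 bits), because no other treatment is derivable from the published
protocol. And each (protein, model) pair reports one best envelope —
multi-domain proteins yield one region per model — because detection is
reported at the protein level. Imported HMMER3 ASCII models score
consistently *within* this engine, but absolute values are not expected
to reproduce HMMER's (different null model and entry/exit architecture).

### Tiers

Hits are labelled with the nested bit-score tiers
**tolerant (15) / moderate (25) / stringent (35)**; the moderate cutoff
is the default reporting threshold, trading recall against precision.
Tier nesting (hits at 35 ⊆ 25 ⊆ 15) is asserted property-style on
generated proteomes.

## Model building

`build_phmm()` turns a multiple sequence alignment into a model:

* **Match columns**: weighted gap fraction < 0.5. Exactly-half-gapped
  columns become inserts.
* **Sequence weights**: position-based (Henikoff) weights, normalised to
  mean 1; duplicated sequences are automatically down-weighted.
* **Emissions**: background-proportional pseudocounts,
  $e_j(a) = (c_{ja} + \alpha f_a)/(n_j + \alpha)$ with $\alpha = 1$
  (`rre_config()$pseudocount`). The same smoothing, with a uniform prior
  over each state's options, is applied to transitions counted from the
  state paths implied by the match-column assignment.
* Degenerate inputs: an alignment with no qualifying match column is an
  error; a single shared column yields a valid 1-state model; a
  single-sequence "alignment" is allowed only where the exploratory
  pipeline seeds enrichment from one region.

## E-values

The published protocol thresholds on bit scores; E-values are provided
for SSN compatibility and for enrichment admission. `calibrate_evalue()`
scores `n_random` background sequences and fits a Gumbel by maximum
likelihood, giving $E(s) = n_{db} \, e^{-\lambda (s - \mu)}$. The fit is
checked against an independent grid-search likelihood maximizer. For
pairwise (Smith–Waterman) E-values the package uses fixed
Karlin–Altschul constants ($\lambda = 0.267$, $K = 0.041$ for
BLOSUM62/11/1) rather than re-estimating them: SSN thresholds only need a
monotone, reproducible score→E map.

## The exploratory pipeline

Stage 1 scans with the exploratory model set and keeps hits with bit
score ≥ 25 and alignment length ≥ 50 residues; envelopes are excised with
15 flanking residues per side. Stage 2 expands each candidate into a
profile by **iterative enrichment** over a user-supplied companion
database (3 iterations, admission at E ≤ 0.05, re-alignment of admitted
sequences along their Viterbi paths), then aligns that profile against
reference RRE profiles with a **profile–profile local alignment** using
the co-emission log-odds column score
$S(i,j) = \log_2 \sum_a p_i(a) q_j(a) / f_a$ and affine column-gap
penalties (open 3 bits, extend 0.3 bits). Pure-background columns score
at most 0, so unrelated profiles produce no positive local alignment.

The original confirmation step thresholds an HHsearch probability whose
internals are not reproducible from the published description. The
package's documented surrogate is a logistic calibration
(`calibrate_stage2()`) of synthetic positive/negative labels on the
profile–profile score and aligned length; a candidate confirms when its
calibrated probability reaches 0.90 *and* the alignment spans at least 50
columns — both conditions, never one. On cleanly separated synthetic
training sets (the common case) the logistic degenerates and the fit
falls back, with a message, to a steep logistic centred on the midpoint
between the best negative and the worst positive score; predicted
probability remains strictly increasing in score either way. The
calibration is seeded, deterministic, and intended to ship alongside the
reference profiles. The reference "structures" of the original protocol
are replaced by reference *profiles* built from user-supplied or fixture
alignments; no structure parsing or secondary-structure scoring is
attempted, which is the main respect in which the exploratory mode here
is a sequence-only approximation of the original.

## Regulator filtering

Helix-turn-helix DNA-binding domains are structurally homologous to RREs
and dominate the false positives. `regulator_filter()` scans each hit's
parent protein against a set of regulator models, each with a trusted
bit-score cutoff, and flags the hit when a regulator match at or above
its cutoff overlaps the RRE envelope by ≥ 1 residue. Flagged hits are
retained with the flag set — removal is an explicit option — so output
files record the overlap rather than silently dropping hits.

## Clustering, SSNs and seed selection

* `greedy_cluster()` is longest-first greedy clustering at a pairwise
  identity threshold (default 0.80, the de-duplication level of the
  exploratory database build). Identity counts residue-paired columns
  only — terminal and internal gap columns are excluded from the
  denominator — a choice documented here because every published
  clustering tool differs on it. Greedy order makes the result
  deterministic and oracle-checkable against all-pairs connected
  components on planted fixtures.
* `build_ssn()` draws an edge when $-\log_{10} E \ge$ the alignment-score
  threshold (22 and 25 are the thresholds used for the published
  networks); edge sets are nested across thresholds.
* `conflate_repnodes()` collapses sequences above 60% or 80% identity
  onto representative nodes, re-attaching and de-duplicating edges.
* `select_diverse_seeds()` takes one member per connected component in
  size-descending order (5–20 seeds); when components are fewer than the
  minimum, the largest components contribute extra members round-robin.
  The round-robin rule is this package's own construction — the original
  selection was manual on network visualizations.

## Genomic context

ORF distance is the difference of gene indices along the locus, strand
ignored, because co-occurrence windows are counted in open reading
frames. Shipped rule forms: a window-2 radical-SAM rule and an AND rule
(leader peptidase *and* lasso cyclase) defaulting to whole-locus range —
the window for the lasso rule is not pinned down by the protocol, so it
ships as editable JSON config rather than a constant. Precursor
candidates are genes translating to strictly fewer than 150 residues
within a 3-ORF window of the RRE gene. Validation against labelled loci
recomputes per-tier hit counts from scores, so counts are monotone across
tiers by construction and are re-derivable from the raw hit table.

## The synthetic-fixture generator

`make_family()` emulates a curated RRE family: a random consensus of
~90 columns is perturbed per column by Dirichlet noise (concentration 50
around a base mixing the consensus with uniform), and members are sampled
from the resulting generator with known coordinates. The `divergence`
knob (default 0.4, "moderate") controls both the mixture and the indel
rate: at 0 every member equals the consensus; across 0.1–0.7 the mean
within-family identity falls from ≳60% to ≲40%, bracketing the 30–80%
band typical of real RRE families. Locus fixtures reverse-translate
proteins with a fixed codon table into self-consistent GenBank records.

What the generator deliberately does **not** emulate: real amino-acid
composition biases, correlated (structure-driven) column substitutions,
the secondary-structure signal that structure-aware methods exploit, and
homology *between* families. Passing tests therefore demonstrate that the
machinery is correct and well-calibrated under its own assumptions — they
do not measure recall on real proteomes, where inter-class homology and
HTH confounders are harsher.

## Numerical and interface choices

* **Coordinates** are 1-based inclusive everywhere (R convention,
  matching Biostrings/IRanges); emitted TSV/FASTA coordinates are
  likewise 1-based inclusive, so the flank arithmetic reads: envelope
  20–90, flank 15, protein length 200 → region 5–105, clipped at the
  bounds.
* **Tie-breaks**: equal-scoring Viterbi paths resolve toward the smaller
  envelope start, then smaller end; equal best-fit bit scores resolve to
  the lexicographically first model name; clustering ties resolve by id.
* **Non-standard residues**: B/Z/U/O map to X with a warning; X emits the
  background (0 bits) during scoring.
* **Multi-record GenBank files** are treated as independent loci, one per
  record.
* Problem sizes used by the shipped tests were chosen as representative
  desk-scale study conditions: a 200-member family of ~90 columns with 20
  training seeds and 180 held-out members plus 1000 length-matched
  decoys for the recall/false-positive simulation; three 40-member
  families, six fused hosts and five decoys for the exploratory
  end-to-end run; 100 synthetic positives and 100 negatives for stage-2
  calibration; 12-sequence planted fixtures for clustering/SSN checks.

## Known limitations

Bit scores are not HMMER-compatible in absolute value; one envelope per
(protein, model) means tandem RRE repeats within one protein surface only
once per model; enrichment never splits a family into subfamilies; the
stage-2 probability is a calibrated surrogate, so its absolute scale is
only as meaningful as the calibration set; and the center-star aligner is
a minimal utility for seed sets, not a replacement for a progressive
aligner on large diverse families.
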