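---
title: "Detecting discontinuous protein domains by segment assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting discontinuous protein domains by segment assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domex)
```

## The problem

Sequence-based domain boundary predictors partition a protein chain into
contiguous segments, but a substantial fraction of structural domains —
roughly 15% in structure-classification databases — are *discontinuous*:
they are formed by two (rarely more) segments that are far apart in
sequence and fold together in space, e.g. the CATH-style assignment
`1-156|342-393`. A boundary predictor alone cannot say which non-adjacent
segments belong together. This package takes predicted boundaries as input
and decides, for every pair of non-adjacent segments, whether their
concatenation looks like a known single domain.

## The model

Given a chain split into segments $S_1, \dots, S_{n+1}$ by $n$ predicted
boundaries, every non-adjacent pair $(S_p, S_q)$, $q \ge p + 2$, with both
segments at least 40 residues long, is concatenated into a putative domain
$Q = S_p \cup S_q$ and searched against a library of single-domain
sequences. Each template hit $T$ is judged on four quantities.

**Template-similarity score.** $\mathrm{TS} = s \cdot h \cdot l$, where
$s$ is the global sequence identity of the alignment, $h = \min(E_0,
-\log_{10} E)/E_0$ (with $E_0 = 10$, clamped below at 0) is the normalised
E-value, and $l$ is a sigmoid coverage factor: 0 when the alignment covers
no more than a third of $Q$, and $1 / (1 + (1/(3c - 1))^5)$ above, where
$c$ is the fraction of $Q$'s residues that are aligned. $l$ passes 0.5 at
$c = 2/3$ and approaches $\approx 0.97$ at full coverage.

**Symmetry index.** A real joint template matches *both* segments with
similar identity and coverage. Splitting the alignment columns at the
junction between the two segments gives per-segment vectors $v_k = (s_k,
c_k)$, and $\mathrm{SI} = \lVert v_p - v_q \rVert$. A template matching
only one segment scores near $\sqrt 2$; a symmetric match scores near 0.

**Length error.** Homologous domains have similar lengths, so hits must
satisfy $e = |L_T - L_Q| / L_Q < 0.2$.

**Cutoff constraint.** Rather than tuning the TS and SI cutoffs
independently, they are tied through a one-parameter piecewise-linear
constraint

$$T_{SI} = f(T_{TS}, b) = \begin{cases}
0.3 & T_{TS} > 0.15 + b/2 \\
2\,T_{TS} - b & 0.05 + b/2 < T_{TS} \le 0.15 + b/2 \\
0.1 & b/2 < T_{TS} \le 0.05 + b/2 \\
0 & T_{TS} \le b/2
\end{cases}$$

which keeps the SI cutoff in the useful band $[0.1, 0.3]$ and lets a
single parameter $b$ trade recall against precision. A hit is accepted
when $e < 0.2$, its TS-score exceeds $b/2$, and its SI does not exceed
$f(\mathrm{TS}, b)$ evaluated *at the hit's own TS-score*. The default
operating point is $b = 0.3$.

**PPA filter.** Templates from sequence-derived libraries (Pfam-like,
tagged `SEQUENCE`) lack structural confirmation and produce more spurious
matches than structure-derived ones (CATH/SCOP-like, `STRUCTURE`). When
$b < 0.5$, sequence-source hits must additionally achieve a
profile–profile alignment score below $T_{PPA} = -1.90$. When several
hits pass, the one with the lowest PPA-score wins, and when several
candidates sharing a segment are accepted, conflict resolution keeps the
lowest-PPA assembly per segment.

## The PPA score

The profile–profile aligner is a global affine-gap dynamic program over
per-residue profile columns augmented with predicted secondary structure.
The exact functional form of such scores is tool-specific; the choices
here are:

* **Column score** = dot product of the two profile columns plus a bonus
  $w_{ss}$ (default 1) when the secondary-structure states agree.
* **Column scaling.** Profile columns (PSSM log-odds, or the BLOSUM62 row
  of the residue for single-sequence pseudo-profiles) are scaled to unit
  Euclidean norm, making the dot product a cosine similarity in
  $[-1, 1]$. This has two consequences we rely on: aligning a column to
  itself is provably at least as good as any substitution (raw BLOSUM
  rows violate this for M, S and V, which would let point mutations
  *improve* a self-match), and a perfect ungapped self-alignment has a
  known score.
* **Normalisation.** The reported PPA-score is $-(\text{DP optimum} /
  \text{alignment length})$, so good alignments are negative and the
  perfect self-match scores exactly $-(1 + w_{ss}) = -2$. On this scale
  the default cutoff $-1.90$ sits just short of a perfect match: an
  all-coil single-sequence profile pair passes at roughly $\le 10\%$
  mismatching columns, which is the intended strictness for
  unconfirmed sequence-database templates.
* **Gaps**: affine, open 7, extend 0.5 (configurable); on the cosine
  scale this makes gaps expensive, appropriate for candidate/template
  pairs that already passed the $e < 0.2$ length filter.

Secondary structure enters as a single pluggable input (a PSIPRED-format
`.ss2` file or an `H`/`E`/`C` string); consensus logic across predictors
is out of scope, and in the absence of a prediction an all-coil stub is
used, which turns the ss term into a constant offset that cancels between
competing templates.

## Search backends

Two interchangeable backends implement the library search:

* `builtin_backend()` — BLOSUM62 local (Smith–Waterman) affine-gap
  alignment of the bare candidate against every record
  (`Biostrings::pairwiseAlignment`), with a Karlin–Altschul E-value
  $E = K m n e^{-\lambda S}$ using the standard gapped BLOSUM62
  constants ($\lambda = 0.267$, $K = 0.041$, gap open 11, extend 1);
  $n$ is the total residue count of the library. It is deterministic,
  needs no external binaries, and is the backend used throughout the
  test suite.
* `psiblast_backend()` — a two-stage profile search through the external
  `psiblast` binary: stage one iterates against a background set
  (default: the library itself) to build a PSSM, stage two searches the
  library with that profile. Stage counts and inclusion thresholds are
  explicit configuration, since profile-search protocols vary between
  installations.

Identity is counted as identical aligned columns over aligned columns
(gap columns excluded); coverage as aligned query residues over candidate
length. When splitting at the junction, a column that is a gap in the
query is attributed to the part holding the nearest aligned query residue
on its left, so identity and coverage counts are conserved exactly across
the split — a property the test suite checks on 1,000 random alignments.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `b` | 0.3 | recall/precision trade-off in $f(T_{TS}, b)$ |
| `e_max` | 0.2 | relative length-error cutoff (strict `<`) |
| `t_ppa` | −1.90 | PPA-score cutoff for sequence-source hits |
| `ppa_applies_below_b` | 0.5 | PPA filter active when $b$ is below this |
| `E0` | 10 | E-value normalisation parameter |
| `min_len` | 40 | minimum segment length, matching the ±20-residue boundary tolerance of upstream predictors |
| `max_evalue` | 10 | search-stage E-value cutoff (keeps $h \ge 0$) |
| `identity_cutoff` | 0.90 | library redundancy threshold |
| `allow_reversed` | FALSE | also try C→N segment order (segment-swapped domains) |

Inequality conventions: the decision is `SI ≤ cutoff` and `e < e_max`
(the worked acceptance arithmetic is treated as normative for SI);
`domex_thresholds(strict = TRUE)` flips SI and TS to strict
inequalities. The boundary points between the pieces of $f$ are assigned
to the lower piece; continuity at the two inner breakpoints makes that
choice value-identical either way. When a passing hit has no computed
PPA-score (structure-source hits when ranking only), it ranks at 0 —
i.e. behind every hit whose alignment scored better than indifferent —
with TS-score, E-value and template id as deterministic tie-breaks.

## Library redundancy filtering

Deduplication is greedy longest-first clustering (CD-HIT style): records
are visited in order of decreasing length (ties by id), and a record is
dropped exactly when its identity to an already-retained record reaches
the cutoff. Identity is identical aligned residues from a global
BLOSUM62 alignment divided by the shorter sequence's length. Greedy
longest-first was chosen for determinism and because it retains the
longest representative of each redundancy class; the procedure is
idempotent.

## The synthetic benchmark generator

`generate_fixtures()` emulates the construction used for training such a
detector: chains of 3–6 segments in which a planted non-adjacent pair is
homologous to a library template (the template is the concatenation of
the two segments with independent point substitutions at
`mutation_rate`), negative chains with no joint template, and random
decoy records length-matched to two-segment assemblies so the length
filter is exercised nontrivially. A `reversed_fraction` of positives is
built in swapped segment order to model segment-swapped domains, which
forward-only assembly provably cannot recover.

Defaults (20 chains, 4 segments of 60–120 residues, mutation rate 0.1,
half the chains discontinuous, 20 decoys) mirror the regime the method
is designed for: ~10% divergence from the nearest template, and domains
of realistic lengths. What the generator does *not* emulate: insertions
and deletions beyond an optional uniform indel rate, realistic amino-acid
covariation, compositional bias, repeats, and remote (<30% identity)
homology. Passing tests on these fixtures therefore demonstrate the
correctness of the machinery and the calibration logic, not the recall
one would obtain against real remote-homology libraries, which depends
on profile search sensitivity.

## Calibration

Three sweeps reproduce the training protocol on any scored sample cache
(`score_samples()` runs the search once; the sweeps reuse it):

* `calibrate_est()` — exhaustive grid search of independent cutoffs
  $T_{TS} \in [0.1, 1]$, $T_{SI} \in [0.05, 0.5]$, step 0.05 (19 × 10
  cells), reporting recall/precision/MCC per cell. Ties in MCC resolve
  to the most permissive (lowest) cutoffs.
* `calibrate_ecv()` — the constrained rule swept over
  $b \in \{0.1, \dots, 0.9\}$.
* `calibrate_pct()` — per $b$, the PPA cutoff swept from 0.0 to −5.0 in
  steps of −0.1 (51 values), applied to sequence-source hits, reporting
  the MCC-maximising cutoff (ties to the most permissive).

Samples are counted per segment pair, not per chain. Metrics with empty
denominators are reported as `NaN` with a warning rather than coerced to
0, so degenerate sweeps are visible instead of silently optimistic.

## Evaluation

`ndo_score()` implements a normalized domain-overlap score between two
partitions of a chain: the residue-overlap matrix between predicted and
reference domains is matched one-to-one by exact maximum-weight matching
(bitmask dynamic programming), and the matched overlap is divided by the
chain length. Identical partitions score 1; the score is symmetric for
full partitions. As the published definition of this family of scores is
procedural rather than closed-form, the implementation is validated
property-wise (exhaustive permutation matching on small cases, symmetry,
identity).

## Numerical and degenerate-input choices

* `h` is clamped at 0 for $E > 1$, where the formula would go negative.
* Zero hits is a prediction ("all continuous"), not an error; empty
  FASTA files and unresolvable source tags are fatal.
* The MCC numerator/denominator are computed in double precision
  (integer arithmetic overflows beyond a few hundred samples).
* The DP traceback resolves score ties toward the aligned state, making
  reported alignments deterministic.
* `decide()` is invariant to hit order; all ranking chains end in a
  lexicographic template-id comparison.

## Problem sizes in the test suite

The suite validates the aligners against brute-force recursions on
instances up to 30 residues, the splitting conservation laws on 1,000
random alignments, threshold recovery on a separable 200-positive /
400-negative scored benchmark, and the full pipeline on 20-chain
fixtures (~35 library records) — sizes chosen so the whole suite
exercises every code path in a few minutes on one core.

## Known limitations

* Only two-segment discontinuous domains are assembled; three-segment
  domains (rare in structure databases) are not enumerated.
* The PPA cutoff −1.90 is meaningful only under this package's score
  normalisation; profiles scored by other tools need recalibration via
  `calibrate_pct()`.
* The builtin backend scores bare sequences, not profiles; remote
  homologs below ~30% identity will often be missed unless the
  `psiblast` backend is used.
* Boundary quality is consumed, not judged: segments are taken literally
  from the input TSV, and `min_len` is applied to the predicted (not
  true) segment lengths.
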