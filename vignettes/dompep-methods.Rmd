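---
title: "dompep: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dompep: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dompep)
```

dompep predicts interactions mediated by modular peptide-binding domains.
This vignette explains the statistical machinery, the choices that were
genuinely open when the package was designed, and what the test suite does
and does not establish.

## The data model

Everything starts from an `interaction_table`: a domains × peptides matrix
of outcomes in {BOUND, UNBOUND, UNTESTED}, optionally backed by quantitative
dissociation constants (Kd, µM) with a classification cutoff of 100 µM —
the boundary itself counts as binding. Two window conventions are
supported: PDZ models see the five C-terminal residues of a ligand
(P-4..P0); SH2 models see the six residues flanking a phosphotyrosine
(pY-2..pY+4, the invariant pY excluded). Longer peptides are truncated to
the window on ingestion; the full string is kept for display.

UNTESTED is a first-class outcome, not a missing value to impute: array
panels differ between domains, and treating untested cells as unbound would
corrupt the denominators of every overlap statistic below.

## Pairwise specificity statistics

**Ligand-binding similarity (LBS).** For domains *i*, *j* and the peptides
co-tested on both, with `B_ij` bound by both and `B_iNB_j` bound by *i*
only:

- standard: `LBS = B_ij / (B_ij + B_iNB_j + B_jNB_i)` — the Jaccard index
  of the binder sets; appropriate for quantitative, saturating panels.
- minimum-denominator: `LBS = B_ij / min(B_i, B_j)` — robust to unequal
  detection depth between array experiments. When one domain's screen
  detects 173 binders and another's only 40, all 40 shared, the standard
  form reports 0.23 although the specificities are identical; the
  minimum-denominator form reports 1.

The variant is a configuration switch (`pairwise_metrics_table(...,
lbs_variant=)`), defaulting to standard for PDZ-style data and
minimum-denominator for SH2-style array data.

**PWM distance.** A domain's position weight matrix holds plain
per-position residue frequencies over its binding windows — no pseudocounts
by default (a Laplace `alpha` exists but is 0), because the statistic is
defined on observed percentages and both compared domains pass the same
≥ 10-binder gate. The distance between PWMs *a*, *b* with *w* columns is

d(a,b) = (1/w) · Σᵢ arccos⟨âᵢ, b̂ᵢ⟩ / (π/2),

where âᵢ is row *i* rescaled to unit Euclidean norm and inner products are
clipped to [0, 1]. Frequency vectors are non-negative, so each angle lies
in [0, π/2] and d in [0, 1]: 0 iff per-position frequencies are
proportional, 1 iff every position has disjoint residue support. The angle
(not its cosine) is used so that near-identical profiles are not
excessively rewarded nor dissimilar ones excessively penalized. Whether to
average per-column angles or take a single angle over the flattened matrix
is not decidable from the definition's constraints alone — both respect the
range and the identity axiom — so both are implemented
(`pwm_distance(..., method=)`); the per-column average is the default
because it weights window positions equally regardless of their entropy.

**Domain sequence identity (DSI).** Global Needleman–Wunsch alignment
under BLOSUM62 with affine gaps (open 10, extend 0.1, both exposed).
Identity is counted over the full alignment length, gap columns included —
the convention of EMBOSS needle. The alternative (identical columns over
gap-free columns only) was measured and rejected: with a cheap gap
extension the aligner concentrates matches into few gap-free columns, and
unrelated random 90-mers then average ~35% "identity", which would poison
any threshold calibrated on DSI. Under the alignment-length denominator
unrelated pairs average ~13%, while genuinely related domains, which align
nearly gap-free, are barely affected.

## Calibrating thresholds with LBS

LBS is the empirical ground truth for "same specificity", but it needs
binding data on both sides; DSI needs only sequence. The calibration step
(`calibrate_thresholds()`) bins domain pairs by DSI (band edges 0, 30, 40,
50, 60, 100) and by PWM distance (width-0.1 bins) and computes mean LBS per
bin, using only pairs where both domains have ≥ 10 binders:

- the DSI threshold is the lowest band edge from which that band and every
  higher band reaches mean LBS ≥ 0.7;
- the PWM-distance threshold is the widest distance prefix whose populated
  bins all reach the cutoff;
- a compound clause (DSI ≥ x **and** PWM < y) is emitted when an
  intermediate DSI band reaches the cutoff only at small PWM distance —
  this automated derivation is a reconstruction of what is otherwise a
  by-inspection judgement, and clauses subsumed by a wider clause are
  pruned.

Empty bins are neutral: they neither qualify nor veto. If no bin reaches
the cutoff anywhere, the rule is returned empty with an `insufficient`
flag; consumers must branch on it rather than receive a silently
permissive rule. The 0.7 LBS cutoff is a coverage/stringency compromise;
raising it can only tighten thresholds (tested property).

Because most users will not have a large array panel of their own,
`default_threshold_rule()` ships the published per-family clauses: PDZ —
DSI ≥ 50% or PWM distance < 0.3; SH2 — DSI ≥ 60%, or PWM < 0.1, or
DSI ≥ 40% and PWM < 0.3.

`find_similar_domains()` applies a rule to a query: DSI clauses need only
sequences; PWM clauses additionally require ≥ 10 binders on both sides.
Members are ordered by PWM distance ascending (undefined last), ties by
DSI descending — PWM distance is the more direct specificity measure, and
this order drives the pooling below.

## Models

Peptides are one-hot encoded (20 slots per window position, alphabetical
residue order: 100 dimensions for PDZ, 120 for SH2) and classified with a
linear-kernel soft-margin SVM (`e1071`, C defaulting to 1 and exposed —
the regularization level is not pinned by any design constraint, and the
Scrib-panel conclusions are insensitive across C ∈ {0.1, 1, 10}).
Negatives are sampled without replacement from background-proteome windows
at a 5:1 ratio, excluding the current pool's positive windows *only* —
binders of other family domains are not presumed negative for the query,
since low-DSI pairs demonstrably share ligands.

`build_dompep_model()` trains candidates on nested pools — query alone,
then adding group members one at a time in group order — resampling
negatives per pool from a seed derived from the run seed, and scores each
candidate by leave-one-out cross-validation. The candidate with the best
LOOCV wins; ties go to fewer pooled domains, so the result is never
strictly worse than the query-only model. LOOCV is scored as held-out AROC
rather than classification accuracy: at 5:1 imbalance the all-negative
classifier already achieves 0.83 accuracy, which would mask real
differences between candidates (a plain-accuracy option exists). Whether
negatives should be resampled per candidate pool or shared across pools is
not externally determined; per-pool resampling with a fixed seed keeps
candidates independent while staying bit-reproducible, and reproducibility
of the whole pipeline under a fixed seed is a tested property.

Models need at least three positive ligands; below that
`build_dompep_model()` refuses rather than fitting something meaningless.
For a query with no data at all, `substitute_model_lookup()` ranks existing
models by DSI (candidates ≥ 40% shown, top 10), flagging those below the
per-family trust guidance (PDZ ≥ 50%, SH2 ≥ 60%) as not recommended.

## Scanning and stringency

`scan_proteome()` extracts one window per protein for PDZ (its C-terminal
5-mer) and one per fully-flanked tyrosine for SH2 — every tyrosine is
scanned regardless of phosphorylation state, a deliberate
over-approximation consistent with models trained on synthetic pY-peptide
arrays. Raw decision values are standardized to Z scores against the score
distribution of the scanned database itself (mean 0, SD 1 over the run —
exact identities, tested); a stored reference from a previous large scan
can be supplied instead, so small target sets can be judged against
proteome-wide statistics.

Stringency cutoffs are anchored at true-positive rates of 70/50/30% on the
vertically averaged ROC of the available models (mean FPR at fixed TPR;
vertical averaging is the stated choice where "average ROC" is otherwise
ambiguous). Note the direction: a *lower* TPR anchor means a *higher*
score threshold and fewer, more confident calls, so the TPR-30% anchor is
the **high**-stringency cutoff and TPR-70% the **low** one. This keeps the
call sets nested (HIGH ⊆ MEDIUM ⊆ LOW), which any monotone grading must
satisfy.

## Evaluation

`aroc()` uses the rank (Mann–Whitney) form with half-credit for ties, so
the statistic is invariant under strictly monotone score transforms and
equals the trapezoidal area of the returned curve (verified against each
other on 1,000 random instances and against an independent ROC
implementation). Paired model comparisons use the Wilcoxon signed-rank
test, zero differences discarded, exact null for ≤ 25 untied differences
and the continuity-corrected normal approximation otherwise.

`table1_validation()` evaluates the bundled 56-peptide Scrib PDZ panel:
labels from Kd ≤ 100 µM, scores either the panel's own published
per-peptide prediction scores (deterministic) or a user-supplied retrained
model scanned over the 56 C-termini (exploratory). The printed-score mode
exists to validate the *evaluation machinery* — retraining the original
models exactly would require the full unpublished training arrays. Two
panel quirks are preserved verbatim: one peptide's C-terminus is printed
with nine residues rather than ten (its 5-mer window is unaffected), and
one borderline affinity (102 ± 40 µM) sits just above the cutoff, so the
strict ≤ 100 count for the first domain is 13 where 14 has also been
reported; the package does not second-guess the printed values.

## The synthetic-data generator

`generate_family()` builds what the real array panels look like
structurally: by default 8 domains in 2 specificity groups, a 220-peptide
array with 40 binders per domain, and a 2,000-protein background — sizes
chosen so a full metrics→calibration→grouping→training pass exercises
every code path at desk scale. Domain sequences are evolved from per-group
ancestors by seeded point mutations; rates come from expected-identity
calibration (a pair independently mutated at rate *r* keeps ≈ (1−r)² of
its sites), targeting 70% identity within and 30% between groups. Realized
between-group DSI lands in the mid-30s rather than at 30 because global
alignment inflates identity slightly for diverged pairs; both values sit
safely on their intended sides of the 50% threshold. Array peptides are
drawn half from sharp planted PWMs (Dirichlet-style, concentration 10) and
half from natural background composition (a Robinson–Robinson style
frequency table); a domain binds the 40 peptides with the highest
log-likelihood under its group's PWM plus a small per-domain jitter, after
which 2% of outcome cells are flipped — array screens have a small error
rate, and recovery tests should tolerate it.

Because the bound set is a likelihood-truncated sample, the empirical PWM
of a domain's binders converges to the *truncated* motif distribution, not
the planted PWM itself: it carries a bounded selection bias toward the
motif core that does not vanish with more binders. The tests therefore
assert proximity and discrimination (close to the own-group generator, far
from the other group's) rather than asymptotic convergence.

What passing recovery tests on these fixtures shows: the pipeline
identifies planted specificity structure through realistic noise, window
logic and seeds are sound, and models separate motif from background. What
it does not show: performance on real PDZ/SH2 data, whose sequences are
not mutated copies of a common ancestor, whose motifs are not
position-independent, and whose array errors are not uniform — the bundled
Scrib panel and the worked overlap examples are the real-data anchors.

## Numerical conventions and limitations

Kd exactly at the cutoff is BOUND; undefined metrics are carried as `NA`,
never dropped or imputed; inner products are clipped before `acos`;
LBS/PWM distance require ≥ 10 binders per domain; model selection breaks
LOOCV ties toward fewer pooled domains; all randomness flows from explicit
seeds. Known limitations: no phospho-state prediction (every tyrosine is
scanned), no contextual filtering (localization, co-expression), linear
decision functions only, and no probability calibration of SVM outputs —
raw decision values and Z scores are the interface.
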