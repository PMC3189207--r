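# dompep

Prediction of protein–protein interactions mediated by modular
peptide-binding domains — PDZ domains, which read the extreme C-terminus
(P-4..P0) of their partners, and SH2 domains, which read phosphotyrosine
contexts (pY-2..pY+4). The package is aimed at signalling and interactomics
groups who have domain–peptide array data (or want to reuse published
panels) and need per-domain binding predictors that can be applied across a
proteome.

## The method

Most domains have too few experimentally verified ligands to train a model
on their own, so the central problem is deciding *which other domains'
binders may be pooled with a query's*. dompep does this with three pairwise
statistics:

- **LBS** (ligand-binding similarity) — the overlap of two domains' binder
  sets on co-tested peptides. Standard form
  `LBS = B_ij / (B_ij + B_iNB_j + B_jNB_i)` (the Jaccard index of binder
  sets); minimum-denominator form `LBS = B_ij / min(B_i, B_j)` for array
  data with unequal detection depth (a domain pair with 173 vs 40 binders
  and full nesting scores 0.23 under the standard form but 1 under the
  minimum-denominator form, matching its true shared specificity).
- **PWM distance** — per window position, the angle between the two domains'
  unit-normalized residue-frequency vectors, normalized by π/2 and averaged
  over positions; 0 = identical specificity profile, 1 = disjoint residue
  support, defined only for domains with ≥ 10 binders.
- **DSI** (domain sequence identity) — percent identity from a global
  Needleman–Wunsch alignment (BLOSUM62, gap open 10 / extend 0.1).

LBS is the empirical ground truth of "same specificity"; binning domain
pairs by DSI and by PWM distance and asking where mean LBS reaches 0.7
*calibrates* admission thresholds on the other two statistics
(`calibrate_thresholds()`). The shipped defaults are the published rules:
PDZ pairs are specificity-similar when DSI ≥ 50% **or** PWM distance < 0.3;
SH2 pairs when DSI ≥ 60%, **or** PWM distance < 0.1, **or** DSI ≥ 40% and
PWM distance < 0.3.

Admitted neighbours are pooled with the query in nested candidate training
sets (orthogonal 0/1 encoding, 100 dims for PDZ / 120 for SH2; negatives
sampled 5:1 from background-proteome windows; linear-kernel SVM), and
leave-one-out AROC decides how much pooling actually helps
(`build_dompep_model()`). Trained models scan proteomes
(`scan_proteome()`), scores are standardized to Z scores against the
scanned database, and TPR-anchored stringency cutoffs grade the calls.

## Worked example

```r
library(dompep)

# a synthetic PDZ-style family: 8 domains in 2 planted specificity groups,
# 40 binders each on a 220-peptide array, 2000 background proteins
fam  <- generate_family(synthetic_family_spec(seed = 7))
rule <- default_threshold_rule("PDZ")
grp  <- find_similar_domains("D01", fam$domain_seqs, fam$table, rule)
grp
#> similarity_group: query D01, 3 member(s)
#>  member      dsi pwm_distance clauses
#>     D04 68.88889   0.05986539    1, 2
#>     D02 67.77778   0.06823093    1, 2
#>     D03 63.33333   0.08161956    1, 2

model <- build_dompep_model("D01", grp, fam$table, fam$background, seed = 101)
model
#> binding_model: D01 (PDZ), 41 pos / 205 neg, pooled domains: D01, LOOCV 0.895

pred <- scan_proteome(model, fam$background[1:500])
head(as.data.frame(pred), 3)
#>   protein window position raw_score  z_score
#> 1 bg00350  IHNQL      203 0.8517510 2.909343
#> 2 bg00273  GENMF      124 0.6841585 2.723797
#> 3 bg00387  SGYIV      250 0.5775271 2.605742
```

The group members are exactly D01's planted specificity mates, each admitted
by both the DSI clause (clause 1) and the PWM-distance clause (clause 2);
model selection kept the query-only candidate here because its 41 binders
already saturate the motif. Scanned records carry `raw_score` and
`z_score`; a Z score of 3 means the window scores three standard deviations
above the average window of the scanned database.

The bundled validation panel — 56 human C-terminal peptides with measured
affinities against the three Scrib PDZ domains — is evaluated with:

```r
table1_validation()$per_domain
#>   domain n_pos      aroc
#> 1   PDZ1    13 0.8497317
#> 2   PDZ2    14 0.7891156
#> 3   PDZ3    38 0.8757310
```

where `n_pos` counts peptides with Kd ≤ 100 µM and `aroc` is the area under
the ROC curve of the panel's per-peptide prediction scores against those
labels (the probability that a random binder outscores a random non-binder).

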