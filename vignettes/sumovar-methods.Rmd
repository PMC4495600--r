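---
title: "Predicting sumoylation sites and classifying variant effects: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting sumoylation sites and classifying variant effects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sumoylation is the covalent attachment of a SUMO protein to a lysine
residue of a substrate.  The canonical recognition context is the ΨKxE
consensus: a large aliphatic hydrophobic residue (Ψ ∈ {L, V, I, M, F}) at
position −1, the modified lysine, any residue at +1 and a glutamate at +2,
with an acidic (NDSM) stretch often found in the ten residues downstream.
Because an amino-acid substitution can create or destroy a site, or flip
the status of a neighbouring site, variant effects on sumoylation are a
mechanistic hypothesis for otherwise unexplained disease mutations.

`sumovar` provides the full chain needed to study this offline:

1. a sequence-based **site predictor** (21-mer windows around each lysine,
   several feature encodings, F-score ranking with forward wrapper
   selection, and an ensemble of soft-margin RBF-kernel classifiers trained
   on balanced negative draws, with specificity-calibrated probability
   cutoffs);
2. a **variant-effect classifier** that compares the predicted (or
   annotated) sumoylation status of every lysine whose window overlaps a
   substitution, before and after the substitution;
3. **statistics**: confusion metrics and ROC/AUC, Fisher/chi-square
   contingency tests, a two-sample logo, and an iterative motif extractor;
4. a **synthetic data generator** that emulates a proteome with planted
   consensus sites and constructs variants with known ground-truth effects.

## The site predictor

Each lysine is represented by the window of 10 residues on either side
(length 21, `'X'`-padded at sequence ends; the window covers the NDSM
region downstream of the consensus).  Positives are annotated sites;
negatives are **all other lysines of the same, experimentally investigated
proteins** — a deliberately conservative negative definition.  A greedy
identity filter on the 21-mers (identity > 0.3 to any retained fragment,
`'X'` never matching) stands in for whole-database clustering when
redundancy reduction is requested.

### Encodings

| family | dimension | content |
|---|---|---|
| `physchem` | 21 × 8 | per-position property values (hydropathy, hydrophilicity, volume, polarity, pI, mass, helix/sheet propensity); `'X'` → 0 |
| `cksaap` | 400 × \|k\| | counts of ordered residue pairs separated by k ∈ {0..4} positions, normalised by the number of such pairs (L−k−1); pairs touching `'X'` are ignored |
| `ss` | 21 × 3 | one-hot H/E/C secondary structure from an annotation table |
| `aasa` | 21 + 1 | per-position accessible surface area plus the window mean |
| `pssm` | 21 × 20 | profile scores from a PSI-BLAST-dialect ASCII matrix |

The exact feature composition of the original 401-dimensional predictor is
not public; here each encoder has a fixed documented dimension and the
selection stage reconciles the choice.  Structure and profile encoders
consume pre-computed files only and degrade gracefully (with a warning) to
sequence-only mode when the files are absent, so the predictor runs on
synthetic or sequence-only data.

### F-score ranking and wrapper selection

For feature *i* the F-score is

$$F_i = \frac{(\bar x_i^{+}-\bar x_i)^2 + (\bar x_i^{-}-\bar x_i)^2}
{\tfrac{1}{n^{+}-1}\sum_k (x_{k,i}^{+}-\bar x_i^{+})^2 +
 \tfrac{1}{n^{-}-1}\sum_k (x_{k,i}^{-}-\bar x_i^{-})^2}.$$

A feature with zero within-class variance in both classes scores 0 when
its numerator is 0 and +∞ otherwise (a perfect separator, ranked first).
Ties in the ranking are broken by column name for determinism.  F-scores
are averaged over the ten balanced training sets; a single forward
best-first pass then examines features in rank order and keeps one iff it
**strictly** improves (tolerance 1e−9) the mean 10-fold cross-validation
accuracy — averaged over the ten balanced sets.  That averaging is
essential: measured on one noisy evaluation, a pure-noise feature is
accepted ~20–25% of the time; averaged over ten independent sets the rate
drops below 10%.  The empty-set baseline is the majority-class rate.

Selection matters for variant calling, not just for compactness: without
it the near-linear kernel (γ ≈ 0.002 on min-max-scaled features) spreads
the margin over thousands of correlated columns, and a lysine that keeps
Ψ(−1) but loses E(+2) still scores ≈ 0.6.  With selection the wrapper
retains precisely the consensus features (the k = 1 `K·E` pair count and
the E(+2) property channels), and such half-consensus mutants drop to
p ≈ 0.002 — which is what makes loss-of-site variants detectable at the
default threshold.

### The classifier ensemble

No SVM binding ships with the supported environment, so the soft-margin
kernel classifier is implemented in the package: an SMO solver for the
C-SVC dual (maximal-violating-pair working-set selection, analytic
two-variable update, compiled via Rcpp) with the RBF kernel
K(x, y) = exp(−γ‖x−y‖²).  Features are min-max scaled to [0, 1] with
training ranges stored in the model — without this, raw property scales
(volumes ≈ 100) would push the shipped γ into the degenerate regime.  The
shipped defaults are the tuned optimum of the original predictor:
**C = 8, γ = 0.001953**; a grid search is deliberately not run by default.

Because negatives outnumber positives ~25:1, ten balanced negative sets
are drawn (without replacement within a set, independently across sets)
and one classifier is trained per set; the **ensemble probability is the
unweighted mean of member probabilities** (the simplest exchangeable
combination; the source procedure does not specify one).  Member
probabilities come from a Platt sigmoid fitted on the training decision
values rather than on internal cross-validated ones: this is 5× cheaper
inside the cross-validation loops, and since the sigmoid is monotone it
changes neither ranking metrics nor quantile-based threshold calibration.

### Specificity thresholds

The `default` call threshold is probability 0.5.  The 70/80/90/95%
specificity options are empirical nearest-rank quantiles of held-out
negative scores.  Held-out is taken seriously: scores come from an
**out-of-bag** scheme in which every pool negative is scored by the mean
of the members whose balanced draw did not contain it.  (Calibrating on
out-of-fold scores from refitted 90%-models, the first design tried,
overshoots: fold models score negatives systematically higher than the
full ensemble, and the achieved specificity at the 0.90 level was 0.94
rather than 0.90 ± 0.02.)  On fresh negatives from the generator the
achieved specificities land within two points of their levels.

## Variant-effect classification

For a substitution at position *p*, every lysine (wild-type or mutant)
whose 21-mer window overlaps *p* is a candidate.  Status before/after
comes from annotation when available (site tables; curated per-variant
effects of `removed`/`created`/`retained`), otherwise from the ensemble at
the chosen specificity level; annotated evidence takes precedence.  Rules,
in order:

1. wild type is K at a sumoylated position and the mutant is not K →
   **Type I(−)** (site destroyed); mutant is K and predicted modified →
   **Type I(+)** (site created).  The variant position takes precedence
   over neighbour logic.
2. otherwise, for each neighbouring lysine: off→on → **II(+)**;
   on→off → **II(−)**; on→on → **III** (the site persists but its
   recognition context — plausibly the E3 ligase that reads it — has
   changed); off→off → no call.
3. several affected lysines → the call with the largest |Δprobability| is
   reported; all candidates are kept in an attribute for audit.

Type IV (PTM-type switching) is represented in the type enumeration but
never emitted.  One property the threshold sweep does **not** have: only
the Type I counts are monotone in the specificity level, because II/III
calls compare statuses on both sides of the substitution — raising the
cutoff can convert a III call into a II(−).  Fragment-level calls are
monotone; the per-type sweep counts are reported as observed.

## Statistics

`fisher_exact_2x2` sums hypergeometric probabilities of tables at least as
extreme as observed (two-sided by probability mass); `pearson_chi2` is the
classic Σ(obs−exp)²/exp with upper-tail p and optional continuity
correction.  Both are provided because the source analysis names both for
the same tables; the class summary records which was used (Fisher is the
2×2 default).  The two-sample logo tests each (position, residue) cell
with a pooled two-proportion z-test **with continuity correction** — the
uncorrected z is anti-conservative at the small counts a 20-letter
alphabet produces, flooding null comparisons with spurious cells (without
correction, a null dataset shows at least one α = 0.001 cell about half
the time; with it, almost never).  The motif extractor iteratively fixes
the most significant (position, residue) pair by exact binomial
enrichment against the background, recurses on the matching subsets, and
removes matched foreground fragments before searching for the next motif.
No heuristic pruning is applied.

## The synthetic world

The generator emulates: 100 proteins, lengths uniform on 100–400, residues
i.i.d. uniform over the 20 canonical amino acids, 200 planted K sites (≥5
apart, full windows), each carrying Ψ at −1 **and** E at +2 with
probability `motif_q = 0.8` — chosen once as a realistic consensus
fidelity, since a substantial minority of experimentally mapped sites
deviate from ΨKxE.  This yields ≈ 1450 lysine fragments, of which 200 are
positives.  Variants are constructed, not sampled: K→R at planted sites
(I−), centre→K inside background consensus contexts (I+), E(+2)→G at
planted sites (II−), +2→E next to background lysines with Ψ(−1) (II+),
and consensus-preserving within-window substitutions (III); shortfalls are
warned about, never silent.

What the generator does *not* emulate: realistic residue composition and
local sequence correlation, homologous fragment families, protein-level
annotation noise (false negatives among "non-sites"), and any structural
or evolutionary signal (fabricated profiles are format-valid stand-ins
whose scores merely favour the observed residue).  A green end-to-end test
therefore establishes that the machinery is correct and the consensus
signal is learnable — not that real-proteome performance figures are
reproduced.  The published genome-scale numbers depend on external
corpora and are treated as inputs where printed, never as things this
package could recompute.

## Numerical choices and edge cases

* SMO stopping tolerance 1e−3 on the duality gap; intercept from free
  support vectors (fallback: midpoint of the violating-pair bounds).
* Probabilities are clamped by construction to (0, 1); degenerate
  single-class training data raises immediately.
* F-score: 0/0 → 0, positive/0 → +∞ sentinel ranked first.
* Quantile type for threshold calibration: nearest rank (type 1).
* ROC points group tied scores into one cutoff; AUC is trapezoidal and
  equals the Mann–Whitney statistic to 1e−12.
* Percentages are reported at two decimals, matching the source tables;
  raw fractions remain available from the underlying counts.
* 1-based coordinates everywhere; `'X'` padding never matches in identity
  computations and contributes zeros to every encoder.
* Variant tokens accept three-letter, one-letter and mixed residue codes
  (`Lys477T`), with whitespace ignored.

## Known limitations

* The SMO solver is plain maximal-violating-pair; for the few-hundred-row
  balanced sets used here it converges in milliseconds, but it is not a
  general-purpose large-scale SVM.
* Platt scaling on training decisions is slightly optimistic about member
  confidence; consumers needing calibrated probabilities should rely on
  the specificity thresholds, which are calibrated out-of-bag.
* The greedy identity filter is order-dependent (documented, deterministic)
  and is not a substitute for proper clustering of full-length proteins.
* Annotation-only classification cannot distinguish II(−) from III without
  a curated effect; absent both a model and an effect, an annotated
  neighbouring site is assumed to persist (yielding III, the conservative
  reading of an unchanged modification with a changed context).
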