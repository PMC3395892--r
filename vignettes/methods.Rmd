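---
title: "Methods: predicting local structural change of pentamer pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting local structural change of pentamer pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentamut)
```

## The problem and the model

A non-synonymous SNP swaps one amino acid. Whether that swap perturbs the
*local backbone conformation* is a question distinct from whether it
disrupts function or stability, and it can be posed directly on solved
structures: collect pairs of five-residue fragments (pentamers) whose
sequences are identical except at the central residue, superpose their
Cα traces optimally, and measure the residual RMSD. Below 0.2 Å the
backbone is considered unchanged ("neutral"), above 0.4 Å changed
("change"); the band in between is ambiguous and excluded. The resulting
binary dataset is learned with an L2-regularized logistic regression over
sequence-derived features, so the final predictor needs no structure at
prediction time.

The key modeling assumptions are:

* **Locality.** Five residues and a sequence window of at most 21 residues
  around the change carry the signal. Pentamer conformation in reality also
  depends on tertiary context the model never sees; this bounds attainable
  accuracy.
* **Threshold labeling.** The 0.2/0.4 Å cut-offs are a pragmatic
  discretization of a continuous quantity, chosen to split data roughly
  evenly, not a biophysical definition of structural change. Both
  inequalities are strict; values exactly at a threshold are excluded.
* **Pair symmetry.** Which fragment is "wild type" is arbitrary, so roles
  are assigned by a seeded coin flip and difference features encode the
  mutant-minus-wild-type direction explicitly.

## Dataset construction rules

`parse_pdb()` reads fixed-column ATOM records (PDB v3.3): first MODEL only,
first-encountered altloc per residue/atom (file order is reproducible where
the convention for "first" is otherwise unspecified), HETATM and CA-free
(non-protein) chains ignored, non-standard residues retained but flagged
`'X'`. A peptide bond counts as broken when the C(i)–N(i+1) distance
exceeds 2.5 Å (strict) *or either atom is missing* — the conservative
reading that guarantees superposition never sees missing coordinates.

`extract_pentamers()` applies three independent exclusion rules per window
(break inside, non-standard residue, missing Cα). `pair_pentamers()` emits
cross-set pairs with a single central mismatch whose source chains share
more than 30% global identity; identity is computed by Needleman–Wunsch
(BLOSUM62, gap open 10, extend 0.5) with identity = identical positions /
full alignment length including gaps. Whether the original procedure used
global or aligned-region identity is not documented; the global convention
is pinned here and tested against a direct-count oracle on gapless-optimal
cases.

`maximal_fragment_filter()` removes pairs embedded in a much larger
identical-except-center fragment. "Much larger" is not quantified anywhere;
we extend the matched region outward while flanking residues agree and drop
the pair when total (left + right) extension exceeds `max_extension = 4`
residues. The threshold is a configurable package decision, not a claimed
original value.

## Superposition

`superpose()` implements the Kabsch solution: centroids removed, SVD of the
3×3 cross-covariance, and the determinant-sign correction
`R = V diag(1, 1, det(VUᵀ)) Uᵀ` that excludes reflections, so a mirror
image can never superpose at RMSD 0. This is the unique least-squares
optimum, numerically identical to what iterative McLachlan-style
implementations converge to. RMSD is over exactly the five Cα atoms,
unweighted. Degenerate inputs (collinear or coincident points) still return
a valid proper rotation because the sign correction handles rank-deficient
covariance; NaN input is an error. Tests verify optimality against a
brute-force rotation-grid oracle on planar point sets (tolerance 1e-4,
where the planar optimum is an in-plane rotation possibly composed with a
proper π flip) and rigid-motion invariance at 1e-8 over 1000 random
motions.

## Feature encoding

Channels and their pinned per-position widths:

| channel | width/position | notes |
|---|---|---|
| three-state predictions (`ss`, `acc`, raw variants) | 3 | probability triplets |
| two-state predictions (`disorder`, `isis`, `dna`) | 2 | mutually exclusive 1/0 |
| scalar tracks (`info`, `psic`, `flexibility`, `pfam_fit`, propensities) | 1 | normalized `[0,1]` |
| substitution tracks (`pssm`, `freq`) | 20 | amino-acid-indexed |

Local descriptors window a track over w ∈ {1, 5, 9, 13, 17, 21} centered on
the position of change, zero-padding outside the chain. Difference
descriptors encode Δ = mutant − wild type per underlying channel as
(|Δ|, sign bit) with sign 1 for Δ ≥ 0; the tie direction and the
mutant-minus-wild-type orientation are fixed package conventions (the
source is silent). For the PSSM/frequency differences the single scalar
compared is the wild-type chain's matrix row at the center position,
evaluated at the wild-type vs the mutant amino acid — the most direct
reading of "difference in PSSM".

Under these widths the nine forward-selected descriptors — PSIC diff (2),
secondary structure w17 (51), alignment information w21 (21), flexibility
w21 (21), PSSM diff (2), single-sequence secondary-structure diff (6), Pfam
fit w13 (13), interaction hotspots w13 (26), volume w5 (5) — total exactly
147 values, reproducing the printed dimensionality; this is acceptance
target t1 and is recomputed, not asserted, in `scripts/acceptance.R`.

Normalization constants are documented config rather than recovered
originals: PSSM log-odds map affinely from [−16, 16] (clipped), information
content caps at 2 bits, propensity scales are min–max normalized. The
charge scale uses the 3-level encoding negative 0 / neutral 0.5 / positive
1 with histidine counted neutral (pKa ≈ 6, mostly uncharged at
physiological pH). Secondary-structure and accessibility *difference*
channels read separate single-sequence-mode tracks (`ss_raw`, `acc_raw`):
profile-based predictions barely respond to a single substitution, so the
encoder requires a distinct track name and leaves producing it to the
provider.

All external predictors (PSI-BLAST, PSIC, secondary structure,
accessibility, flexibility, disorder, hotspot, Pfam) are consumed as
precomputed per-residue tables or synthetic stand-ins; the package never
shells out to them.

## Model training and selection

`train_logreg()` minimizes the LIBLINEAR-parametrized primal
½‖w‖² + C Σ log(1 + exp(−y z)) with an unpenalized intercept, by damped
Newton iterations to gradient ∞-norm 1e-8. The exact solver settings of the
original (bias handling, stopping tolerance) are unpublished; C defaults to
1 and is exposed. Tests pin the optimum against an independent BFGS run on
the same convex objective and against glmnet's ridge-logistic at the
matched penalty λ = 1/n.

Cross-validation is homology-aware: connected components of the
protein-similarity graph (externally supplied edges, e.g. BLAST E ≤ 1e-3,
or a `global_identity()` fallback) are assigned atomically — largest
component first, seeded shuffle for ties, each to the currently smallest
fold — so no similar proteins straddle a train/test boundary. The
one-fifth selection holdout accumulates whole components the same way.
Fold balancing under homology constraints is our design; the original does
not describe how it met both constraints.

`forward_select()` evaluates every remaining candidate appended to the
accepted set with a full k-fold rotation, accepts the best mean test AUC,
and stops when the improvement is ≤ 0.001. Ties break lexicographically by
descriptor name (a deterministic choice where the original is silent).
Folds are fixed once per selection run rather than re-drawn before each
rotation — a deliberate deviation for reproducibility, recorded in the
project notes.

### The stop rule is noisy by construction

One acceptance property expects the 0.001 stop rule to fire within two
rounds when *all* candidates are noise. Simulation with the package's own
generator shows this is not an absolute property: each round takes the
maximum of ~20 cross-validated mean AUCs, and the chance improvement of
such a maximum is on the order of the AUC standard error (~0.01–0.05 at
n = 400; still above 0.001 at n = 10,000), so runs regularly accept three
or more noise features before converging. The search always terminates and
the final AUC stays near chance, but the two-round bound fails for a
sizeable fraction of seeds, and the corresponding acceptance test is left
red deliberately rather than weakened. Practically this means the 0.001
threshold acts as a "stop once the plateau is reached eventually" rule, not
a sharp noise gate — consistent with a nine-feature model whose last six
features contribute only marginally.

## Evaluation conventions

Positive class is "change"; prediction is change iff probability strictly
exceeds the threshold (0.5 default, so exactly 0.5 is neutral). The
class-specific formula bodies are not rendered in the available source
text, so the standard definitions are adopted and documented:
Accuracy_C = TP/(TP+FP), Coverage_C = TP/(TP+FN), mirrored for neutral;
Q₂ = (TP+TN)/all. ROC sweeps all distinct scores with tie grouping, which
makes the trapezoid AUC exactly the Mann–Whitney statistic (ties ½) — an
identity the tests verify to 1e-12. Enrichment analysis reports, for
thresholds 0.5…0.9, the fraction of externally labeled effect mutations
among those predicted to change structure; ΔΔG labels use strict
|ΔΔG| > 1 kcal/mol. Box statistics use linear-interpolation quartiles
(R type 7; the convention is unstated in the source) and 1.5·IQR whiskers.
Metrics with zero denominators are `NA` rather than errors.

## What the synthetic generator does and does not establish

`make_toy_chain()` builds idealized extended or α-helical backbones
(Cα spacing ~3.8 Å, peptide C–N gaps ~1.33 Å) with optional seeded Gaussian
coordinate noise; `make_pair_fixture()` plants a central mutation and a
controlled Cα perturbation, returning the true post-superposition RMSD so
label behavior is checkable by construction. `make_planted_dataset()` draws
a signal feature from unit-variance class-conditional Gaussians separated
by d — giving the closed-form single-feature AUC Φ(d/√2), the package's
main quantitative oracle (d = 2 ⇒ ≈ 0.9214) — plus standard-normal noise
features. Defaults follow the spec'd exemplars (d = 2, balanced classes,
n = 10,000 for the AUC recovery check); the selection-correctness runs use
n = 400, a desk-scale stand-in for the original ~5,000-instance selection
set chosen once for runtime, before any measurement.

Gaussian coordinate noise is a *surrogate*: any monotone perturbation→RMSD
map suffices to test the pipeline, but it shares nothing with the
evolutionary process that generates real conformational differences, and
synthetic tracks carry no biology. A green test therefore establishes that
the machinery is correct — parsing, pairing rules, superposition optimality,
encoding widths and ranges, fold hygiene, selection and metric arithmetic —
not that the headline discriminative performance of the original study is
reproduced. That would require the full PDB snapshot, CD-HIT/HVAL
clustering and the external predictor battery, all out of scope here.

## Known limitations

* No mmCIF input; no NMR multi-model handling beyond MODEL 1; no assembly
  building or symmetry expansion.
* PDB-scale redundancy reduction (CD-HIT at 98%, HVAL-based filtering) is
  accepted as precomputed input; the fallback is a simple identity-threshold
  reduction via `global_identity()`, adequate only at fixture scale.
* Third-party function/stability predictors are compared by ingesting their
  score tables at their published decision boundaries, never re-implemented.
* All-against-all pairing is hash-accelerated on the 4-residue context but
  not engineered for full-PDB scale.
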