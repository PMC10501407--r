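---
title: "Methods: QSAR models, synthetic ground truth and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QSAR models, synthetic ground truth and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmQSAR)
```

gbmQSAR implements a complete structure–activity modelling workflow for a
congeneric series of dihydropteridone PLK1 inhibitors: a linear model built
by heuristic forward descriptor selection, a nonlinear model found by gene
expression programming (GEP), a 3D similarity-field (CoMSIA-style) model
fit by PLS, the standard external/internal validation statistics, and a
candidate-design stage. This vignette explains the models, their
assumptions, the tunable parameters, what the synthetic-data generators do
and do not emulate, and the design decisions taken where conventions
diverge.

## Activity scale

Assay potencies are IC50 values in µM. All models work on
pAct = 9 − log10(IC50/µM), which compresses the dynamic range and makes
*higher = more potent*: the packaged 34-compound table (0.18–1.07 µM)
spans pAct 8.97–9.74, with compound 21E the most potent. Printed
literature sometimes states this transform as "log(IC50) + 9"; that form
is *increasing* in IC50 and is inconsistent with reported predicted
activities near 9.5–9.6 for the most potent analogs, so the decreasing
form is the default. The literal increasing variant remains available via
`transformActivity(..., formula = "literal")` for audit purposes.

Train/held-out partitions (`splitDataset`) use seeded uniform sampling
without replacement; for a ratio a:b the held-out size is
round(n·a/(a+b)), so 34 compounds give 8/26 at 1:3 (the 2D protocol) and
7/27 at 1:4 (the 3D protocol). The original test-set membership is not
recoverable from the printed table, so membership here is always an
explicit function of the seed, which is recorded in all outputs.

## Heuristic linear modelling

`fitMlr` is ordinary least squares with the diagnostics selection relies
on: R², leave-one-out R²cv computed through the hat-matrix identity
e·i/(1 − h·ii) (algebraically identical to n refits, and tested against
them), s² = RSS/(n − k − 1), per-coefficient t values and the overall F.
The "s²" label follows the residual-variance reading: a value like 0.02 on
a few dozen compounds is only consistent with a variance-like quantity,
not a raw residual sum of squares, so the raw RSS is reported alongside.
Degenerate responses (zero variance) get R² = 0 by convention rather than
NaN.

`prefilterDescriptors` removes constant columns, columns with missing
values and, for every pair correlated at |r| ≥ 0.80 (the cap used
throughout), the member less correlated with the activity. The cap is
applied again as an admissibility constraint during selection, so selected
subsets always satisfy the pairwise condition.

`heuristicSelect` is greedy forward search maximizing R², implemented by
orthogonalizing candidates against the selected block so each step costs
one matrix product rather than p refits. Equal-gain ties resolve to the
lexicographically smaller descriptor name for reproducibility. The
*recommended* size is the last k whose R² gain reached `stopDelta`
(default 0.02; the plateau criterion in the source workflow is stated only
qualitatively). A caveat worth knowing: with very wide candidate sets the
best-of-p spurious gain at step k is approximately 2·log(p)/(n − k) times
the residual fraction, which for 500 candidates on 34 compounds stays
near or above 0.02 out to sizes 7–8. The recommended size under the
default `stopDelta` therefore tends to overshoot a six-descriptor truth by
one or two — this is a property of greedy selection at that n/p ratio, not
of the implementation, and the trace object exposes the full gain sequence
so users can apply a stricter rule.

The published six-descriptor model is shipped verbatim
(`referenceHmModel()`): intercept −24.280, coefficients for NFA, MRCH,
MECN, TEIZP, ZXS, MCIHN, and the published diagnostics (R² 0.6682, R²cv
0.5669, s² 0.0199) carried as metadata. They are *not* recomputed: they
were obtained on a commercial (CODESSA-type) descriptor matrix that is not
publicly available.

## Gene expression programming

The GEP engine evolves fixed-length Karva chromosomes: each gene has a
function-bearing head of length h and a terminal-only tail of length
t = h·(amax − 1) + 1, which guarantees every breadth-first decoding
terminates inside the gene. Multigene chromosomes are joined by a linking
operator ("+" by default). The function set is {+, −, ×, ÷, inv, sin},
all weight 1. The "inverse" operator is 1/x; a natural-log reading of the
symbol is available via `defaultFunctionSet(inverse = "ln")` since the
printed symbol is ambiguous.

Operator rates are not published for this workflow, so the defaults follow
standard GEP practice: mutation 0.044, IS/RIS/gene transposition 0.1 each,
one-/two-point recombination 0.3 each, gene recombination 0.1, population
50, head length 8, three genes. All are configurable via `gepConfig`.
Selection is elite roulette: fitness-proportional sampling with the elite
individual(s) copied unconditionally, which makes best-so-far fitness
non-decreasing.

Two numerical contracts matter. First, division or inversion by a value
below 1e−12 in magnitude yields UNDEFINED (NA), which propagates to the
root; a tree with any undefined training prediction scores fitness 0.
This deliberately avoids "protected division" conventions that return 1
and thereby reward pathological denominators. Second, fitness is the
coefficient of determination 1 − RSS/TSS clamped at 0 (constant trees
score 0), *not* squared correlation — a tree must match the response's
scale, not merely its shape. Because the engine uses no random numerical
constants (the published equation contains none), trees cannot express
large additive offsets; the pipeline therefore standardizes the activity
before the GEP stage and reports fits on that scale.

The published nonlinear equation ships as a plain-text transcription
parsed by a recursive-descent parser with conventional precedence (unary
calls bind tightest; × and ÷ left-associative over + and −). Its printed
structure is preserved exactly, including a self-cancelling
(MECN − MECN) subexpression and a leading 1/(TEIZP − NFA) term that is
undefined when TEIZP = NFA. The parser/evaluator pair is verified against
an independent evaluation route on random bindings at 1e−10.

## CoMSIA-style 3D modelling

Molecules are superposed on a template by Kabsch least-squares rotation
over mapped scaffold atoms (reflections excluded; collinear maps
rejected). The field grid is a cube of pitch 2 Å extended 4 Å beyond the
union bounding box — a single point molecule yields 5×5×5 = 125 grid
points. Five similarity fields are evaluated at every point with Gaussian
distance attenuation exp(−α·r²), α = 0.3 Å⁻², no distance cutoff, and the
similarity-index sign convention (negated sums). Field weights per atom:
steric = r³ (Bondi vdW radii), electrostatic = partial charge,
hydrophobic = an atom-typed lookup table shipped with the package,
donor/acceptor = rule flags (H on N/O marks a donor; N and O are
acceptors). The probe carries unit weight in every field. These probe and
atom-parameter choices are the conventional CoMSIA defaults; the source
workflow says only "default probe".

Columns with standard deviation below `minSigma = 0.05` similarity units
are masked (the commercial analog is an energy-unit column filter, which
does not transfer). PLS is NIPALS-style latent-variable extraction; LOO Q²
is computed per component count by explicit refits, and the optimal number
of components (ONC) maximizes Q², smallest count on ties (the source
reports an ONC but no rule). The refit at ONC reports R²,
SEE = sqrt(RSS/(n − c − 1)), F = (R²/c)/((1 − R²)/(n − c − 1)) and field
contribution fractions: per-field sums of |coefficient|·column-sd,
normalized to 1 (the corresponding published row sums to 1.215 as printed,
so normalization is by contract here). Contours select grid points whose
coefficient·sd product lies strictly above the 80th / below the 20th
percentile of their field (SYBYL-convention defaults, configurable), and
export as OpenDX scalar grids.

## Validation statistics

External validation uses R²ext = 1 − Σ(y − ŷ)²/Σ(y − ȳtrain)², which may
be negative. rm² = r²·(1 − sqrt(r² − r₀²)) penalizes divergence between
the free and through-origin fits; because the through-origin direction is
ambiguous in parts of the literature, both the
predictions-on-observations ("direct") and reversed variants are
computed, and "overall" is their mean. Negative radicands (through-origin
fit slightly better) are clamped to 0, where rm² reduces to r².
Y-randomization permutes the response (seeded), refits with the model
structure held fixed (same descriptor subset or ONC; a full re-selection
mode would multiply cost without changing the question being asked) and
reports R²p = R²·sqrt(R² − mean(R²r)) plus the per-iteration scrambled
values; 0.5 is the conventional robustness line for all three statistics.
All three are verified against independently written implementations at
1e−10.

## Synthetic ground truth

The generators exist so that every stage can be tested against known
truth, at the study's own problem sizes, with no external inputs.

The **linear preset** (`paperPresetLinear`) emulates the 2D regime:
34 compounds × 500 standard-normal descriptors, ten equicorrelated
nuisance blocks of ten at r = 0.9 (via the Cholesky factor of the block
correlation matrix), a six-descriptor causal subset named after the
published descriptors with coefficient magnitudes proportional to the
published ones, noiseless activities rescaled to span 8.97–9.74, and
Gaussian noise sized so the true-model R² is about 0.67. Note a structural
consequence of proportional coefficients: three descriptors carry ~99% of
the signal variance, so selection at n = 34 recovers the dominant three
reliably and the minor three rarely — realistic for this data regime.

The **nonlinear plant** evaluates an arbitrary expression tree over the
descriptors, flags rows where it is undefined, and adds seeded noise (the
noise stream is drawn from a fixed offset of the spec seed so it is
independent of the matrix stream).

The **field plant** (`generateAlignedMolecules`) emulates a congeneric
series stacked on a template: a fixed three-atom scaffold shared by all
molecules plus decoration atoms at substitution sites common to the whole
series (each molecule occupies a random subset of sites with 0.35 Å
jitter and randomized charges, hydrophobicities and donor/acceptor
flags). The planted coefficient vector is a random, singular-value-
weighted combination of the top-k right singular directions of the
centered field matrix (k = 6 by default) — i.e. exactly the coefficient
space a k-component PLS model spans. This makes "parameter recovery"
well-posed: a coefficient vector sparse in arbitrary grid columns is
largely outside the identifiable row space at n ≈ 50 and cannot be
recovered by any method from these data. The noiseless activity is
rescaled to the assay span and Gaussian noise (default preset 0.06,
giving a planted-signal R² near 0.9, typical of a good 3D-QSAR fit) is
added.

What the generators do *not* emulate: the physical marginal distributions
of real quantum-chemical descriptors, chemically valid bond graphs and
conformers, or correlations between 2D descriptors and 3D fields (the two
branches draw independent synthetic worlds). Passing recovery tests
therefore demonstrate correctness of the estimators under the stated
statistical structure, not predictive validity on real compounds.

## Pipeline, problem sizes and numerical choices

`runPipeline` chains simulate → hm → gep → comsia → validate → design with
per-stage seeds derived as fixed offsets of one master seed; reruns with
the same configuration are bit-identical. Default sizes are the emulation
presets: 34 × 500 for selection, GEP population 100 for up to 60
generations on the six causal descriptors, 50 molecules (40 train / 10
validation at 1:4) for the 3D branch, 20 Y-randomization scrambles, 200
designed candidates. The standalone GEP recovery setting (population 500,
cap 200 generations) recovers a planted a + sin(b) within a couple of
generations in practice. A stage failure aborts downstream stages;
completed results and a status manifest are preserved.

Other numerical details: matrix work uses QR (rank deficiency is reported
with the names of dependent columns); LOO shortcuts guard 1 − h with the
machine epsilon; model serialization prints 17 significant digits so text
round-trips are exact; candidate ranking breaks prediction ties by id.

## Known limitations

* The published headline statistics (linear R² 0.6682 family, nonlinear
  0.79/0.76, the 3D Q²/R²/SEE/F row, external 0.65/0.64/0.61 and docking
  scores) depend on commercial descriptor/field software outputs that are
  not public; they are carried as metadata, never recomputed. Two printed
  3D Q² values (0.628 and 0.682) disagree with each other; both are
  recorded in the model metadata.
* Structures of the assayed compounds are printed only as figures; the
  fixture carries ids and IC50 values, and no structure reconstruction is
  attempted.
* The design stage exposes the mechanism (template + explicit modification
  library) rather than the original 200 hand-designed analogs, whose
  generation was not disclosed.
* Docking and force-field minimization are out of scope; 3D inputs are
  accepted as given conformers.
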