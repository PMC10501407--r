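# gbmQSAR

2D and 3D quantitative structure–activity relationship (QSAR) modelling for
dihydropteridone-class PLK1 inhibitors assayed against glioblastoma cells,
built as a reusable, fully tested R package. It is aimed at computational
medicinal chemists who want the complete workflow — descriptor selection,
symbolic regression, 3D similarity fields, statistical validation and
candidate design — without depending on commercial descriptor or field
software.

## What it computes

Activities are modelled on the transformed scale **pAct = 9 −
log10(IC50/µM)**, so more potent compounds score higher (the packaged
34-compound assay table spans 8.97–9.74).

* **Heuristic linear modelling** (`prefilterDescriptors`,
  `heuristicSelect`, `fitMlr`): greedy forward selection over a wide
  descriptor matrix under a pairwise collinearity cap (|r| < 0.80),
  scoring subsets by R², leave-one-out R²cv (hat-matrix identity) and
  s² = RSS/(n−k−1). The published six-descriptor equation (NFA, MRCH, MECN,
  TEIZP, ZXS, MCIHN) ships verbatim as `referenceHmModel()`.
* **Gene expression programming** (`evolveGep`, `decodeChromosome`,
  `parseExpression`): a full GEP engine over fixed-length Karva
  chromosomes — breadth-first decoding, elite roulette selection, mutation,
  IS/RIS/gene transposition and one-/two-point/gene recombination — with
  the six-operator function set {+, −, ×, ÷, inv, sin}. The published
  nonlinear equation is shipped as a parsed expression tree
  (`publishedGepModel()`), including its printed quirks (a self-cancelling
  MECN − MECN term; 1/(TEIZP − NFA) undefined when TEIZP = NFA).
* **CoMSIA-style 3D modelling** (`alignToTemplate`, `buildGrid`,
  `assembleFieldMatrix`, `fitPls`, `contourMaps`): Kabsch scaffold
  superposition; five Gaussian similarity fields (steric, electrostatic,
  hydrophobic, H-bond donor/acceptor) with attenuation α = 0.3 Å⁻² on a
  2 Å grid extended 4 Å beyond the molecules; PLS (NIPALS) with LOO Q² and
  ONC selection; SEE, F, per-field contribution fractions; favored and
  disfavored contour grids exported in OpenDX format.
* **Validation** (`r2Ext`, `rm2`, `yRandomization`): external R²ext against
  the training mean, rm² (direct, reversed and overall, with through-origin
  R₀²) and 20-fold Y-randomization summarized as R²p = R²·√(R² − mean R²r),
  with the conventional robustness line at 0.5.
* **Design** (`enumerateCandidates`, `predictAndRank`): candidate analogs
  of a template from an explicit modification library, scored by every
  fitted model and ranked by the primary (3D) model.
* **Synthetic ground truth** (`paperPresetLinear`,
  `generateDescriptorMatrix`, `generateAlignedMolecules`): seeded
  generators planting linear, nonlinear and 3D-field structure–activity
  relationships at the study's problem sizes (34 compounds × 500
  descriptors with block collinearity; congeneric molecule series on a
  shared scaffold), so every stage is testable with known truth.

`runPipeline(defaultPipelineConfig(seed))` chains all stages
(simulate → hm → gep → comsia → validate → design) with a shared seed
ledger and writes provenance-stamped artifacts.

## Worked example

```r
library(gbmQSAR)

cs <- table1CompoundSet()        # packaged 34-compound assay fixture
cs
#> CompoundSet with 34 compounds ( .../dihydropteridone_ic50.csv )
#>   activity (pAct) range: 8.9706 - 9.7447
#>   roles: unassigned:34

referenceHmModel()               # the published six-descriptor equation
#> LinearQsarModel (published six-descriptor model)
#>   intercept: -24.28
#>   NFA           0.29798
#>   MRCH          0.44403
#>   MECN           5.6298
#>   TEIZP        -0.57965
#>   ZXS            3.6953
#>   MCIHN          -3.837
#>   r2 = 0.6682  r2_cv = 0.5669  s2 = 0.0199

# a 3D model on a synthetic congeneric series with planted ground truth
g   <- generateAlignedMolecules(fieldPlantSpec(nMolecules = 50,
                                               noiseSd = 0.06, seed = 8))
fit <- fitPls(g$truth$fieldMatrix, g$activity, maxComponents = 10)
fit
#> PlsQsarModel: ONC = 4
#>   q2 = 0.8374  r2 = 0.9289  SEE = 0.0520  F = 146.8885
#>   field fractions: S:0.946 E:0.008 H:0.009 D:0.017 A:0.021
cor(fit@coefficients, g$truth$weights)
#> [1] 0.967
```

The model print shows the LOO cross-validated Q², the optimal number of
PLS components (ONC), the non-CV R², the standard error of estimate and
how much each similarity field contributes to the model; the final
correlation measures how well the fitted coefficient vector recovers the
planted one. The published model's stats (r2 = 0.6682 etc.) are carried as
metadata from the original study, whose commercial descriptor matrix is
not available; they are not recomputed here.

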