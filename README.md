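# gaborSeverity

Continuous severity scoring of colonic inflammation from HE-stained
histology images.

Expert histological grading of colitis — in DSS mouse models and human
ulcerative colitis biopsies — uses coarse ordinal scales with substantial
rater dependence. `gaborSeverity` implements an automated, continuous
alternative built from spatial-frequency texture analysis: 512 × 512
grayscale cutouts are convolved with a bank of 216 Gabor filters

$$g_{\lambda,\theta,\varphi,\sigma,\gamma}(x,y) =
  \exp\!\Big(-\tfrac{x'^2+\gamma^2 y'^2}{2\sigma^2}\Big)
  \cos\!\Big(2\pi\tfrac{x'}{\lambda}+\varphi\Big),
  \qquad \sigma/\lambda = \tfrac{1}{\pi}\tfrac{\sqrt{\ln 2}}{2}
  \tfrac{2^b+1}{2^b-1},$$

over 6 orientations × 3 aspect ratios × 3 wavelengths × 4 octave
bandwidths. Responses are max-pooled over orientation (36 maps), each map
is summarised by mean, histogram skewness and histogram entropy
(108 features), and the first principal component of the training feature
matrix — min–max normalised to [0, 1] — is the severity score: 0 means no
inflammation, 1 the most severe inflammation in the training cohort. A
pairwise expert-agreement protocol (agreement rate, mismatch-versus-Δ
curve, resolution estimate) validates the score against human ranking, and
a synthetic generator of histology-like cutouts with known latent severity
makes the whole pipeline testable without slide data.

Intended users: groups quantifying mucosal inflammation in animal-model or
biopsy imaging who want a scalar, reproducible severity axis rather than an
ordinal grade.

## Worked example

```r
library(gaborSeverity)

cohort <- generateCohort(6, levels = c(0, 0.5, 1), seed = 42)  # 18 cutouts
X      <- extractFeatureMatrix(cohort$cutouts)                 # 18 x 108
model  <- fitSeverityModel(X, labels = cohort$truth$severity)
scores <- severityScore(model, X)

model
#> SeverityModel on 108 features
#>   centring: TRUE  standardised: FALSE
#>   PC1 variance fraction: 98.1%
#>   PC2, PC3: 1.2%, 0.7%
#>   raw PC1 training range: [-31.64, 26.17]

cor(cohort$truth$severity, scores$score, method = "spearman")
#> [1] 0.9442674

tapply(scores$score, cohort$truth$severity, mean)
#>         0       0.5         1
#> 0.1461238 0.5956626 0.9000202
```

PC1 absorbs ~98% of the feature variation and the normalised score tracks
the latent severity of the generated cutouts: mean score rises from 0.15
(healthy) through 0.60 (intermediate) to 0.90 (severe), with rank
correlation 0.94. `contributions(model)` shows which filter triples and
statistics carry the axis; `screeTable(model)` gives the per-component
variance shares.

Real images enter through `readHistologyImage()` (PNG/TIFF, 8/16-bit, gray
or RGB), `normalizeIllumination()` (additive white-peak alignment against a
reference image) and `extractCutout()`. Expert pair choices recorded as CSV
are analysed with `comparisonRecords()`, `agreementRate()` and
`mismatchCurve()`. A command-line wrapper for the whole pipeline is in
`inst/scripts/severity-cli.R` (subcommands `simulate`, `features`, `fit`,
`score`, `validate`).

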