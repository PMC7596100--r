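# immunospat

Spatial statistics and maximum-likelihood inference of immune-cell
infiltration in tumour point patterns.

## What it does

Digital-pathology pipelines reduce an immunohistochemistry slide to a
*point pattern*: the (x, y) coordinates of each stained immune cell
(e.g. CD68+ macrophages) inside a region of interest, here a
1.5 mm × 1.5 mm tile.  How deeply those cells infiltrate the tumour
cell nests correlates with prognosis, but manual scoring is slow and
semi-quantitative.  `immunospat` provides a quantitative pipeline:

1. **Spatial statistics.** For a pattern of n points it computes the
   pair correlation function g(r) (with exact analytic edge correction
   on the rectangular window), the nearest-neighbour CDF G(r), the
   spherical-contact / empty-space CDF F(r), and the J-function
   J(r) = (1 − G(r)) / (1 − F(r)), and summarises the pattern by

   * g_max = max g — peak clustering intensity,
   * F_max = min { r : F(r) = 1 } — radius of the largest empty circle
     ("immune desert" size, mm),
   * J_min = min J ∈ [0, 1] — clustering depth,

   plus the cell density d (cells/mm²).

2. **Synthetic tissue generation.** Two-compartment tumour-nest/stroma
   geometries from median-thresholded Gaussian random fields (nest
   length scale l ~ U[0.1, 0.75] mm), cell density
   d ~ Normal(333, 170) truncated at 150 cells/mm², a 0.02 mm
   hard-core exclusion between cell centres, and a tunable
   infiltration ratio ρ = d_t/d_s ∈ [0, 0.5] (0 = complete exclusion
   from nests, 1 = uniform mixing).

3. **Inference.** Per-ρ feature distributions are modelled as
   Gaussians whose means and SDs follow exponential curves
   a·e^(−bρ) + c; the covariance Σ(ρ) combines fitted SDs with
   empirical feature correlations.  For an observed pattern, the
   profile log-likelihood over ρ yields the MLE η and a 95%
   profile-likelihood CI (threshold χ²₀.₉₅,₁/2 = 1.9207), from any of
   the seven subsets of {g_max, F_max, J_min}.

## Worked example

```r
library(immunospat)

# generate one synthetic pattern with known infiltration
params <- generation_params(rho = 0.2, d = 333, l = 0.4)
p <- generate_pattern(params, seed = 7)
p
#> point_pattern: 749 points in 1.5 x 1.5 mm window (d = 332.9 cells/mm^2)

summary_features(p, seed = 8)
#> summary_features: g_max = 1.529, F_max = 0.126 mm, J_min = 0.000, d = 332.9 cells/mm^2

# train a (small) feature model and infer rho for the pattern
train <- simulate_feature_table(rep(seq(0, 0.5, 0.05), each = 60), seed = 42)
model <- train_feature_model(train)  # warns: J_min SD curve interpolated
estimate_rho(summary_features(p, seed = 8), model, subset = "gFJ")
#> rho_estimate [gFJ]: eta = 0.264, 95% CI [0.160, 0.418]
```

The 95% interval covers the generating ρ = 0.2 (this pattern's J_min
happens to sit at its clustered extreme, pulling η up slightly);
larger training ensembles (200+ patterns per ρ) tighten the fitted
curves and the intervals.  `predict_batch()` +
`validation_report()` score any subset of statistics on a labelled
ensemble by R² about the identity line ρ = η and by mean CI width.

A command-line wrapper is installed at
`inst/cli/immunospat-cli.R` with subcommands `synth-generate`,
`featurize`, `train`, `predict`, `validate` and `reproduce-figures`,
driven by a YAML config plus flags; all randomness flows from one
master seed.

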