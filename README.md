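# lysoquant

Quantitative analysis of lysosomal physiology and protein traffic from
fluorescence microscopy, built around the assays used to study how the
antioxidant Lipocalin ApoD protects lysosomes under oxidative stress:

- **Single-lysosome pH** from ratiometric dye emission spectra: each
  lysosome's 420–700 nm spectrum is fitted with a five-parameter
  Weibull peak
  `f(λ) = y0 + a·((c−1)/c)^((1−c)/c)·u^(c−1)·exp(−u^c + (c−1)/c)`,
  `u = (λ−x0)/b + ((c−1)/c)^(1/c)`, the I(470)/I(524) ratio of the
  fitted curve is inverted through a linear calibration built from
  ionophore-clamped standards (pH 4.0–5.5), and per-class pH frequency
  distributions and modal bins are reported. Lysosomes are classified
  ApoD-positive/negative from the immunolabel channel.
- **Population pH** from plate-reader excitation ratios
  (mean F340/mean F390 over six replicate reads per well) inverted
  through monotone piecewise-linear interpolation of clamped standards
  (pH 4.0–6.0).
- **Pixel colocalization**: Gaussian preprocessing, Otsu or manual
  thresholding, the intensity correlation quotient
  `ICQ = #{(A−Ā)(B−B̄) > 0}/#{(A−Ā)(B−B̄) ≠ 0} − 0.5 ∈ [−0.5, 0.5]`
  (|2×ICQ| < 0.1 is chance), percent pixel overlap referenced to a
  channel, and triple-mask conjunction.
- **Object analysis**: 3D connected components (6/18/26-connectivity)
  with voxel volumes and centroids, 2D particle statistics, per-cell
  integrated intensity and fold change.
- **Eye-surface regularity** for compound-eye degeneration assays:
  local-maxima detection, nearest-neighbor distances, a regularity
  index `IREG = n_spots/(1 + CV)` and percent recovery.
- **Feature selection**: the two-round PCA workflow over per-cell
  imaging variables with a two-factor comparison of component scores.

A first-class **synthetic-data module** generates every input the
pipeline consumes — vesicle-bearing two-channel stacks with controlled
colocalization, pH-dependent emission spectra, clamped calibration
standards, excitation plates, jittered hexagonal lattices, particle
fields — with known ground truth and explicit seeds, so the whole
pipeline is testable end to end without any microscopy data.

Intended users are microscopists and image-analysis scientists who
need reproducible, scriptable versions of these standard readouts, or
a simulation harness to validate their own variants.

## Worked example

Simulate 30 control ApoD-negative lysosomes, build the calibration
from clamped standards generated by the same spectral model, and
recover the pH distribution:

```r
library(lysoquant)

gt  <- spectrum_ground_truth(condition = "control", class = "ApoD-",
                             seed = 2)
cal <- fit_emission_calibration(
  standards_to_ratios(make_calibration_standards(gt)))
recs <- estimate_lysosome_ph(make_spectra(gt)$spectra, cal)
ph_distribution(recs$ph)$modes
#>   group mode_center  n
#> 1   all        4.45 30
```

The modal bin [4.4, 4.5) recovers the simulated population mode of
pH 4.4 (bin centers are quantized to 0.05). The population assay
recovers the paraquat-induced alkalinization:

```r
ex  <- make_excitation_readings(seed = 1)
pop <- population_ph_excitation(split(ex$wells$f340, ex$wells$well),
                                split(ex$wells$f390, ex$wells$well),
                                ex$standards)
pop
#>      well    ratio       ph clamped
#> 1 control 1.890929 4.578821   FALSE
#> 2      CQ 1.035909 5.500003   FALSE
#> 3      LS 1.886103 4.584020   FALSE
#> 4    PQ2h 1.403421 5.104052   FALSE
```

PQ2h minus control is +0.53 pH units against a designed +0.5; the
chloroquine positive control reads at the alkaline end as designed.

The numbered scripts under `analysis/` run the full workflow —
`01_simulate.R` writes every synthetic dataset with its truth tables,
`02_colocalization.R` through `06_feature_selection.R` reproduce the
colocalization, object, pH, eye-regularity and PCA analyses — writing
provenance-stamped CSVs under `results/`.

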