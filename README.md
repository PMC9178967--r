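# wmhpenumbra

Synthetic-cohort analysis of white matter hyperintensity (WMH) lesions and
their perilesional "penumbra" with quantitative MRI.

White matter hyperintensities are the most common incidental MRI finding in
aging. The normal-appearing white matter (NAWM) around a WMH often shows
sub-visible change, and the open question is *what kind*: accumulating
interstitial fluid (potentially reversible) or loss of myelin
(irreversible). Diffusion metrics — fractional anisotropy (FA) and mean
diffusivity (MD) — are sensitive to both and cannot tell them apart.
Multi-echo T2 relaxometry adds the missing specificity:

- **MWF** (myelin water fraction): the area of the T2 spectrum from 10 to
  40 ms over the total spectral area — a myelin-specific marker;
- **GMT2** (geometric mean T2 of the intra/extracellular pool):
  `exp( Σ aᵢ ln T2ᵢ / Σ aᵢ )` over 40–200 ms — an interstitial-fluid
  marker.

The package implements, as tested and reproducible code over synthetic
cohorts with known ground truth:

1. **Phantom generation** — tissue-label volumes (ventricles, CSF rim,
   grey matter, NAWM, periventricular and deep WMH blobs, optional
   single-hemisphere stroke lesion), programmed parameter maps with a
   quadratic perilesional fluid gradient (`v(d) = v₀ + Δv·max(0, 1−d/6mm)²`),
   a group-restricted WMH myelin deficit, two-pool multi-echo signals with
   EPG stimulated-echo physics, B1 (flip-angle) inhomogeneity and Rician
   noise, and diffusion-weighted signals over a 60-direction b=700 s/mm²
   scheme. NIfTI + FSL-style `bval`/`bvec` + TSV covariates out.
2. **T2 relaxometry** — extended-phase-graph decay bases (validated against
   an isochromat oracle), voxelwise flip-angle estimation,
   Lawson–Hanson NNLS with Tikhonov regularization tuned so the misfit
   lands in a 1.02–1.025 × χ²min window, and MWF/GMT2 maps.
3. **Diffusion tensor** — two-pass weighted linear least squares, FA/MD
   maps.
4. **Perilesional ROIs** — exact anisotropic Euclidean distance transform,
   five 2 mm rings from 2 to 10 mm around the WMH with 1 mm CSF and 10 mm
   stroke exclusions, periventricular/deep classification by 26-connected
   ventricular contact, hemisphere splitting, per-ROI metric means.
5. **Mixed-effects models** — distance(quadratic contrast)×group,
   distance×hemisphere and log-lesion-volume families via lme4/lmerTest
   (Satterthwaite df) with scanner and nested-participant random effects,
   and Tukey-adjusted post hoc contrasts via emmeans.

## Worked example

```r
library(wmhpenumbra)

# one voxel: simulate a two-pool decay and fit it back
seqp <- scanner_sequence("A_32echo")      # 32 echoes, 10 ms spacing
set.seed(1)
et   <- simulate_echo_train(mwf = 0.15, ie_t2 = 80, flip_angle = 140,
                            seq = seqp, s0 = 1000, noise_sigma = 5)
fit_voxel(et)
#> Myelin water fit
#>   MWF        : 0.1048
#>   GMT2       : 76.29 ms
#>   flip angle : 139.8 deg
#>   chi2 = 616.4 (mu = 0.000505)
```

The fit recovers the programmed flip angle (140°) to a fraction of a
degree and the intra/extracellular T2 (80 ms) to a few ms; single-voxel
MWF at SNR 200 carries sampling noise of a few hundredths (the analysis
operates on ROI means, where this averages out).

```r
# a small end-to-end cohort: simulate -> fit maps -> rings -> models
cfg  <- run_config(seed = 2, n_older = 3, n_stroke = 3,
                   out_root = "penumbra_demo")
fits <- run_all(cfg)
print(fits$distance_group_GMT2)
#> Linear mixed model [distance_group], outcome GMT2
#>                    term estimate    se        df        p
#>             (Intercept)  80.4100 0.349  1.999269 1.89e-05
#>                   age_z   0.1864 0.254  1.999709 5.40e-01
#>                  moca_z   0.2466 0.254  1.998891 4.34e-01
#>              distance.L  -8.7120 0.342 25.999961 6.41e-20
#>              distance.Q   3.7750 0.342 25.999961 2.59e-11
#>             groupstroke   1.7680 0.494  1.999566 7.00e-02
#>  distance.L:groupstroke  -5.1150 0.483 25.999961 6.46e-11
#>  distance.Q:groupstroke   2.0690 0.483 25.999961 2.25e-04
```

With only 3+3 subjects the quadratic distance term for GMT2 is already
decisive (p = 2.6e-11: the programmed fluid gradient), while MWF shows no
distance main effect (p = 0.28) but a clear distance×group interaction
(p = 0.0014) — the programmed stroke-restricted myelin deficit inside
the lesion. Outputs land under
`penumbra_demo/`: per-subject NIfTI maps, ring ROI volumes, the long
ROI table (`rois/roi_table.tsv`), per-model TSVs under `stats/`, a config
snapshot and an MD5 manifest.

A thin command-line wrapper over the same functions ships as
`inst/cli/penumbra.R` (`simulate`, `fit-mwi`, `fit-dti`, `rois`, `stats`,
`run-all`, with `--config`, `--seed`, `--out`, `--deep-only`,
`--hemisphere-split`).

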