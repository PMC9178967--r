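---
title: "Quantitative MRI of the WMH penumbra: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MRI of the WMH penumbra: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

White matter hyperintensities (WMHs) are focal lesions of presumed vascular
origin. The normal-appearing white matter (NAWM) around them — the
"penumbra" — often shows sub-visible microstructural change. Two candidate
mechanisms are increased interstitial fluid and loss of myelin, and
conventional diffusion metrics cannot separate them: fractional anisotropy
(FA) and mean diffusivity (MD) respond to both. Multi-echo T2 relaxometry
adds specificity: the myelin water fraction (MWF, the 10--40 ms share of
the T2 spectrum) indexes myelin content, while the geometric mean T2 of
the intra/extracellular pool (GMT2, the 40--200 ms band) indexes
interstitial fluid.

This package implements the full analysis chain over *synthetic* cohorts:
a brain phantom with programmed tissue truth, signal simulation for a
multi-echo spin-echo (GRASE-like) readout and a 60-direction diffusion
protocol, voxelwise fitting of MWF/GMT2 and FA/MD, construction of 2 mm
perilesional distance rings, and the linear mixed-effects models relating
ring means to distance, group, hemisphere and lesion volume. Because the
cohort is simulated with known ground truth, every stage can be tested
for parameter recovery, programmed-null behaviour and type-I error.

# T2 relaxometry

## Signal model

Each voxel's multi-echo decay is a two-pool mixture,

$$ S(t_n) = S_0\left[\,f\,b_{20}(t_n;\alpha) + (1-f)\,b_{T_2^{ie}}(t_n;\alpha)\,\right], $$

where $f$ is the MWF, the myelin pool relaxes with $T_2 = 20$ ms, the
intra/extracellular pool with $T_2^{ie}$ (80 ms in healthy NAWM), and
$b_{T_2}(t;\alpha)$ is the echo amplitude predicted by the extended phase
graph (EPG) at refocusing flip angle $\alpha$. The EPG propagates the
configuration states (F+, F-, Z) through the refocusing train with
relaxation over each half echo spacing and one crusher dephasing shift per
half interval; at $\alpha = 180°$ it collapses to
$\exp(-n\,\Delta TE/T_2)$, and at lower angles stimulated-echo pathways
move signal into later echoes. The implementation is validated against an
independent isochromat (Bloch rotation-matrix) ensemble to $10^{-12}$ or
better per echo. Longitudinal regrowth of the $Z_0$ state is ignored
(unit-amplitude basis; the assumed $T_1 = 1000$ ms affects only the decay
of stored longitudinal states, to which the estimates are insensitive at
these TRs).

## Spectrum estimation

The fit inverts the decay onto a 40-bin logarithmic T2 grid from 10 to
2000 ms. The grid places no bin exactly at 40 ms, so the MWF (10--40 ms,
inclusive) and GMT2 (40--200 ms, inclusive) windows never share a bin.
The estimator is Tikhonov-regularized non-negative least squares:

$$ \min_{a \ge 0}\; \lVert B a - s \rVert^2 + \mu \lVert a \rVert^2, $$

with $\mu$ chosen by bisection in $\log\mu$ so that the data misfit
$\chi^2(\mu)$ lies within $[1.02, 1.025] \times \chi^2_{\min}$ of the
unregularized Lawson--Hanson solution. Because $\chi^2(\mu)$ is nearly
flat over a wide range of $\mu$ (an ill-posed direction of the inverse
problem), the solver converges to the *smallest* $\mu$ reaching the
window: larger in-window weights oversmooth the spectrum and bias MWF
downward. When the window is unattainable (a noiseless, exactly
representable signal) the unregularized solution is returned with
$\mu = 0$ and flagged.

The refocusing angle is estimated per voxel before the final fit: the
unregularized NNLS residual is scanned over a 90--180° grid in 2° steps
using a coarse 8-bin spectrum, then refined by parabolic interpolation. A
flat residual profile (pure-noise voxel) returns 180° with a
low-confidence flag.

## What accuracy to expect

At a first-echo SNR of 200 the per-voxel myelin pool is only weakly
identified: removing it entirely costs a misfit far below the noise
floor. Measured on 500 simulated voxels (MWF uniform on 0--0.3, IE T2
80 ms, flip uniform on 110--180°), the median absolute errors are about
0.02--0.03 for MWF (with a systematic negative component of roughly 0.02
attributable to the regularization window itself — a narrower window
would be more accurate but is not the convention this estimator follows),
about 3 ms for GMT2 and about 1° for the flip angle. Downstream analyses
operate on ROI means over tens to thousands of voxels, where the random
part of these errors averages out; the systematic MWF component is shared
by all ROIs and groups and therefore cancels from the contrasts of
interest. Rician noise is not bias-corrected before fitting (at these
SNRs the magnitude bias is ~$\sigma/400$ of the signal), which we note as
a limitation.

# Diffusion tensor

Signals follow $S_i = S_0 \exp(-b_i\, g_i^\top D\, g_i)$. The tensor is
fit by two-pass weighted linear least squares on $\ln S$: an ordinary LS
pass followed by a refit weighted by the squared predicted signals.
FA is $\sqrt{3/2}\,\lVert\lambda - \bar\lambda\rVert / \lVert\lambda\rVert$
and MD is $\operatorname{tr}(D)/3$. Negative eigenvalues from noisy fits
are clamped to zero for FA/MD with a per-volume count. The noiseless
round trip (simulate, then fit) is exact to $10^{-9}$.

# The phantom and the programmed truth

The label geometry is deliberately simple: a brain ellipsoid with a
sulcal CSF rim and grey-matter shell, paired ventricles, ellipsoidal
WMH blobs (up to two periventricular and five deep) (periventricular blobs grown from a voxel face-adjacent to the
ventricles; deep blobs kept at least 2 mm away), and for stroke-like
subjects a single-hemisphere stroke lesion. Label codes: 0 background,
1 ventricular CSF, 2 sulcal CSF, 3 grey matter, 4 NAWM, 5 WMH, 6 stroke.

Fluid-linked truth maps (IE T2, MD, FA) follow a programmed radial
profile of the distance $d$ to the WMH:

$$ v(d) = v_{\text{NAWM}} + (v_{\text{WMH}} - v_{\text{NAWM}})\,
   \max(0, 1 - d/r)^2, \qquad r = 6\ \text{mm}, $$

a quadratic decay of the perturbation that levels off exactly at 6 mm —
inside the 10 mm analysis range, so the outer rings measure clean
baseline. True MWF is *flat* across NAWM in both groups and reduced
inside the WMH only for the stroke group: this builds in the
hypothesized dissociation (a fluid penumbra without a myelin penumbra)
as the recoverable truth, and makes the older-adult MWF contrast an
exact programmed null. The refocusing flip-angle field is a smooth
quadratic polynomial spanning roughly 110--180°, so stimulated-echo
correction is non-trivial but recoverable.

Default tissue values (chosen once as field-typical): NAWM MWF 0.12, IE
T2 80 ms, FA 0.45, MD 0.80e-3 mm²/s; WMH at a 0.3 mL reference severity:
IE T2 95 ms, FA 0.30, MD 1.10e-3; grey matter 0.03 / 90 ms / 0.15 /
0.90e-3; CSF long-T2 single pool. Lesion severity scales with the log of
the measured lesion volume: about +3 ms IE T2, +0.06e-3 MD and −0.02 FA
per log-unit, and — for the stroke group only — an MWF deficit of
0.04 + 0.05 per log-unit around a 0.5 mL centre (clipped to
0.005--0.105). The deficit slope was set by a design power analysis: the
lesion-volume model carries no group term, so the group-mean MWF
difference lands in its residual, and the within-group coupling must be
steep enough (relative to that residual, at 20 + 14 subjects and the
realized log-volume spread) for the programmed association to be
recoverable. The slope is steep around the centre rather than larger on
average, which leaves the group contrast itself unchanged.

## Cohort structure

Subjects alternate across two scanner configurations (32 echoes at 10 ms
spacing, TR 1000 ms; 48 echoes at 8 ms, TR 1073 ms) that differ only in
echo train and noise level, and scanner enters all models as a random
effect. Multi-echo noise is Rician with a spatially uniform sigma set by
a first-echo SNR of 200 (180 for the second configuration) referenced to
the mean NAWM first-echo amplitude; diffusion noise uses SNR 50 at b = 0.
Ages are uniform on 45--80 years; MoCA scores are drawn around 27 (SD 2)
for older adults and 25 (SD 3) for the stroke group. WMH target volumes are
log-normal with group medians of roughly 0.15 mL (older-adult-like) and
0.9 mL (stroke-like), capped at 2.5 mL: the real-cohort distributions are
reported only as medians/IQRs and their upper range does not fit a
desk-scale phantom grid, so the generator preserves the ordering, the
skew and the under-10 mL older-adult inclusion rule rather than the
absolute scale. Large lesion loads are split over up to five deep blobs
plus one or two periventricular blobs (radius caps 3.2 and 4.5 mm) so
realized label volumes track the target monotonically; the measured
label volume, not the target, is what enters the covariate table and the
severity scaling. Stroke hemispheres alternate by subject index.

The default grid is 40 x 40 x 32 voxels at 1 mm isotropic — large enough
for ventricles, lesions, 10 mm of perilesional shell and the 10 mm
stroke exclusion, small enough that a 34-subject cohort runs end to end
in minutes. What the phantom does *not* emulate: realistic cortical
folding and fibre architecture, partial-volume mixtures at tissue
boundaries, motion/eddy artifacts, registration error between modality
spaces (all volumes share one grid), and bias fields other than the
refocusing angle. Passing tests therefore demonstrate the correctness of
the estimators and the analysis chain under the stated noise model, not
robustness to those real-data effects.

# Perilesional rings

Distances are Euclidean between voxel centers in physical mm (exact
separable distance transform, honoring anisotropic voxels). ROI
construction follows a fixed order: (1) exclusions — NAWM and WMH are
trimmed of voxels within 1 mm of CSF and within 10 mm of a stroke
lesion; (2) ring $k$ collects trimmed NAWM voxels whose distance to the
original WMH lies in $(2(k-1), 2k]$ mm for $k = 1..5$ — half-open, so a
voxel at exactly 2 mm belongs to the inner ring once. WMH connected
components use 26-connectivity, and a component is periventricular iff
any voxel is 26-adjacent to ventricular CSF ("contact in 3-D space"
stated without a connectivity rule; 26 is the permissive reading, and a
`deep_only` switch reproduces the deep-lesion-only restriction). By
default all WMH voxels are pooled for the main analysis. Empty rings are
retained with a warning and dropped at extraction.

# Mixed-effects models

Ring means feed three model families, all with standardized age and MoCA
as covariates and scanner as a random intercept; repeated-measures models
nest participant within scanner. Continuous predictors are standardized
within group. P-values use the Satterthwaite approximation (lmerTest);
REML throughout. Fits flag singular random-effects estimates — with only
two scanner levels the scanner variance often hits the boundary, which is
inherent to the design and does not bias the fixed effects.

- **Distance x group**: distance enters as a 6-level ordered factor
  (WMH, 2, ..., 10 mm) carrying only the linear and quadratic orthogonal
  polynomial codes. Both columns are reported; the quadratic column is
  the headline "Distance" term, matching the quadratic-contrast design.
  The group factor uses the older-adult level as baseline so the reported
  coefficient is the stroke-level effect (labelled "Group (S)").
- **Distance x hemisphere**: unilateral-stroke subjects only (bilateral
  subjects are dropped with a message), hemisphere varying within
  subject, contralesional baseline, coefficient labelled
  "Hemisphere (I)".
- **Lesion volume**: WMH-ROI rows only, one per subject, with the
  natural log (base unstated in the source convention; natural log
  chosen and documented) of the whole-brain WMH volume as the predictor
  and only the scanner random intercept.

Post hoc contrasts use emmeans with the Tukey studentized-range
adjustment ("Tukey's PSD" and "Tukey's HSD" both appear in the
literature for this procedure; they are treated as the same HSD
adjustment): all 15 pairwise distance contrasts for a distance main
effect, and the distance-within-group plus group-within-distance family
(36 contrasts) for an interaction.

A direct ROI-level generator (`simulate_roi_table()`) mirrors the model's
own data-generating process (scanner and subject intercepts plus
residual noise around a programmed profile) for power and type-I
studies: under its programmed null, 200 scaled-down replicates of the
distance-by-group model reject the quadratic distance term at close to
the nominal 5% rate.

# Problem sizes and reproducibility

The shipped checks use: 500 voxels for relaxometry recovery; 50 random
instances against the exhaustive NNLS oracle; 20 random label volumes
(20--40 voxels per side, mixed voxel sizes including 0.94 x 0.94 x 3 mm)
against the brute-force ring oracle; a 20 + 14 subject end-to-end cohort
on the default grid; and 200 null replicates at 8 + 6 subjects for
type-I error. Every generator is deterministic given its seed;
per-subject and per-stage seeds derive from the master seed so stages
can re-run independently, and `run_all()` resumes at the stage level and
writes an MD5 manifest of every artifact.

# Known limitations

- Per-voxel MWF carries a negative bias of about 0.02 from the
  regularization window convention (see above); contrasts between ROIs
  or groups are unaffected, absolute MWF levels are slightly
  conservative.
- Rician bias is not corrected before fitting.
- Two scanner levels make the scanner variance component only weakly
  estimable (kept for structural fidelity to the modelling convention).
- The phantom's geometry is schematic; see the simulation-design section
  for the real-data features it does not emulate.
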