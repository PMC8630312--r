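---
title: "Methods: per-cell strain mapping and monolayer kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-cell strain mapping and monolayer kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

When a confluent epithelial monolayer is stretched on an elastic substrate,
the interesting quantity is not the nominal substrate strain but the strain
each *cell* actually experiences: cells differ in size, shape and stiffness,
and their individual strains can deviate by several percent from the field
average. `cellstrain` estimates a small-strain tensor per cell from a pair
of fluorescence images taken before and after stretch, using a membrane
marker (an E-cadherin fusion or similar) that outlines every cell. Around
this core the package also quantifies two common readouts of the monolayer's
mechanical response: collective migration speed over time (PIV) and
cortical enrichment of a contractility marker (a GFP-myosin analogue).

# Strain model

Displacements $u_x, u_y$ between the reference (pre-stretch) and deformed
(post-stretch) frames define the in-plane infinitesimal strain tensor

$$ e_{xx} = \frac{\partial u_x}{\partial x},\qquad
   e_{yy} = \frac{\partial u_y}{\partial y},\qquad
   e_{xy} = \tfrac12\left(\frac{\partial u_x}{\partial y}
                        + \frac{\partial u_y}{\partial x}\right), $$

with $x$ the applied-stretch direction (second array axis; the package
fixes this convention everywhere). We use the symmetric (standard) shear
definition. We deliberately use the *infinitesimal* tensor, not
Green–Lagrange: at the 15–20% strains these devices reach, the quadratic
term would add $\tfrac12 e_{xx}^2 \approx 0.01{-}0.02$; all reported values
are displacement-gradient strains and should be compared as such.

The pipeline estimates the displacement field in two stages:

1. **Global affine registration.** The deformed image is registered onto
   the reference with a 2D affine transform $x' = Ax + t$ driven by a
   Mattes-style mutual-information (MI) metric. For an affine map the
   displacement gradient is constant and the strain tensor is the
   symmetric part of $A - I$ (`affine_to_strain()`), which is what a
   whole-field analysis would report.
2. **Dense refinement and per-cell fit.** A grid of interrogation blocks
   (32 px, spacing 8 px) is matched by normalised cross-correlation around
   the affine-predicted position, giving a dense displacement field; for
   every segmented cell the local affine model $u(x) = Gx + c$ is fitted
   by least squares over the grid points inside the cell mask (at least 6
   required) and the cell's tensor is the symmetric part of $G$. For a
   spatially uniform deformation this reduces to the global result; for
   heterogeneous fields it resolves strain cell by cell. We fit a local
   model to a shared dense field rather than re-registering per-cell
   patches: small cells contain too little texture for a stable
   independent registration.

# Numerical choices that matter

**Preprocessing.** Both images of a pair are conditioned identically
(asymmetric preprocessing is a registration bias and is impossible through
`preprocess_pair()`): Gaussian smoothing at a 2 px FWHM, then CLAHE. The
stated smoothing scale is implemented as a symmetric odd-support kernel
with FWHM = 2 px ($\sigma \approx 0.85$ px) — an even 2×2 kernel has no
centre and would shift the image by half a pixel. Boundary handling is
reflect padding for all filters. CLAHE uses an 8×8 tile grid and clip
fraction 0.01 by default (exposed in the configuration; the clip is a
fraction of tile histogram mass and is converted internally to EBImage's
uniform-height multiple).

**Registration.** The MI metric uses 50 bins with *linear partial-volume*
binning, which keeps the metric continuous in the transform parameters so
a Nelder–Mead simplex can reach subpixel accuracy; optimisation runs on a
3-level image pyramid with two simplex restarts per level. Two details are
easy to get wrong and are central to accuracy:

- *Fixed sample support.* Metric samples are taken on a fixed stride in a
  central window (70% of the field). If instead all pixels are sampled and
  out-of-bounds samples dropped, the sample count varies with the
  transform and MI acquires an overlap bias large enough to matter at the
  tolerances the per-cell analysis needs.
- *Capture range.* MI has a narrow basin (a few pixels in translation,
  roughly ±0.15 in scale at membrane-texture resolution), so the coarsest
  pyramid level explores several deterministic starts — the supplied
  initialisation, a translation seeded by a whole-field cross-correlation
  scan, and x-scale offsets bracketing the physiological stretch range —
  and keeps the best optimum before refining up the pyramid.

The procedure is fully deterministic (no random sampling), the transform
direction (reference → deformed) is asserted by tests, and failure —
a worsened metric or a transform outside validity bounds
($\max|A-I| > 0.6$ or $\det A \le 0$) — raises an error carrying both
metric values, never a silent identity.

**Dense displacement.** Blocks are matched with *affine window
deformation*: the deformed-frame search patch is sampled on the
affine-warped grid, so the known global stretch is compensated and the
correlation only measures the residual displacement. Without this, block
matching decorrelates under 15% strain — residual scatter grows by over
an order of magnitude — and locks onto whichever membrane dominates a
block. Blocks whose search patch leaves the deformed field are flagged
invalid rather than edge-clamped; clamping systematically understates
edge-block displacements. Subpixel peaks use a 3-point parabolic fit.

**Segmentation.** Marker-controlled tessellation: Otsu threshold on the
smoothed membrane image → connected interior regions as markers (specks
below 9 px discarded) → `EBImage::propagate()` assigns every pixel to a
marker across the membrane ridge. The inclusion filter (defaults: area
30–1500 µm², solidity ≥ 0.8, eccentricity ≤ 0.95, border cells excluded)
reproduces the usual "size or shape minimums" practice; thresholds are
configuration-exposed because published values rarely are. Segmentation
runs on the reference frame only; deformed-frame masks are obtained by
mapping the reference masks through the recovered transform, avoiding
identity switches. For shape change the mapped masks are drawn on an
enlarged canvas (`map_labels(expand = TRUE)`): clipping at the field edge
otherwise truncates near-edge masks and understates the mean area change
by about a percentage point.

**Shape metrics.** Area is the pixel count times the squared pixel size;
eccentricity comes from the moment-matched ellipse,
$e = \sqrt{1 - (b/a)^2}$ (with a $+1/12$ pixel-integration term in the
second moments). Perimeter is the *crack length* — the total length of
exposed pixel edges. It is exact for axis-aligned rectangles and biased
upward by up to $4/\pi$ for smooth boundaries; we accept this bias because
the package reports perimeter *percent changes*, in which a multiplicative
estimator bias cancels. Absolute perimeters of round cells should be read
with this in mind.

**PIV.** Single-pass FFT cross-correlation with a 96×48 px interrogation
window at 50% overlap (grid spacing = half a window). Velocity vectors are
invalidated by a peak1/peak2 signal-to-noise threshold (1.3) plus a 3 SD
outlier cut, and invalid vectors are excluded from statistics — never
zero-filled or interpolated, since interpolation would bias the mean-speed
statistic. The hourly series is the mean of per-pair mean speeds (mean of
vector magnitudes, a motility measure) over 6 consecutive 10-minute pairs,
and the normalized series divides by the first (pre-stretch) hour.
Single-pass matching is adequate because monolayer drift per frame
(≤ a few px) is small relative to the window; a multi-pass
window-deforming PIV is out of scope and would matter only for strongly
sheared flows.

**Cortical index.** Per cell: mean intensity in the band within 1.5 µm of
the cell boundary divided by the mean over the remaining interior. The
underlying ImageJ procedure in the source literature is not published in
formula form; this band/interior ratio with a binary threshold (default
1.5) is our reconstruction, with both parameters exposed. As a ratio of
means it is gain-invariant; cells with no interior left after band
erosion, or zero interior intensity, are flagged undefined and leave the
denominator of the fraction-positive summary.

# The synthetic generator: what it emulates, what it does not

Every stage is validated against `generate_monolayer()` and its
companions, which produce: a Lloyd-relaxed Voronoi tessellation of convex,
roughly isotropic cells at a programmed density (default 2200 cells/mm² —
the low-density epithelial regime of 2.0–2.5×10³ cells/mm²; the
high-density regime 3.0–4.0×10³ is reachable through the same parameter);
membrane-painted boundaries (2 px); intracellular speckle (30% of the
cytoplasmic level, smoothed at σ = 1.2 px) so registration and PIV have
intensity signal inside cells; and additive Gaussian noise, parameterised
as membrane-contrast SNR (default 10). Deformations are applied by exact
inverse-mapping bilinear resampling (uniform affine about the field
centre; a linearly graded $e_{xx}$ with closed-form inverse; stepwise
ramps), so per-cell ground truth is analytic. Bilinear rather than bicubic
interpolation is used deliberately: it cannot overshoot at the bright
membrane lines, and the acceptance suite shows strain-recovery error with
it sits orders of magnitude below every tolerance of interest. Time-lapse
movies advect the texture
from an enlarged canvas so content never runs out at the field edge, and
the default drift heading (30°) exercises both velocity components.

What the generator does **not** emulate — and therefore what passing
tests do *not* establish about real data: out-of-plane motion and focus
drift, photobleaching, cell rearrangements/divisions during the
before/after interval, non-convex or strongly elongated cells, spatially
correlated (non-Gaussian) camera noise, and genuinely heterogeneous
per-cell mechanical response (in the synthetic fields every cell deforms
with the substrate). The observed few-percent spread of real per-cell
strains is a biological observation, not an acceptance bound here.

# Validation conditions and problem sizes

The validation suite runs the full pipeline on a 512×512 px field at
0.5 µm/px (≈ 144 cells at the default density, SNR 10) for the headline
15%-stretch recovery, and 256×256 px fields for the strain ramp
(0–20% in 2% steps), the graded field (0 → 10% across the field), the
noiseless area-consistency check, kinetics (four programmed hours at
10-minute frames) and cortical classification (40% of cells at 2×
enrichment). These sizes were chosen as the smallest fields that keep
≥ 20 analyzable interior cells and a PIV grid of ≥ 30 windows, so that
per-cell means are stable.

# Known limitations

- The infinitesimal strain tensor under-reports large stretches relative
  to finite-strain measures (documented above, not corrected).
- Crack-length perimeters are biased for smooth boundaries; use percent
  changes.
- Cells whose affine-predicted search patch leaves the deformed field
  carry no displacement samples and are reported as not included; at 15%
  stretch this removes a band of near-edge cells.
- Single-pass PIV; no trajectory-level statistics (MSD, tracking).
- Segmentation assumes a bright, mostly closed membrane outline; it is not
  a learned segmenter and will merge cells across large membrane gaps.
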