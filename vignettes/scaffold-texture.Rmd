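---
title: "Scale-dependent texture of porous scaffolds: methods and design notes"
author: "lacunatex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-dependent texture of porous scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lacunatex)
```

# The problem

Porous scaffolds for tissue regeneration are characterized routinely by
porosity, pore size and surface area, but these macroscopic descriptors do
not capture *how* the void space is distributed. Fractal dimension, the
classical refinement, measures how much space a structure fills, not how it
fills it: objects with identical fractal dimensions can look completely
different. Lacunarity closes this gap. It measures the deviation of a
pattern from translational invariance — its "gappiness" — as a function of
observation scale, so a single structure yields a curve rather than a
number, and two scaffolds with equal porosity can be told apart by the
shapes of their curves.

`lacunatex` implements this analysis for 3D binary pore/solid voxel volumes
as they arise from segmented micro-CT stacks, together with the segmentation
and geometry stages upstream of it and synthetic generators that provide
ground truth for every stage.

# The gliding-box model

A cubic box of side $r$ voxels is superimposed on the volume and glides at
unit stride over every position fully inside it, giving
$N(r) = \prod_a (d_a - r + 1)$ positions for dimensions $d_a$. The pore
count $S$ per box defines the occupancy distribution
$P(S, r) = n(S, r)/N(r)$, and lacunarity is its normalized second moment:

$$\mathrm{LAC}(r) = \frac{\mu_2(r)}{\mu_1(r)^2}
  = 1 + \frac{\sigma_s^2(r)}{\bar S(r)^2} \ge 1 .$$

Useful exact identities follow directly from the definition and are
enforced by the test suite:

* $\mathrm{LAC}(1) = 1/n$ for any arrangement with porosity $n$ (unit boxes
  see a Bernoulli marginal), so the curve's maximum sits at $r = 1$;
* $\mathrm{LAC} = 1$ at $r$ equal to the side of a cubic volume (a single
  box, zero variance);
* a structure that is exactly periodic with period $p$ has
  $\mathrm{LAC} = 1$ at every $r$ that is a multiple of $p$ (every such box
  holds the same count — note this holds *at multiples of the period*, not
  at arbitrary $r$, where boxes straddle tile boundaries and the variance
  can be nonzero);
* an i.i.d. Bernoulli field obeys
  $\mathrm{LAC}(r) \approx 1 + (1-p)/(p\,r^3)$.

Because LAC depends on porosity, structures of different void fraction are
compared through the relative lacunarity function

$$\mathrm{RLF}(r) = \frac{-\ln \mathrm{LAC}(r)}{\ln n},$$

which is $1$ at $r = 1$ for every $0 < n < 1$ and $0$ wherever
$\mathrm{LAC} = 1$. The **randomness scale** is the smallest $r$ with
$\mathrm{LAC}(r) \le 1 + \varepsilon$: above it the structure appears
homogeneous. "Close to 1" has no canonical quantification, so
$\varepsilon$ is an exposed parameter with default $0.05$; the box size of
the largest slope change of $\ln \mathrm{LAC}$ versus $\ln r$ is reported
as a secondary, threshold-free diagnostic.

## Numerical choices

* **Box enumeration.** $N(r) = \prod_a (d_a - r + 1)$, the full 3D product.
  Boxes lie fully inside the volume — no wrap, no padding — and the stride
  is exactly one voxel.
* **Variance convention.** Population variance over all $N(r)$ box
  positions (divide by $N(r)$): the box set is exhaustive, not a sample.
* **Fast path and oracle.** Box counts come from a 3D summed-volume
  (integral-volume) table, giving each count in $O(1)$ after one $O(V)$
  pass; counts and their squares stay exact in doubles far beyond $256^3$
  volumes. An independent `bruteForceLacunarity()` (literal triple loop,
  no shared code) is kept as the oracle; a property sweep over random
  volumes asserts equality to $10^{-12}$.
* **Degenerate inputs.** An all-solid volume has $\bar S = 0$ and
  lacunarity is undefined (the ratio diverges as the mean vanishes); this
  is an error, not a sentinel value. The RLF normalization is undefined at
  $n \in \{0, 1\}$; `relativeLacunarity()` rejects those, while
  `lacunarityCurve()` applies the limit convention RLF $= 0$ for the
  all-pore volume (where LAC $\equiv 1$) and records NA otherwise.
* **Box-size grid.** All integers from 1 to $\min(64, \text{smallest
  dimension})$ by default — 64 is where curves of typical scaffold volumes
  have flattened (the representative elementary volume) — overridable by an
  explicit list. Logarithms are natural throughout.
* **Non-cubic volumes** are accepted everywhere; $r$ is capped by the
  smallest dimension.

# Segmentation

Micro-CT slices are binarized per 2D slice (matching the slice-wise
acquisition workflow), with the polarity convention pore = dark (air
attenuates X-rays less than material) and an explicit flag for the
opposite convention.

* **Niblack**: $T = m + k\,s$ over a local window (defaults: window 25 px,
  $k = -0.2$, the customary values from the local-thresholding literature;
  the source papers for these criteria drive the defaults since typical
  CT workflows rarely report them).
* **Sauvola**: $T = m\,(1 + k\,(s/R - 1))$ with $k = 0.2$ and $R$ = half
  the image's dynamic range (0.5 for unit-range images).
* **Global**: Otsu (via EBImage), mean, or a fixed value.
* **Edge handling**: reflect padding — avoids border bias without
  inventing data. Local statistics use integral images, so windows cost
  $O(1)$ per pixel.

Strategy selection scores every candidate by the normalized
cross-correlation of Fourier phases between the original grayscale and the
segmented image, and keeps the argmax. Three conventions make this score
well defined and deterministic:

* the correlation is the zero-lag Pearson correlation of the wrapped phase
  angles in $(-\pi, \pi]$, DC term excluded — the simplest reading of
  "cross-correlation of Fourier phases" (alternatives such as the
  phase-only correlation peak exist; the chosen reading is recorded here so
  results are reproducible under a stated definition);
* the segmented candidate is scored in the *original's* display polarity
  (the solid mask $1 - b$ under pore-is-dark): a perfect binarization is
  then a positive linear transform of a noiseless original and scores
  $+1$, whereas scoring the pore mask directly inverts intensities and
  mis-ranks candidates;
* numerically real DFT coefficients (Nyquist terms of real images) sit on
  the $\pm\pi$ branch cut and take phase $0$ or $\pi$ from the sign of the
  real part; numerically zero coefficients have no phase and take $0$.

Phase is invariant to positive linear intensity rescaling, so the score
compares structure, not contrast. Exact ties are broken by a fixed method
order (otsu < niblack < sauvola < mean < fixed, later wins), so selection
is deterministic. Scoring is per slice, with the per-slice method and score
logged; whether aggregate-volume scoring would choose differently is an
open question we sidestep by reporting the full log.

# Synthetic ground truth

No public scaffold CT data accompany this class of analysis, so the package
generates its own test volumes with known properties:

* `regularLattice()` — exactly periodic structures, the analytic case with
  LAC $= 1$ at period multiples;
* `bernoulliVolume()` — maximal randomness at a given porosity, the
  closed-form case;
* `foamVolume()` — union of overlapping spherical pores (truncated-normal
  radii, voxel centre-in-sphere voxelization: the simplest unambiguous
  rule) added until the realized porosity first crosses the target. The
  generator stops at the first crossing rather than hitting the target
  exactly — overshoot of at most one sphere — which matches the
  statistical character of freeze-dried foams; the realized porosity is
  recorded and always equals a direct voxel count.
* `occludePores()` — reduces pore volume by a relative fraction, emulating
  particle deposition. Two mechanisms: removing randomly selected *whole
  pores* (the spheres recorded by the foam generator) and voxel-wise
  *erosion* of the pore phase. Whole-pore removal is the default for foams
  because it reproduces what occlusion does to real composite scaffolds —
  the surviving pores keep their size while the structure grows sparser,
  so the porosity-normalized heterogeneity (RLF) rises at every scale;
  uniform erosion, by contrast, shrinks all pores in lockstep and leaves
  the normalized curve slightly *lower*. Both modes remove voxels in a
  seeded fixed order, making the operation monotone in the fraction.
* `renderGrayscaleStack()` — maps solid to bright (0.8) and pore to dark
  (0.2), adds Gaussian noise and an optional linear illumination gradient,
  clamping to [0, 1], with the generating volume retained as ground truth.

Default study conditions mirror realistic scaffold morphometry: target
porosities in the 0.6–0.85 range (the regime of freeze-dried composite
scaffolds, e.g. 81%/70%/68% across increasing filler content), a mean pore
radius of 7.5 voxels at 8.7 µm/voxel — i.e. ~130 µm pores at half scale,
keeping pore size well above voxel size — and 64³ working volumes standing
in for 256³ acquisitions.

What the generators do *not* emulate: freeze-drying physics, anisotropic or
elongated pores, CT reconstruction artifacts (beam hardening, rings),
partial-volume gray levels, or correlated noise. Passing tests therefore
demonstrate the correctness of the statistics and the qualitative behavior
of the pipeline on foam-like textures, not segmentation performance on any
particular scanner's output.

# Subvolume heterogeneity

Regional heterogeneity is probed by cutting parallel slabs (e.g. three
520 µm slabs, which is 60 voxels at 8.7 µm — micrometre thicknesses round
to the nearest voxel, minimum 1) and comparing their RLF curves. The
divergence summary is the maximum over common box sizes of the RLF range
across slabs; box sizes exceeding a slab's thickness are dropped for that
slab with a note, since a 60-voxel slab cannot host a 64-voxel box. Slab
positions are explicit, with an equispaced default, as no canonical
placement exists.

Visual curve comparison is replaced by a Monte-Carlo calibration:
`homogeneousDivergenceBand()` simulates re-seeded homogeneous Bernoulli
volumes under the same slab geometry and reports the divergence
distribution; its 95th percentile is the default threshold for calling a
divergence "remarkable". The acceptance suite checks both directions at
64³ with 100 replicates: a homogeneous volume falls inside the band, a
fixture built from three slabs of deliberately different foam parameters
falls above it.

# Reproducibility and problem sizes

Every random draw is scoped to an explicit per-operation seed
(`withr::with_seed`), leaving the global RNG untouched; identical spec +
seed yields bit-identical volumes across runs. The pipeline is
deterministic end to end, and re-running a config reproduces its CSV/JSON
outputs byte for byte.

The validation suite runs at deliberately desk-friendly sizes: oracle
equivalence on 100+ volumes of 8³–16³, closed-form recovery on ten 32³
fields, qualitative orderings and Monte-Carlo bands at 64³, segmentation on
96×96 slices. These sizes are chosen so the full suite completes in well
under a minute of compute per module while leaving every assertion
statistically comfortable; the statistics themselves scale to 256³
acquisitions unchanged (the summed-volume pass is linear in voxels per box
size).

# Known limitations

* Lacunarity is resolution-dependent: curves from images of different voxel
  size are not directly comparable. Within this package the concern is
  mitigated when pore size is many times the voxel size (≥ 10–15×).
* The gliding-box statistic is isotropic; directional heterogeneity is
  averaged away. Anisotropic variants are out of scope.
* Segmentation quality bounds everything downstream. The phase-NCC
  selection minimizes, but cannot eliminate, reconstruction uncertainty,
  and no machine-learned or artifact-correcting methods are provided.
* Synthetic foams are qualitative analogues of real scaffolds: they match
  porosity and pore-size scale but no higher-order morphology, so
  cross-checks against real data remain the user's responsibility.
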