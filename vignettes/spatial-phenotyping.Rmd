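---
title: "Registration and spatial quantification of serial-section IHC with spaRQ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration and spatial quantification of serial-section IHC with spaRQ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multiplexed imaging measures several proteins on one section, but most
laboratories stain serial sections: consecutive thin slices of one tissue
block, each stained by standard immunohistochemistry (IHC) for a different
marker with a brown DAB chromogen and a hematoxylin counterstain.  Because
consecutive sections a few micrometres apart show nearly the same tissue
architecture, two markers' spatial relationship can be recovered by
*registering* the section images into a common frame and then *overlaying*
their DAB-positive areas.  spaRQ implements that workflow in two parts:

* **Spa-R** — estimate, for each moving section, the similarity transform
  (rotation, isotropic scale, 2-D translation) that best aligns it to a
  reference section, by maximising mutual information.
* **Spa-Q** — separate hematoxylin and DAB by colour deconvolution,
  threshold each marker's DAB channel, and quantify per-ROI (region of
  interest, e.g. a tumour lesion polygon) the stained area percentages, the
  pairwise overlap (OL), a signalling-signature subclass, and a
  pseudo-coloured overlap landscape.

A coordinate convention used throughout: `x` = column, `y` = row, origin at
the top-left pixel, 0-based, with pixel centres at integer coordinates.

## The registration model

A similarity transform maps moving-image coordinates into the fixed frame,

$$x_f = c + t + s\,R(\theta)\,(x_m - c),$$

with centre $c$ fixed to the image centre (the convention had to be chosen;
any centre parameterises the same family).  The registration metric is
Shannon mutual information in bits, computed from a 50-bin-per-axis joint
histogram of the fixed image and the resampled moving image, over the
overlap region only — pixels mapped outside the moving image are excluded
rather than filled, so a white background cannot drive the maximum.  Images
enter the metric as Rec. 601 luminance.

### Optimizer

The search is a seeded one-plus-one evolutionary strategy over a
coarse-to-fine image pyramid.  The parameter vector is
$(\theta, \log s, t_x/W, t_y/W)$ — rotation in radians, log scale, and
translation normalised by the fixed-image width — so a single scalar search
radius is meaningful across parameters; per-parameter step scales
$(1, 0.5, 0.25, 0.25)$ keep translation steps small relative to rotation
once the initial scan has placed translation near its optimum.  At each
pyramid level the radius starts at `initial_radius`, multiplies by
`growth_factor` after a step that improves the metric and by
`growth_factor`$^{-1/4}$ otherwise, and the level ends when the radius
falls below `epsilon` or after `max_iterations` candidate steps.  The
returned transform is the best-metric candidate seen, and the identity
transform always competes at the end, so the result is never meaningfully
worse than no registration at all.

Defaults (changeable through `registration_params()`):

| parameter        | default  | meaning                                        |
|------------------|----------|------------------------------------------------|
| `max_iterations` | 100      | candidate steps per pyramid level              |
| `initial_radius` | 0.0018   | starting step radius, normalised units         |
| `pyramid_levels` | 3        | coarse-to-fine levels (block-mean halving)     |
| `epsilon`        | 1.5e-06  | convergence tolerance on the step radius       |
| `growth_factor`  | 1.05     | radius growth on success                       |
| `seed`           | 1        | RNG seed of the stochastic search              |
| `histogram_bins` | 50       | bins per axis of the MI histogram              |

The iteration budget is interpreted *per pyramid level*, matching the
notion of an optimisation that "runs to a maximum number of iterations, or
until it converges"; convergence means the search radius has shrunk below
`epsilon`.  In practice `epsilon` at its default is rarely reached within
100 iterations, which is why iteration count — not `epsilon` or
`growth_factor` — is the parameter that visibly controls registration
quality.  The test suite checks exactly that ordering.

### Initialisation

The optimizer is local, so it is initialised by a deterministic scan: a
grid over rotations (±12° in 2° steps) and scales (0.90–1.10 in 0.02
steps), where each candidate's translation is read off the FFT
cross-correlation of the background-subtracted "darkness" (255 − gray)
images, run one pyramid level above the coarsest so that tissue texture
still carries orientation information.  Candidates are ranked by mutual
information evaluated on a fixed central window (15–85 % of each axis):
ranking on the full overlap region would systematically favour larger
rotations, because a larger rotation shrinks the overlap, excludes more
background, and thereby inflates the overlap-only statistic.  Refinement
below the grid pitch is deliberately left to the evolutionary search — a
stronger initialisation would make the iteration count irrelevant, which
contradicts the tool's observed behaviour.

Two centred images of constant intensity are degenerate for MI; in that
case `register_pair()` warns and returns the identity transform with
`converged = FALSE`.

## The staining model

Brightfield stain mixing is linear in optical density (OD).  Per channel,

$$\mathrm{OD}_c = -\log_{10}\!\big(\max(I_c, 1)/I_0\big), \qquad I_0 = 255,$$

with the intensity clamped at 1 to avoid infinite densities.  The H-DAB
stain matrix has unit columns proportional to $[0.650, 0.704, 0.286]$
(hematoxylin) and $[0.072, 0.954, 0.283]$ (DAB); the residual third vector
is the normalised cross product of the two, hence exactly orthogonal to
both — the best-conditioned completion of the basis — with its sign chosen
to make the component sum positive.  Deconvolution is the per-pixel
$3\times3$ solve $d = M^{-1}\,\mathrm{OD}$.

Thresholding uses the ImageJ convention: each stain's density plane is
re-expressed as an 8-bit pseudo-channel $255 \cdot 10^{-d}$ (255 = no
stain), negative densities clipped to zero first, and a pixel is positive
when the pseudo-channel is *strictly below* the threshold.  Thresholds are
configuration inputs, not estimated from the data: in this workflow they
come from expert consensus and the same marker's threshold must be applied
identically to every sample in a run (`threshold_config()` holds them in
one validated object).  The tissue mask thresholds Rec. 601 luminance the
same way.

On quantisation: with 8-bit input images, rounding alone perturbs a
channel's OD by up to $0.5/(I \ln 10)$, which after the matrix inverse can
reach $\sim 10^{-2}$ in density at moderately dark pixels.  Density
recovery is therefore exact (to machine precision) for continuous
intensities, and quantisation-limited — not algorithm-limited — for 8-bit
pixels; the test suite asserts both, the second against the propagated
quantisation bound rather than a fixed constant.

## Quantification

All percentages are relative to the ROI's *tissue* area (the tumour area),
not the polygon's pixel count: for marker masks $A$, $B$, ROI mask $R$ and
tissue mask $T$,

$$\mathrm{area}_A = 100\,\frac{|A \cap R \cap T|}{|R \cap T|}, \qquad
  \mathrm{OL} = 100\,\frac{|A \cap B \cap R \cap T|}{|R \cap T|}.$$

so always $\mathrm{OL} \le \min(\mathrm{area}_A, \mathrm{area}_B)$.  ROI
polygons rasterise by the even-odd rule on pixel centres.  An ROI with no
tissue pixels makes these ratios undefined: the low-level functions raise
an error naming the ROI, while the `run_spaq()` pipeline records zeros for
such an ROI (a blank slide quantifies to zero, not to a failure) and
continues.

The signature rule classifies each lesion from two overlap values with a
strict cutoff (default 15 %): `MAPK_mTOR` iff OL(pERK/p4EBP1) > 15 % and
OL(pAKT/p4EBP1) ≤ 15 %, `AKT_mTOR` symmetrically, `Null` if neither
exceeds the cutoff — so exactly (15, 15) is `Null`.  Both exceeding the
cutoff yields `Dual` with a warning: the rule can mathematically produce
it, although the two signatures were observed to be mutually exclusive in
tumour lesions, so `Dual` is representable rather than an error.  Which
marker pair feeds which class is configuration, not hard-coded biology.

Landscape masks colour each ROI pixel exhaustively and exclusively:
marker-A-only yellow (255, 255, 0), marker-B-only orange (255, 165, 0),
overlap red (255, 0, 0), everything else white.  The named colours are
fixed to these CSS values; conservation (red = intersection count,
yellow + orange + red = union count) is asserted in the tests.

## The synthetic slide generator

`generate_slide_series()` builds the validation world: a lesion blob with a
smoothed random-polar-radius outline (non-convex, to stress ROI
rasterisation), a hematoxylin texture field (smoothly correlated
multiplicative noise, correlation length 25 px, amplitude 15 %), and two
marker regions constructed as discs whose radii and separation are solved
(lens-area equation) so the realised pixel-count fractions match the
request — by default 30 % / 25 % with 10 % overlap, the regime where the
subclassification rule is exercised on both sides of its cutoff.  Each
non-reference section receives its own similarity transform drawn uniformly
from the documented recovery envelope (rotation ±10°, scale 0.9–1.1,
translation up to 5 % of width), per-section texture noise, additive 8-bit
Gaussian noise (sd 5), and a 1 px jitter of its marker-region geometry —
emulating the decorrelation of sections cut micrometres apart.  RGB is
synthesised by the forward Beer–Lambert model with the same stain matrix
the analysis uses, and the ground-truth table reports *realised* fractions
by pixel counting, so it is exact by construction even under jitter.

What the generator does not emulate: nuclei and cellular texture, staining
artefacts (folds, edge effects, uneven DAB development), scanner colour
profiles, and deformable (non-rigid) section distortion.  Passing tests
therefore demonstrate correctness of the algorithms under the stated image
formation model, not robustness to every histological artefact; on real
slides the similarity-transform assumption itself is the main limitation.

`make_overlap_pair()` is the exact-arithmetic companion: it builds two
masks with requested area and overlap counts rounded to whole pixels, for
tests where the answer must match a counting oracle exactly.

## Validation problem sizes

The registration properties are validated on 512 × 512 synthetic pairs (20
seeded draws for transform recovery; recovery tolerance ±0.5°, ±1 % scale,
±2 px) and on 256 × 256 pairs for the iteration/epsilon comparisons (10
seeds each); quantification exactness uses 1000 random mask pairs and the
full register-then-quantify loop runs at 512 × 512 with ±1.5 percentage
point tolerance against the generator's truth table.  These sizes keep the
whole suite comfortably reproducible on a laptop while staying inside the
regime the defaults were designed for (the recovery envelope above).

## Known limitations

* The transform family is rigid-plus-scale; tissue folds, stretching and
  section-to-section deformation are out of scope.
* Overlap is pairwise; three-marker simultaneous overlap is not computed.
* Quantification is area-based, not single-cell; a marker's positive area
  is the thresholded DAB footprint, with no cell segmentation.
* Thresholds are inputs; no automatic threshold selection (e.g. Otsu) is
  provided, because the workflow this package implements treats thresholds
  as expert-consensus constants shared across samples.
* For tissue-microarray spots classified by dominant phenotype no numeric
  rule exists; the 15 % rule plus the option of using total ROI area as
  the denominator is what the package offers.
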