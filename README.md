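# spaRQ — spatial phenotyping of serial-section immunohistochemistry

Most pathology labs measure several protein markers not by multiplexed
imaging but by staining *serial sections* — consecutive micrometre-thin
slices of one tissue block, each stained by standard IHC with a brown DAB
chromogen over a hematoxylin counterstain. Consecutive sections share
nearly the same tissue architecture, so the spatial relationship between
two markers can be recovered computationally: align the section images
into a common frame, segment each marker's DAB-positive area, and overlay
them. spaRQ implements that pipeline for R users (image analysts, tumour
biologists, computational pathologists) in two cooperating halves:

* **Spa-R (registration).** For each moving section, estimate the
  similarity transform `x_f = c + t + s·R(θ)·(x_m − c)` — rotation θ,
  isotropic scale s, translation t about the image centre c — that
  maximises the mutual information
  `MI(F, M∘T) = Σ p(f,m) log₂[p(f,m)/(p(f)p(m))]`
  between the fixed reference and the resampled moving image. The
  optimizer is a seeded one-plus-one evolutionary strategy on a
  coarse-to-fine pyramid (defaults: 100 iterations per level, 3 levels,
  initial radius 0.0018, growth factor 1.05, epsilon 1.5e-06), initialised
  by a rotation×scale grid scan with FFT cross-correlation translation.
* **Spa-Q (quantification).** Convert RGB to optical density
  (`OD_c = −log₁₀(I_c/255)`), deconvolve with the H-DAB stain matrix
  (unit vectors ∝ [0.650 0.704 0.286] for hematoxylin, [0.072 0.954 0.283]
  for DAB), threshold the 8-bit per-stain pseudo-channels (`255·10^−d`,
  positive = strictly below threshold), and report per ROI: tissue area,
  each marker's positive area %, their overlap
  `OL = 100·|A∩B∩ROI∩tissue|/|ROI∩tissue|`, a signalling-signature class
  (`MAPK_mTOR` / `AKT_mTOR` / `Null`, strict >15 % OL cutoff), and a
  pseudo-coloured landscape (yellow/orange for single markers, red for
  overlap).

A synthetic serial-section generator with exact ground truth
(`generate_slide_series()`, `make_overlap_pair()`) makes the whole
pipeline testable without any slide scans.

## Worked example

```r
library(spaRQ)

# a synthetic serial-section pair with known ground truth
gen <- generate_slide_series(synthetic_slide_spec(size = c(512, 512), seed = 42))
fit <- register_pair(gen$images$pERK, gen$images$p4EBP1,
                     registration_params(seed = 7))
print(fit)

thr <- threshold_config(dab_threshold = c(pERK = 101, p4EBP1 = 101),
                        tissue_threshold = 200)
res <- run_spaq(gen$images$pERK, fit$registered, gen$rois, thr,
                marker_names = c("pERK", "p4EBP1"))
print(res$records, digits = 4)
print(gen$truth, digits = 4)
```

prints

```
Similarity-transform registration (mutual information)
<similarity_transform rot=7.3848 deg  scale=1.08107  t=(-10.701, 17.164) px  centre=(255.5, 255.5)>
  final metric: 0.9355 bits   iterations: 300   converged: FALSE
  roi_name tissue_area_px pERK_pct p4EBP1_pct overlap_pct signature
1 lesion_1          84369    29.99      25.01       9.694      <NA>
  roi_name tissue_px pERK_pct p4EBP1_pct ol_pERK_p4EBP1_pct
1 lesion_1     84369    29.99       25.2              9.716
```

The fitted transform (7.38°, scale 1.081, t = (−10.7, 17.2) px) is the
estimated section-mounting offset; `iterations: 300` is the summed
one-plus-one budget over the three pyramid levels, and the metric is the
final mutual information in bits. The quantification row says: within the
ROI's 84,369 tissue pixels, 29.99 % are pERK-positive, 25.01 %
p4EBP1-positive, and 9.69 % positive for both — within a quarter of a
percentage point of the generator's ground truth (bottom row) after
registration, thresholding and rasterisation. With a second overlap value
for pAKT/p4EBP1, `classify_signature(9.69, 2.1)` returns `"Null"`: neither
overlap exceeds the strict 15 % cutoff.

`run_pipeline("config.yaml")` wires the same steps end-to-end from a
config file (paths, thresholds, marker pairs, signature rules, seed) and
writes registered uncompressed TIFFs, `registration_log.csv`, mask and
landscape images, `results.csv`/`results.xlsx`, and the exact config used.
The thin CLI wrapper lives at `inst/cli/spa-rq.R`
(`spa-rq.R run --config config.yaml`, plus `register`, `sweep`,
`generate` subcommands).

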