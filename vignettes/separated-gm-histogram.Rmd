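---
title: "Separated gray-matter histogram analysis of amyloid PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separated gray-matter histogram analysis of amyloid PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyhist)
```

## The model

Amyloid PET quantification conventionally reduces a brain volume to a
composite SUVR (ComSUVR): regional uptake ratios against the cerebellar
cortex, averaged over amyloid-prone neocortex. `amyhist` implements a
complementary, histogram-based view built on a three-component model of the
SUVR distribution over the brain parenchyma:

* **G1** — gray matter without pathological amyloid, Gaussian with mean
  $\mu_{G1} \approx 1$ (cortical uptake matches the cerebellar reference);
* **G2** — amyloid-bearing gray matter, Gaussian with $\mu_{G2} > \mu_{G1}$
  and mixing proportion $\pi_{G2}$ within GM;
* **WM** — white matter with off-target tracer binding, Gaussian with mean
  $\mu_W \approx 1.5$, highly variable across individuals.

GM and WM are assumed to occupy 43% and 57% of the parenchyma. The
whole-brain histogram is the mass-weighted sum of the three curves; as
$\pi_{G2}$ and $\mu_{G2}$ grow, the GM histogram transitions from one
narrow peak through a wide peak to two peaks, and the whole-brain histogram
peak migrates from left of the mean (mode/mean ratio MMR < 1) to right of
it (MMR > 1).

The per-subject procedure is:

1. SUVR normalization against the cerebellar-cortex reference; regional
   SUVR and ComSUVR on the native grid.
2. Upsampling (default factor 2, cubic) of SUVR and tissue-probability
   volumes, to reduce histogram discretization artifacts.
3. Masks: parenchyma where $p_{GM} + p_{WM} > 0.5$ (strict, excluding
   CSF); pure-tissue GM and WM masks where the single-tissue probability
   exceeds 0.6, keeping partial-volume boundary voxels out.
4. Histograms at bin width 0.05 SUVR, half-open bins aligned to multiples
   of 0.05.
5. Whole-brain descriptive parameters: bias-corrected sample skewness
   $\frac{n}{(n-1)(n-2)} \sum ((x_i - \bar x)/s)^3$, mode (maximal bin
   center, ties to the lowest bin), MMR = mode/mean.
6. GM-histogram decomposition into two Gaussians by
   expectation–maximization, reporting $\mu_{G1} \le \mu_{G2}$,
   $\pi_{G2}$, and the bias-corrected excess kurtosis of the GM values
   (GM-kurtosis); WM-histogram mean $\mu_W$.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| parenchyma threshold | 0.5 | probability | strict `>`: "exceeds 50%" |
| tissue purity threshold | 0.6 | probability | excludes GM/WM boundary mixing |
| bin width | 0.05 | SUVR | histogram resolution |
| upsample factor | 2 | – | doubles samples per bin at modest cost; the source protocol upsamples without stating a factor |
| EM tolerance | 1e-8 | relative LL | with 4 jittered restarts + deterministic median-split start |
| variance floor | 0.025 | SUVR | half a bin; prevents single-bin collapse |
| degenerate threshold δ | 0.10 | SUVR | two bin widths; below it πG2 is flagged unreliable |

The kurtosis estimator defaults to the standard bias-corrected form with
correction term $3(n-1)^2/((n-2)(n-3))$. A variant with $3(n-1)$ in place
of $3(n-1)^2$ — as printed in some software documentation — is available
via `formula = "printed"`; the two agree as $n \to \infty$.

### Degenerate decompositions

When the data are effectively one Gaussian, a forced two-component split
places both means nearly on top of each other and $\pi_{G2}$ becomes an
arbitrary split fraction. Such fits (separation < δ) are flagged
`degenerate` and a warning is carried in the subject record; this is the
mechanism by which visually negative subjects can show outlying high
πG2 at low µG2.

## The synthetic world

`generate_phantom()` builds a seeded 3-D brain-like phantom: an
ellipsoidal cerebrum whose WM core and GM shell volumes follow the 57/43
split, cortical G2 patches grown as contiguous regions until the planted
πG2 share is reached, a cerebellar compartment held at SUVR 1 (the
reference truth is exact by construction), a CSF rim at SUVR 0.3, PET-like
blur, additive Gaussian noise, blurred-indicator tissue-probability maps,
and an AAL-style label volume (reference core + five cortical sectors).

Deliberate idealizations, and what they mean for a green test:

* **Cortex thickness.** The GM shell is ~12–16 mm thick, several times
  real cortical thickness. With a 6 mm point-spread function a 3 mm ribbon
  retains almost no pure-GM voxels; the thick shell is what makes planted
  ground truth recoverable at all. Green recovery tests therefore
  establish the correctness of the *pipeline machinery*, not clinical
  accuracy under realistic partial-volume loss.
* **Trans-axial PET blur.** The emulated acquisition chain describes its
  Gaussian post-filter as trans-axial, so the phantom smooths in-plane
  (x, y) only; axial resolution is left at the 4 mm voxel sampling.
  Isotropic 3-D blur at 6 mm erodes even mid-shell values by ~5% of the
  G2–CSF contrast, beyond the pipeline's recovery tolerances.
* **Probability-map smoothness.** Tissue indicators are blurred at 14 mm
  FWHM, emulating population-average probabilistic atlas maps. This makes
  the >60% purity threshold select mid-shell voxels — exactly the
  partial-volume-exclusion role the threshold plays on real maps. Sharper
  maps would admit eroded edge voxels and bias every GM parameter.
* **Cerebellum.** Modelled as mixed 0.5/0.5 GM/WM tissue (folia are thin
  at PET resolution): it joins the parenchyma mask but neither pure-tissue
  mask, and the reference ROI is the compartment's interior core, as
  atlas ROIs sit inside the structure. The reference mean is then immune
  to edge erosion.
* **Noise.** Additive Gaussian (SD 0.05 SUVR) after smoothing — a
  stand-in for reconstruction noise, adequate for histogram machinery but
  not a scanner simulation.

Not emulated: real anatomy and cortical folding, registration error,
scanner physics (sinograms, attenuation, scatter), age/atrophy effects on
the 43/57 split.

## Numerical choices

* Bins are half-open $[a, a+w)$; a value exactly on an edge belongs to the
  upper bin; a tiny forward nudge (1e-9 of a bin) absorbs representation
  error for values written as exact edge multiples.
* Moments are computed from the masked voxel values (exact); binned
  variants exist for parity checks and agree to $O(w^2)$.
* Mixture fitting on raw voxel values by default; fitting the 0.05-binned
  counts as weights agrees within 0.01 on all parameters and is available
  (`fit_binned = TRUE`) since the published analysis may have used either.
* Mode ties break toward the lowest-SUVR bin (deterministic, conservative
  toward low accumulation).
* Expected model curves integrate the Gaussian density over each bin
  (CDF differences), so component masses are exact.
* Upsampling output index $j$ samples input coordinate $j/f$: original
  lattice points are reproduced exactly and the affine keeps the
  index-origin world position fixed. Labels always use nearest-neighbour;
  probabilities are clipped to [0, 1] after cubic interpolation.

## Design decisions on open ground

* The composite ComSUVR averages regional means unweighted; a
  voxel-weighted variant is a flag. Left/right homologues share one name.
* Regional SUVR is computed on the native grid (upsampling serves only
  the histograms).
* The cerebellum is not excluded from the whole-brain mask by default;
  `exclude_labels` can mask any labelled structure out of the tissue maps.
* The model-curve trajectory used to demonstrate the unimodal → wide →
  bimodal transition is (πG2, µG2) = (0.02, 1.2) → (0.5, 1.28) →
  (0.6, 1.8) at σ = 0.15. An equal-weight, equal-σ two-Gaussian mixture
  is bimodal once separation exceeds 2σ; the middle point is chosen just
  below that threshold so it genuinely shows a single wide peak
  (its simulated GM-kurtosis, ≈ −0.44, matches the wide-peak example the
  method was built to capture).
* Spearman p-values use the exact permutation distribution for n ≤ 9 and
  the t-approximation otherwise; they are reported, never asserted.

## Worked example

```{r example, eval = FALSE}
tspec <- three_component_spec(muG2 = 1.6, piG2 = 0.5)   # positive-like case
ph <- generate_phantom(phantom_spec(seed = 1), tspec)
rec <- evaluate_subject_volumes(ph$suv, ph$p_gm, ph$p_wm, ph$labels)
rec
#> <subject_record> subject
#>   ComSUVR 1.2412 | skewness -0.8497 MMR 1.1288 | GM-kurtosis -1.7313
#>   muG1 1.0222 muG2 1.5748 piG2 0.4609 | muW 1.4995
```

The fitted µG2 and πG2 sit within 0.03 / 0.04 of the planted 1.6 / 0.5;
µG1 and µW recover the model anchors 1.0 and 1.5; MMR > 1 and strongly
negative GM-kurtosis show the positive pattern. Every number above is
produced by the code (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`, which recompute these quantities from scratch).

## Known limitations

* The two-component decomposition is the model's ceiling: mixed pathology
  needing ≥ 3 GM components is out of scope.
* Recovery tolerances hold in the phantom's idealized geometry; on real
  data, partial-volume loss at 3 mm cortex biases µG2 downward in ways no
  desk-scale test can bound.
* The NIfTI reader covers single-file NIfTI-1 with the common datatypes;
  two-file pairs and NIfTI-2 are not supported.
* Registration and segmentation are upstream: all volumes must be
  co-registered on a shared grid (affines equal to 1e-4 mm).
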