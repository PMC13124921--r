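# amyhist

Separated gray-matter histogram analysis of amyloid PET SUVR images.

## Who this is for

Amyloid PET is usually read visually and quantified by a composite SUVR
(standardized uptake value ratio against the cerebellar cortex, averaged
over frontal, posterior cingulate, precuneus, parietal and lateral temporal
cortex — "ComSUVR"). `amyhist` implements a histogram-based alternative for
researchers working on objective amyloid quantification: it separates the
brain SUVR distribution into its tissue components and summarizes each with
a handful of shape parameters that track amyloid burden.

## The model

The parenchymal SUVR distribution is modelled as three Gaussian components:

- **G1**: amyloid-free gray matter, mean µG1 ≈ 1 (cortex matches the
  cerebellar reference);
- **G2**: amyloid-bearing gray matter, mean µG2 > µG1, proportion πG2 of GM;
- **WM**: white matter with off-target binding, mean µW ≈ 1.5.

with GM/WM occupying ≈ 43% / 57% of the parenchyma. Per subject, the
pipeline computes:

- **whole-brain histogram** (voxels with p_GM + p_WM > 0.5, bin width 0.05
  SUVR): bias-corrected skewness, mode, and **MMR** (mode/mean ratio;
  < 1 in amyloid-negative patterns, > 1 in positive ones);
- **GM histogram** (p_GM > 0.6): bias-corrected excess kurtosis
  (**GM-kurtosis**, near 0 for sharp unimodal, strongly negative for
  broad/bimodal) and a two-Gaussian EM decomposition giving **µG1, µG2,
  πG2** (fits with nearly coincident means are flagged degenerate);
- **WM histogram** (p_WM > 0.6): **µW**;
- **ComSUVR** from an AAL-style label volume and a configurable region
  scheme.

A three-component forward simulator (`expected_curves`, `sample_voxels`)
and a seeded 3-D brain phantom generator (`generate_phantom`) provide
ground truth, so the entire pipeline is testable without patient data.

## Worked example

```r
library(amyhist)

# a positive-pattern phantom: planted muG2 = 1.6, piG2 = 0.5
tspec <- three_component_spec(muG2 = 1.6, piG2 = 0.5)
ph <- generate_phantom(phantom_spec(seed = 1), tspec)

rec <- evaluate_subject_volumes(ph$suv, ph$p_gm, ph$p_wm, ph$labels)
rec
#> <subject_record> subject
#>   ComSUVR 1.2412 | skewness -0.8497 MMR 1.1288 | GM-kurtosis -1.7313
#>   muG1 1.0222 muG2 1.5748 piG2 0.4609 | muW 1.4995
```

Reading the output: µG1 ≈ 1.02 and µW ≈ 1.50 recover the model anchors;
the fitted µG2 (1.57) and πG2 (0.46) recover the planted amyloid component
within the pipeline's tolerances despite 6 mm PET smoothing; MMR > 1 and
the strongly negative GM-kurtosis are the positive-pattern signatures.
On a synthetic 30-subject cohort, fitted µG2 correlates with measured
ComSUVR at Spearman ρ ≈ 0.999 and GM-kurtosis at ρ ≈ −0.96 (see
`tests/testthat/test-acceptance.R`).

File-based use (NIfTI-1 volumes, all co-registered):

```r
rec <- evaluate_subject("pet.nii.gz", "p_gm.nii.gz", "p_wm.nii.gz",
                        "labels.nii.gz", scheme = "scheme.json")
write_subject_record(rec, "subject.json")
```

or from the shell via the bundled CLI:

```sh
exec/amyhist phantom  --out ph/ --seed 1 --muG2 1.6 --piG2 0.5
exec/amyhist evaluate --pet ph/suv.nii.gz --gm ph/p_gm.nii.gz \
                      --wm ph/p_wm.nii.gz --labels ph/labels.nii.gz \
                      --out rec.json
exec/amyhist cohort   --records rec1.json,rec2.json,rec3.json --out cohort.csv
exec/amyhist simulate --out curves.csv --muG2 1.4 --piG2 0.5
```

## Documentation

`vignettes/separated-gm-histogram.Rmd` describes the model and its
assumptions, every tunable parameter, what the phantom does and does not
emulate (hence what a green test establishes), and the numerical design
choices.
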