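# spectralPCa

Spectral and statistical assessment of prostate cancer on biparametric
MRI (BP-MRI).

## The problem

A biparametric prostate MRI exam provides three scalar volumes: the
apparent diffusion coefficient map (ADC), a high b-value diffusion
image (HBV), and a T2-weighted structural image. Prostate tumors show
a characteristic joint contrast — low ADC, high HBV, low T2 — which
suggests treating the registered exam as a three-band *spectral* image
and borrowing target-detection machinery from hyperspectral imaging.

`spectralPCa` implements that pipeline end to end:

1. **Registration** — resample the three sequences to a common grid
   (coarsest in-plane spacing, reference slice spacing), translate by
   header origins in whole voxels, crop to the common field of view,
   and stack into a `registered_cube` whose every voxel carries a
   spectrum *x* = (ADC, HBV, T2).
2. **Background model** — mean *m* and covariance *CM* of normal
   prostate tissue over a gland-minus-lesion mask, with
   principal-component filtering and two shrinkage-regularized
   variants (identity target and diagonal target), the shrinkage
   weight selected by leave-one-out Gaussian likelihood.
3. **Spectral scores** — per-band z-scores with an RMS combination,
   the signal-to-clutter ratio
   SCR = (S−m)ᵀ CM⁻¹ (S−m),
   and the per-voxel adaptive cosine estimator

   ACE(x) = [(x−m)ᵀ CM⁻¹ (S−m)]² / { [(x−m)ᵀ CM⁻¹ (x−m)] · [(S−m)ᵀ CM⁻¹ (S−m)] },

   the squared cosine between whitened voxel and whitened signature,
   scored in [0, 1].
4. **Morphometrics** — threshold the ACE map (τ = 0.9), label 3D
   connected components (26-connectivity), drop blobs under 5 voxels,
   and measure blob volume (mL) and eccentricity
   E = (l−s)/l from scatter-matrix axis lengths (0 = ball, 1 = line).
5. **Calibration** — map an external AI detector's
   clinical-significance likelihood to a continuous ISUP grade, either
   piecewise-linearly through (0,0), (0.5,2), (1,5) or as
   c·atanh(p) with c = 2/atanh(0.5) ≈ 3.6409, capped at 5.
6. **Statistics** — univariate/multivariate regression of features on
   ISUP grade, and logistic AUROC over 1000 randomized stratified
   70/30 splits with a 2.5–97.5 percentile interval against the
   CsPCa label (ISUP ≥ 2).
7. **Synthetic cohort** — a fully seeded phantom generator with
   planted grade-dependent contrast, volume, and shape effects, plus a
   surrogate AI detector, so the whole pipeline is testable without
   patient data.

## Worked example

```r
library(spectralPCa)

spec   <- synthetic_cohort_spec(n_patients = 20, seed = 71)
cohort <- generate_cohort(spec)
cohort
#> <synthetic_cohort> 20 patients, seed 71

res <- run_pipeline(cohort, pipeline_config(n_iter = 200, seed = 1))
res$report[, c("model", "R1", "p1", "R_multi", "auroc",
               "auroc_ci_low", "auroc_ci_high")]
#>                              model    R1       p1 R_multi auroc auroc_ci_low auroc_ci_high
#> 1                       scr_modreg 0.857 1.37e-06      NA 0.901        0.664             1
#> 2                           zscore 0.857 1.38e-06      NA 0.917        0.556             1
#> 3                     total_volume 0.886 2.10e-07      NA 0.954        0.778             1
#> 4                  avg_blob_volume 0.757 1.13e-04      NA 0.942        0.667             1
#> 5                      ecc_largest 0.498 2.53e-02      NA 0.694        0.333             1
#> 6                    ai_likelihood 0.921 8.33e-09      NA 1.000        1.000             1
#> 7               ai_avg_blob_volume 0.420 6.54e-02      NA 0.771        0.333             1
#> 8  ai_avg_blob_volume + scr_modreg 0.420 6.54e-02   0.861 0.902        0.664             1
#> 9      ai_avg_blob_volume + zscore 0.420 6.54e-02   0.859 0.913        0.667             1
#> 10             zscore + scr_modreg 0.857 1.38e-06   0.859 0.849        0.444             1
```

The planted effects are recovered with the expected signs: spectral
contrast (SCR, z-score) and blob volume correlate strongly and
positively with grade, eccentricity weakly and positively *here* only
because a 20-patient cohort is noisy — across seeds its planted sign
is negative (see the test suite's parameter-recovery property).

Individual stages are exported too:

```r
p <- cohort$patients$p001
p$adc
#> <sequence_volume ADC> 40x40x16 voxels, spacing 2, 2, 3 mm, origin 0, 0, 0 mm

f <- extract_patient_features(p, pipeline_config())
round(unlist(f[c("scr_modreg", "zscore", "total_volume",
                 "ecc_largest", "ai_likelihood")]), 3)
#>    scr_modreg        zscore  total_volume   ecc_largest ai_likelihood
#>        42.441         4.657         1.320         0.526         0.218
```

Cohorts round-trip through a directory layout of per-patient NIfTI
volumes plus `metadata.csv` / `ground_truth.json`
(`write_cohort()` / `load_cohort()`), and pipeline configurations can
be read from YAML (`read_pipeline_config()`).

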