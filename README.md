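# aslnorm

Direct spatial normalization of arterial spin labeling (ASL) perfusion
images to a standard-space template, using the perfusion contrast itself
instead of a structural scan.

## Why

Regional cerebral blood flow (CBF) analysis of ASL data needs every
subject's CBF map in a common stereotactic space. The usual route runs
through segmentation and normalization of a T1-weighted image — which breaks
down in infants, where ongoing myelination leaves the T1w image with almost
no gray/white matter contrast. ASL, in contrast, shows a robust perfusion
difference between gray matter (GM, ~60 ml/100 g/min) and white matter
(WM, ~20 ml/100 g/min) from an early age. `aslnorm` exploits that contrast
directly:

1. A **pseudo-CBF target** is built in template space as
   `v_GM * P_GM + v_WM * P_WM` from the template's tissue probability maps
   (defaults `v_GM = 60`, `v_WM = 20` ml/100 g/min), smoothed to the ASL
   acquisition resolution (default 3.75 x 3.75 x 4.0 mm FWHM).
2. The native CBF image is registered to that target with a **rigid**,
   **rigid + affine**, or **rigid + affine + nonlinear** transform. The
   nonlinear deformation is parameterized by a separable tensor product of
   low-frequency discrete cosine (DCT) basis functions, 16 per dimension,
   under a bending-energy penalty; the similarity is sum-of-squared
   differences after a closed-form global intensity scaling.
3. The nonlinear strategy runs in **two iterations**: after a rough
   rigid + affine alignment, subject-specific GM/WM perfusion values are
   estimated by least squares on resolution-matched tissue maps and the
   pseudo-CBF target is rebuilt with them before the DCT stage.
4. All estimated transforms are composed into a **single deformation field**
   and the native image is interpolated exactly once into template space.
5. Quality is scored with the **real-valued Tanimoto coefficient**
   `TC = 100 * sum(ab) / (sum(a^2) + sum(b^2) - sum(ab))` over brain-masked,
   97th-percentile-normalized intensities (joint exclusion of
   above-percentile voxels); TC > 70% is conventionally read as excellent
   agreement. Overlay montages (CBF with the 50% WM partial-volume border)
   support visual review, and per-region mean CBF can be extracted from any
   integer label atlas.

A self-contained synthetic phantom (ellipsoidal pediatric-like brain with a
lobulated GM shell, WM core, CSF rim, ventricles and deep GM nuclei; seeded
smooth ground-truth warps including a trigonocephaly-like frontal
narrowing; coarse noisy native ASL grid) makes every stage testable without
any imaging data.

## Worked example

```r
library(aslnorm)

# a synthetic subject: 4 mm smooth warp + pose offset + noise (sd 5)
subj <- make_subject(phantom_spec(seed = 1))

res <- normalize_asl(subj$native_cbf, subj$template, strategy = "dct")
res$tissue_cbf_used
#>     v_gm     v_wm 
#> 58.69800 20.60346

ref <- build_pseudo_cbf(subj$template)
real_valued_tc(res$cbf_std, ref, subj$template$brain_mask)
#> <similarity_score> TC 98.58% over 52000 voxels (p97 normalization)

displacement_error(res$field, subj$true_field, subj$template$brain_mask)$mean_mm
#> [1] 1.699045
```

The two-iteration scheme has replaced the 60/20 reference values with the
subject's own estimated GM/WM perfusion; the normalized volume agrees with
the template reference at TC 98.6% (far above the 70% "excellent" mark),
and the composed deformation field lands within ~1.7 mm (mean, over the
brain) of the simulated ground truth — most subjects recover to ~1 mm, with
the remainder limited by displacement components the perfusion contrast
cannot see (see the methods vignette).

From a shell, the same pipeline is available as:

```sh
inst/cli/aslnorm simulate --n 8 --seed 1 -o cohort/
inst/cli/aslnorm normalize --strategy dct --cbf cohort/sub01_cbf.nii.gz \
  --template-gm cohort/template_gm.nii.gz --template-wm cohort/template_wm.nii.gz -o out/
inst/cli/aslnorm evaluate --inputs sub01:dct:out/sub01_cbf_std.nii.gz \
  --reference ref.nii.gz --mask mask.nii.gz -o tc
```

`normalize` writes, per subject: the standard-space CBF NIfTI, a JSON
transform-chain container, a cost-trace CSV and an overlay montage PNG.

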