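# dgspect

Dual-gated (cardiac × respiratory) SPECT myocardial-perfusion simulation,
4D reconstruction, and motion-compensated attenuation-correction
comparison.

## What it is for

Dual-gated SPECT bins the acquired photons by both ECG phase and
respiratory phase, freezing cardiac and respiratory motion at the price of
severe photon starvation in every bin. Reconstruction then has to decide
which attenuation map to put inside the system matrix: a respiratory
motion-matched map per phase (MAC) or a single motion-averaged map (AAC).
`dgspect` provides an end-to-end in-silico laboratory for this question,
for researchers in emission-tomography image reconstruction:

* a **geometric moving-torso phantom** (ellipsoidal torso, lungs, liver,
  half-ellipsoid LV shell) with configurable respiratory translation
  (default 1.59 cm SI / 0.95 cm AP for the heart), cardiac contraction,
  and a transmural perfusion defect (20% uptake reduction, 20 mm × 100°)
  at anterior/inferior/lateral/septal positions;
* an **analytic projector** `H` with depth-dependent Gaussian blur
  (≈1.3 cm FWHM at the 28.5 cm rotation radius), voxelized attenuation,
  optional kernel scatter, and an exact adjoint;
* Poisson **acquisition simulation** (8×10⁶ expected counts over all
  gates at full scale);
* **OSEM** and a cardiac motion-compensated **4D MAP reconstruction** per
  respiratory phase, solved by a relaxed block-sequential (BSREM-type)
  algorithm with a spatiotemporal Gibbs prior
  `p(I) ∝ exp(−β_s U_s − β_t U_t)`;
* post-reconstruction **respiratory motion-compensated filtering (RMC)**:
  cardiac summation, single-step optical-flow deformation estimation
  `DVF_{j←i} = (Img_j − Img_i)∇Img_i / (|∇Img_i|² + (Img_j − Img_i)²)`,
  warping, and distance-weighted temporal fusion;
* **evaluation**: relative RMSE and SSIM over an LV region against ideal
  (noise-free, attenuation-free, blurred) OSEM references, intensity
  profiles, a 4-channel channelized Hotelling observer (CHO) with internal
  noise, ROC area (Az), and paired bootstrap significance tests.

The experiment driver compares three arms: `4d-mac` (no respiratory
filtering), `4d-rmc-mac`, and `4d-rmc-aac`.

## Worked example

```r
library(dgspect)

cfg <- experimentConfig("desk")      # 32^3 grid, 32 views, 4x4 gates,
                                     # 5 noise realizations, anterior lesion
res <- runExperiment(cfg)
s   <- summarizeResults(res)
aggregate(mean ~ arm + metric, s$by_gate, mean)
#>          arm metric      mean
#> 1     4d-mac   rmse 0.8031581
#> 2 4d-rmc-aac   rmse 0.6379832
#> 3 4d-rmc-mac   rmse 0.6361407
#> 4     4d-mac   ssim 0.4873669
#> 5 4d-rmc-aac   ssim 0.5404242
#> 6 4d-rmc-mac   ssim 0.5430226
res$observer
#>          arm   lesion   az
#> 1     4d-mac anterior 0.44
#> 2 4d-rmc-mac anterior 0.68
#> 3 4d-rmc-aac anterior 0.72
```

Reading the output: respiratory motion-compensated filtering lowers the
LV-region relative RMSE of the dual-gated reconstruction by about 21% and
raises SSIM by about 11%, and lesion detectability (Az) rises from chance
level to 0.68–0.72 — the photon-starved 4D reconstructions alone are too
noisy for the observer. Matched attenuation (`4d-rmc-mac`) is slightly
more accurate than averaged (`4d-rmc-aac`) in RMSE/SSIM, most visibly at
the extreme respiratory phases, while their detectability difference is
small — the qualitative pattern expected from the underlying study design.

Lower-level functions are exported individually (`generatePhantom`,
`forwardProject`/`backProject`, `simulateAcquisition`, `osem`, `bsrem4d`,
`rmc`, `choStudy`, ...); see the methods vignette
(`vignettes/dgspect-methods.Rmd`) for the model, parameter meanings and
design choices. A thin CLI lives at `inst/cli/dgspect.R`:

```sh
Rscript inst/cli/dgspect.R run-experiment --profile desk --out out/
```

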