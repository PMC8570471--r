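# ogmua

Oscillating-gradient and microscopic-anisotropy diffusion MRI:
simulation, fitting, and test-retest statistics for preclinical
(mouse-brain) studies.

Two advanced dMRI contrasts go beyond conventional DTI/DKI. **OGSE**
(oscillating gradient spin echo) varies the oscillation frequency *f* of
the diffusion gradients to probe short diffusion times; tissue mean
diffusivity follows the power law

    MD(f) = MD0 + Λ·√f

and the *diffusion dispersion rate* Λ (µm²·ms⁻¹·Hz⁻½) and
ΔMD = MD(190 Hz) − MD(0 Hz) are the metrics of interest. **µA dMRI**
compares powder-averaged signals under linear (LTE) and spherical (STE)
tensor-valued encoding; the cumulant representation
ln S_X(b) = ln S₀ − bD + b²D²K_X/6 for X ∈ {LTE, STE} yields the linear
and isotropic kurtoses, and

    µA² = D²(K_LTE − K_STE)/6 = ln(S_LTE/S_STE)/b²,
    µFA = sqrt(1.5·µA²/(µA² + 0.2·D²))

quantify microscopic anisotropy free of fiber-orientation-dispersion
confounds. This package is for researchers planning or analyzing such
experiments: it implements the encoding waveforms and b-tensors, a
synthetic test-retest cohort generator with known ground truth, the
voxel-wise and ROI estimators (MD per frequency, ΔMD, Λ, µA, µFA, K_LTE,
K_STE, DTI MD/FA), and the reproducibility statistics used to judge them
(Bland-Altman, between/within-subject CVs, van Belle and paired-t sample
sizes, SNR maps).

The µA fit is a joint constrained linear least-squares problem — shared
intercept and diffusivity across encodings, with D ≥ 0 and
w_LTE ≥ w_STE ≥ 0 (w_X = D²K_X) — solved exactly per voxel by active-set
enumeration.

## Worked example

Simulate a mouse-brain-like phantom, run both protocols noiselessly, and
recover the ground truth:

```r
library(ogmua)

layout <- phantom_layout()                      # 16 x 16 x 4, 5 ROIs + CSF
ground_truth_table(layout$substrates)[1:3, 1:6]
#>   roi    MD0    lambda      dMD    muA   muFA
#> 1  CC 0.6452 0.005463 0.07530 0.2466 0.7958
#> 2  IC 0.6452 0.005065 0.06981 0.2145 0.7306
#> 3  HC 0.7133 0.006820 0.09401 0.1383 0.4873

ogse <- generate_dataset(layout, build_protocol("ogse", seed = 1))
series <- md_series(ogse)                      # MD map per frequency
roi <- roi_dispersion(series, layout$labels,
                      mask = csf_mask(series$md_maps[[1]]),
                      roi_names = layout$roi_names[1:5])
roi[1:3, c("roi", "md0", "lambda", "dMD")]
#>   roi       md0      lambda        dMD
#> 1  CC 0.6306329 0.005470750 0.07544895
#> 2  IC 0.6308421 0.005109781 0.07040472
#> 3  HC 0.6676875 0.006684064 0.09212686

mua <- generate_dataset(layout, build_protocol("mua", seed = 1))
fit <- joint_kurtosis_fit(powder_average(mua))
mean(fit$muFA[layout$labels == layout$roi_names["CC"]])
#> [1] 0.7717652
```

The ROI estimates sit within a few percent of the generating values; the
small shortfalls are the cumulant-truncation bias of single-shell and
kurtosis fitting at the protocol b-values, quantified in the methods
vignette (`vignettes/methods.Rmd`).

Reproducibility statistics on a simulated 12-subject test-retest cohort
come from `run_pipeline(default_config(seed = 1))`, or step by step via
the analysis scripts:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort -> results/cohort
Rscript analysis/02_fit_metrics.R       # metric maps + ROI table
Rscript analysis/03_reproducibility.R   # Bland-Altman, CVs, CV maps
Rscript analysis/04_sample_sizes.R      # sample-size grids (4-12% effects)
```

A run at the default settings prints, per metric, the mean |bias|,
between- and within-subject CVs, e.g.

```
lambda   mean |bias| 0.0001399, between CV 10.5%, within CV 5.3%
muA      mean |bias| 0.002589, between CV 7.1%, within CV 4.0%
muFA     mean |bias| 0.002431, between CV 1.1%, within CV 0.8%
K_ste    mean |bias| 0.007062, between CV 8.6%, within CV 6.5%
```

reproducing the qualitative ordering reported in vivo: negligible
test-retest biases, within-subject CVs below between-subject CVs, µA/µFA
the most reproducible metrics and K_STE the least, and voxel-wise CVs far
higher for the OGSE metrics than for µA/µFA.

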