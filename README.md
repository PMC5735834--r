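# cinelv

Denoising and left-ventricular function analysis for low-SNR cardiac cine
MRI.

Small-animal cardiac cine acquisitions made with a birdcage volume coil are
noisy, and the clinically relevant outputs — end-diastolic volume (EDV),
end-systolic volume (ESV), ejection fraction (EF) and left-ventricular mass
(LVM) — are read off manual segmentations of those noisy images. `cinelv`
implements the full evaluation pipeline for asking whether post-hoc denoising
improves those measurements: three edge-preserving 3D denoisers applied per
cardiac phase, image-quality metrics, cardiac function parameters, and
observer-agreement statistics, exercised end to end on a synthetic
left-ventricle cine phantom with simulated observers.

## What is implemented

**Denoisers** (each on one 3D phase volume; `denoise_series()` maps them over
the phase axis):

* `anisotropic_diffusion()` — Perona–Malik diffusion
  ∂ₜu = ∇·(e^{−(|∇u|/κ)²} ∇u) in conservative flux form with Neumann
  boundaries.
* `total_variation()` — the ROF problem
  min_u TV(u) + ‖u − f‖²/(2λ), solved by Chambolle's dual projection.
* `ornlm()` — optimized Rician non-local means: voxelwise NLM over a
  11³-voxel search volume with 3³-voxel patches (26 neighbors), averaging the
  *squared* image and removing the Rician bias,
  û = √(max(NLM(u²) − 2σ², 0)), using E[M²] = S² + 2σ².

**Noise** — Rician simulation (`add_rician_noise()`), background noise
estimation with Rayleigh correction (`estimate_sigma()`,
`default_background_roi()`).

**Metrics** — SNR = mean(ROI)/SD(background), CNR = SNR_blood − SNR_myo
(`compute_snr()`, `compute_cnr()`, `quality_report()`).

**Function** — per-phase voxel-counted volumes, EDV/ESV/EF and
LVM = myocardial volume × 1.05 g/cm³ (`phase_volumes()`,
`compute_function()`).

**Agreement** — paired absolute/relative differences, Pearson r, two-tailed
paired t-test, gold-standard comparison, and the assembled
intra-/inter-observer tables (`paired_differences()`, `paired_ttest()`,
`exvivo_comparison()`, `build_table()`).

**Phantom & study** — a rat-scale short-axis cine phantom with known truth
(`generate_phantom()`), stochastic contour observers whose precision is tied
to image contrast (`simulate_observer()`, `cnr_linked_jitter()`), and a fully
seeded study driver (`run_study()`) with `tidy()`/`glance()`/`autoplot()`
methods. A command-line front end lives in `exec/cinelv`.

## Worked example

A demonstration-scale study (64×64 in-plane, 5 subjects, 4 phases; the native
acquisition grid is 256×256 × 15 slices × 16 phases):

```r
library(cinelv)
report <- run_study(demo_study_config(master_seed = 7))
report
#> <study_report> 5 subjects x 4 conditions (master seed 7)
#>  condition snr_blood        cnr
#>      aniso  88.47191  45.030480
#>      ornlm  45.83570  23.910414
#>        raw  12.40435   6.135448
#>         tv 977.70444 480.667713
```

The injected noise was calibrated so raw blood SNR ≈ 12; all three filters
raise SNR and CNR far above the raw level, with total variation flattening
the pure-noise background most aggressively. The inter-observer agreement for
LVM (observer 1 vs observer 2, difference normalized to the pair average):

```r
subset(tidy(report), parameter == "LVM" & study == "inter",
       select = c(condition, mean_rel_pct, sd_rel_pct, r, p))
#>  condition mean_rel_pct sd_rel_pct     r      p
#>        raw       -5.522      4.106 0.942 0.0309
#>      aniso        0.000      0.000 1.000 1.0000
#>         tv        0.000      0.000 1.000 1.0000
#>      ornlm       -0.013      0.116 1.000 0.7040
```

On raw images the two simulated observers disagree by ~5.5% in mass
(significant at p < 0.05), while on filtered images the contrast-linked
contour jitter drops below the voxel grid and the observers essentially
reproduce the truth — the qualitative filtered-versus-raw effect the pipeline
is built to measure. `tidy(report, "gold")` compares each observer's LVM
against the phantom's true mass (the ex-vivo stand-in), and
`autoplot(report)` draws the relative-difference bars by condition and
parameter. The methods vignette
(`vignettes/denoising-cardiac-cine.Rmd`) documents the models, the parameter
defaults and what this phantom can and cannot say about real data.

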