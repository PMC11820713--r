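# radarbp

Non-contact estimation of per-beat cardiac timing and cuffless blood
pressure from continuous-wave quadrature Doppler radar.

## The problem

A K-band Doppler radar pointed at the chest measures displacement `x(t)`
through the phase of its baseband quadrature pair

    I(t) = cos(θ + 4πx(t)/λ + ΔΦ(t)),   Q(t) = sin(θ + 4πx(t)/λ + ΔΦ(t)),

where `λ` is the carrier wavelength and `ΔΦ` residual phase noise. Most of
`x(t)` is respiration; the cardiologically interesting part is a pair of
brief high-frequency vibration bursts per heartbeat — one at the systole
onset (ventricular contraction, the R peak of a synchronized ECG) and one at
the diastole onset (valve closure, the T-wave end). `radarbp` recovers the
timing of those bursts and predicts blood pressure from them:

1. **Integrated spectrum.** Band-pass `I`, `Q` to 8–30 Hz, form
   `S = I + jQ`, take a short-time Fourier transform (256 ms Hann window),
   and sum the power over 5–30 Hz at each frame. Each beat shows two peaks —
   one per burst.
2. **Segmentation.** Two estimators label each frame as systole or diastole:
   a four-state cyclic duration-dependent hidden semi-Markov model
   (logistic-regression emissions, dwell-extended Viterbi
   `δ_t(j) = max_d δ_{t−d}(pred j) · p_j(d) · Π b_j(O_s)`), and a 1D U-net
   (encoder filters 32/64/128, 256-filter bottom, skip connections, 1024-point
   input) trained with MAE loss against ECG-derived 0/1 labels.
3. **Blood pressure.** Per 10 s segment (5 s overlap), mean IBI, systolic and
   diastolic durations and the pulse-wave width at 25% of peak feed a
   grid-searched random forest, evaluated under subject-grouped 5-fold
   cross-validation. A conventional baseline (peaks of the 0.5–2 Hz pulse
   wave) and exact ECG features bracket the comparison.

Because the reference dataset is closed, the package ships a physics-based
simulator (`generate_cohort()`) that reproduces the study conditions —
24.25 GHz carrier, 1 kHz sampling, supine resting subjects with respiration,
per-beat chest vibrations and duration-coupled blood pressure — with full
ground truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(radarbp)

cohort <- generate_cohort(n_subjects = 10, duration_s = 120, seed = 11)
prep   <- prepare_cohort(cohort)

# train HSMM + U-net on 8 subjects, evaluate durations on the other 2
de <- duration_experiment(prep, train_subjects = 1:8, test_subjects = 9:10,
                          unet_cfg = unet_config_scaled(learning_rate = 0.003),
                          seed = 1)
de$metrics
#>    source   feature       mae_s      rmse_s n_matched
#> 1     bpf diastolic 0.075182078 0.077345871       159
#> 3     bpf  systolic 0.074286679 0.076579368       159
#> 7    hsmm diastolic 0.010151221 0.020454994       281
#> 9    hsmm  systolic 0.010208433 0.020815737       281
#> 10   unet diastolic 0.006122176 0.008050693       281
#> 12   unet  systolic 0.005673705 0.007573605       281
```

Read: against the ECG ground truth of the two held-out subjects, the U-net
recovers systolic/diastolic durations to ~6 ms and the HSMM to ~10 ms,
while the conventional pulse-wave baseline is an order of magnitude worse
(~75 ms) — the segmentation-on-integrated-spectrum approach, not the
band-pass proxy, is what makes the timing features usable. The full
cross-validated blood-pressure experiment is one call:

```r
report <- run_experiment(cohort, k = 5, seed = 1,
                         unet_cfg = unet_config_scaled(learning_rate = 0.003))
print(report)
```

A thin command-line front end is included:

```sh
Rscript inst/cli/radarbp.R simulate --subjects 5 --duration 120 --seed 1 --out cohort/
Rscript inst/cli/radarbp.R run --subjects 5 --duration 60 --seed 1 --report report.json
```

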