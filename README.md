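# qtdecay

Model-based estimation of QT intervals for fetal mouse electrocardiograms.

## The problem

The QT interval — from the onset of the QRS complex to the end of the T
wave — measures ventricular electrical systole and is the key biomarker for
long QT syndrome. In fetal mice the T wave is effectively unmeasurable: its
amplitude is tiny and the fetal mouse heart is far smaller than a human
fetal heart. `qtdecay` implements an estimator that predicts the end of the
T wave from the RR interval alone, so QT intervals can be studied in fetal
mice (e.g. for drug-induced QT prolongation work) without ever measuring a
T wave. It is aimed at researchers analyzing fetal ECG recordings,
optionally alongside co-registered Doppler ultrasound for validation.

## The model

Ventricular repolarization decays like a discharging capacitor. With the RC
time constant identified with RR/2π (the cut-off frequency taken as the
heart rate), each beat carries the decay curve

```
R(t) = v0 · exp(−2π t / RR),   v0 = 100,
```

with `t` in ms since the R peak. A rate-dependent threshold constant

```
k = | mean(R(t)) / x + 2π / x² |,   x = 1000 / RR  (s⁻¹)
```

marks where repolarization ends; the `+2π/x²` term accommodates the short
mouse action potential (the human variant subtracts `6π/x²` instead). The
estimated T-wave end is the median of the sample times whose amplitude
falls strictly inside the band

```
T_E = median { t : k − 0.5 < R(t) < k + 1 },
```

and the QT interval is assembled as `(R − Q) + T_E`, using the measured
per-beat Q-to-R separation when a signal is available or a configurable
8 ms default when only RR intervals are given.

Around the estimator the package provides the full validation workflow:
automatic R/Q fiducial detection, two-clock alignment via shared marker
pulses, Q-to-aortic-closure (Q-Ac) intervals from Doppler event
timestamps, difference percentages `100·(Q-Ac − QT)/Q-Ac`, Bland–Altman
limits of agreement and Pearson correlation — plus a synthetic
co-registered fECG/Doppler generator with exact ground truth.

## Worked example

```r
library(qtdecay)

# QT from RR alone, at the five recorded per-fetus mean RR intervals
qt_from_rr(c(264, 256, 273, 276, 390))
#>   rr_ms        k t_end_ms qt_ms
#> 1   264 4.631955      127   135
#> 2   256 4.478737      125   133
#> 3   273 4.805287      130   138
#> 4   276 4.863291      131   139
#> 5   390 7.151258      162   170
```

`k` is the threshold constant for each beat, `t_end_ms` the estimated
T-wave end after the R peak, and `qt_ms` the assembled QT interval (here
with the 8 ms default Q-R offset). The full signal workflow:

```r
# simulate a co-registered recording, then estimate and validate
dir <- tempfile(); cfg <- sim_config(n_beats = 69, seed = 1)
run_simulate(cfg, dir)
est <- run_estimate(file.path(dir, "signal.csv"), dir)
est$summary
#>    n rr_mean_ms rr_sd_ms qt_mean_ms qt_sd_ms
#> 1 69   267.5652 25.10828   136.3188 7.898237
report <- run_validate(file.path(dir, "beat_table.csv"),
                       file.path(dir, "timing.csv"),
                       file.path(dir, "report.json"))
c(report$bias_ms, report$pct_within_loa, report$pearson_r)
#> [1] -3.0811295 97.1014493  0.9569952
```

The 69 detected beats average RR 267.6 ms and model QT 136.3 ms. The
validation bias of −3.1 ms recovers the 3 ms electromechanical lag the
generator injects (model QT sits just below Q-Ac), with 97% of the
differences inside the Bland–Altman limits and r = 0.96. The same workflow is
available from a shell via the installed `exec/qtdecay` script
(subcommands `simulate`, `estimate`, `validate`).

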