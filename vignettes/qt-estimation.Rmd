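---
title: "Model-based QT estimation for fetal mouse ECG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based QT estimation for fetal mouse ECG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtdecay)
```

## The estimation problem

The QT interval runs from the onset of ventricular depolarization (the Q
fiducial) to the end of repolarization (the end of the T wave). In fetal
mice the T wave cannot be measured reliably: its amplitude is minute, the
heart is tiny, and fetal recordings are noisy. `qtdecay` therefore
estimates the *end* of the T wave from the RR interval alone, and measures
only the robust fiducials (R peaks and the Q troughs just before them)
from the signal.

## The decay model

The repolarization phase of a cardiac action potential decays much like
the voltage across a discharging capacitor. An RC discharge obeys
$V(t) = v_0 e^{-t/RC}$ with time constant $RC = 1/(2\pi f_c)$. Identifying
the cut-off frequency $f_c$ with the instantaneous heart rate ($1/f_c
\to RR$) gives the per-beat decay curve

$$R(t) = v_0\, e^{-2\pi t / RR}, \qquad v_0 = 100,$$

with $t$ in ms after the R peak and $RR$ the interval from the previous R
peak. A rate-dependent threshold constant marks where on that decay the
repolarization ends:

$$k = \left|\frac{\overline{R(t)}}{x} + \frac{2\pi}{x^{2}}\right|,
\qquad x = \frac{1000}{RR}\ \mathrm{s}^{-1},$$

where $\overline{R(t)}$ is the mean of the decay curve over one beat. The
$+2\pi/x^2$ term is the mouse-specific adjustment: murine action
potentials are far shorter than human ones (repolarization is carried
largely by the transient outward K$^+$ current), so the threshold is
raised and the T end pulled earlier. The human variant of the model
instead *subtracts* $6\pi/x^2$; `model_config(species = "human")` switches
the sign and coefficient, and nothing else. The estimated T end is the
median of the sample times whose amplitude lies strictly inside a band
around $k$:

$$T_E = \mathrm{median}\,\{\,t : k - 0.5 < R(t) < k + 1\,\},$$

and the QT interval is assembled as $QT = (R - Q) + T_E$.

### Assumptions

* The repolarization decay is exponential with rate $2\pi/RR$ — i.e. the
  time constant scales with the beat length, which is what couples QT to
  RR.
* $T_E$ is referenced to the R peak. The band median is a time *on the
  decay curve*, whose origin we anchor at the R peak; QT then needs the
  measured (or assumed) Q-to-R separation. With an 8&nbsp;ms Q-R offset
  this anchoring reproduces all five per-fetus reference QT means within
  2&nbsp;ms of the values obtained in co-registered validation recordings,
  which we confirmed against a closed-form continuous-time oracle (below)
  before freezing the discrete implementation.
* The model predicts *electrical* systole; the Doppler aortic-closure
  event used for validation follows it by a small electromechanical lag,
  so model QT is expected to sit slightly below Q-Ac.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `v0` | 100 | – | Canonical curve height; puts `k` in the 2–8 range for physiological RR. |
| `fs` | 1000 | Hz | Acquisition rate of the target recordings; 1 ms grid. |
| `species` | mouse | – | Sign/coefficient of the $\pi/x^2$ correction. |
| `qr_offset_ms` | 8 | ms | Fetal mouse Q-to-R separation used when only RR is known; replaced by the measured per-beat $R - Q$ when a trace is available. |
| `min_rr_ms` | 120 | ms | Peak-separation floor, well under the shortest physiological fetal mouse RR (~150 ms). |
| `min_prominence` | 0.3 × Q99.9(\|amplitude\|) | signal units | Scale-free height threshold; see below. |
| `q_window_ms` | 20 | ms | Q search window; spans the narrow murine QRS. |

### Numerical choices

* **Mean of the decay curve.** $\overline{R(t)}$ is computed by
  trapezoidal integration of the sampled curve over one full period
  $[0, RR]$. The naive mean of the samples on $[0, RR)$ is a left Riemann
  sum whose $O(1/fs)$ bias (≈0.2 at $RR = 256$ ms, fs = 1000 Hz) is large
  enough to move $k$ visibly; the trapezoidal mean is $O(1/fs^2)$-accurate
  and converges to the closed-form period mean
  $v_0(1 - e^{-2\pi})/2\pi \approx 15.886$.
* **Band membership and ties.** The band inequalities are strict, as the
  model defines them; an even-sized in-band set takes the mean of the two
  central times. Because the sampled curve is strictly decreasing, the
  in-band times are consecutive grid points and the discrete median stays
  within one sample of the continuous band midpoint
  $\tfrac{RR}{4\pi}\left[\ln\frac{v_0}{k+1} + \ln\frac{v_0}{k-0.5}\right]$ —
  the closed-form oracle the test suite checks against across
  RR ∈ [200, 450] ms.
* **Degenerate inputs.** `sample_decay()` requires at least two samples
  per beat; an empty threshold band raises an error naming the band (it
  signals an RR far outside the model's range or a sampling rate too low
  to populate the band). Across RR ∈ [150, 600] ms at 1000 Hz the band is
  never empty.
* **First beat.** The first detected beat has no preceding R peak, hence
  no RR, and is dropped from the beat table.

### Peak detection

R peaks come from `pracma::findpeaks` (local maxima with a minimum height
and separation). The default height threshold is $0.3 \times$ the 99.9th
percentile of the absolute amplitude. A lower percentile (e.g. the 95th)
fails on exactly the signals this package targets: QRS spikes occupy a few
percent of samples at most, so mid-range percentiles sit at the noise
floor and admit spurious peaks in the gaps between beats. The 99.9th
percentile sits on the spike tops themselves, keeping the rule scale-free
(gain-invariant) while anchoring it to the feature of interest. Q troughs
are the amplitude minima in the 20 ms window before each R peak. Manual
vetting of detected peaks is replaced by `qc_report()` (beat count, RR
histogram, flagged beats); detection parameters remain overridable.

## Validation workflow

The ECG and Doppler systems are independently clocked; shared marker
pulses recorded on both give the constant offset as the mean of the
pairwise marker differences (`align_by_markers()`, which warns when the
residual SD exceeds 5 ms — a sign of mismatched markers). Each Doppler
aortic-closure event, mapped onto the ECG clock, is assigned to the beat
whose Q most recently precedes it, one-to-one; two events in one beat is
an error rather than a silent choice. Agreement between model QT and Q-Ac
is summarized by the difference percentage
$100\,(Q\text{-}Ac - QT)/Q\text{-}Ac$ (signed per beat; record summaries
report the mean absolute value, which is what makes per-fetus values
non-negative), Bland–Altman bias and limits of agreement
$\mathrm{bias} \pm 1.96\,\mathrm{SD}$ (sample SD, $n-1$; the standard
limits without small-sample variants), the percentage of differences
inside the limits, and the Pearson correlation.

## What the synthetic generator emulates — and what it does not

`sim_config()` / `simulate_recording()` emulate the validation study's
recording setup: truncated-normal RR trains (floor 150 ms, preventing
unphysiological beats) at the five observed per-fetus regimes
(`mouse_fetus_profiles()`: RR 264±28, 256±0.52, 273±4, 276±1.1, 390±86 ms;
69+10+111+48+71 = 309 beats), a stylized beat template (unit triangular R
spike, Q trough of depth 0.3 at $R - 8$ ms, low half-sine T hump), Gaussian
noise, Doppler aortic-closure events lagging the T end by 3 ± 2 ms on a
shifted clock, and marker pulses on both clocks. The default noise SD of
0.01 sits about 20 dB below the RMS of the rendered signal. The 3 ms lag
default reproduces the *direction* of the observed bias (model QT slightly
below Q-Ac); its true magnitude in fetal mice is unknown, so only the sign
is meaningful.

Two deliberate limitations define what passing tests do and do not show:

* **The rendered T hump ends exactly at the model-predicted T end.** This
  is circular by design: the generator validates the plumbing — detection,
  alignment, matching, statistics — not the physiological truth of the
  decay model, which only real co-registered Doppler data can validate.
* The waveforms are stylized: no maternal ECG contamination, no baseline
  wander, no Doppler velocity waveforms (aortic closure enters as a
  timestamp, as it does after manual reading of the Doppler trace), and
  noise is white Gaussian. Fiducial-recovery results on synthetic data
  are therefore an upper bound on real-data performance.

## Problem sizes and reproducibility

The test suite and the acceptance script run the synthetic study at its
natural size (5 fetuses, 309 beats, ~15 s of signal per fetus at 1000 Hz)
and fiducial recovery on 500-beat traces; both complete in seconds. All
simulation functions take an explicit seed and leave the caller's RNG
stream untouched; identical configurations are bit-identical, and every
simulated dataset is written with a JSON manifest carrying the full
configuration and seed needed to regenerate it.

## Known limitations

* The human-mode coefficient is carried over from the human variant of
  the model; it is provided as a species switch but has not been refit
  here against human data.
* No QTc (rate-corrected QT) formulas are included; the model's output is
  the uncorrected per-beat QT.
* Q-Ac validation assumes one aortic-closure timestamp per beat from an
  upstream reading step; Doppler image processing is out of scope.
* With very low sampling rates the band may contain no samples; the
  estimator refuses rather than extrapolates.
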