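---
title: "A two-stage cascade model of cerebrovascular regulation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage cascade model of cerebrovascular regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadeTFA)
```

## The model

Cerebral blood flow is buffered against arterial-pressure fluctuations at
two levels: the large cerebral arteries (dynamic cerebral autoregulation,
dCA) and the downstream cortical microcirculation. This package treats the
pressure-to-oxygenation pathway as a *series linear system*:

- stage 1, `H1(f)`: mean arterial pressure (MAP, mmHg) to cerebral blood
  flow velocity (CBFV, % of mean);
- stage 2, `H2(f)`: CBFV to a NIRS-derived oxyhaemoglobin index
  (O2Hb, % of mean);
- the total pathway, `H0(f)`: MAP to O2Hb, estimated directly.

Each transfer function is `H(f) = Sxy(f)/Sxx(f)` from Welch cross-spectral
estimates, summarised by gain `|H|`, phase `arg(H)` and magnitude-squared
coherence `|Sxy|^2/(Sxx Syy)`. For a true series system the cascade
combination

```
Gc = G1 G2,   Pc = wrap(P1 + P2),   Cc = C1 C2
```

must reproduce the directly estimated `G0, P0, C0`. The package's central
scientific claim is therefore testable *within* the data: estimate the two
stages and the total pathway from the same recording, combine the stages,
and compare. The coherence product relation is exact at the population
level when the disturbances entering at the flow and oxygenation stages
are mutually independent and the first-stage disturbance propagates
through stage 2 (shown analytically by factorising
`C0 = C1 C2` under those assumptions); it is a modelling approximation
otherwise.

The oxygenation signal is the spatially-resolved-spectroscopy
oxyhaemoglobin index `O2Hb_SRS(t) = TOI(t) x nTHI(t)`: TOI is the
oxygenated fraction of total haemoglobin and nTHI the relative total
haemoglobin, so by the volume-fraction principle their product tracks
oxyhaemoglobin content (arbitrary units).

### Assumptions

* **Linearity and open loop.** The cascade is a feed-forward LTI model.
  Nonlinear autoregulation and feedback from flow to pressure are outside
  the model; coherence is the per-band reliability gate for interpreting
  gain and phase.
* **CBFV as a flow surrogate.** Constant middle-cerebral-artery diameter
  is assumed, as in conventional dCA work.
* **Stationarity** over the analysed segment (5 min by default).

## Preprocessing

1. **Beats.** R-peaks come from supplied event times or from an
   amplitude-threshold ECG detector with a physiological R-R bound of
   0.3-2.0 s (30-200 bpm); out-of-bound intervals are rejected with a
   warning. Each channel is reduced to one value per cardiac cycle by the
   time-average over the R-R interval `[t_k, t_{k+1})` — the integral of
   the piecewise-linear interpolant divided by interval length, exact for
   constants and ramps and robust to unequal channel rates. The beat
   timestamp is the interval onset; any consistent convention shifts phase
   by less than one beat, and onset is the common choice in dCA practice.
2. **Oxygenation index.** `TOI x nTHI` is computed *at beat level* from
   the beat-averaged indices, matching the beat-to-beat analysis of all
   other channels. (Within a beat both indices are nearly constant, so
   beat-averaging before or after the product differs only at second
   order.)
3. **Normalisation.** CBFV and O2Hb become percent of their segment mean;
   MAP stays in mmHg, so stage-1 gain is %/mmHg and stage-2 gain %/%.
   (Some dCA work normalises pressure too; gain units in %/mmHg require
   keeping it absolute, which is the convention adopted here.)
4. **Uniform grid.** Linear interpolation to 2 Hz — ample for
   cerebrovascular dynamics below 0.5 Hz. Interior NaN gaps (e.g.
   finger-cuff recalibration) are bridged linearly beforehand.
5. **Detrend.** A third-order polynomial is subtracted after resampling;
   the residual has zero mean to numerical precision and the operation is
   idempotent.

## Spectral estimation

Welch's method with 256-point segments, 50% overlap and a periodic Hann
window; one-sided density scaling. At 2 Hz this gives the conventional
0.0078125 Hz bin spacing. No per-segment detrending is applied beyond the
global cubic detrend, and no adjacent-bin smoothing. The cross-spectrum is
`mean(Conj(X_k) Y_k)`, which makes phase positive when the output leads
the input — the expected sign of the autoregulatory phase lead. Phase is
reported wrapped to (-pi, pi] and never unwrapped; wrap handling is by
exclusion (below).

With a 5-min record at 2 Hz the segmentation yields **3** windows. The
widely used critical coherence 0.34 assumes **five** windows; the package
reports the actual `n_segments`, notes the mismatch whenever the default
threshold is used, and can recompute the threshold for any segmentation
(below). This inconsistency is surfaced deliberately rather than silently
reconciled.

## Band summaries and the phase-exclusion rule

Resting summaries are arithmetic means over the bins whose centres fall in
VLF 0.02-0.07, LF 0.07-0.20 and HF 0.20-0.35 Hz (left-closed, right-open;
DC is never included). For the repeated sit-stand manoeuvre (10 s sitting,
10 s standing — a 0.05 Hz forced oscillation that raises signal-to-noise),
the summary averages exactly the two bins flanking 0.05 Hz, 0.046875 and
0.0546875 Hz.

At the lowest resting frequencies the upstream phase lead approaches +pi
and can wrap to negative values. Bins below 0.10 Hz with negative
MAP-to-CBFV phase are therefore excluded from the phase means of the
upstream stage and of the cascade (whose phase inherits the same wrap);
gain and coherence means keep all bins, and the rule is inactive for
sit-stand data. The rule is keyed to the *upstream* phase because that is
where autoregulatory wrap occurs; the downstream stage lags and does not
wrap below 0.10 Hz. Band-mean phase is the arithmetic mean of wrapped
per-bin phases after exclusion (not a circular mean), matching standard
dCA practice.

## Critical coherence

Significance of coupling is a strict comparison of band-mean coherence
against a critical value (default 0.34). `coherence_critical_value()`
recomputes that limit by Monte Carlo: pairs of independent white Gaussian
noise series, sized to give exactly `n_segments` 50%-overlapping windows,
are run through the package's own Welch estimator, and the 95th percentile
of the *band-averaged* coherence (default: a six-bin band, the VLF width
on the standard grid) is returned. The band-mean statistic is the one the
threshold is applied to in practice, and it reproduces the conventional
published values (0.51, 0.41, 0.34, 0.29 for 3, 4, 5, 6 windows); the
per-bin 95th percentile is substantially higher (about 0.54 for five
windows) and is *not* what the conventional threshold describes.

```{r, eval = FALSE}
coherence_critical_value(n_segments = 5, n_sim = 10000, seed = 1)  # ~0.34
coherence_critical_value(n_segments = 3, n_sim = 10000, seed = 1)  # ~0.53
```

## Cohort validation

`compare_cascade_total()` correlates the cascade-derived and directly
estimated indices across subjects per metric, band and condition: Pearson
r with a Fisher-z 95% confidence interval (the standard parametric choice
when no method is otherwise specified), R-squared from the simple
least-squares regression (identically r^2), and a two-sided p-value.
Cascade combination happens on each subject's own spectra first;
summaries and correlations come after. Group-mean products (e.g.
multiplying group-mean stage gains) are illustrative only and generally
differ from the mean of per-subject products.

## The simulator

`simulate_subject()` generates recordings from a known ground truth so
every estimator can be validated end to end:

* **Drive.** At rest, band-limited 1/f-like pressure noise over
  0.01-0.40 Hz (SD 3 mmHg — giving VLF pressure spectral densities of the
  order observed in healthy adults); for sit-stand, a 0.05 Hz square wave
  (15 mmHg peak-to-trough, 1 s Gaussian-smoothed edges) plus residual
  noise.
* **Stage 1** is a first-order (optionally second-order) stable high-pass,
  `g1 B(i f/fc)/|B(i 0.05/fc)|` with `B(s) = s/(1+s)` and corner 0.07 Hz:
  positive low-frequency phase (`atan(fc/f)`, about +0.95 rad at 0.05 Hz)
  and mild gain rise with frequency, the qualitative dCA signature. The
  gain parameter `g1` (default 1.5 %/mmHg) is anchored at the 0.05 Hz
  reference frequency, where published group means are ~1.5-1.6 %/mmHg;
  no published parametric autoregulation model is implied — the pipeline
  treats the stage empirically and the tests only need a known truth with
  the right phase sign.
* **Stage 2** is a first-order low-pass (DC gain `g2` = 0.18 %/%, corner
  0.15 Hz) with a pure 1.5 s transport delay: strong attenuation
  (~0.17 %/% at 0.05 Hz) and negative phase
  (`-atan(f/fc) - 2 pi f tau`, about -0.79 rad at 0.05 Hz).
* **Noise structure.** The flow-stage disturbance is added to CBFV and
  *propagates through stage 2*; the oxygenation-stage disturbance is
  independent. This is exactly the structure under which the population
  identity `C0 = C1 C2` holds, making the coherence-product claim
  falsifiable by simulation.
* **Channels.** Signals are synthesised in the frequency domain on a
  500 Hz grid (so the stage responses are exact, not discretised filter
  approximations) and decimated to the recorded rates: pulsatile arterial
  pressure at 250 Hz and CBFV at 100 Hz (the cardiac pulse is a zero-mean
  function of beat phase, so beat averaging removes it exactly up to
  discretisation), NIRS at 5 Hz, ECG at 250 Hz. Beat times come from an
  integrate-and-fire heart-rate process around the condition mean (69 bpm
  rest / 83 bpm sit-stand). nTHI is 1 (rest) or 1.06 (sit-stand) plus a
  slow fluctuation of SD 0.02 — published nTHI group means are ~1.00-1.06
  with small SD — and TOI is the oxygenation target divided by nTHI, so
  the product carries the intended signal exactly.
* **Cohorts** jitter the stage gains by +/-20% (relative) and the delay by
  +/-0.3 s, uniformly, with per-subject seeds derived from one master
  seed.

### What the simulator does *not* emulate

Real recordings contain nonlinear and time-varying autoregulation,
CO2 and heart-rate coupling into CBFV, measurement artifacts beyond NaN
gaps, extracerebral NIRS contamination, and closed-loop pressure-flow
interactions. Passing the simulation-based tests therefore demonstrates
that the *estimation pipeline* is correct for the model class the cascade
assumes — not that human data satisfy that model.

## Numerical choices and verified properties

* **Problem sizes.** Identity and recovery properties are verified on
  5-min simulated records (the standard protocol length; 3 Welch
  windows) for the cascade identity, on a 40-subject noiseless cohort for
  the perfect-correlation check, on 100 replicates for the
  coherence-product identity, and on a 30-min noiseless record for
  stage-response recovery, where segment-averaging noise is comfortably
  below the 5%/0.05 rad acceptance bounds.
* **Cascade identity.** With no stage noise, per-bin cascade and total
  estimates agree within 2% gain and 0.02 rad on bins with coherence
  above 0.99, and cohort correlations for gain and phase at 0.05 Hz equal
  1 to within ~1e-8 — the residual is second-order spectral leakage (the
  algebraic identity `(Spv/Spp)(Svc/Svv) = Spc/Spp` is exact only when
  each windowed segment satisfies the stage relations exactly).
* **Leakage bias at the lowest bins.** With the steep 1/f resting drive,
  the Welch estimate of the rapidly varying high-pass stage is biased low
  by up to ~5% at the lowest VLF bin (0.023 Hz) regardless of record
  length — an intrinsic resolution effect of 128 s windows, worth
  remembering when interpreting VLF gain in real data. Stage-recovery
  accuracy is therefore verified with a spectrally flat drive, which
  isolates estimator fidelity from this input-spectrum effect.
* **Estimator conventions.** Periodic Hann window; one-sided density
  scaling `2/(fs sum(w^2))` with DC and Nyquist halved; invalid bins
  (zero input power) are flagged and excluded from summaries rather than
  propagated; an empty band summarises to NA, never 0.
* **Ties and boundaries.** Band membership is left-closed right-open on
  bin centres; the coupling test is strictly greater than the threshold;
  wrapped phases live in (-pi, pi] with the boundary mapped to +pi.
* **Determinism.** All randomness flows through explicit seeds
  (simulation, cohort jitter, Monte Carlo threshold); the RNG state of
  the calling session is saved and restored.

## Limitations

* The critical-coherence default (0.34) presumes five windows; 5-min
  records at 2 Hz give three. Both the mismatch message and
  `coherence_critical_value()` exist so users confront this explicitly.
* The phase-exclusion rule discards information rather than unwrapping;
  bands whose phase bins are all excluded return NA.
* Gain comparisons between the cascade and total pathway degrade above
  0.2 Hz in low-coherence data — expected from the coherence product and
  from low signal-to-noise, and visible in the simulator when stage noise
  is large.
* The beat-level `TOI x nTHI` product assumes both indices are
  approximately constant within a beat; violent intra-beat NIRS swings
  would break the factorisation (not the estimator).
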