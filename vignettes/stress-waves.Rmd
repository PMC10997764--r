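---
title: "Decoding plant stress from multiplexed H2O2 and salicylic-acid nanosensor waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding plant stress from multiplexed H2O2 and salicylic-acid nanosensor waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytowave)
```

## The problem

Plants answer very different insults — a cut, a bacterial infection, excess
light, heat — with the same fast chemical messenger: an apoplastic burst of
hydrogen peroxide that travels outward from the stressed tissue. Stress
identity is nevertheless recoverable, because the *shape* of the local
H2O2 waveform (its width, production and decay rates) and the *timing* of
the subsequent salicylic-acid (SA) response differ by stress. Multiplexed
near-infrared nanosensor imaging makes both signals observable in a living
leaf: an SA-selective SWNT sensor spot, an H2O2-selective spot, and an
inert reference spot are read out together under one laser, and the
reference channel cancels illumination and leaf-movement drift.

`phytowave` implements the computational side of such an experiment:

1. **calibration** — fitting and inverting the Langmuir binding model of a
   sensor, with a detection limit;
2. **imaging** — turning raw intensity stacks plus ROI masks into
   ratiometric quench series and pixel-wise concentration maps;
3. **wave_features** — FWHM, production/decay rates, onset times and wave
   velocities from concentration series and maps;
4. **kinetics** — simulation and fitting of the mass-action reaction
   network that generates stress-specific waveforms;
5. **synthetic_data** — a generator of ground-truth-known frame stacks for
   the four stress archetypes, so that every stage above is testable
   without raw sensor data (none is published).

The numbered scripts under `analysis/` run these stages end to end and
write their tables under `results/`.

## Sensor model

A sensor's fractional quench follows the Langmuir adsorption isotherm

$$ r(c) = \frac{r_{\max}\, c}{K_D + c}, $$

with $K_D$ the dissociation constant (concentration at half-maximal
response) and $r_{\max}$ the saturating quench fraction. Responses are
stored as signed fractions with quenching positive — one convention
everywhere, since mixed "% quenching" and "% turn-on" language invites sign
errors. Fitting uses bounded Levenberg–Marquardt least squares with ten
log-spaced $K_D$ starts ($K_D \in (10^{-3}, 10^5)$ µM,
$r_{\max} \in (10^{-3}, 1]$), because sparse titrations can place the
half-saturation point anywhere across decades. The limit of detection is
the concentration whose response equals three times a supplied noise SD,
computed analytically through the inverse curve; the noise SD is an
explicit input because the underlying raw spectra are unpublished (the
default SA value, 0.0186, is back-solved so that the fitted curve yields
the characterized ~4.4 µM limit).

Inversion is exact, $c = K_D r/(r_{\max}-r)$. Two edge policies matter in
pipelines: negative quench (reference-channel jitter) clips to 0 µM and is
counted, and saturated responses ($r \ge r_{\max}$) map to a reported
ceiling (default $10 K_D$) rather than erroring mid-run — both counts
surface in the run report.

## Reaction network

The kinetic model couples an autocatalytic H2O2 burst to delayed SA
release through a chain of intermediates, with a generic inhibitor branch:

* $A + P \xrightarrow{k} 2A$ — autocatalytic H2O2 ($A$) production from an
  RBOH-like precursor pool $P$;
* $A \xrightarrow{k_d} B$ — H2O2 degradation;
* $A + pF \xrightarrow{k_{F1}} F_1$, then
  $F_1 \to F_2 \to \cdots \to F_n \xrightarrow{k_s} S$ — H2O2 activates an
  SA-precursor pool, and SA emerges after an $n$-stage chain;
* $A + pI \xrightarrow{k_I} I$ and $I + pF \xrightarrow{k_r} xF_1$ — an
  inhibitor that deactivates the SA precursor (dead end $xF_1$).

Stress is an instantaneous seed $a_0$ of $A$ at $t_{stress}$ — the
simplest mechanism consistent with a wave that appears within minutes.
Secondary bursts (observed under high light and heat at 2 h and 1.5 h
post-stress) re-inject precursor ($p_2$ added to $P$ at $t_2$), with the
integration restarted at the discontinuity so no solver step straddles it.
Integration uses `deSolve::lsoda` at rtol 1e-8 / atol 1e-10.

Three stoichiometric conservation laws hold exactly and are audited on
every trajectory: H2O2 bookkeeping
($A + B + \sum F_i + S + I + xF_1 - (P_{\mathrm{injected}} - P) - a_0$),
the SA-precursor pool ($pF + \sum F_i + S + xF_1 = pF_0$) and the
inhibitor pool ($pI + I + xF_1 = pI_0$). The delay structure carries the
biology: more intermediates (at fixed total chain throughput) and more
inhibitor precursor both postpone SA onset, which is how a late,
post-wave SA response (infection) and an early, intra-wave response
(light, heat) coexist in one mechanism. $n$ defaults to 3 — a small
number, deliberately arbitrary — and is configurable 1–6.

Fitting minimizes a weighted sum of squares over the non-frozen
parameters, weights equal to the inverse squared series maxima so the
µM-scale disparity between H2O2 and SA does not let one channel dominate
(a series with zero maximum gets weight zero, which also handles the
wounding case of no SA at all). Free parameters are optimized in log
space by Levenberg–Marquardt from Latin-hypercube perturbations of the
initial guess (default 16 starts, factors in [0.5, 2]). Parameters whose
initial value is zero stay frozen — log space cannot leave zero, and a
zero rate is a structural statement, not a starting guess.

## Imaging pipeline

Per the acquisition protocol the pipeline emulates (30-s exposures), the
default frame interval is 0.5 min. For an H2O2 spot the intensity series
averages the 200 mask pixels with the largest total first-to-last quench,
selected once for the whole record so the series tracks one coherent,
maximally responding region; SA and reference spots use the plain ROI
mean. The ratiometric quench is

$$ r(t) = 1 - \frac{I_{act}(t) / \bar I_{act}^{pre}}{I_{ref}(t) / \bar I_{ref}^{pre}}, $$

which cancels any multiplicative factor shared by both spots exactly, and
is then smoothed with a centered 10-point moving average (shrinking
windows at the edges, so a constant series is preserved exactly).
Pixel-wise maps normalize each pixel to its own pre-stress mean and divide
by the reference ROI's scalar drift series — the reference spot is
spatially separate, so no per-pixel reference exists. The pre-stress
baseline is all frames before `t_stress`.

## Wave features

* **FWHM** — time between the two crossings of baseline + half the peak
  amplitude, linearly interpolated, crossing nearest the peak on each
  flank. Baseline is the pre-stress mean, making the statistic invariant
  to vertical scaling and offset.
* **Production / decay rates** — least-squares slopes over the 10–90%
  amplitude band of the rising and falling flanks (×60 to µM/h), not a
  pointwise maximum gradient, for robustness to frame noise. The falling
  flank ends at the first sample below the 10% level *or* where the
  series turns back up by more than 5% of the amplitude above its running
  minimum — the inter-burst dip. Without that stop, a slowly decaying
  wave followed by a secondary burst (the heat archetype sits almost
  exactly on the 10% level at the dip) would have its decay regression
  polluted by the second wave. Slow waves that never fall to 10% truncate
  at the record end.
* **Onset time** — first post-stress time above baseline mean +
  $k_{sd}\cdot$SD for 3 consecutive samples, relative to `t_stress`;
  `NA` when never (the wounding SA channel). Defaults: $k_{sd} = 3$ with
  an absolute SD floor of 0.05 µM applied as a minimum. Two departures
  from the obvious 1-SD rule, both forced by the smoothing: a 10-point
  moving average makes neighbouring samples strongly correlated, so a
  20-frame pre-stress baseline contains only ~2 independent noise values
  — it underestimates its own SD badly, and 1-SD sustained exceedance
  then fires on noise essentially always. The 3-sigma-with-floor rule is
  robust to this; the floor (~3× the pipeline's smoothed noise at the SA
  operating point) also gives noise-free synthetic truth, whose baseline
  SD is exactly zero, a meaningful threshold.
* **SA wave velocity** — stress-site distance over mean onset time,
  reported to 3 decimals in cm/min. The sensor-spot distance adopted is
  1.0 cm.
* **ROS front velocity** — pixels binned by distance from the stress site
  (default 0.05 cm bins); a bin arrives when its median concentration
  exceeds a threshold (default 25% of the spatial peak); velocity is the
  least-squares slope of distance against arrival time.

## Synthetic data: what it emulates, and what it does not

`make_fields()` builds ground-truth fields on a 128×128 grid (0.01
cm/pixel, 240 min at 0.5-min frames, stress at t = 10 min):

* **H2O2** — the network's $A(t)$ waveform time-shifted by
  distance/wave-speed: a constant-speed traveling wave with a fixed local
  waveform.
* **SA** — zero until a source onset time, then a two-dimensional
  Gaussian plume centered at the stress site with variance
  $\sigma_0^2 + 2D(t - t_{on})$ whose *total amount* follows the
  network's $S(t)$ (scaled by the source area $2\pi\sigma_0^2$). The
  plume conserves mass as it spreads — the center dilutes — which is what
  makes the spatial-integral audit in the test suite possible; a
  center-amplitude-follows-$S(t)$ variant would create mass from nothing
  as the plume widens.

`render_stack()` is the forward measurement model: sensor pixels emit
$I_{base}(1 - r(c))\,d(t) + \varepsilon$ with $I_{base}$ = 10,000 counts,
$d(t)$ a multiplicative drift shared by *all* spots including the
reference (sinusoid of period 60 min at the configured amplitude plus a
5% linear ramp — an engineering choice to exercise the ratiometric
contract, not a claim about real lasers), and $\varepsilon$ Gaussian with
SD 1% of $I_{base}$ by default. The reference spot responds to nothing.
Rendering is deterministic under the configured seed.

The H2O2 sensor's calibration constants are not published; rendering uses
a clearly labeled synthetic Langmuir placeholder ($K_D$ 100 µM,
$r_{\max}$ 0.8), and any curve of the same form can be substituted. The
SA curve is the characterized one ($K_D$ 32 µM, $r_{\max}$ 0.462).

**Presets.** The four stress archetypes are frozen parameter sets
(`inst/extdata/presets.json`, tuned once by deterministic optimization
against the characterized temporal signatures and not revisited): wounding — a
fast narrow wave (FWHM 17 min, rates 54/28 µM/h, front 0.19 cm/min) and
no SA; Xcc infection — a broad wave (FWHM ~31 min, 26/16.5 µM/h, 0.20
cm/min) with SA onset at 87 min, after the wave has decayed below
half-maximum; high light — a similar wave (front 0.08 cm/min) with early
SA onset (22.5 min) and a mild secondary burst at 2 h; high heat — fast
production with very slow decay (106/12 µM/h, front 1.20 cm/min),
intermediate SA onset (35.5 min), secondary burst at 1.5 h. Secondary
injections are sized so a visible but mild bump results (the light bump
is ~13% of the primary peak); an injection too small to outpace decay
would contradict the observed bursts. Ground-truth features are computed
from the noise-free fields *through the same 10-point smoother the
pipeline applies*, so that round-trip comparisons measure the effect of
noise rather than the smoother's systematic bias on narrow waves.

**Geometry.** The SA spot is centered exactly 1.0 cm from the stress
site — that distance enters the velocity ratio. The H2O2 spot sits at
0.29 cm so that even the slowest front (0.08 cm/min) reaches it within a
few minutes, preserving the relative-timing signatures at the measurement
site; its distance is not a calibrated quantity. Front-velocity tracking
uses an alternative elongated-band layout and faster frames (6-s frames
for the heat preset), because a 1.2 cm/min front crosses the imaged strip
in under a minute and arrival times must resolve across several distance
bins.

What the generator does *not* emulate: leaf texture and vasculature,
chlorophyll autofluorescence, sensor photobleaching, spatially varying
drift, reaction–diffusion coupling of the H2O2 wave (the local waveform
is imposed, not propagated), or biological replicate variability. Passing
round-trips therefore demonstrate the pipeline's correctness under its
own stated measurement model — not performance on real leaves.

## Fitting scope

The reaction network describes concentrations at the source; the
pipeline's SA spot series additionally reflects plume transport (it rises
and then fades as the plume dilutes past the spot). Kinetic fits are
therefore run against source-level series; when the model is fitted to
pipeline-extracted data to ask a structural question — does the secondary
injection improve the light-stress fit? — the SA channel is excluded via
the zero-weight rule and the comparison is made on the H2O2 channel,
where it is decisive (see `analysis/05_fit_model.R`).

## Numerical choices and degenerate inputs

* Solver tolerances rtol 1e-8 / atol 1e-10; conservation drift on preset
  trajectories is below 1e-12 µM.
* All-zero titration responses: explicit fit-failure ($r_{\max}$
  unidentifiable). Fewer than 4 titration points: input error.
* A flank that never crosses half-maximum raises an error naming the
  flank; fewer than 2 samples in a rate band suggests finer sampling.
* Onset with a zero-SD baseline uses the 0.05 µM floor (see above).
* FWHM flank crossings with multiple intersections take the crossing
  nearest the peak.
* Problem sizes in the shipped tests and acceptance script — 128×128
  stacks at 0.5-min frames, 100 randomized conservation draws, 20-seed
  recovery at 5% noise, RK4 oracle at 1 ms steps over 30 min — were
  chosen to exercise every code path at full default resolution while
  keeping a complete run in the minutes range on one CPU.

## Known limitations

* The SA plume is a single diffusing Gaussian; real SA fields show
  heterogeneous accumulation within the spot.
* The H2O2 wave speed is imposed rather than emerging from a
  reaction–diffusion mechanism, so speed and waveform are independent
  knobs here, which they are not in a living leaf.
* Fitted rate constants are effective, not molecularly identified; no
  attempt is made to match any particular laboratory's fitted constants
  numerically — only the waveform features the model must reproduce.
* Onset-detection conventions vary across laboratories (SD multiple,
  sustainment); the 3-sigma sustained rule here is a documented choice,
  and truth and pipeline use it consistently.
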