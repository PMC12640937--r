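---
title: "From patch-clamp sweeps and paced action potentials to drug potency and repolarization statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From patch-clamp sweeps and paced action potentials to drug potency and repolarization statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(patchpharm)
```

## The problem

Drug-induced block of the hERG potassium channel is the dominant cause of
QT prolongation and torsade de pointes, but the clinical consequence of a
given hERG potency depends on what the same drug does to the inward
currents that oppose repolarization: the L-type calcium current (I~CaL~)
and the late sodium current (I~NaL~). Cardiac safety profiling in the
CiPA spirit therefore needs three things measured consistently:

1. **Potency per channel** — concentration–inhibition curves from
   voltage-clamp recordings on overexpression cell lines, summarised by an
   IC~50~ and Hill coefficient per drug and current;
2. **Selectivity** — ratios of those IC~50~s (e.g. hERG-to-I~CaL~), which
   decide whether a "calcium blocker" is actually a multi-channel blocker
   at clinical exposure;
3. **Integrated effect** — what the drug does to the action potential of
   adult human ventricular tissue: APD~30/50/90~, triangulation
   (APD~90~ − APD~30~) and beat-to-beat short-term variability (STV).

`patchpharm` implements this chain end to end, together with a synthetic
data generator whose programmed ground truth lets every stage be verified
without access to raw laboratory records.

## Voltage-clamp model and current isolation

A `cell_recording` holds ordered sweeps under one `voltage_protocol`
(contiguous hold/step/ramp segments, junction-potential-corrected
voltages stored as commanded). The three standard protocols are built by
`build_standard_protocol()`: hERG (+40 mV for 500 ms, ramp to −80 mV at
−1.2 V/s, every 5 s, 5 kHz), I~CaL~ (0 mV for 40 ms, +30 mV for 200 ms,
ramp to −80 mV, every 5 s, 10 kHz) and I~NaL~ (−120 mV recovery step,
−15 mV for 40 ms, +40 mV for 200 ms, ramp to −95 mV at −1.35 V/s, every
10 s, 10 kHz). Each begins with a 100 ms baseline hold followed by the
hyperpolarizing monitoring step (−80→−90 mV; −95→−120 mV for I~NaL~). We
place the baseline hold *before* the monitoring step — rather than making
the step the first segment — because the input-resistance calculation
needs pre-step samples at the holding potential within the same sweep.

For the I~CaL~ protocol we follow the stated ramp endpoints (+30 → −80 mV
over 100 ms, i.e. −1.1 V/s); a −1.2 V/s figure sometimes quoted for this
ramp is inconsistent with those endpoints and matches the hERG ramp
instead.

The drug-sensitive component is isolated by one of two routes
(`isolation_method()`):

* **Reference-blocker subtraction** (hERG: 1 µM E-4031; I~NaL~: 300 µM
  tetracaine): the residual traces under a saturating blocker are averaged
  pointwise and subtracted from every sweep.
* **Passive subtraction** (I~CaL~): per sweep, the resting input
  resistance is computed from the monitoring-step deflection and Ohm's
  law, and `I_passive(t) = I_hold + (V(t) − V_hold)/R_in` is subtracted.
  Referencing the leak to the holding condition makes the correction
  vanish at rest, which is the only anchoring consistent with using the
  holding current as a health indicator.

Amplitudes are then measured in an explicit `measurement_window`. The
defaults name the regions where drug effects are quantified: the peak
outward tail on the hERG ramp, the peak inward current during the I~CaL~
0 mV step, and the mean inward current over the middle 50% of the I~NaL~
ramp. Whether "peak" or "mean" is the right statistic inside the ramp
region is not uniquely determined by practice; both are supported and the
choice is part of the logged run configuration. Peak measurements are
taken on a 1 ms moving-average of the trace so that the extremum reflects
the current rather than single-sample noise — the analogue of the 2.2–3
kHz hardware filtering applied at acquisition; because the smoothing
distorts the template proportionally in control and drug epochs, it
cancels exactly in the inhibition ratio.

### Stability gating instead of rundown correction

Whole-cell currents run down independently of drug. The package does not
detrend; like the operator practice it replaces, it *gates*: an epoch
enters the analysis only if the least-squares slope of its relative
amplitude over the trailing 20 sweeps is within ±1 %/min
(`assess_stability()`). Two numerical choices matter here:

* **Window length.** With realistic recording noise (2% of the control
  amplitude) the slope estimator over 6 sweeps (30 s) has a sampling SD
  near 0.5 %/min — random flagging would dominate the gate. Twenty sweeps
  (100 s at the 5 s inter-sweep interval) bring the SD to roughly
  0.3 %/min, well under the 1 %/min tolerance, and 100 s is still a
  realistic judgement window for an operator watching an amplitude trend.
* **Reference amplitude.** For drug epochs the slope is normalised to the
  *control* amplitude rather than the epoch's own mean. A strongly
  blocked current has a near-zero mean, and normalising to it would
  reject precisely the concentrations with the largest effects for purely
  arithmetic reasons; normalising to control measures drift in the same
  units as the inhibition error it would induce.

Fractional inhibition is `1 − mean(last 10 drug amplitudes)/mean(last 10
control amplitudes)`. Negative values (current growth) are retained so the
fit sees what the cells produced; constraint to [0, 1] happens only
through the Hill model's fixed asymptotes.

## The Hill fit

Pooled per-cell points (never concentration means) are fit with

$$f(c) = \frac{1}{1 + (\mathrm{IC}_{50}/c)^{n_H}},$$

minimum and maximum fixed at 0 and 1. `fit_hill()` minimises the SSE over
$(\log_{10}\mathrm{IC}_{50}, \log n_H)$ — log parameterisation for
conditioning and positivity — from a fixed multi-start grid (25 log-spaced
IC~50~ values spanning the concentration range ±2 decades × slopes
{0.5, 1, 2, 4}), refining the three best grid points with Nelder–Mead and
breaking ties by lowest SSE then lowest $n_H$. The procedure is
deterministic given the data. Data sets with fewer than two distinct
concentrations, or with inhibition uniformly near 0 or 1, are rejected as
unidentifiable rather than fit.

```{r}
spec <- voltage_clamp_sim_spec(true_ic50 = 1, true_n_h = 1,
                               fraction_sd = 0.05, seed = 1)
pts <- simulate_concentration_response(spec)
fit <- hill_ci(fit_hill(pts), method = "bootstrap", seed = 1)
fit
```

**Confidence intervals.** The default is a nonparametric bootstrap over
*cells* — cells, not points, are the independent units, and a cell exposed
to two concentrations contributes both its points to each resample —
with percentile intervals from 1000 refits started at the full-data
solution. The alternative is an asymptotic Wald interval on the log scales
from the residual Jacobian. For the repeated-sampling coverage experiment
(500 simulated designs of 5 concentrations × 5 cells, noise SD 0.05) we
use the Wald interval: it is the method whose coverage can be measured at
that replication depth in reasonable time, and on well-behaved data the
two intervals agree (a unit test checks they overlap). Observed coverage
sits near 93–94%, inside the 90–98% band expected for an asymptotic
interval at this sample size.

Selectivity ratios (`selectivity_ratio()`) normalise units (nM/µM/mM)
before dividing and carry an explicit rounding convention; published
ratios are quoted variously to the nearest integer or one decimal, and
half-up rounding reproduces them to within one integer in the worst case
(2651.5 → 2652 vs a printed "∼2,651").

## AP features

`detect_beats()` segments a paced train at its stimulus times. Per beat:
resting potential = mean over the 20 ms before the stimulus; capture
requires a depolarization ≥40 mV above rest within 50 ms of the stimulus;
AP onset is the upstroke crossing of 10% of the amplitude above rest
(interpolated) — a definition tied to the membrane response rather than
the stimulus artifact; APD~x~ is the time from onset to the first
interpolated downward crossing of `peak − x% × amplitude`. Taking the
*first* crossing makes the measurement well-defined when a plateau hump
re-crosses the level; such re-depolarizations are reported as a flag
(`repolarization_flag`), not as an APD change. Amplitude is peak minus
rest (not peak minus 0 mV).

STV is computed from exactly 30 successive APD~90~ differences (31
beats): $\mathrm{STV} = \sum |\mathrm{APD90}_{n+1} -
\mathrm{APD90}_n|/(30\sqrt{2})$. At 2 Hz a 30-beat window spans 15 s
rather than 30 s; the 30-difference convention is the one consistent with
the fixed $30\sqrt2$ divisor, so it is the default at both rates (the
window length is a parameter for anyone wanting the literal 30 s at
2 Hz). Under i.i.d. Gaussian jitter of SD $\sigma$ the statistic has mean
$\sigma\sqrt{2/\pi}$, which the tests verify by Monte Carlo.

Percent changes versus the vehicle epoch are signed; classification
against the per-parameter, per-rate thresholds (APD~30~ 12.0/12.1%,
APD~50~ 9.1/9.7%, APD~90~ 6.9/7.5%, triangulation 9.0/10.2%, STV
102.6/164.3% at 1/2 Hz, shipped as a versioned JSON resource) uses the
absolute value. Tissue QC keeps a trabecula only when its baseline
APD~90~ lies in [200, 450] ms and no metadata exclusion (perfusion
interruption, unstable baseline, inadequate exposure) applies.

## What the generator emulates — and what it does not

`simulate_voltage_clamp_cell()` composes, per sweep at wall time $t$:

* a fixed unit-amplitude current template per protocol (tail bump on the
  hERG ramp, inward transient at the I~CaL~ 0 mV step, sustained inward
  ramp current for I~NaL~) whose window statistic is exactly ±1, so the
  programmed amplitude is the recoverable truth;
* rundown = fast exponential phase (default 10% of amplitude, τ = 0.5
  min) × constant slow rate (0.4 %/min) — a minimal rendering of the
  multi-phase rundown seen in whole-cell recordings;
* Hill-governed block washing in exponentially (τ = 0.3 min) to
  steady state;
* ohmic leak from the programmed input resistance (150 MΩ) and holding
  current, plus i.i.d. Gaussian noise (default 1%, stress-tested at 2% of
  the 800 pA control amplitude).

Epoch lengths mirror recording-until-stable practice: 40 control sweeps
(3.3 min, enough for the fast rundown phase to decay below the gate), 36
drug sweeps (3 min, ≈10 wash-in time constants before the last 10
traces), 5 reference-blocker sweeps. The AP generator builds each beat
from rest through a 1.5 ms raised-cosine upstroke and a monotone cubic
(Fritsch–Carlson) repolarization passing exactly through the three
programmed percent-repolarization anchors, so feature extraction recovers
the programmed APDs to within a sample. Baseline morphology (rest −85
mV, peak +35 mV, APD~30/50/90~ = 200/260/320 ms, jitter SD 1.25 ms ≈
baseline STV 1 ms) is typical of paced human trabeculae and passes the QC
bounds. Drug modes apply percent effects to the anchors:

| mode | APD~30~ | APD~50~ | APD~90~ | pattern |
|---|---|---|---|---|
| `herg_block` | +8% | +20% | +35% | late prolongation → triangulation ↑ |
| `ical_selective` | −8% | −8% | −8% | uniform shortening → triangulation flag silent |
| `mixed_block` | −30% | −20% | −10% | early shortening → triangulation ↑ |
| `inal_block` | −5% | −8% | −12% | late shortening, −5% amplitude |

The `ical_selective` magnitude is −8% by construction: equal-percent
shortening moves triangulation by the same percent, and the selective
calcium-blocker signature being emulated is "APDs shorten while the
triangulation change stays inside its 9% threshold", which bounds the
uniform effect below 9%.

Deliberately **not** modelled: biophysical (Hodgkin–Huxley / O'Hara-type)
AP dynamics, frequency- and state-dependent block, capacitance
transients, series-resistance artifacts, autocorrelated or alternans-like
APD noise, EADs beyond the re-crossing flag, and temperature effects.
Passing tests therefore demonstrate that the *analysis chain* is correct
and unbiased under the stated noise model — not that real cells satisfy
that model. In particular, drug-application durations in real experiments
are adaptive and rundown need not be exponential; the gate, not the
generator, is what protects the inhibition estimate against those.

## Problem sizes and numerical choices

The replicated experiments run at fixed sizes chosen to estimate each
quantity to usefully better precision than the band it is checked
against: 200 replicate designs for IC~50~ recovery bias, 500 for CI
coverage (binomial SE ≈ 1.1% at 93%), 10⁴ windows for the STV Monte
Carlo (SE ≈ 0.2%), and 9–15 simulated cells for the end-to-end
fractional-block recovery. Crossings and onsets are linearly
interpolated between samples; ties in the multi-start fit break toward
the shallower Hill slope; bootstrap resamples that lose identifiability
are dropped and the bootstrap is declared degenerate if they exceed 20%.
All randomness flows through explicit seeds — the generators restore the
caller's RNG state.

## Known limitations

* Nominal, not analytical, drug concentrations: potency errors from
  compound loss or insolubility propagate directly into IC~50~s.
* The Hill model assumes complete block at saturation (Emax = 1); partial
  blockers need a different upper asymptote and are out of scope.
* The stability gate controls, but does not remove, rundown bias: a slow
  rundown inside tolerance still inflates inhibition slightly (≲0.015 at
  the default 0.4 %/min over the 1.8 min between the averaged control and
  drug windows).
* STV's closed-form check relies on i.i.d. jitter; real beat-to-beat
  series are autocorrelated and the statistic's sampling distribution
  there is not characterised here.
* The CSV recording dialect is the only on-disk format; vendor binary
  formats (ABF) are out of scope.
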