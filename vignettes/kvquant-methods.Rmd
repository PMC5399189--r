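---
title: "Methods: quantifying Kv2.1-dependent excitability phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Kv2.1-dependent excitability phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvquant)
```

kvquant packages the complete quantification chain used to characterize a
hyperexcitability phenotype in cultured hippocampal neurons in which loss of
somatic delayed-rectifier (Kv2.1) conductance, oxidative stress and channel
clustering are measured jointly: whole-cell voltage-clamp I--V analysis,
spontaneous calcium-spike detection, hydroethidine (HEt) ROS quantification,
immunofluorescence cluster quantification, and the group statistics that
compare strains (non-transgenic vs. a triple-transgenic AD model) and
treatments (Kv2.1 block by guangxitoxin, antioxidants). Because primary
recordings of this kind are rarely deposited, every analysis stage is paired
with a seeded generator that produces the corresponding modality with known
ground truth, so the whole chain is testable end to end.

## Voltage-clamp model and I--V analysis

The synthetic cell is a single-compartment membrane under ideal voltage
clamp. Each sweep of the step protocol (holding $-60$ mV; 1 s test pulses
$-100..+60$ mV in 10 mV increments; 500 ms tail at $-30$ mV; 25 µs/point
sampling by default) is the sum of

* a delayed-rectifier current $I_K = g_{max}\,B(V)\,(1-e^{-t/\tau})\,(V-E_K)$
  with Boltzmann gate $B(V) = 1/(1+e^{-(V-V_{1/2})/k})$ and a single,
  voltage-independent activation time constant $\tau$ (default 20 ms). A
  first-order gate is the simplest kinetic scheme consistent with the slow,
  non-inactivating activation of Kv2.1 over 1 s pulses; inactivation is
  deliberately omitted.
* an ohmic leak $g_{leak}(V-E_{leak})$,
* a capacitive transient at every voltage transition whose *sampled* values
  are bin averages of the continuous exponential, so that the discrete sum
  equals the transient charge $C_m\,\Delta V$ exactly at any sampling rate
  (this is what an integrating digitizer records, and it is what makes
  charge-based capacitance estimation exact on synthetic data),
* additive Gaussian current noise (default SD 20 pA).

Defaults are calibrated so the non-transgenic scenario produces a $+60$ mV
steady-state current of $\approx 3.1$ nA at $C_m \approx 60$ pF
($\approx 51$ pA/pF): $V_{1/2} = 8$ mV and $k = 12$ mV are typical somatic
delayed-rectifier values, and $g_{max}$ is back-computed from the target
peak current via $g_{max} = I_{60}/(B(60)(60-E_K))$.

**Leak subtraction.** Linear leak and capacitive components are cancelled by
the P/N method: the averaged response to $N = 4$ sub-pulses, scaled to the
test-step amplitude, is subtracted from each sweep. The generator emits
*hyperpolarizing* sub-pulses (amplitude $-|\Delta V|/N$ from holding,
whole waveform scaled) rather than same-polarity ones: a same-polarity P/4
sub-pulse for a $+60$ mV step reaches $-30$ mV, where the gate is already
$\approx 4\%$ open, which contaminates the scaled leak template by up to
13% of the test current and biases the fitted slope $k$ by $\approx 0.75$
mV. Hyperpolarizing sub-pulses keep the gate shut for every test polarity;
the only remaining systematic error is the $\sim$pA gate current at
$-70\ldots-62$ mV sub-pulses, visible in the chord conductance near $E_K$.
When no sub-sweeps are stored, a fallback fits a line to the steady-state
currents at $\le -70$ mV (where the delayed rectifier is shut) and subtracts
the fitted ohmic leak; applying the fallback twice is a no-op within noise.

**Steady state, density, conductance.** Steady-state current is the mean
over exactly the last 500 ms of the test pulse (last sample inclusive).
Density is $I_{ss} \cdot 1000 / C_m$ (pA/pF). Chord conductance is
$g = I_{ss}/(V-E_K)$ with $E_K = -79.4$ mV for the standard 5/117 mM
solutions at the 58 mV/decade slope; the activation curve is normalized by
the maximum chord conductance over $V \ge 0$ mV, so the fitted $G_{max}$
should come out $\approx 1$ (a useful sanity check). Chord conductance is
intrinsically ill-conditioned within a few mV of $E_K$ — picoamp residuals
are divided by a sub-mV denominator — so shape checks and normalization use
depolarized potentials. Normalization is per cell, before any averaging
across cells.

**Boltzmann fit.** $G(V) = G_{max}/(1+e^{-(V-V_{1/2})/k})$ is fitted by
Levenberg–Marquardt from a coarse multi-start grid over $(V_{1/2}, k)$
(every combination of $V_{1/2} \in \{-40,\ldots,40\}$ mV and
$k \in \{5,10,15,25\}$ mV), keeping the best converged solution; $k$ is
bounded positive. On noiseless model data the parameters are recovered to
four decimals; with 20 pA sweep noise the end-to-end median absolute error
of both $V_{1/2}$ and $k$ stays below 1 mV.

## Calcium-spike detection

Somatic Fluo-4 traces are simulated as a drifting baseline plus transients
from a homogeneous Poisson process. Each transient rises linearly over
0.2 s and decays exponentially with $\tau = 1.5$ s — values chosen so that
events remain resolvable at the routine 1 s frame interval — with amplitude
drawn from a normal distribution in percent of the local baseline,
truncated below at the 25% detection threshold. The truncation point
matters: reported spike rates and amplitudes are *detected-event*
statistics (the detection rule guarantees every counted event exceeded
25%), so a generator preset of "6.312 min$^{-1}$ at 85.71%" describes a
population that is detectable by that same rule; drawing amplitudes below
threshold would build in events the measurement could never count.
Scenario presets use the reported group means (non-transgenic
1.958 min$^{-1}$ at 131.4%, transgenic 6.312 min$^{-1}$ at 85.71%, etc.;
amplitude SD 40%, the package's choice as the per-event spread is not
reported).

Detection follows the percent-of-baseline convention: a rolling lower
10th-percentile baseline over 30 s (edge-padded; the estimator is the
package's choice, as the original procedure normalizes to baseline without
defining it), normalization to $\Delta F/F_0 \times 100$, and peak counting
with three rules:

1. amplitude above 25% of baseline (the detection threshold of the original
   procedure, applied to peak amplitude; a bout-based alternative can be
   emulated by raising `min_separation_s`),
2. local maxima closer than two frames are merged to the larger peak,
3. a counted peak must have topographic prominence of at least half the
   threshold, which rejects noise ripples riding on sustained suprathreshold
   activity at high event rates.

Raw frequency is `n_spikes / duration` in min$^{-1}$. The group-level rate
estimator corrects this count for two well-characterized losses of the
sampled measurement:

* **Threshold attenuation.** A transient's peak *sample* reads
  $A e^{-\max(0, u - t_{rise})/\tau}$ with sampling phase $u \sim U(0,
  \Delta t)$, so events with amplitude near threshold are caught only when
  a frame lands early on the decay. Each detected event is therefore
  weighted by the inverse of its detection probability
  $\pi(A) = \min\!\big(1, (t_{rise} + \tau \ln(A/\text{thr}))/\Delta
  t\big)$ (Horvitz–Thompson weighting, amplitudes de-attenuated by the
  mean phase factor, weights capped at 5). The weights are exactly 1 for
  amplitudes above $\sim$1.7× threshold, so typical cohorts are
  unaffected.
* **Pile-up.** A ~1.5 s transient sampled at 1 s cannot resolve events
  closer than the merge window: for a Poisson process with paralyzable
  dead time $\tau_d$ the observed rate is $r_{obs} = r e^{-r\tau_d}$. The
  dead time follows from the detector's geometry — peaks are quantized to
  frames, so the merge half-window blocks separations up to
  (half-window + ½) frames — and the estimator inverts this relation on
  the mean weighted frequency (correcting per ROI and then averaging would
  bias upward by Jensen's inequality; the SEM is propagated by the delta
  method).

With both corrections, cohorts of 300 ROIs
recover generator rates of 2–13 min$^{-1}$ within sampling error at the
framing appropriate to the rate (1 s routinely; 0.5 s for toxin-challenge
rates, as in the original fast-acquisition protocol). Fifteen events per
minute at 1 s framing is beyond what any peak counter can resolve with
these kinetics; the package does not attempt it, and the recovery tests use
the fast framing for such rates.

The optional first-minute activity screen (keep ROIs with at least one
spike in the first 60 s) mirrors the session-selection rule of the original
experiments; it is off by default because it biases rate estimates upward
at low rates.

## ROS (HEt) quantification

HEt oxidation is irreversible, so even resting neurons show a rising
signal. The generator produces a piecewise-linear cumulative expectation
(basal slope, stimulus slope during the challenge window, basal slope
again) plus Gaussian noise, with optional shared lognormal cell-to-cell
scaling of both slopes (CV 0.6 in the scenario presets, matching the
reported spread). The stimulus-evoked quantity is the trapezoidal integral
of fluorescence above the *extrapolated pre-stimulus linear trend* over the
stimulus window; for a noiseless extra slope $s$ over duration $T$ this is
exactly $sT^2/2$, which pins the scenario slopes to the reported AUC values
($s = 2\,\mathrm{AUC}/T^2$ for the 5-min challenge). A mean-baseline mode
is kept for signals that genuinely do not accumulate at rest.

Trend extrapolation dominates the estimator's variance: the fitted slope
error is amplified by $\sim T^2/2$. With a 3-minute pre-stimulus baseline
(the default; a 1-minute baseline would make estimator noise several times
the biological spread) the per-ROI AUC SD lands near the reported
between-neuron spread. Resting ROS is summarized separately as the mean
pre-stimulus fluorescence per ROI.

## Clusterization index

The generator draws a centered soma disk (structural channel) and places
disk-shaped clusters uniformly inside it, union-merged, until the covered
fraction of the soma *first reaches* the target, so the realized fraction
(reported in the metadata, and by construction identical to the
mask-derived fraction) overshoots by at most one cluster. Radii vary ±40%
around a 3 px mean in a 192×192 image with a 64 px soma.

Quantification thresholds the puncta channel by Otsu's criterion restricted
to somatic pixels (plus an exposed offset for sensitivity analysis), drops
objects below 4 px (shot-noise guard), and reports
$100 \cdot \text{cluster area} / \text{soma area}$ — the percentage of
somatic membrane occupied by channel clusters. The soma mask comes either
from the structural channel (Otsu, largest component, hole filling) or is
supplied directly, mirroring manually drawn somatic regions. The index is
invariant under intensity rescaling of either channel, bounded in
$[0, 100]$, and monotone under cluster addition. Analysis is single-plane
2D throughout. Mean recovery bias stays below 2 percentage points across
target fractions 10–40% at channel noise up to 10% of the puncta amplitude.

## Group statistics

Two-group comparisons use the unpaired two-sided pooled-variance t test or
the Mann–Whitney test (the latter is the convention for the index data);
multi-group designs use one-way ANOVA with all-pairs Bonferroni adjustment
$p_{adj} = \min(1, m\,p)$. SEM is SD/$\sqrt{n}$ with $n$ = ROIs or cells.

I–V families are compared by a two-way ANOVA (group × voltage). Because
each cell contributes its whole curve through a single conductance scale,
treating cell × voltage points as independent replicates would be
pseudoreplication and rejects true nulls far above the nominal level; the
group effect is therefore tested in the between-cell error stratum
(`aov(y ~ group*voltage + Error(cell))`), with per-voltage Welch-t
contrasts (Bonferroni) providing the familiar per-voltage stars. A Friedman
test over the voltage-blocked group mean curves is available as the
non-parametric alternative; the ANOVA is the default. With a single shared
voltage the design degenerates exactly to the unpaired comparison.

## Pipeline and its validation scale

`run_pipeline(list(preset = "study"), seed)` generates all study conditions
and reports eleven comparisons. The qualitative direction set that defines
phenotype reproduction — transgenic spike frequency ↑, amplitude ↓, current
density ↓, evoked and resting ROS ↑, clusterization ↑; Kv2.1 block on
non-transgenic cells: frequency ↑, density ↓; Kv2.1 block on transgenic
cells: density unchanged (p > 0.05); antioxidant on transgenic cells:
frequency ↓ — is tracked by `directions_ok`. Directions are read from the
sign of the mean difference; "unchanged" is operationalized as
non-significance at $\alpha = 0.05$, which carries an irreducible ~5%
per-run false-alarm rate under the null. The +60 mV peak-current
comparison is reported alongside but not part of the direction set: at the
study's own group sizes (10 vs 17 cells, between-cell CV ≈ 0.35 as implied
by the reported SEMs) its sign flips in ~2% of cohorts.

Default pipeline sizes are chosen as the smallest that keep every
direction decision far from its noise floor: 60 calcium ROIs per group
(40 for the fast-framing toxin conditions), the study's own cell counts for
electrophysiology (10/17/6/5), 108/145 ROS ROIs, 36/26 images, and 0.5
ms/point simulated sampling (the steady-state window statistics are
insensitive to sampling once the window holds hundreds of points). Unit
and acceptance tests use the same or smaller sizes so the full suite runs
in minutes on one core.

## What the generators do and do not emulate

The generators reproduce the statistical structure the analyses assume:
Poisson event timing, percent-of-baseline amplitudes, cumulative dye
oxidation, linear leak, first-order gating, hard-disk puncta. They do not
emulate photobleaching, movement artifacts, series-resistance error,
A-type current contamination, dye saturation, cluster intensity gradients,
or astrocytic K⁺ buffering. Passing recovery tests therefore demonstrates
correctness of the estimators under the stated model, not robustness to
every artifact of real recordings; the analysis functions are nevertheless
applicable to real CSV/TIFF inputs through the same entry points.

## Numerical choices and degenerate inputs

Multi-start bounds keep $k \ge 10^{-3}$ mV; non-convergence from every
start returns the best attempt flagged `converged = FALSE`. Chord
conductance points at $V = E_K$ are excluded with a warning. A baseline
window longer than the trace falls back to a global percentile. Zero-spike
ROIs carry an `NA` mean amplitude and are skipped in group amplitude
means. Zero-variance inputs to the t test raise a degenerate-input error.
The dead-time inversion caps at the maximum resolvable rate $1/\tau_d$.
All randomness flows from one integer seed through labelled substreams
(`substream_seed`), so any single ROI, sweep or image can be regenerated
in isolation and two runs with the same seed produce byte-identical
reports.
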