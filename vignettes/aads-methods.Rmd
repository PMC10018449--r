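---
title: "Modelling absorbance-activated droplet sorting: signals, triggers and junction outcomes"
author: "aads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling absorbance-activated droplet sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aads)
```

## The system being modelled

In absorbance-activated droplet sorting (AADS), water-in-fluorinated-oil
droplets carrying a chromogenic enzyme assay stream past a pair of optical
fibers. An LED (455 nm for tartrazine or reduced WST-1) illuminates the
channel; a photodetector converts transmitted light to voltage. Each droplet
produces a dip in the voltage trace whose depth encodes its absorbance, and a
controller decides in real time whether to fire a dielectrophoretic electrode
pulse that deflects the droplet into a positive collection outlet against a
bias-oil barrier. At kilohertz droplet rates, every stage of this chain —
optics, signal processing, trigger timing, junction physics — contributes its
own failure modes. This package provides a desk-scale, fully synthetic model
of the chain so that detection algorithms and gating strategies can be
developed, stress-tested and evaluated against known ground truth before
touching hardware.

The package has five layers, each usable on its own:

* `optics.R` — closed-form relations: mixture refractive index, droplet
  geometry, Beer–Lambert absorbance, voltage transduction.
* `simulate_trace()` — synthetic photodetector traces with a ground-truth
  event log.
* `detect_events()` / `stream_detector()` — constant-memory streaming peak
  detection.
* `decide()` / `schedule_pulses()` / `run_sorter()` — the causal trigger
  engine.
* `resolve_outcome()` / `run_mock_screen()` — the stochastic junction model
  and screen-level evaluation statistics.

## Optical model

Voltage transduction is log-linear: a droplet of absorbance $A$ produces a
minimum voltage

$$V_{\min} = \min\!\left(V_0 \, 10^{-A},\; V_{sat}\right),$$

where $V_0$ is the oil-only baseline and $V_{sat}$ the photodetector ceiling.
This choice makes voltage space and absorbance space exactly interconvertible
below saturation: `peak_absorbance()` is the exact inverse of
`transmitted_voltage()`, and the round trip is tested to $10^{-9}$.
Saturation is treated as clipping, never as an error — information loss at
the ceiling is a physical fact of the instrument and is surfaced through the
detector's `saturated` flag instead.

Absorbance follows Beer–Lambert, $A = \varepsilon c \ell$, with the path
length $\ell$ equal to the droplet's spherical diameter
$d = (6V/\pi)^{1/3}$ capped at the channel depth (a droplet as large as the
channel travels as a plug; an uncapped diameter would overestimate the
path). All volumes are picolitres and lengths micrometres internally; the
single conversion to centimetres lives inside `absorbance()`.

No extinction coefficient for the model dye at 455 nm is assumed from
literature; the default $\varepsilon = 38\,000\ \mathrm{L\,mol^{-1}cm^{-1}}$
is chosen once so that the canonical strong population (5 mM in a 75 pL
droplet, $\ell \approx 52\ \mu m$) reads close to 1 AU, which puts both
canonical populations comfortably inside the quantitative range of the
transduction. It is an exposed population parameter, not a constant.

## Refractive-index matching and the shoulder model

The most distinctive artifact of droplet absorbance traces is the pair of
*shoulders* — voltage excursions above baseline at each droplet edge, caused
by refraction at the curved water–oil interface. Blending the carrier oil
(HFE-7500, $n_D = 1.29$) with a high-index additive
(1,3-bis(trifluoromethyl)-5-bromobenzene, $n_D = 1.427$) raises the oil
index toward the aqueous phase and suppresses the shoulders.

Two modelling choices here were genuinely open:

* **Mixing rule.** Only a monotone trend of trace shape with additive
  fraction is empirically established. We use the linear volumetric
  (Arago–Biot) rule $n = (1-\phi)n_{base} + \phi n_{add}$ — the simplest
  monotone rule, exact at both endpoints, and trivially invertible
  (`match_fraction()`). It is documented as replaceable; nothing downstream
  depends on its specific curvature.
* **Shoulder amplitude.** We model the shoulder peak as
  $s = k\,(n_{aq} - n_{mix})^2\,V_0$ — *quadratic* in the index mismatch, as
  for Fresnel reflectance at a weak-contrast interface
  ($R \approx (\Delta n / 2n)^2$). A quadratic law is the natural
  small-contrast limit for any interface-scattering mechanism, vanishes
  smoothly at the match point, and — unlike an amplitude linear in
  $|\Delta n|$ — reproduces the qualitative progression seen in practice:
  saturation-clipped shoulders in plain oil, prominent shoulders up to
  ~27.5% additive, and no discernible edge structure from ~30% additive
  onward, all with a single gain constant ($k = 300$ V per squared index
  unit by default).

The aqueous phase of a real screen is not pure water: buffer, substrate and
cell lysate raise its refractive index. The default $n_{aq} = 1.337$ is
representative of such assay mixes and places the exact match point at
$\phi^\star = `r round(match_fraction(1.337), 3)`$ — inside the empirically
favoured 30–35% additive window, and close to the 35% working concentration
commonly chosen. Matching pure water ($n_D = 1.333$) instead requires
$\phi = `r round(match_fraction(1.333), 4)`$, also inside that window. At the
default 35% additive the residual mismatch contributes a shoulder of
$\sim 0.3$ mV — far below the noise floor, i.e. operationally shoulder-free.

## Trace synthesis

`simulate_trace()` places $\lfloor T f \rfloor$ droplets at period $1/f$
(optional Gaussian timing jitter, clamped so transit windows never overlap,
keeping the truth log disjoint and ordered). Each droplet contributes a
waveform over its transit window:

* a **flat-bottomed dip** with raised-cosine ramps over the outer 30% of the
  transit. The flat bottom (the droplet center filling the fiber's
  acceptance cone) guarantees that the sampled minimum equals the
  Beer–Lambert prediction exactly in the noise-free case — an invariant the
  tests check to $10^{-12}$ — rather than depending on where samples happen
  to fall on a rounded vertex;
* **shoulder lobes** (raised cosine) over the outer 15% of the transit at
  each edge, with the quadratic amplitude above;
* additive i.i.d. Gaussian noise (default 0.5% of $V_0$) applied in voltage
  space, then clipping to $[0, V_{sat}]$.

Empty droplets (no chromophore) are given a small residual dip, 2% of $V_0$
by default: real empties remain visible through residual refraction and
lensing even in matched oil, and the instrument must see them to measure
droplet frequency and to gate on occupancy. `droplet_waveform()` itself
produces a perfectly flat segment for a zero-concentration population unless
a residual dip is requested, so the two effects are separable.

The default acquisition rate is 100 kHz — roughly 40 samples per droplet at
1 kHz with the default 0.4 transit fraction. Acquisition hardware for such
devices is not standardized; 100 kHz keeps every feature of the waveform
several samples wide while staying cheap to simulate. Trains whose
parameters would yield fewer than 8 samples per droplet are rejected rather
than silently aliased.

The "baseline offset" alternative to index matching (spiking a constant
absorber concentration into every droplet to lift all dips above the
saturation-obscured region) needs no dedicated machinery: add the offset to
every population's concentration.

## Streaming peak detection

The detector is a per-sample state machine (implemented in C++ via Rcpp, the
usual idiom for signal-processing hot loops) with strictly constant memory
and work per sample, so the same code path serves offline analysis and an
emulated real-time controller. Feeding the trace in chunks of *any* size —
including one sample at a time — produces bitwise-identical output; the test
suite checks chunk sizes 1, 7, 997 and whole-trace against each other and
against an independent offline segmentation oracle.

Key design choices:

* **Causal smoothing.** A 5-sample causal moving average precedes all
  thresholding and minimum extraction. At the default noise this suppresses
  single-sample excursions (the effective threshold is $>5\sigma$) without
  biasing dip minima, because the dip bottom is flat over many more than 5
  samples. On deep dips (low $V_{\min}$) the log transform amplifies voltage
  noise; smoothing keeps the mean absolute absorbance error of the canonical
  5 mM population within the 0.02 AU recovery tolerance.
* **Guarded baseline.** The baseline is an exponential moving average
  (default $\alpha = 0.01$) updated *only* from samples inside the baseline
  band, so dips and shoulders cannot drag it. It is seeded by the median of
  the first 10 ms; that window is buffered (bounded, ~1000 samples) and
  replayed through the state machine once the seed is known, so droplets in
  the first 10 ms are still detected — important when every event counts.
* **Band-exit opening, hysteresis closing.** An event opens when the
  smoothed signal leaves the band in either direction — below
  `enter_delta` (a dip) or above `shoulder_delta` (an edge shoulder). It
  closes after 3 consecutive samples within `exit_band` of the baseline
  frozen at opening. Shoulders therefore never appear as separate events:
  they are absorbed into the adjacent dip, which is precisely how the true
  minimum "between the spikes" is recovered for partially matched oils.
* **Fail-safe flags.** Events wider than `max_width`, truncated at
  end-of-trace, or whose minimum never crossed `enter_delta` below baseline
  are flagged `unresolved` and carry no absorbance (broad merged peaks with
  no identifiable maximum — the failure mode of large droplets in unmatched
  oil). Events touching $V_{sat}$ on the raw samples are flagged
  `saturated`. Neither flag ever triggers the sorter. Events narrower than
  `min_width` are discarded as noise blips. Ties between equal minima go to
  the earliest sample.

`event_frequency()` is the reciprocal *median* inter-event interval — robust
to occasional missed or split events, and all events count, since empties
matter for frequency.

## Trigger engine

Decisions are made at event close, not at the minimum: a causal controller
cannot know the minimum is final until the signal has returned to baseline.
The gate is expressed in absorbance units so it is invariant to baseline
drift (a volts mode reproduces simpler firmware). Unresolved and saturated
events never trigger. Each accepted decision at time $t$ yields an electrode
pulse $[t + \text{delay},\ t + \text{delay} + \text{width}]$; a decision
inside the refractory period of the previous accepted pulse is dropped and
logged (a sorter cannot stack pulses — dropping, not queueing, mirrors the
hardware). The device's true delay/width/refractory values are
instrument-specific; the defaults (0.5 ms / 0.1 ms / 0.5 ms) are geometric
guesses on the scale of one droplet period at 1 kHz and are fully exposed.

## Junction model

The junction model is deliberately phenomenological: the only physics
asserted is monotonicity — the force needed to pull a droplet into the
positive outlet grows with droplet volume and with droplet frequency. We use
a power law $F_{req} = \alpha V^\beta f^\gamma$ with $\beta = \gamma = 1$ by
default and $\alpha$ normalised so $F_{req}(75\ \mathrm{pL}, 1\ \mathrm{kHz}) = 1$.
A pulsed droplet:

* crosses intact with certainty if $F_{app} \ge (1+m)F_{req}$ (default
  margin $m = 0.2$);
* crosses but may fragment against the gapped divider in the marginal zone
  $F_{req} \le F_{app} < (1+m)F_{req}$;
* stays in the negative outlet below $F_{req}$, fragmenting on collision
  with probability rising smoothly with the deficit.

Fragmentation probability is $\tanh(s\,x/2)$ in the relative deficit
$x = ((1+m)F_{req} - F_{app})/F_{req}$ — a logistic-family ramp with one
sharpness parameter, zero exactly at the comfort boundary. Fragmented
droplets produce the *partial* false categories (a fragment ends in the
wrong outlet); a fragmented droplet is never "correct". Unpulsed droplets
follow the bias-oil barrier into the negative outlet intact. A pulse whose
interval covers another droplet's junction arrival deflects that neighbour
too (a possible false positive), and the triggering droplet then fails the
"sorted alone" criterion even though its own body went to the right outlet.

The default applied force (1.6) was calibrated once, before any evaluation,
to the qualitative pattern reported for this class of device: certain intact
sorting at 1 kHz ($F_{app} > 1.2$), marginal crossing at 1.5 kHz
($1.5 \le F_{app} < 1.8$), failed crossing at 2 kHz ($F_{app} < 2$). Only
this ordering — not per-category bar heights, which are available only
graphically in the literature — is treated as a modelling target.

## Evaluation statistics

`tally_outcomes()` reports the six category fractions (summing to 1 exactly)
plus the overall correct fraction under the sorted-alone rule.
`true_positive_rate()` rounds to the nearest integer percent, the convention
under which 34 positive clones of 38 tested reads as 89%. Two enrichment
conventions are implemented because both are current in the droplet
literature and they answer different questions:

* fraction ratio (`enrichment_zinchenko()`):
  $\dfrac{p_a/(p_a+n_a)}{p_b/(p_b+n_b)}$ — bounded above by the reciprocal
  initial fraction;
* odds ratio (`enrichment_baret()`):
  $\dfrac{p_a/n_a}{p_b/n_b}$ — unbounded, reported as `Inf` with a warning
  when no negatives survive.

Whenever sorting actually enriches (fraction ratio $> 1$), the odds ratio
dominates the fraction ratio; a randomized-grid test checks this. Published
headline enrichment folds for mock screens are generally computed from
*measured* initial fractions rather than the nominal mixing ratio, so
nominal-count arithmetic need not reproduce them; the package computes both
conventions from whatever counts it is given and leaves the provenance of
those counts to the caller.

## The mock screen

`run_mock_screen()` chains everything end to end: Poisson encapsulation
(empty with probability $e^{-\lambda}$; positive via thinning,
$P = 1 - e^{-\lambda p}$, with $p$ the positive cell fraction of a 1:100
library), trace synthesis, streaming detection, gating on the
high-absorbance population, pulse scheduling, junction resolution, outcome
tallies, enrichment counts, and a simulated secondary plate assay in which
recovered clones are drawn from two Gaussians and classified by the two-SD
rule. One global seed derives per-stage substreams, so the whole screen is
exactly reproducible while each stage remains independently testable.

Default problem sizes are deliberately desk-scale: $10^4$ droplets (10 s of
trace at 1 kHz) for the screen, 100-droplet runs for sorting-efficiency
experiments, and a 20 s train (20 000 droplets, $2\times10^6$ samples) for
peak-extraction validation. These sizes give tight Monte-Carlo error on
every reported fraction while a full screen runs in seconds; all of them are
arguments, not constants.

Note one intrinsic property of the two-SD rule: a genuinely positive clone
falls below the positive band with probability $\approx 2.3\%$ by
construction, so even a perfectly pure recovered pool shows a plate-assay
true-positive rate slightly below 100% on average. The sorting-side purity
invariants are therefore asserted on the pool composition itself.

## What the simulator does and does not capture

The generator reproduces the features that drive detector and trigger
design: baseline drift-free traces with edge shoulders, Beer–Lambert dip
depths, saturation clipping, Gaussian noise, empty droplets, timing jitter
and two-population mixtures. It does **not** model hydrodynamics (droplet
formation, spacing feedback, bias-oil laminar flow), wavelength-resolved
optics or Mie scattering (shoulders are phenomenological), surfactant
chemistry, droplet merging, or assay kinetics (plate-assay values are drawn
from Gaussians, not from an enzyme model). Passing the recovery and
efficiency suites therefore demonstrates correctness of the *signal
processing and decision chain* under the stated signal model — not
instrument performance on real emulsions, where non-Gaussian noise, baseline
drift and polydispersity will erode the margins reported here.

## Numerical conventions

* All randomness flows through R's RNG; every entry point takes a seed and
  restores the caller's RNG state. Derived substream seeds stay below
  $2^{31}$.
* Degenerate inputs fail loudly with classed conditions
  (`aads_config_error`, `aads_data_error`), which the CLI maps to exit
  codes 2 and 3.
* Trace files are plain CSV (`time_s,voltage_v`), event/pulse/outcome logs
  are TSV, all with headers and dot-decimal formatting regardless of locale
  (written via `data.table::fwrite`).
* Ties: equal minima resolve to the earliest sample; the debounce counter
  resets on any excursion out of the exit band.
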