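---
title: "Models and methods behind srkchan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind srkchan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`srkchan` analyses single-channel current recordings of sarcoplasmic
reticulum (SR) K⁺ channels — the trimeric intracellular cation (TRIC)
channels that carry counterion current while the ryanodine receptor (RyR)
releases Ca²⁺ — recorded from planar lipid bilayers under voltage clamp. It
also ships a ground-truthed simulator of such recordings, so every analysis
stage can be validated against known gating. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
simulator does and does not emulate.

## The gating model

SR K⁺ channels gate between a closed level (C), a full-open level (O) of
roughly 210 pS, and a family of subconductance levels. Because essentially
all transitions between C and O pass through a sublevel, and because the
individual sublevels are too brief and too numerous to classify reliably,
the package adopts the merged-substate convention: a single noisy class S
placed exactly midway between C and O, with class standard deviation fixed
at one-half the substate amplitude. Gating is modelled as a linear
continuous-time Markov chain

    C  <->  S  <->  O

with four free rate constants; the direct C–O rates are structurally zero in
the generator. Dwell times in each state are exponential with rate equal to
the state's total exit rate; stationary occupancies come from the null space
of the generator matrix (`stationary_dist()` solves the augmented
least-squares system πQ = 0, Σπ = 1).

Total open probability (`po_total`) is occupancy-based: the fraction of time
in any conducting class, p(S) + p(O). The percentage contribution of the
full-open class to the total, 100·p(O)/po_total, is reported alongside. A
current-weighted alternative (counting S as half a channel) would be
possible; the occupancy definition was chosen because the full-open
contribution is conventionally expressed as a percentage of the total open
probability, which presupposes occupancy weighting.

## The simulator

`sample_dwell_path()` draws a CTMC path (exponential dwells, successors
proportional to off-diagonal rates; the final dwell is truncated at the
record end and flagged censored so dwell analysis can exclude it).
`render_trace()` converts a path into a digitized record: the class-mean
waveform is filtered with a Gaussian FIR filter and Gaussian noise with the
class SD is then added at the digitization rate. Filtering the *signal*
models the finite bandwidth of the recording chain (event edges acquire the
filter's rise time) while the added noise retains exactly the requested
per-class SD — so a rendered baseline with `baseline_sd = 0.5` pA really has
a 0.5 pA SD, which is the natural way to specify recording quality. The
analysis-side filter in `preprocess()` does act on the noise, as it does in
real analysis.

The Gaussian filter is an FIR with coefficients from the Gaussian impulse
response truncated at ±4σ, with σ_t = 0.1325/f_c (the standard relation
between the −3 dB cutoff and the time-domain width used in single-channel
electrophysiology). Defaults mirror common practice for these recordings:
digitization at 20 kHz, a 1 kHz recording filter (4 kHz for mixed-species
records, which is needed to resolve RyR events), and resampling to 10 kHz
before idealization.

Multichannel records sum per-channel filtered currents and overlay one
shared Gaussian noise process — a single bilayer/amplifier noise source —
with the substate class contributing its extra variance per channel while
occupied. In `facilitated` mode the opening rates (C→S, S→O) of every
channel are scaled by `factor^(N−1)` before simulation. This is a
deliberately minimal embodiment of cooperative facilitation: channels still
gate on independent random streams, so level occupancies remain binomial at
the shifted per-channel Po — matching the experimental observation that
multichannel occupancies follow binomial predictions even when Po is
elevated. The shipped presets are calibration fixtures, not measurements:

* `wt`-like: Po ≈ 0.35, full-open contribution ≈ 75%, mean full-open time
  150 ms, no facilitation;
* `ko`-like: Po ≈ 0.12, contribution ≈ 44%, mean full-open time 40 ms, mean
  substate time 3 ms, facilitation factor 2 — which makes the analytic
  per-channel Po at N = 4 about 6.8 times the lone-channel value, in the
  regime reported for clustered TRIC-B channels.

Rate constants for both presets were fixed once, from the stationary
solution, to sit in these physiological ranges.

## Idealization

`skm_idealize()` implements segmental k-means: iterate Viterbi decoding
(Gaussian emissions, Markov transitions) with re-estimation of the free
emission parameters from the assigned samples and of the transition matrix
from path counts, until the decoded path repeats (the path-stability
stopping rule) or 100 iterations. Design choices:

* **Substate constraint.** With `constraint = "substate"`, mean(S) is pinned
  to the C/O midpoint and sd(S) to half the substate amplitude, re-derived
  from the fitted C and O classes every iteration and never free-fit.
* **Initial transitions** are uniform off-diagonal with self-probability
  0.99 — at a 10 kHz analysis rate dwells span many samples, so
  self-transitions dominate regardless of kinetics.
* **Ties** in the Viterbi back-pointers break toward the lower-conductance
  class, making decoding deterministic.
* **Direct C–O transitions stay decodable**: transition probabilities are
  estimated from path counts with a 0.5 pseudocount per cell, so the
  substate-transit audit (`substate_transit_fraction()`) measures, rather
  than assumes, that open/close transitions pass through S. The pseudocount
  means the joint log-likelihood maximizes a very slightly smoothed
  objective; in practice it is non-decreasing across iterations to well
  under one part in 10⁴.
* **Degenerate classes**: a class assigned fewer than `min_class_n` samples
  keeps its previous parameters; fitted SDs are floored at 10⁻⁴ pA.

On traces of a dozen samples the decoded path equals exhaustive enumeration
of all 3ⁿ paths under the fitted parameters (checked in the test suite), and
on simulated records at the bundled noise levels per-sample accuracy exceeds
95%. The 50% threshold method (`threshold_idealize()`) is provided for RyR
records, where the open level is far above everything else.

## Event post-processing

`strip_short_events()` removes events shorter than the resolution cutoff
(default 0.6 ms): scanning left to right, each short event is deleted and
its duration appended to the preceding surviving event (a leading short
event merges forward instead), then adjacent same-class events merge. When
the idealization carries an analysis rate the arithmetic is done in integer
sample counts, so total duration is conserved exactly and the operation is
idempotent. First and last events border the record and are censored: they
count toward occupancy but are excluded from mean open times and event
frequencies.

`fit_iv()` is ordinary least squares of unitary current on holding
potential, with the slope reported in pS; reversal near 0 mV is expected in
symmetrical solutions but not enforced.

## Dwell-time analysis

Lifetime distributions are fitted by maximum likelihood on the raw, unbinned
dwells with explicit left-truncation at the stripping cutoff; log-binned
histograms (`log_bin()`, uniform in log₁₀ time, where each exponential
component peaks at its time constant) are for display only. Ignoring the
truncation would bias short time constants, which is why the truncated
likelihood is used instead of fitting the binned counts.

A k-component exponential mixture left-truncated at t₀ is exactly a mixture
of the same time constants on the excess t − t₀ with reweighted areas, so
`fit_exp_mixture()` runs EM on the shifted dwells and maps the areas back to
the untruncated scale (a_j ∝ a'_j·exp(t₀/τ_j), computed in log space). For
k = 1 the closed form τ = mean(t) − t₀ is returned directly. EM uses ten
seeded starts with log-spaced initial time constants; `select_num_components()`
additionally warm-starts each order k+1 from the accepted order-k fit with
its largest component duplicated — the initial mixture density is then
identical to the order-k optimum, so fitted log-likelihoods are
non-decreasing in k by construction. Model order is chosen by a sequential
likelihood-ratio test, 2·ΔlogLik against chi-square with 2 degrees of
freedom per added component at α = 0.05, stopping at the first
non-significant improvement. The df/α convention is declared here rather
than inherited: it is the standard choice for this test in single-channel
software, and the type-I behaviour it implies (~5% over-selection per added
component) is verified by simulation in the test suite. No missed-event
correction beyond the explicit truncation is applied.

## Multichannel analysis

For N identical channels the record is idealized over N+1 equally spaced
levels (`multilevel_idealize()`); substate classes are omitted, since merged
sublevels cannot be attributed between channels. `count_channels()` takes N
as the highest occupied level — in experiments this is established by a
maximal-activation episode at strongly positive potential; in simulation any
long segment serves. Per-channel open probability is the mean fraction of
open channels, p̂ = Σ k·P_k / N.

`binomial_test()` compares observed level occupancies with Binomial(N, p̂).
Consecutive samples are strongly autocorrelated, so the statistic is scaled
by an effective number of independent observations taken as the number of
level-transition events. Implementing the naive chi-square on that scale
revealed a genuine miscalibration: time-averaged occupancies of independent
two-state channels are not a multinomial sample. The residual decomposes
into the orthogonal-polynomial (Krawtchouk) modes of the binomial weight,
and the degree-m mode relaxes m times faster than a single channel, so its
variance relative to the multinomial value is 4Np(1−p)/m. The test therefore
scales each squared mode by m/(4Np̂(1−p̂)), which restores the nominal
chi-square null exactly in the two-state independent limit (measured type-I
error 4–7% at α = 0.05 under the three-channel conditions the package
targets). Estimating p̂ from the same record removes the degree-1 mode,
leaving N−1 degrees of freedom. When any expected count falls below 5 the
classical pooled cell-count chi-square is used instead.

**Known limitation.** The mode calibration assumes each channel's conducting
indicator relaxes single-exponentially. For aggregated schemes with bursty
conducting dwells (e.g. the facilitated 3-state preset, whose open bursts
mix brief substate visits with long full openings) the per-record statistic
is anticonservative; for such generators the appropriate check — and the one
used in the package's own validation — is agreement of occupancies averaged
over records with the binomial prediction, which holds to within 0.02
because rate-scaled channels remain independent.

## Two-species records

When an RyR co-incorporates with one or two K⁺ channels, the record is
decoded over the composite level model (`build_species_model()`): all
(n_K_open, RyR state) compositions with additive amplitudes — four levels
for one K⁺ channel, six for two. The K⁺ substate is omitted (at the 4 kHz
filtering needed to resolve RyR events it is poorly resolved), so the
multispecies K⁺ open probability refers to full openings only and is
documented as such; a K⁺ channel that spends substantial time at the
half-amplitude sublevel will have that time split between the adjacent
composite levels, which is a limitation of the substate-free model rather
than of the decoder. Decoded levels map deterministically to per-species
event sequences. In place of interactive event checking, events shorter than
two filter rise times (0.3321/f_c each) are flagged and the flagged fraction
reported. The 50% RyR threshold route (`ryr_po_threshold()`) remains valid
whenever the RyR amplitude is at least twice the total possible K⁺ current
(the ~4:1 amplitude ratio guarantees this for one K⁺ channel) and
cross-validates the model-based decomposition to within 0.02 on simulated
records.

## What the simulator does and does not emulate

It emulates: stationary Markov gating with the merged-substate convention;
Ohmic class amplitudes at a fixed holding potential; Gaussian recording
noise with a noisier substate; Gaussian filtering and digitization; additive
superposition of channels and species; rate-scaled facilitation with
independent streams; censoring at record ends. It does not emulate: bilayer
capacitance transients or voltage steps mid-record; drift, flicker (1/f)
noise, or baseline wander; open-channel noise beyond the substate class;
modal gating or true state coupling (available only as the explicit
cooperativity oracle `sample_coupled_level_path()`, which exists to give the
independence test something it must reject); pharmacological block
kinetics; non-stationary or ligand-dependent gating. Passing tests therefore
demonstrate correctness of the analysis chain under the stated statistical
model, not robustness to every artefact of real bilayer data.

## Problem sizes used in validation

The bundled validation uses problem sizes chosen to keep Monte-Carlo error
well inside each tolerance: 200 random micro-traces for the exhaustive-path
comparison; three 20 s records (600 000 digitized samples) for idealization
accuracy; 20 replicates of 5 000 dwells for mixture recovery and 10 000
dwells for five-component selection; 200 eight-second three-channel records
for test calibration; 1 000 s of lone-channel gating for the facilitation
ratio; and a 3×3 grid of 30 s two-species records (fast-gating generators,
so the finite-record wander of the true Po stays small against the 0.05
orthogonality band).
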