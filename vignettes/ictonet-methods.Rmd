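---
title: "Methods: directed background-EEG networks and virtual resection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directed background-EEG networks and virtual resection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ictonet` implements a longitudinal background-EEG analysis chain:
preprocessing, surrogate-corrected lagged cross-correlation networks,
network asymmetry measures, and a theta-neuron virtual-resection model of
node ictogenicity. This vignette explains each model, the tunable
parameters and their defaults, the numerical choices made where the design
was genuinely open, and what the synthetic-data generator does and does not
emulate.

## Preprocessing

Recordings are re-referenced to the channel average, notch-filtered at the
power-line frequency and its harmonics (50/100/150 Hz, 2 Hz-wide
second-order band-stops), and band-passed 1–150 Hz with an order-2
Butterworth filter. All filters are applied forward and reverse
(`signal::filtfilt`), so the net response is zero-phase — essential here,
because the connectivity estimator reads directionality off cross-correlogram
*lags*, and any phase distortion would masquerade as spurious lead/lag
structure.

Background segments of 1 s are taken by deterministic left-to-right tiling
of the recording, keeping a window only if every sample is at least 1 s
away from every annotated generalized-spike or artifact onset. The eligible
count can be capped (default 83), either by truncation or by a seeded random
subsample; tiling plus an explicit seed keeps segment selection fully
reproducible. Event detection itself is out of scope: onsets are consumed
as annotations.

## Connectivity estimation

For a channel pair the lagged cross-correlation is computed exactly as the
sum of products at each relative shift, normalized by the zero-lag
autocorrelations so that every autocorrelogram equals 1 at lag zero. No
mean subtraction is applied by default — the estimator is defined on raw
products — but `demean = TRUE` is available as a sensitivity switch; after
1 Hz high-pass filtering and average re-referencing the difference is
negligible.

Each 1 s segment is cut into 21 windows of 500 ms. Stated as "21 windows
with a 25 ms overlap", these numbers are mutually inconsistent (500 ms
windows overlapping by 25 ms would give at most 2 windows per second); 21
windows of 500 ms in 1 s force a 25 ms *stride*, which is what
`connectivity_plan()` implements, treating the window count as
authoritative.

Lags shorter than 2 ms are masked to suppress volume conduction (a shared
source reaches all electrodes at essentially zero lag), and lags beyond
250 ms are discarded as physiologically implausible for direct coupling.
The mask is specified in time and converted through the sampling rate
(`lag_mask_for_fs()`: `ceiling(0.002 fs)` to `round(0.25 fs)` samples,
i.e. 8–1000 samples at 4 kHz), so lower-rate data are handled
consistently.

Per window and ordered pair, three readings of the masked correlogram half
are taken: the largest positive value (MAX), the magnitude of the deepest
negative value (MIN), and their maximum (ABS). Negative lags feed the
forward element `c_ij` (channel i leads), positive lags the reverse. By
construction ABS = max(MAX, MIN) per element, which the test suite checks
as an invariant.

Significance is assessed against 100 ensembles of univariate IAAFT
surrogates (10 iterations each, ending on the amplitude-adjustment step so
the value distribution is preserved exactly), windowed identically to the
data. One ensemble per segment serves all three variants. Per element, a
two-sided rank-sum test compares the 21 data values with the 100 × 21
surrogate values, Bonferroni-corrected over the `n(n-1)` elements at
FWER < 0.05. Significant elements are rescaled to the surrogate-excess
weight `(median_data - median_surr) / (1 - median_surr)`; this can go
negative when the surrogate median exceeds the data median, and such values
are clamped to zero because downstream sum-normalization (and the coupling
term of the dynamical model) presume nonnegative weights. Segment matrices
are averaged per recording and normalized by their total weight.

**Known limitation.** The 21 windows overlap by 75%, so the per-element
data values are strongly correlated while the rank-sum test prices them as
independent. Under fully independent channels this admits a few weak
spurious elements per matrix (weights roughly an order of magnitude below
planted couplings) rather than a strictly empty matrix. This is a property
of the published procedure, not of this implementation — we verified that
substituting one more surrogate for the data segment reproduces the same
rate, ruling out estimator bias — and it is why recordings are screened by
`qc_exclusion()` on both segment count and nonzero-element count. Tests
assert sparsity and weakness of these spurious weights, and the planted
direction-recovery checks show genuine couplings dominate them by roughly
an order of magnitude.

## Network measures

Degree imbalance (weighted outdegree − indegree) classifies nodes as
temporal sources or sinks; it sums to zero over any matrix. The global
battery has 20 scalars; the underlying conventions are under-specified in
the literature it mirrors, so they are fixed here and surfaced in the
implementation:

* Directed Laplacian `L = D_out - W`. The *degree of asymmetry* is the
  spectral norm of the skew part `(L - L')/2 = (W' - W)/2` — the only
  nondegenerate reading of "largest eigenvalue" of a skew-symmetric matrix,
  whose spectrum is purely imaginary. It is zero iff the weights are
  symmetric and invariant under adding any symmetric matrix.
* Path measures (betweenness, shortest paths, harmonic closeness) use edge
  length `1/weight` on directed nonzero edges; unreachable pairs contribute
  zero to harmonic closeness and are excluded from shortest-path moments.
* PageRank uses damping 0.85 with out-weight-normalized transitions.
* Assortative mixing is the Pearson correlation, over directed edges, of
  source versus target total weighted degree; the s-metric is the sum over
  edges of the product of endpoint total degrees.
* Neighbor weighted outdegree of a node is the edge-weighted mean of its
  out-neighbors' outdegrees; nodes without out-edges are excluded.
* All variances are population variances, for determinism across platforms.

Matrices are compared by Frobenius distance and embedded with classical
(Torgerson) MDS; the goodness-of-embedding is the Pearson correlation
between input and embedded distances (defined as 1 for a configuration
reproducing constant distances exactly, where the correlation itself is
undefined). Edge-level summaries take the strongest `ceiling(pct/100 *
n(n-1))` connections (ties broken by source/target index; zero-weight
edges never returned) and the fraction of the `n` contralateral
connections among them.

## Theta-neuron model and node ictogenicity

Each node follows the theta-neuron phase model. The printed form of the
model multiplies the input current by `(1 - cos theta)`, under which
`theta = 0` is a fixed point for *any* input and the noise term vanishes
there — the dynamics freeze and no stable excitable state at
`I0 = -1.2` exists. We therefore default to the standard form,

```
dtheta/dt = 1 - cos(theta) + (1 + cos(theta)) * I(t)
```

which has the advertised stable state `theta* = -2 atan(sqrt(-I0))` for
`I0 < 0`; the literal variant is available via `classic_form = TRUE`.

Noise enters as Euler–Maruyama: the increment adds
`(1 + cos theta) * I_noise * sqrt(dt) * xi`, giving a well-defined
continuum limit. A literal per-step reading (`noise_per_step = TRUE`,
noise added to the current without `sqrt(dt)` scaling) is retained as a
flag, but at `dt = 0.01` it corresponds to a tenfold weaker diffusion under
which an uncoupled node at `I0 = -1.2`, `I_noise = 6` essentially never
escapes the resting state — the network then has no baseline spiking for
coupling to amplify, and the 50% operating point is unreachable. The
Euler–Maruyama default is the regime in which the published calibration
procedure is well-posed.

A node is *active* at time t if it spiked (upward crossing of `pi`) within
the trailing `active_window` time units. This detector is the single
largest free choice of the model stage (the original active-state
definition is delegated to prior work and not restated); the default window
of 0.5 time units makes an uncoupled noisy node at the default parameters
active well under 20% of the time, leaving headroom for the coupling to
raise network activity to the 50% operating point. BNI is the mean
per-node active fraction, averaged over `n_runs = 10` independent noise
realizations.

`calibrate_omega()` reuses one seed across evaluations (common random
numbers), making BNI a deterministic near-monotone function of `omega`; the
target is bracketed by doubling from 1 (capped at `2^15`) and bisected
until `|BNI - target| <= tol` (default 0.05) or the bracket shrinks below
1e-2 of its scale. Node ictogenicity removes one node at a time — the
removed node is silenced but the coupling sum stays normalized by the full
`N`, so surviving weights are unchanged — and reports
`NI_i = (0.5 - BNI_post)/0.5` averaged over runs, with per-run replicates
retained.

Simulation sizes: the reference duration is 4e6 steps of `dt = 0.01`; the
package's tests and the acceptance script run 4e5 steps (and 1e5 for the
multi-seed hub-recovery sweeps), sizes at which the BNI estimator's run-to-run
spread is already far inside the calibration tolerance for 6-node networks.

## Synthetic EEG generator

The generator exists so every downstream stage has inputs with known ground
truth. Channels are signed, lagged mixtures of band-limited (1–150 Hz)
Gaussian sources plus white sensor noise on a mirror-symmetric electrode
grid (default 5 × 6, 30 channels, 4 kHz). Each mirror pair of channels gets
a pair of sources (one leading from each side, 15 ms inter-hemispheric lag,
alternating signs to plant anticorrelations), a within-hemisphere coupling
to the next ipsilateral channel (10 ms lag), and a shared zero-lag
background component standing in for volume conduction.

Stages emulate a longitudinal design around a focal left-sided insult:
`day0` and `sham` mixing commutes with the contralateral permutation
(verified as a test invariant), while `day7` and `day28` multiply outgoing
gains from the left posterior node set by 1.75 and 2.5 respectively and
shrink inter-hemispheric gains to 0.6 and 0.35 — planting both the
positive degree imbalance and the loss of mirror symmetry that the
measures should recover. `day7`/`day28` recordings carry planted
generalized-spike transients (40 ms biphasic, announced only through their
onset annotations downstream). Default cohort sizes mirror the study
design (11 subjects at day0 and day28, 7 at day7, 4 sham); the default
per-recording duration is 60 s, enough for several dozen background
segments, with longer recordings available by argument. Amplitudes are
arbitrary units — the connectivity estimator is scale invariant by
construction, so no microvolt calibration is attempted.

What the generator does *not* emulate: realistic EEG spectra (sources are
filtered white noise, not AR fits to real recordings), nonstationarity,
muscle/movement artifacts with realistic morphology, finite-conductivity
volume conduction beyond a shared zero-lag component, or any biophysical
forward model. Passing recovery tests on these fixtures therefore shows the
*chain* is correct — directions, symmetries and hubs planted in the data
come out of the analysis — not that the method's sensitivity on real
epicranial EEG matches the synthetic case.

## Statistics

Rank tests use the tie- and continuity-corrected normal approximation
throughout (group sizes here are 21 vs 2100, or single-digit subject
counts; exact enumeration at `n <= 10` serves as the test oracle, which the
approximation tracks to a few hundredths at worst). AUROC is the
tie-aware exceedance probability `U/(n_a n_b)`. Cohort comparisons test
each node, control FDR over nodes at `q = 0.1` by Benjamini–Hochberg, and
report only nodes that additionally clear an AUROC gate (< 0.2 or > 0.8
two-sided; > 0.8 for one-sided increases), mirroring the conjunction of
significance and effect size used to flag nodes in the source analysis.
Note that under the global null the number of BH-reported nodes is far
below `q × n_nodes` (BH controls the *rate among rejections*, not the
rejection count); the calibration property one can actually test — and the
suite does — is that raw level-`q` rejections average `q × n_nodes` per
label permutation while gated reports stay rare.

## Pipeline and reproducibility

`run_pipeline()` drives cohort generation → preprocessing → connectivity →
metrics → (optional) ictogenicity → statistics from one
`pipeline_config()`, writing tidy CSVs plus a JSON manifest with an MD5
checksum per output. Every stochastic stage requires an explicit seed, and
derived sub-seeds are computed arithmetically (all below 2^31), so the same
configuration reproduces byte-identical outputs. Configurations round-trip
through YAML. Recordings and matrices are serialized as CSV with JSON
sidecars — plain-text formats that diff and version cleanly and need no
binary dependencies.
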