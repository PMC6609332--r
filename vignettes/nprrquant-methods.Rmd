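---
title: "Quantifying neuropeptide release reporter imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuropeptide release reporter imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3.5)
library(nprrquant)
library(dplyr)
```

## The measurement problem

Neuropeptides are packaged in dense-core vesicles (DCVs) and released by
stimulus-evoked fusion. A neuropeptide release reporter (NPRR) is a
neuropeptide-precursor::GCaMP fusion that is sorted into DCVs; its
fluorescence is quenched in the acidic, low-calcium vesicle lumen and
increases when fusion exposes it to the neutral, high-calcium extracellular
space. Imaging such a reporter at the *Drosophila* larval neuromuscular
junction during trains of electrical nerve stimulation yields ROI
fluorescence time series whose shape carries the release signal:

* a **rising phase** whose peak lags stimulation onset by seconds (DCV
  fusion is slower than calcium influx);
* a **falling phase** that begins *before* stimulus offset, as the
  releasable vesicle pool depletes;
* an **undershoot** below the pre-stimulation baseline during the
  inter-stimulation intervals (released reporter diffuses away and the
  remaining labelled pool is smaller than at rest), followed by a
  **recovering phase** as DCVs are replenished.

A cytosolic calcium indicator (GCaMP6s) in the same cells shows none of
this: its response is near-instantaneous, plateaus through the stimulus,
and never falls below baseline. Blocking vesicle fusion with tetanus toxin
light chain (TNT) abolishes both the peaks and the undershoot. These
qualitative contrasts are what the package's metrics are designed to
quantify, and what its synthetic-data generator reproduces with known
ground truth.

The second, independent measurement in scope is stereological: on
immuno-EM micrographs, gold particles marking the reporter are counted in
geometrically defined compartments (DCV counting discs, plasma-membrane
band, remaining bouton cytoplasm, outside), and labelling densities per
µm² localise the reporter to DCVs.

## The trace model

The generator (`simulate_nprr_traces()`) is a deliberately minimal
pool-depletion model — the simplest mechanism that produces all three
phases. Per ROI, with releasable pool $P$ ($P(0)=1$) and released signal
$R$ ($R(0)=0$):

$$
\frac{dP}{dt} =
\begin{cases}
-\,k_d \, u \, P & \text{during stimulation} \\
(1 - P)/\tau_r & \text{otherwise}
\end{cases}
\qquad
\frac{dR}{dt} = g \, f \, u \, P - R/\tau_c
$$

where $f$ is the stimulation frequency, $u = \mathrm{logistic}\!\big((f -
f_{1/2})\,\beta\big) \cdot \gamma_k$ is the drive (with per-trial gain
$\gamma_k$), $k_d$ the pool depletion rate, $\tau_r$ the replenishment
time constant, $g$ the fluorescence gain per Hz and $\tau_c$ the clearance
time constant of released reporter. The cumulative unreplenished release
is $D = 1 - P$ and

$$
\Delta F/F(t) = R(t) - c_u \, D(t) + \varepsilon(t), \qquad
\varepsilon(t) \sim \mathcal{N}(0, \sigma^2),
$$

with raw fluorescence $F = F_0\,(1 + \Delta F/F)$. The undershoot term
$c_u D$ represents the dilution of released reporter and the transiently
smaller labelled pool; recovery follows $\tau_r$.

### Parameters and defaults

| Parameter | Default | Units | Role |
|---|---|---|---|
| `baseline_f` | 100 | a.u. | resting fluorescence |
| `release_gain_per_hz` ($g$) | 0.012 | 1/Hz | peak amplitude scale |
| `pool_depletion_rate` ($k_d$) | 0.35 | 1/s | sets peak latency and pre-offset decline |
| `pool_replenish_tau` ($\tau_r$) | 25 | s | recovery speed between trials |
| `signal_clearance_tau` ($\tau_c$) | 2 | s | decay of released signal |
| `undershoot_coupling` ($c_u$) | 0.12 | – | undershoot depth |
| `freq_threshold`, `freq_slope` | 40 Hz, 0.15 | – | logistic frequency dependence |
| `trial_gain_schedule` | 1 | – | per-trial drive modulation |
| `noise_sd` | 0 | ΔF/F | per-frame Gaussian noise |

The defaults were chosen once to reproduce the published kinetics of the
reporter in Type III motor neurons under the standard protocol (four 70 Hz
trials of 18 s separated by 42 s, 1 frame/s): peak latency of a few
seconds (within the reported 0.5–5 s range), decline beginning before
offset, undershoot of roughly a quarter of the peak, and near-complete
recovery over a 40 s interval. `mode = "type_ib"` lowers the frequency
threshold to 12 Hz (slope 0.25) so that responses are detectable at
10–20 Hz, mirroring the greater sensitivity of Type Ib neurons; in the
default Type III mode, responses below 30 Hz are small. The trial-gain
schedule is descriptive, not mechanistic: a first-trial gain below 1
emulates reporters whose first peak is characteristically lower, while the
default schedule lets pool dynamics alone produce a mild progressive
decline.

Two modelling points deserve emphasis:

* **TNT mode.** Fusion block means nothing is released: `mode = "tnt"`
  sets both the release gain and the undershoot coupling to zero, so the
  deterministic trace is identically zero. Setting the release gain alone
  to zero would leave a phantom undershoot from pool book-keeping, which
  has no physical counterpart when no labelled vesicle fuses.
* **The calcium control** (`simulate_gcamp_traces()`) is not a second
  mechanistic model: it is a piecewise rise-plateau-decay trace (rise to
  plateau within one frame, exponential decay with $\tau_c$ after offset,
  plateau linear in $f$), which is all the downstream contrasts require:
  immediate peak, no pre-offset decline, and non-negative
  inter-stimulation integrals.

### Numerical integration

The state equations are integrated with classical fourth-order
Runge–Kutta at 10 sub-steps per frame, with the piecewise-constant drive
frozen at each sub-step midpoint so that no integration stage straddles a
stimulus on/off discontinuity (trial boundaries fall on frame times in the
protocols used). This keeps the integrator within a fraction of a percent
of a reference integration on a 100-fold finer grid — the test suite
asserts agreement within 1% of the trace amplitude at all frame times — at
negligible cost. A first-order scheme at the same step size would sit near
that tolerance rather than comfortably inside it, which is why the
higher-order scheme was preferred.

## From raw fluorescence to metrics

**ΔF/F** (`compute_dff()`) normalises each ROI to the mean of its raw
fluorescence over a pre-stimulation baseline window, by default from the
start of the recording to 2 s before the first onset. The recordings the
package targets mark a background span before the first trial but no fixed
length, so the default uses all of it minus a 2 s guard; the window is an
explicit argument and is echoed into every output for provenance. The mean
(not the median) is used as the baseline statistic, and this choice is
recorded in the metrics report.

**Per-trial baseline correction** (`correct_trial_baseline()`) subtracts,
for each trial, the mean ΔF/F of the 5 s immediately preceding its onset.
Subtraction is used rather than division because after an undershoot the
pre-trial level sits near zero, where a ratio is unstable, and subtraction
preserves ΔF/F units (peak height *above the pre-stimulation level of that
trial*). Each trial's corrected segment starts at its own pre-window so
that, after correction, every trial's pre-onset mean is exactly zero and
the operation is idempotent — two properties the test suite asserts at
1e−12.

**Metrics.** Peaks and latencies (`trial_peaks()`) search only the
in-stimulation window $[{\rm onset}, {\rm offset}]$ — the read-out is the
in-stimulation response, so post-offset excursions are ignored — with ties
resolved to the earliest frame. Integrals (`interval_integrals()`) are
trapezoids on the actual frame times, reported both raw (ΔF/F·s) and
normalised per second, for each trial window and each inter-stimulation
interval; a negative interval integral is the undershoot read-out.
Tri-phasic segmentation (`segment_phases()`) runs on a 3-frame
moving-average smoothed trace (phase boundaries are otherwise dominated by
single-frame noise at 1 fps); the falling onset is the first post-peak
time from which the smoothed trace declines for at least two consecutive
frames, the undershoot interval is the maximal contiguous sub-baseline
(< −`eps`, default 0.01) span of the following interval, and a flat trial
is flagged undefined rather than raising an error. Frequency responses
(`normalize_frequency_response()`) are expressed as a percentage of the
peak at a reference frequency (70 Hz by default). The bouton/inter-bouton
contrast (`bouton_ibi_ratio()`) averages frame-wise ratios of class means
within each trial, excluding frames whose denominator falls below a
configurable floor (default 0.01 ΔF/F) — near-zero inter-bouton values
would otherwise blow the ratio up; the excluded fraction is always
reported alongside the ratio.

```{r traces, message = FALSE}
protocol <- make_protocol(4, 18, 42, 70, pre_window = 30, post_window = 30)
traces <- simulate_nprr_traces(protocol,
                               trace_sim_params(noise_sd = 0.02, seed = 1))
dff <- compute_dff(traces)
autoplot(dff)
trial_peaks(dff) |> summarise(across(c(peak, latency_s), mean), .by = trial)
```

## Stereology

Annotations are plain geometry: gold coordinates and DCV centres in nm, a
bouton outline polygon, the micrograph area in µm². Compartments are
assigned per particle with the priority DCV disc > membrane band >
cytoplasm > outside (`assign_gold_compartments()`); the disc wins where
regions overlap because gold within the 50 nm counting disc of a DCV
centre is its own category. Areas follow the point-counting conventions:

* DCV area $= n_{\rm DCV}\,\pi r^2$ with $r = 50$ nm;
* membrane band area $=$ perimeter × 40 nm — the band spans 20 nm on
  *each side* of the outline, since "within 20 nm of the membrane" does
  not specify sidedness; curvature corrections are negligible at these
  scales;
* cytoplasm area $=$ bouton area − inner half-band (perimeter × 20 nm) −
  DCV disc area. Only the inner half of the band lies inside the outline,
  so only it is subtracted; the DCV subtraction is the default and an
  unsubtracted variant is always reported as well, since the convention
  behind published ratios is not always stated;
* bouton area comes from the outline polygon (exact shoelace) by default,
  or from a grid-intersection estimate (`grid_area_estimate()`, cell-centre
  grid convention) when point counting is preferred.

The headline statistic is the DCV/cytoplasm density ratio
(`density_report()`), computed under both pooling schemes — summing counts
and areas across images before dividing (`pooled`, the default) and
averaging per-image ratios (`per_image_mean`) — because published averaging
schemes often go unstated; all four variants (2 poolings × 2 area
conventions) appear in every report. Background labelling
(`background_density()`) pools control images (blank resin, muscle,
non-expressing genotype) into total gold over total area and compares it
against a 0.6 gold/µm² ceiling. An optional aggregate filter was
considered and rejected: with annotation-level inputs, aggregate removal
belongs upstream in the annotation step, not in the counting.

The EM generator (`simulate_em_annotation()`) draws a convex perturbed
polygon occupying a set image fraction, places non-overlapping DCV discs
whose counting discs also clear the membrane band (so the simulated
compartments are mutually exclusive and the ground-truth labels are exact),
and draws per-compartment Poisson counts with uniform positions. Its
default densities (30, 2, 8, 0.5 gold/µm² for DCV, cytoplasm, membrane,
outside) encode a 15:1 DCV/cytoplasm contrast of the same order as
published reporter enrichments.

```{r em}
ann <- simulate_em_annotation(em_sim_params(seed = 1))
report <- density_report(lapply(1:20, function(s)
  simulate_em_annotation(em_sim_params(seed = s))))
glance(report)
```

## Statistics

Group comparisons use the Mann–Whitney U test (`mann_whitney_u()`), exact
by full enumeration of all $\binom{n_a+n_b}{n_a}$ rank assignments when
both groups have ≤ 8 observations and the pooled sample is tie-free, and a
tie- and continuity-corrected normal approximation otherwise; at the
sample sizes these experiments produce (n = 6–12), the exact path is the
usual one, and the method actually used is recorded in every result.
Normalised responses are compared against zero with a one-sample t test
(`one_sample_t()`). Sidedness defaults to two-sided — the sidedness
convention behind published stars is rarely stated — and no
multiple-testing correction is applied, matching per-comparison star
reporting (`significance_stars()`: \*, \*\*, \*\*\*, \*\*\*\* for
p < 0.05, 0.01, 0.001, 0.0001). Both choices are recorded in results
rather than silently assumed.

## What the synthetic data does and does not establish

The generators reproduce the *structure* of the real data — tri-phasic
release kinetics with frequency dependence, class-contrasted traces,
compartmental Poisson gold placement — with known ground truth, which is
what makes every downstream stage testable: ΔF/F round-trips the
generator's truth to machine precision, metric recovery is tested under
noise across seeds, density-ratio recovery is tested within Poisson
sampling error across 100 simulated micrograph sets.

They deliberately omit much of what makes real recordings hard: motion
and muscle-contraction artefacts, bleaching, focus drift, heterogeneous
ROI amplitudes, spatially correlated noise, non-Poisson gold clustering
(aggregates), and segmentation error in outlines. Passing tests therefore
demonstrate the correctness of the quantification given clean annotated
inputs, not robustness to acquisition artefacts — the package assumes
registration, ROI tracing and annotation happened upstream, and none of
those steps are in scope. Test problem sizes (e.g. 50-seed recovery runs,
100-seed density recoveries, 10,000-replicate null simulations) were
chosen as the smallest sets that make the corresponding sampling bands
tight enough to be meaningful.

## Known limitations

* The trace model is phenomenological; its parameters summarise kinetics
  and are not estimates of biophysical constants. Fitted values of, say,
  $k_d$ should not be read as vesicle-pool half-lives.
* ΔF/F assumes a positive, stationary pre-stimulation baseline; recordings
  whose baseline drifts during the background span need the per-trial
  correction, and strongly bleaching recordings are out of scope.
* The membrane band area uses the perimeter approximation; for highly
  non-convex outlines with features at the 20 nm scale it would be biased,
  but annotated bouton outlines are smooth at that scale.
* `bouton_ibi_ratio()` is undefined when the inter-bouton signal never
  clears the floor (the flag, not a number, is returned); this is inherent
  to ratio read-outs near zero, and the exclusion rule is logged so it can
  be tightened or loosened deliberately.
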