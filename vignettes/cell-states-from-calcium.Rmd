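---
title: "Inferring calcium-signaling cell states from single-cell parameter ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring calcium-signaling cell states from single-cell parameter ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcistate)
```

# The question and the approach

Clonal cell populations respond to the same ATP stimulus with strikingly
different calcium transients. Two explanations compete: accumulated
stochastic fluctuation (an unstructured cloud in cell-state space) versus a
mixture of distinct functional states (clusters). Clustering the traces
themselves rarely decides the issue, because a trace conflates many
mechanisms. `calcistate` instead uses the *kinetic parameters* of a
mechanistic signaling model as the cell-state signature: each cell's trace
is fitted individually, the fit's full posterior uncertainty is retained as
a parameter *ensemble*, and cells are clustered by a distance that respects
that uncertainty. A cluster in parameter space is then interpretable: the
parameters that separate clusters name the mechanism that differs.

# The calcium model

## Structure and assumptions

The model couples a minimal receptor/PLC/IP3 cascade to the classic
two-variable reduction of IP3R channel gating:

* **Receptor and PLC.** Receptor dynamics are collapsed into an
  ATP-dependent step that decays exponentially (first-order receptor
  desensitization, rate `k_r`) multiplying a linear PLC activation gain
  `k_plc`; active PLC decays at `k_plc_deg`. This avoids a fifth state
  variable while capturing the transient nature of the drive.
* **IP3.** Produced as a Hill function of PLC (maximal rate `v_ip3_prod`,
  half-saturation `k_plc_half`, coefficient `n_hill`); degraded linearly at
  `k_ip3_deg`.
* **Calcium.** Released from the ER through IP3R channels with the
  Li-Rinzel cubic open probability built from the IP3-activation constant
  `d1`, the calcium-activation constant `d5`, and the gating variable `h`;
  pumped back by SERCA (Hill-2, `v_serca`, `k_serca`); a passive ER leak
  balances the pump at rest. All calcium fluxes are scaled by a single
  buffering factor `beta_buf`. There is no mitochondrion, no plasma-membrane
  leak, and no store-operated entry, so total cellular calcium `ca_tot` is
  conserved and ER calcium is eliminated algebraically:
  `ca_er = (ca_tot - ca) / c_er`.
* **Gating.** `dh/dt = a2 (dinh (1 - h) - ca h)`: calcium inactivates the
  channel with equilibrium constant `dinh` at rate `a2`.

Seventeen parameters are free; the frozen order is exported by
`calci_param_names()` and every ensemble matrix uses it. Fitting operates on
log10 fold-changes from the reference values, so a parameter vector of
zeros *is* the reference cell.

## Reference values

The published figure equations and the deposited reference table for this
model family were not available to this implementation, so the reference
values in `calci_reference_params()` are assembled from the canonical
Li-Rinzel gating constants (`d1 = 0.13`, `d5 = 0.08234`, `dinh = 1.049` uM,
`a2 = 0.2` 1/(uM s), `v_ip3r = 6` 1/s, `c_er = 0.185`) and Lemon-style pump
and turnover values, with the receptor/PLC/IP3 gains set once so that a
10 uM ATP step produces a realistic transient: a sharp rise (time to half
maximum about 8 s), a peak near 0.9 uM from a 0.1 uM basal level roughly
15 s after stimulation, and a slow decay to an elevated plateau within a
15-minute acquisition. These values were frozen before any acceptance
measurement and are cross-checked in the test suite against an independent
integration of the same equations (frozen as a plain-text fixture labelled a
synthetic oracle stand-in).

## Numerics

There is no stiff-ODE package in the supported environment, so integration
uses an embedded Dormand-Prince RK45 written in C++ with relative tolerance
1e-6 and absolute tolerance 1e-9, stepping exactly onto the output grid and
never across the stimulus discontinuity. The system is only mildly stiff at
reasonable parameters; draws extreme enough to defeat the integrator (step
underflow, runaway states, implied negative ER calcium, non-positive
parameters) are reported as a failure *status*, never an exception — the
ABC sampler scores them as rejections, which is also how inadmissible
parameter regions should be treated statistically.

The ER leak coefficient is not a free parameter: it is closed once per
simulation so that leak exactly balances SERCA pumping at the rest state
implied by the cell's basal calcium. This makes the pre-stimulus fixed
point exact by construction (`find_rest_state()`), anchors every simulation
at the data's own basal level, and keeps the free-parameter count at 17.

# Preprocessing

Raw fluorescence is calibrated with the standard single-wavelength formula
`Ca = Kd (F - Fmin) / (Fmax - F)`; values at or above `Fmax` either error
or, with `clamp = TRUE`, are clamped just below saturation. Traces are
truncated to the post-stimulus window (the first retained frame is the
basal level point) and smoothed with a zero-phase (forward-backward)
second-order Butterworth low-pass. Before filtering, a mirror image of the
signal is concatenated at both ends; without that reflective boundary the
filter's zero initial state drags the trace start toward zero and damps the
sharp initial rise — the test suite demonstrates a several-fold onset-error
reduction from the padding.

The default cutoff is 0.1 Hz at the default 2 s sampling: low enough to
attenuate the 0.2 Hz nuisance band by over 99 percent in amplitude after
the two passes (the bilinear transform's frequency warping helps near
Nyquist), high enough that the reference transient's rise passes
essentially undistorted. The cutoff is configurable; at 0.05 Hz the rise is
visibly smeared and trajectory-feature times shift by more than a sample.

The per-cell acceptance threshold ε_final is the goodness-of-fit score of
the raw trace against its own smoothed version. This is the pivot of the
whole fitting scheme: a simulation is accepted when it agrees with the data
at least as well as smoothing does, so the tolerance automatically adapts
to each cell's noise level.

Trajectory features (basal F0, time to half maximum T50U, time to maximum
Tm, maximum Fm, decay time T50D, trailing steady state Ff) use linear
interpolation between samples for threshold crossings. Cells whose response
amplitude is below a floor are flagged non-responders; traces that never
fall back below half maximum report the censored time-to-end with a flag
(strong responders can plateau above half maximum). Ff averages the last
10 percent of frames by default.

# Goodness of fit and ABC-SMC

The score is the sum of squared errors between simulation and processed
data plus an equally weighted sum of squared errors between their first
differences (forward differences on the shared grid). The derivative term
emphasizes the shape of the transient; with any positive weight the score
is zero only for identical traces.

Per cell, the sampler is pure adaptive rejection in the spirit of ABC-SMC:

1. iteration 0 draws from the log10-uniform [-1, 1] prior box and keeps the
   first `n_particles` draws that simulate successfully;
2. each subsequent iteration proposes by resampling a previous particle
   uniformly and perturbing it with a component-wise Gaussian kernel whose
   variance is `kernel_scale` times twice the previous population's
   component variance; proposals outside the prior box are re-proposed,
   never clipped;
3. the acceptance threshold is the 90 percent score-quantile of the
   previous population, floored at ε_final;
4. the run succeeds when all particles score at or below ε_final, then
   performs `polish_iterations` further rejection passes at ε_final.

Importance weights are deliberately omitted: every stage is plain
rejection, which matches the algorithm's description and keeps the final
population interpretable as "parameters whose simulations agree with the
data within the cell's noise floor". The cost of that simplification is
mixing: without weights, each run's population retains memory of its
descent path, and two independent runs can be statistically
distinguishable even though both fit. Two defaults were set by measurement
to counter this. `kernel_scale = 0.5`: at 1.0 the 17-dimensional kernel is
so overdispersed that acceptance collapses (hours per run), at 0.25 runs
under-mix and fail the convergence test. `polish_iterations = 6`: the
refresh passes at the final threshold decorrelate the sample; on the test
fixture, dual-run convergence went from about one in four seed pairs at
three passes to all pairs at six.

`max_iterations` (default 30; tests use more for hard cells) bounds the
descent, and a per-iteration proposal budget turns a practically
unreachable threshold into a reported `"threshold unreachable"` status.
Both failure modes flag the ensemble non-fitted — pipeline attrition, not
errors.

# The dual-run convergence test

Each cell is fitted twice, independently. If both runs sampled the same
posterior, then in the pooled, per-coordinate z-scored cloud a particle's
nearest neighbor should be from either run with (almost) equal probability.
The test counts same-run nearest neighbors and compares against the exact
finite-sample null probability under permutation, `(n_r - 1)/(n - 1)` per
particle (the idealized 0.5 is available as an option; at n = 500 the
difference is negligible).

One statistical subtlety matters: nearest-neighbor identities are
positively dependent (mutual neighbor pairs, shared neighbors), so the
naive chi-square with multinomial variance is anticonservative — its
measured type-I rate at 2 x 500 particles in 17 dimensions is roughly
0.08-0.12 instead of the nominal 0.05. The default therefore keeps the
chi-square form but uses the exact variance of the same-run count under
random relabeling conditional on the realized nearest-neighbor digraph,
computed in closed form from the counts of ordered edge pairs spanning two,
three, or four distinct vertices. With that variance the measured type-I
rate is statistically indistinguishable from 0.05 (the acceptance suite
verifies this over 200 replicates), and the naive variance remains
available as `variance = "multinomial"`.

Exact ties (duplicated particles, a byproduct of resampling) are handled by
treating zero-distance copies as exchangeable: each particle contributes
the same-identity *fraction* of its duplicate group, query included. This
makes the degenerate case — one run being a permuted copy of the other —
exactly null, hence convergent, as it should be.

# The Kullback-Leibler ensemble distance

For two cells, pool their ensembles in pair-standardized log10 space and
record, for every particle, whether its nearest neighbor belongs to the
same cell. The observed two-category distribution (same-cell/other-cell,
aggregated over both cells) is compared to the analytic permutation null by
KL divergence (nats). Overlapping ensembles give distances near zero;
fully separated ensembles approach the maximal two-category divergence for
the given sizes, a closed form the tests verify exactly. A half pseudo-count
per category keeps perfectly separated pairs finite without reordering
distances. Standardization uses the pooled pair's own statistics so a
pair's distance never depends on unrelated cells.

The aggregated two-category construction is the simplest one consistent
with a "probability that a particle's nearest neighbor is from the same
cell" distribution; it is symmetric in the two cells by construction. The
nearest-neighbor estimator's detection floor is worth knowing: a shift of
one pooled standard deviation along a single one of 17 coordinates is near
the noise level at 150 particles per ensemble and reliably resolved at 400.

# Clustering and cluster characterization

Average-linkage hierarchical clustering runs on the KL distance matrix; the
tree is cut at each candidate k and scored by a Calinski-Harabasz
criterion, `CH(k) = (B/(k-1)) / (W/(n-k))`. Because the inputs are general
dissimilarities rather than points, dispersion needs a distance-based
definition, and the choice matters at desk scale. Measuring dispersion
against cluster *medoids* (summed squared member-to-medoid distance within;
size-weighted medoid-to-overall-medoid distance between) degenerates for
small n: singleton-heavy cuts drive W toward zero and the criterion grows
toward the k boundary regardless of structure — on clean two-regime test
data it selected k = 6 of 12. The default is therefore the standard
kernelized generalization: W is the average pairwise squared distance
within each cluster (exactly the centroid sum-of-squares when distances are
Euclidean) and B = T - W. The medoid variant remains available
(`ch_method = "medoid"`), and medoids are always reported as cluster
representatives. Two further guards: the scanned k is capped at floor(n/2)
(below that, within-dispersion is estimated from almost no pairs), and a
selection is flagged `weak` when the best score sits at the top of the
scanned range or barely rises above the curve's median — a single
unstructured cloud should and does come out flagged.

Clusters are characterized by per-parameter medians and interquartile
ranges of the pooled member ensembles, plus a separation score per
parameter: the standard deviation of cluster medians over the mean
within-cluster particle standard deviation. When synthetic regimes are
constructed to differ only in the IP3R feedback constants, those constants
rank at the top — which is exactly the kind of mechanistic readout that
motivates clustering in parameter space rather than trace space.

Two dispersion-ratio utilities support the comparison between
representations: `variance_ratio()` (coordinate form, between/within sums
of squares on per-cell vectors) and `dispersion_ratio()` (the same ratio
computed from a distance matrix). A caveat discovered during testing: on
per-cell *mean parameter vectors* the coordinate form can favor the trace
representation, because regime offsets live on 3 of 17 coordinates while
within-regime scatter spans all 17; the separation advantage of the
parameter representation shows in the spaces the clusterings actually use
(KL distances versus Euclidean trace distances), which is what the test
suite asserts.

# The synthetic-data generator

`regime_spec()` defines a cell state as a log10-normal cloud: named mean
offsets from reference, a within-regime spread, and a population weight.
The default three regimes encode the qualitative state structure the
pipeline is designed to detect: strong positive calcium feedback (low
`d5`, high `dinh`), strong negative feedback (low `dinh`, with elevated
receptor gain), and weak positive feedback (high `d5`); offsets are 0.5
log10 with 0.1 log10 within-regime spread. `sample_population()` assigns
regimes multinomially and truncates draws to the prior box by redraw;
`render_traces()` simulates each cell, prepends the pre-stimulus baseline
(default 30 s at 2 s sampling), and corrupts the trace with a band-limited
high-frequency nuisance component (a sinusoid near 0.2 Hz with per-cell
random frequency jitter and phase, amplitude 0.02 uM — fast calcium
activity the deterministic model does not capture) plus 0.02 uM iid
Gaussian measurement noise. Simulation failures are re-drawn within the
regime and logged.

What a green test establishes — and what it does not. The generator
produces data from the *same model family* the fitter assumes, with
well-separated regimes and stationary noise. Green end-to-end tests
therefore establish the pipeline's internal consistency (identifiable
parameters are recovered, convergent runs agree, known structure is found
with the right mechanistic attribution) but not robustness to model
misspecification: real cells have oscillatory microdomains, drifting
baselines, segmentation errors, and biology outside this ODE. The
high-frequency nuisance term probes only the mildest form of
misspecification, one the preprocessing is explicitly designed to remove.

`idealized_ensemble()` is a fast path for clustering tests: it draws a
Gaussian posterior around a cell's true parameters directly, with spread
0.2 log10 by default in tests — chosen to mimic the sloppiness of real
fitted ensembles (fitted per-coordinate SDs run 0.3-0.5 log10), which
overlaps within-regime neighbors the way real posteriors do.

# Degenerate inputs and edge cases

* Flat traces: flagged non-responders; features NA.
* Calibration at saturation: error by default, clamp opt-in.
* All-zero distance matrix: k = 1, flagged degenerate.
* Singleton-only clusterings: variance ratio NA with a warning.
* Grossly unequal run sizes (over 4:1): convergence test warns.
* Every stochastic step is reproducible from seeds; the pipeline derives
  per-cell per-run seeds from one master seed and its outputs are
  byte-identical across reruns.

# Known limitations

* Pure rejection SMC without importance weights samples a slightly
  different object than the true ABC posterior (overdispersion of
  intermediate populations); the dual-run test gates the damage but does
  not remove the bias.
* The RK45 integrator is not stiff-capable; a small fraction of admissible
  but extreme parameter draws is rejected for numerical rather than
  statistical reasons, which mildly reshapes posterior tails.
* Single-coordinate ensemble differences below about one pooled SD are
  invisible to the nearest-neighbor KL distance at desk-scale ensemble
  sizes.
* The Calinski-Harabasz criterion assumes compact clusters; elongated or
  nested state structures would need a different selection rule.
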