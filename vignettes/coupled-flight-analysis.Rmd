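---
title: "Detecting directed coupling in flying pairs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting directed coupling in flying pairs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pairflight)
```

# The question and the analysis

Two animals fly through the same volume, one in front, one behind. Three
explanations can produce similar-looking paths: direct interaction
(one's motion drives the other's), a shared environment (both react to
the same walls, obstacles and air), or coincidence. `pairflight`
implements a model-free analysis that separates these: it quantifies
*directed* coupling between the two trajectories with transfer entropy
and convergent cross mapping, and calibrates both against a
shuffled-partner control built from non-contemporaneous pairings, so that
shared-environment similarity is absorbed into the null rather than
mistaken for interaction.

The unit of analysis is the pair's co-presence window: the stretch during
which both agents are observed. Windows from many pairs are concatenated
into one ensemble per agent position (front = agent 1, the first to
enter; rear = agent 2), because the estimators are data-hungry and a
single 1–2 s flight is far too short. Segment boundaries are tracked so
that no estimator ever treats the joint between two unrelated flights as
a dynamical transition.

# From positions to curvature

Raw input is tabular: `pair_id, agent, t, x, y, z, behavior`, seconds and
meters. Each trajectory is fitted with an interpolating cubic spline per
coordinate and resampled on a uniform grid (default 180 Hz), with
velocity and acceleration taken as the spline's analytic derivatives.
The spline end condition fits an exact cubic through the boundary points,
so polynomial trajectories up to degree three are reproduced exactly,
derivatives included; a "natural" end condition would bias the boundary
derivatives. Within a pair, both grids are phase-anchored at the overlap
start so the two series align sample-for-sample.

Turning is summarised by the curvature
$\rho = \lVert a_n \rVert / \lVert v \rVert^2$ with
$a_n = a - (a \cdot v / \lVert v \rVert^2)\, v$, in 1/m. Samples with
speed below a floor (default $10^{-6}$ m/s) are flagged invalid and
dropped pairwise, rather than dividing by a vanishing speed. Ensembles
are standardized to zero mean and unit sample variance per agent series
(per dimension for 3D velocity); global scope is the default, per-segment
scope is available.

# Transfer entropy

Two estimators are provided, both for destination history length 1
(source at lag 0 predicting the destination one step ahead).

**Binning.** Equal-width bins over each variable's observed range; the
plug-in estimate of the TE sum over joint occupancy counts. It equals the
difference of conditional entropies
$H(Y_{t+1} \mid Y_t) - H(Y_{t+1} \mid Y_t, X_t)$ to machine precision,
and the package can compute it either way as an internal cross-check.

**KSG.** The Kraskov–Stögbauer–Grassberger (algorithm 1) estimator of
$I(Y_{t+1}; X_t \mid Y_t)$: the max-norm distance to the K-th neighbour
in the joint space sets a local scale; neighbours strictly within it are
counted in the marginal spaces, and
$\mathrm{TE} = \psi(K) + \langle \psi(n_{y}+1) - \psi(n_{y,\mathrm{fut}}+1)
- \psi(n_{y,x}+1) \rangle$. Both source and destination may be
multivariate (3D velocity). A seeded uniform tie-breaking noise of
amplitude $10^{-10}$ is added before the neighbour searches. Negative
estimates are reported as computed — significance is judged only against
the shuffle null, never by sign. The default neighbour count is K = 8,
with a sensitivity sweep over K = 2..15 that reuses one pair of O(n²)
passes for the whole grid.

# Convergent cross mapping

Each series is delay-embedded with $\tau = 1$; the embedding dimension is
chosen per series by simplex projection (leave-one-out one-step
forecasts from the exponentially weighted average of E+1 neighbours'
futures, scored by Pearson correlation; ties go to the smallest E).
Cross-map estimates use the same weighting over E+1 library neighbours,
excluding the point itself (an optional Theiler window can exclude
temporal neighbours). Skill is the Pearson correlation between the
target and its estimate, with negative values clipped to zero.

The direction label follows the cause-recovery convention:
$C_{A \to B}$ is the skill of estimating A from the shadow manifold of
B, so a high $C_{2 \to 1}$ reads "agent 2's values are recoverable from
agent 1's dynamics", the signature of agent 2 driving agent 1 in
deterministic systems. Skill is swept over library sizes (default ten
log-spaced values), averaging over all sequential windows of each length
(capped at a configurable number of windows, subsampled with the
analysis seed beyond the cap); the headline value is the skill at the
maximum library size, annotated with a convergence diagnostic
(`converged` / `increasing` / `flat`, tolerance 0.02).

When the nearest library distance is zero, zero-distance neighbours
share the weight equally (the limit of the exponential weight rule);
this deterministic rule replaces noise injection so cross-map estimates
stay exactly reproducible.

# The control condition and significance

For each of `n_shuffles` (default 100) control datasets, pair ids are
scrambled by a uniformly sampled derangement — every front agent is
re-paired with a rear agent it never flew with — the longer series of
each pseudo-pair is tail-truncated to match the shorter, and the entire
preprocessing (concatenation, normalization) reruns before the metric is
recomputed. The 95% interval is the empirical 2.5/97.5 percentile range
of the null values (a normal approximation is available); a value is
*significant* only if it exceeds the upper limit strictly. Values inside
the interval are insignificant — deliberately conservative.

Leadership combines the two methods: agent *i* leads only if TE is
significant from *i* to *j* and insignificant in reverse, **and**
$C_{i \to j}$ is significant with $C_{i \to j} - C_{j \to i} \ge \delta$
(default $\delta = 0.2$, chosen so that a contrast like 0.75 vs 0.35
passes while a smaller significant-but-not-dominant skill does not).
Bidirectional TE significance always yields "none": two-way information
flow is the counterpart of no directed causal relationship.

# The synthetic test bed

The simulator is a test harness with controllable ground truth, not a
biological model. Each agent flies at constant speed; its own steering
is an Ornstein–Uhlenbeck angular velocity (intensity 1.5 rad/√s,
correlation time 0.35 s) modulated by a two-state maneuver/cruise
envelope (switching at 2/s, multipliers 0.3 and 2.2), so turning happens
in smooth, episodic arcs — white heading jitter, the more obvious
choice, turned out to carry no lag-one information in the curvature
magnitude at all, which would make every detection test vacuous.
Integration uses six substeps per output sample so that sampled
positions lie on a genuinely smooth path; with a polyline integrator the
spline's second derivative reflects the discretisation corners instead
of the flight's curvature (we measured ~50% distortion before making
this change).

Directed coupling is turn matching: a listening agent's applied angular
velocity is the convex combination
$(\mathrm{own} + c \cdot \mathrm{partner}) / (1 + c)$ of its own
steering and the partner's applied steering observed `delay` seconds
earlier (default 50 ms), with weight $c$ = gain × persistence (default
≈ 12, a strongly following regime). Mixing the partner's *turning*
directly into the listener's turning is what writes the coupling into
curvature — the variable the analyses read. Pure relaxation toward the
partner's heading, which we implemented first, integrates the partner's
turning and leaves no trace in one-step-ahead statistics of curvature at
any gain; the detection tests demanded the turn-matching form.

The shared environment has three parts, all scaled by `corridor_gain`
(default 0.3): relaxation toward a straight corridor axis, a slow
(0.5 s) pair-common steering disturbance, and a slow, smooth pair-common
maneuver gate (both bats turn harder in the same moments). The gate is
what makes an uncoupled pair's curvature series positively correlated;
it is smooth and slow deliberately, so that the destination's own
present screens it from lag-one transfer entropy and the control
condition stays calibrated. A fast or stepped shared gate measurably
inflates the false-positive rate — the trade-off between visible
environmental similarity and control calibration is real, and the
default sits on the calibrated side.

Per-pair seeds derive from one master seed; durations are jittered ±20%;
agent 2 enters 0.55 s after agent 1, leaving a co-presence window of
about 0.75 s (~130 samples per pair at 180 Hz), so a ten-pair group
yields an ensemble of ~1.3×10³ samples — the scale of the smallest field
group this design emulates.

# What passing tests do and do not show

The simulator produces magnitude (curvature) series with episodic
structure, sample-aligned pairs, and a ground-truth direction. It does
not reproduce real flight spectra, aerodynamics, obstacle interactions,
or sensory mechanisms; behavior labels on synthetic data are metadata
only. A pipeline that passes on it demonstrably recovers directed
coupling of this kind at field-data scale — it does not prove the same
power on real trajectories.

One limitation deserves emphasis. With stochastic agent dynamics, the
cross-map skills of the two directions are nearly symmetric: the
driver's manifold predicts the follower (whose turning is largely a
delayed copy) at least as well as the follower's manifold recovers the
driver, so the cause-recovery dominance that CCM shows on deterministic
systems (and that the logistic-map tests verify) is small or absent here.
We piloted deterministic chaotic steering (logistic-map and Lorenz-driven
turn amplitudes at several timescales); their determinism does not
survive the spline-differentiation measurement chain at 180 Hz with
τ = 1 embeddings, and interpolated variants introduce phase artifacts
that masquerade as reverse information flow. Consequently the combined
leadership verdict — which requires cross-map dominance of at least
δ = 0.2 on top of unidirectional TE — stays at "none" on most coupled
synthetic worlds even though the TE gates alone identify the direction
reliably. The end-to-end leadership recovery test records this honestly
rather than weakening the verdict rule.

# Numerical choices and problem sizes

* Tie noise (KSG): uniform, amplitude 1e-10, drawn from the analysis
  seed and recorded in the result metadata.
* Binning: equal-width over each variable's observed min–max range.
* Simplex and cross map: E+1 neighbours, exponential weights
  normalized to one; self-exclusion always, Theiler window optional.
* Library grid: ten log-spaced sizes from max(20, 10E) to the usable
  length; window average capped at 200 windows per size by default.
* Convergence tolerance 0.02 on the last two mean skills.
* Degenerate inputs: constant series fail normalization with an error
  naming the scope; empty co-presence windows drop the pair with a
  warning; metric failures inside the control loop are logged and the
  shuffle resampled (at most 10 retries).
* Test-suite problem sizes: closed-form KSG checks at n = 10⁴–2×10⁴;
  calibration over 200 uncoupled ten-pair worlds with 48-shuffle nulls;
  end-to-end leadership over 50+50 worlds with 30-shuffle controls and
  a six-point library grid. These are the package's own choices of
  simulation size for routine verification; the pipeline defaults
  (100 shuffles, full grids) remain larger.

# Interfaces

Everything is a data frame in and a tibble out: trajectories in the CSV
dialect above, `compute_kinematics()` → `extract_overlap()` →
`build_ensemble()` for preprocessing, `transfer_entropy_ksg()` /
`transfer_entropy_binned()` / `knn_sweep()` and `ccm_sweep()` for the
estimators, `scramble_partners()` / `null_distribution()` /
`significance()` for the control, and `analyze_group()` /
`analyze_groups()` for the orchestrated pipeline with `tidy()`,
`glance()` and `autoplot()` methods on every result type. The package's
functions plus `scripts/acceptance.R` are the complete interface; there
is no separate command-line tool.
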