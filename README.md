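# pairflight

Model-free inference of directed coupling and leadership in pairs of
flying animals, from nothing but their 3D trajectories.

When two animals fly together, does one of them lead? If the front
individual's turning drives the rear one's, their flight paths carry that
signature; if they merely share an environment (the same cave wall, the
same corridor of air), their paths are similar without any information
flowing between them. `pairflight` implements a complete analysis that
separates these cases using two model-free measures of directed coupling,
judged against a shuffled-partner control:

* **Transfer entropy (TE).** The information the source agent's present
  adds about the destination agent's next value beyond the destination's
  own present,

  `T_{X->Y} = sum Pr[y(t+1), y(t), x(t)] log { Pr[y(t+1) | y(t), x(t)] / Pr[y(t+1) | y(t)] }`,

  in nats. Estimated two ways: a plug-in binning estimator and the
  Kraskov–Stögbauer–Grassberger (KSG, algorithm 1) nearest-neighbour
  estimator of the conditional mutual information `I(Y_{t+1}; X_t | Y_t)`,
  with a sensitivity sweep over the neighbour count K (default grid
  2–15, reference K = 8).

* **Convergent cross mapping (CCM).** Delay-embed each series into its
  shadow manifold `(x(t), x(t-tau), ..., x(t-(E-1)tau))` (embedding
  dimension selected by simplex projection, tau = 1); cross-map skill is
  the Pearson correlation between a series and its estimate from the
  *other* series' manifold, clipped at zero, averaged over sequential
  library segments of growing size L. The direction label follows the
  cause-recovery convention: `C_{A->B}` is the skill of estimating A from
  the manifold of B.

* **Shuffled-partner control.** Each front agent is re-paired with the
  rear agent of a *different* pair (a random derangement), series are
  truncated to matching length, and the whole pipeline reruns per
  shuffle. A value is significant only above the 95% interval of the
  shuffle null — similarity that comes from the shared environment
  survives scrambling and is absorbed into the null.

The analyzed variable is the trajectory curvature
`rho = ||a_n|| / ||v||^2` (turning, in 1/m), computed from cubic-spline
resampled positions (default 180 Hz) with analytic derivatives; 3D
velocity is available as a multivariate TE variable. Leadership is
declared only when the two methods agree: significant unidirectional TE
plus dominant, significant cross-map skill in the same direction.

A self-propelled-particle simulator with configurable ground-truth
coupling direction (none / front-to-rear / rear-to-front / bidirectional),
gain, delay, and a shared-environment channel generates test beds for the
whole pipeline, so every stage is verifiable without any field data.

## Worked example

Simulate ten pairs in which the rear agent's turning drives the front
agent's (rear-to-front coupling), then run the full analysis:

```r
library(pairflight)

cfg <- sim_config(coupling_mode = "rear_to_front")
trajectories <- simulate_group(cfg, n_pairs = 10, seed = 1)
analysis <- analyze_group(trajectories, label = "demo", k = 8,
                          n_shuffles = 40, seed = 1)
analysis
#> Coupling analysis 'demo' (curvature, 10 pairs, ensemble length 1283)
#>   T_{1->2} = 0.0305 nats (k = 8): insignificant
#>   T_{2->1} = 0.0603 nats (k = 8): significant
#>   C_{1->2} = 0.463 at L = 1283 (converged): significant
#>   C_{2->1} = 0.607 at L = 1283 (converged): significant
#>   Leadership: none
```

Reading the output: information flows rear-to-front —
`T_{2->1} = 0.060` nats is above its shuffled-partner control interval
while `T_{1->2}` is inside it, which matches the simulated ground truth.
Cross-map skill is higher in the matching direction (0.607 vs 0.463),
but the margin is below the default dominance threshold (`delta = 0.2`),
so the combined leadership verdict stays conservative at `none` (see the
methods vignette for why cross-map dominance is systematically weaker
than TE asymmetry on stochastic flight dynamics).

`tidy()` and `glance()` return the results as tibbles; `autoplot()`
draws the K-sweep with its control ribbon, the CCM convergence curves,
and observed-versus-null histograms. `analyze_groups()` repeats the
analysis per behavior label plus the pooled set and `tidy()` on the
result gives a one-row-per-group summary table.

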