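---
title: "Methods: planning and scoring microgravity-simulator motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planning and scoring microgravity-simulator motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgsim)
```

## The physical model

A random positioning machine carries its samples on a two-axis gimbal. The
package fixes the following convention everywhere: the lab frame is z-up
with gravity $(0, 0, -g)$, $g = 9.80665\,\mathrm{m/s^2}$; the outer axis is
the lab $x$-axis; the inner axis is the $y$-axis of the outer frame. The
rotation mapping sample coordinates to lab coordinates is
$R = R_x(\alpha) R_y(\beta)$, and the gravity direction seen by the sample is

$$u = R^\top (0, 0, -1) = (\cos\alpha \sin\beta,\; -\sin\alpha,\;
-\cos\alpha \cos\beta).$$

The machine does not translate, so a sample mounted at offset $r$ (inner
frame) sits at $r_c(t) = R(t)\,r$; the pivot term of the general
decomposition $r_c = r_p + r_{pc}$ is retained in the data model but fixed
at zero. Velocity and acceleration follow from time derivatives. The
analytic acceleration uses the body angular velocity assembled from the
stored axis rates,
$\tilde\omega = (\dot\alpha\cos\beta,\; \dot\beta,\; \dot\alpha\sin\beta)$,
and its analytic derivative (not a numerical difference), giving the
centripetal-plus-Euler form
$a = R\,(\tilde\omega \times (\tilde\omega \times r) +
\dot{\tilde\omega} \times r)$. Forces on a control volume $V_c$ of density
$\rho$ are $F_a = m a$ and $F_g = m g$ with $m = \rho V_c$; other external
forces (fluid shear, magnetic) act at a far smaller scale on mounted flasks
and are not modeled.

A cross-check route computes the acceleration by second-order central
differences of the position series. Second order (rather than a
higher-order stencil) is deliberate: at the default sampling interval its
truncation error is well above double-precision rounding noise, so the
$O(\mathrm{d}t^2)$ agreement between the two routes is actually measurable —
the test suite fits the log–log error slope and requires $2 \pm 0.2$.

## Residual gravity

The quality of nullification is the running time average of $u$,
$\bar g(T) = \frac{1}{N_T}\sum_{t_k \le T} u(t_k)$, reported in units of
$g$. Its magnitude is identically the mean resultant length of the
direction sample, which gives partial-gravity control an exact handle: a
path whose mean resultant length is $\rho^\ast$ simulates $\rho^\ast g$.

## The three control schemes

**Random walk on the sphere** (`random_walk_sphere`): geodesic steps of
fixed arc (default 5°), turning exactly 90° left or right with probability
½ — the idealized description of conventional random positioning. Defaults
(5°, 10,000 steps) are chosen as a realistic discretization of a slow
laboratory RPM; neither value is critical and both are arguments.

**Conventional random axis control** (`classic_random_control`): each axis
independently holds a random rate, uniform in $[-\dot q_{max}, \dot
q_{max}]$, for a dwell uniform in 1–10 s, then ramps jerk-limited to the
next rate. The dwell range is a plausible controller epoch for a benchtop
machine; it reproduces the characteristic failure of random control: the
direction density concentrates at the gimbal poles ($u_y = \pm 1$ under the
package convention, since $u_y = -\sin\alpha$ and the time-marginal of a
spun angle piles its sine at $\pm 1$). On a dense path sample the
uniformity factor lands in the hundreds.

**Optimized uniform coverage** (`uniform_coverage_planner`). The published
behavior of optimized simulators — near-critical uniformity plus
monotone-envelope nullification — leaves the algorithm itself open, so the
planner is the package's own design:

1. *Waypoints.* Zero-gravity mode uses a spherical Fibonacci lattice of
   $M \approx$ duration / (reference move time) points, rotated by a seeded
   uniform random rotation (seed-dependence without losing low
   discrepancy). Partial-gravity mode draws $M$ waypoints from a von
   Mises–Fisher distribution about $-z$ with concentration $\kappa$ solved
   from $\coth\kappa - 1/\kappa = \rho^\ast$.
2. *Moves.* Between waypoints, inverse kinematics picks the gimbal branch
   nearest the current pose (at gimbal lock, $|u_y| = 1$, the redundant
   inner angle keeps its value), and each axis runs a seven-phase
   jerk-limited S-curve. The quicker axis profile is stretched in time to
   the common segment duration: stretching durations by $s$ and jerks by
   $s^{-3}$ keeps every limit satisfied while ensuring both axes move for
   the whole segment. This synchronization matters: if one axis parks near
   gimbal lock while the other sweeps, the direction crawls (its azimuthal
   speed carries a factor $\cos\alpha$) and the path over-dwells near the
   poles.
3. *Greedy compensation.* The planner tracks the exact running integral
   $S = \int u\,\mathrm{d}t$ of the emitted samples and chooses the next
   waypoint to keep $S$ close to $T\,m^\ast$, where $m^\ast$ is the target
   mean direction vector ($0$ in zero mode, $(0,0,-\rho^\ast)$ in partial
   mode). Contributions are estimated as (segment time) × (midpoint of
   current and candidate direction), with segment times from vectorized
   inverse-kinematics gimbal distances. Keeping $S$ bounded makes the
   residual decay as $\sim 1/T$ — through the $10^{-3}\,g$ level on runs of
   a few thousand seconds — rather than at the Monte-Carlo
   $1/\sqrt{T}$ rate of random control.
4. *Coverage balancing.* A two-axis gimbal cannot traverse near-polar
   azimuthal arcs quickly, so transit samples are mildly biased toward the
   pole caps even with synchronized axes. The greedy choice therefore
   considers all candidates whose compensation miss is within half a
   typical segment contribution of the best, and among them picks the one
   in the currently most under-covered equal-area cell (8 latitude rings
   about the pole axis). The slack bounds the extra drift of $S$ by $O$(one
   segment), preserving nullification, while waypoint placement cancels the
   transit bias. When the miss is large (recovery situations) the planner
   reverts to pure compensation, and the candidate pool is refreshed
   whenever fewer than a quarter of the waypoints remain, so the greedy is
   never stuck with leftovers.

Because compensation drives the running mean itself, partial-gravity
recovery is identity-based: the long-run mean resultant length matches
$\rho^\ast$ to well within the sampling tolerance (tests require 5% on
2000 s runs for $\rho^\ast \in \{0.1, 0.2, 0.4, 0.8\}$).

One consequence of compensation worth stating: the residual magnitude does
not decrease strictly monotonically. $|S|$ hovers around a bounded floor, so
$|\bar g| = |S|/T$ follows a decaying $\sim 1/T$ envelope with small
fluctuations at the floor. The tests therefore assert the bounded-integral
property (and a large net decay), not literal monotonicity.

## The uniformity factor and its reference level

For unit vectors $u_1,\dots,u_n$ with pairwise angles
$\Theta_{ij} = \arccos(u_i \cdot u_j)$ (dot products clamped to $[-1,1]$
before $\arccos$), the package computes the Ajne and Giné statistics

$$A_n = \frac n4 - \frac{1}{n\pi}\sum_{i<j}\Theta_{ij}, \qquad
G_n = \frac n2 - \frac{4}{n\pi}\sum_{i<j}\sin\Theta_{ij},$$

and combines them, by default, into the classical factor
$F^\ast = 4A_n + G_n$ (`normalization = "fn"`; the plain sum of a doubled
Ajne component and $G_n$ is available as `"sum"`). $F^\ast$ is rotation
invariant and grows without bound with concentration; the Rcpp kernel makes
the $O(n^2)$ pair sums cheap up to $n \sim 10^4$.

The widely quoted reference level for this statistic on the sphere is
3.633. Which null quantile it is, is not obvious from secondary sources, so
`calibrate_null()` settles it by Monte Carlo: under the default
normalization the null mean is $\approx 1.50$, the 95th percentile
$\approx 2.75$, and the **99th percentile $\approx 3.63$** (e.g.
`calibrate_null(100, 10000, seed = 1)` gives 3.656; at $n = 200$ with
20,000 replicates the estimate is 3.631). The package therefore treats
3.633 as the asymptotic upper 1% critical point of $F^\ast$: a path scoring
below it is not distinguishable from uniform at the 1% level. Under the
`"sum"` normalization no standard quantile reproduces 3.633 (null mean
1.0, p95 ≈ 1.72), which is why `"fn"` is the default rather than a silent
rescaling.

## Synthetic data and what the tests do (and do not) show

All inputs are generated in code: iid uniform directions (normalized
trivariate Gaussians) and von Mises–Fisher samples (standard inversion
sampler) for calibration and partial-gravity fixtures, plus the planners'
own trajectories. The study conditions used throughout tests and the
acceptance script are: 600 s runs at $\mathrm{d}t = 0.01$ s (60,001 states,
decimation 60 → 1001 direction samples) for short-horizon scoring; 10,000 s
at $\mathrm{d}t = 0.05$ s for the $10^{-3}\,g$ design level; 2000 s at
$\mathrm{d}t = 0.05$ s for partial-gravity recovery; calibration at
$n = 100$ with 10,000 replicates. Default motion limits are 60 °/s,
60 °/s², 120 °/s³ — a typical RPM operating envelope — converted to radians
internally (degrees appear only at the CLI boundary).

These synthetic conditions exercise the mathematics of the motion program,
not the machine: no motor/inertia dynamics, no structural vibration, no
fluid shear inside flasks, no sensor or timing jitter. Equality of
treatment is verified on symmetric synthetic mounting layouts (offsets
$\pm r$ along the inner axis), not on a specific machine's flask geometry.
Passing tests therefore certify the planned trajectory and its statistics;
they do not certify a physical device.

## Numerical choices

* Degenerate pair angles: dot products are clamped to $[\pm 1]$ before
  $\arccos$; $\sin\Theta$ is computed as $\sqrt{1 - d^2}$.
* S-curve segment times are grid-aligned (ceiling to $\mathrm{d}t$);
  endpoint states are set exactly, so planned trajectories are at rest at
  every waypoint to machine precision.
* Inverse kinematics unwraps both solution branches to the current pose and
  picks the smaller squared move; ties at gimbal lock keep the redundant
  angle.
* Trajectory/direction CSVs are written with 17 significant digits so a
  read-back reproduces the doubles exactly, and seeded runs are
  byte-identical.
* The von Mises–Fisher cosine inversion uses the
  $1 + \log(\xi + (1-\xi)e^{-2\kappa})/\kappa$ form, stable for large
  $\kappa$; $\kappa(\rho^\ast)$ is solved by `uniroot` on
  $[10^{-8}, 10^{8}]$.
* All seeded entry points save and restore the caller's RNG state.

## Known limitations

* The planner's uniformity and nullification figures are empirical
  properties of the greedy design, not guarantees; pathological limit
  settings (e.g. rates so low that a single move exceeds the run duration)
  raise an explicit infeasibility error instead.
* The uniformity statistics assume approximately independent samples; the
  default decimation (~1000 points per run) reduces, but does not remove,
  serial correlation. Scores on full-resolution paths are meaningful only
  as relative comparisons.
* Partial-gravity mode controls the *mean* gravity vector; it does not
  shape higher moments of the direction distribution beyond the von
  Mises–Fisher family.
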