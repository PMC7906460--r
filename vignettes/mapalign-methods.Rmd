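---
title: "Diffusion-map alignment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-map alignment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapalign)
```

## The model

`mapalign` treats each video frame of an interacting-agent system as a point
cloud under two different metrics and asks whether the two induced
macro-scale geometries are related. The assumption underlying the diffusion
map step is the standard one of manifold learning: the agents, viewed
through a metric, are samples from (a neighborhood of) a low-dimensional
manifold, so the normalized graph Laplacian built from pairwise affinities
approximates a diffusion operator whose leading eigenfunctions parameterize
the manifold's large-scale structure.

For a frame with $n$ agents and a metric $d$ the pipeline is:

1. **Kernel.** $K(x,y) = \exp\left(-d(x,y)^2 / (d(x,k(x))\, d(y,k(y)))\right)$,
   where $d(x, k(x))$ is the distance to the `k_nn`-th nearest neighbor,
   *excluding the point itself*. Self-exclusion matters: including the point
   would make `k_nn = 1` degenerate (zero bandwidth everywhere). The kernel
   is scale-free — rescaling all distances leaves it unchanged — so no
   global bandwidth is tuned per frame.
2. **Normalization.** The density normalization
   $A' = S^{-1} A S^{-1}$ with $S = \mathrm{diag}(\text{row sums})$, followed
   by row normalization to the Markov operator $\hat A$ (the $\alpha = 1$
   member of the Coifman–Lafon family, which removes sampling-density bias).
3. **Eigensolve.** Performed on the symmetric conjugate
   $D_h^{-1/2} A' D_h^{-1/2}$, which shares $\hat A$'s spectrum but is
   symmetric, so the spectrum is provably real and the eigenvectors are
   Euclidean-orthonormal. Orthonormality is not cosmetic: the analytic null
   of the alignment statistic models projections onto a *k*-dimensional
   subspace spanned by orthonormal vectors, and right-eigenvectors of the
   nonsymmetric $\hat A$ would not satisfy it. (An option retains the
   unit-normalized right eigenvectors for fidelity experiments.)
4. **Diffusion map.** $\psi_k = \lambda_k^t \phi_k$ with $t = 1$ throughout
   the pipeline; $t$ is exposed in the configuration for experimentation
   but every default and every reported statistic uses $t = 1$.

The trivial eigenpair ($\lambda = 1$, the near-constant stationary mode) is
removed by default. It carries no geometric information, and keeping it
would add a guaranteed-aligned mode to *every* pair of geometries,
inflating the alignment statistic between unrelated metrics; with it
removed, mode 1 is the first nontrivial diffusion coordinate.

## The alignment statistic and its null

For bases $\{\phi^{(1)}_j\}$ and $\{\phi^{(2)}_j\}$ the squared projection
$\|\Pi_k \phi\|^2$ of a fixed unit vector onto a uniformly random
$k$-dimensional subspace of $\mathbb{R}^n$ is beta distributed; the
standardization uses mean $k/n$ and variance $2(n-k)k/(n^3+2n^2)$. These
moments identify the shape pair as $(k/2, (n-k)/2)$, and that order is used
for sampling and density evaluation in `null_model()`. The reversed order
$((n-k)/2, k/2)$, which sometimes appears in descriptions of this law, has
mean $(n-k)/n$ and is inconsistent with the stated moments; rather than
silently resolving the ambiguity, the null-model object records the choice
and its justification in a `shape_note` field.

One subtlety the null ignores: bases from *real* data are all orthogonal to
their (removed) trivial mode, which concentrates near a common direction, so
the effective ambient dimension is slightly below $n$ and the null mean of
the squared projection is biased upward by $O(k/n^2)$. The bias is
negligible at the group sizes this package targets ($n \gtrsim 100$); the
null-calibration checks in the test suite and acceptance script therefore
use $n = 200$, which also matches the scale of tracked fish schools.

The statistic $Z_k$ uses a single $k$ for three roles — projection rank,
weight-vector length, and summation range — and the weights
$\hat u = (\lambda_1^{(1)}, \ldots, \lambda_k^{(1)})/\|\cdot\|_2$ are taken
from the retained (post-trivial-removal) spectrum at $t = 1$. If
$\lambda_1 \ldots \lambda_k$ are all numerically zero (e.g. the uniform
operator), the weights are undefined; `map_alignment()` then reports
$Z_k = 0$ with an `unweightable` flag rather than dividing by zero. The
statistic is intentionally asymmetric; the pipeline computes both
directions, and the incoherence gate uses the forward statistic
$Z_k(p, v)$ — position eigenvectors projected onto the velocity subspace —
which is the direction in which a velocity-driven reorganization of a
spatially coherent group is detected.

### Choosing $k$

`suggest_k()` automates the spectral-decay heuristic: the bulk of a noisy
diffusion spectrum decays like a power law, and modes rising above that
tail carry macro-scale structure. For each candidate cut $c$ the tail
$\lambda_{c+1}, \lambda_{c+2}, \ldots$ is fit by least squares on log-log
axes as a power law in its position *within the tail*
($\lambda_{c+m} \approx C m^{-\beta}$), and the smallest cut whose tail
stays within 20% relative error of the fit is returned. Fitting in
tail-relative position rather than absolute mode index makes the criterion
detect exactly the point where the power-law regime begins; a spectrum that
is a pure power law from the first mode yields $k = 1$ (at least one
macro-scale mode is always retained). With several frames' spectra, a
stability diagnostic reports the across-frame coefficient of variation of
each mode's variance-explained fraction $\lambda_j / \sum_i \lambda_i$:
modes whose fraction is stable across frames behave like noise. An
overestimate of $k$ is cheap — additional summands are nearly independent
of the leading structure and contribute standardized noise — so the
package's defaults err large ($k = 15$ for fish-scale data, $k = 10$ for
small simulated flocks).

## Metrics

* **Spatial proximity**: Euclidean, or the toroidal geodesic for the
  flocking model's periodic domain.
* **Velocity profile**: $d^{(2)}(i,j)^2 = \sum_{s=0}^{w-1} \kappa_s
  \|v_i(t{-}s) - v_j(t{-}s)\|^2$ with $\kappa_s \propto e^{-s/\tau}$
  normalized to sum to one. Defaults $w = 10$ frames, $\tau = 5$ frames:
  the window covers the "recent period" over which concerted motion is
  meaningful, and the exponential decay emphasizes the current motion while
  retaining enough history to separate persistent from momentary agreement.
  Both are configurable; the normalization makes a constant velocity offset
  $u$ register as exactly $\|u\|$ regardless of $w$.
* **Lagged velocity profile**: the minimum of the windowed distance over a
  shift $\ell \in \{0,\ldots,\ell_{max}\}$ applied to *either* agent's
  history. Minimizing over which agent is shifted guarantees symmetry,
  which the kernel requires; shifting only a designated agent would not.
  The lag search is a leader–follower device for empirical data
  ($\ell_{max} = 60$ frames = 2 s at 30 fps); it is not asserted to be a
  metric (the minimum of metrics need not satisfy the triangle inequality),
  which the diffusion-map construction does not require. The default is
  $\ell_{max} = 0$: the lag search multiplies per-frame cost by
  $\approx \ell_{max}$ and adds signal only when interactions are genuinely
  delayed, which is also why the end-to-end fixture analyses in the tests
  run unlagged.

Agents missing any frame of the required history window are dropped from
that frame's analysis and reported; fluctuating group composition is the
normal condition for tracked schools, not an error.

## Macrostate classification

Covariance vectors sort $|\xi_{ij}|$ in decreasing order, with exact ties
broken by row-major position — magnitude sorting removes eigenvector sign
ambiguity and index swaps under near-degenerate eigenvalues, and the
deterministic tie-break makes results bit-reproducible. Clustering is plain
k-means (10 restarts, recorded seed, best inertia kept); clusters are
renamed by descending within-cluster mean $Z$, so `G1` is always the most
organized macrostate and naming does not depend on k-means label order. The
gate $Z < 3$ marks frames incoherent: each standardized summand has unit
variance under the null, so 3 is a three-sigma-scale deviation — an
admittedly ad hoc threshold, exposed in the configuration. Frames with
fewer than `min_n = 30` complete-history agents are excluded before the
diffusion analysis: the kernel bandwidths and the beta null both assume a
moderate number of points.

## The flocking simulator

The Vicsek-type model updates every agent synchronously: the new heading is
the circular mean (angle of the summed unit heading vectors — never the
arithmetic mean of angles, which is wrong across the $2\pi$ wrap) of all
agents within toroidal distance $r$, *including the focal agent* (which
also prevents empty neighborhoods), plus one independent
$\mathcal N(0, \epsilon^2)$ draw per agent per step, added after averaging.
Defaults follow the standard study protocol: speed $v = 1/320$ torus units
per step, noise $\epsilon = \pi/5$, and coupling schedules holding
$r_0 = 0.0065$ before ramping linearly to $r_1 = 0.06$ (plus a
constant and an increasing-frequency sinusoid protocol). Neighbor search is
the naive $O(N^2)$ distance matrix, which at the $N \le 800$ scale of these
experiments is faster than maintaining spatial bins in R.

## What the fixture generators emulate — and what they do not

The fixtures are hand-rolled kinematic constructions, deliberately *not*
the flocking simulator, so ground truth is unambiguous and independent of
the method under test:

* **milling**: noisy circular orbits (radius 6–10 units, angular speed
  0.12 rad/frame) about a common centroid;
* **swarm**: mean-reverting jitter around fixed home points — nonzero
  individual speeds, no net group motion, no spatial structure in the
  velocities;
* **polarized-single**: rigid translation (1.2 units/frame, slowly
  wandering heading) plus a smooth stationary vector field over the group's
  cross-section (amplitude 0.15 units/frame) — the spatially correlated
  internal motion (shear, turning waves) that makes a real polarized
  school's velocity geometry mirror its spatial geometry;
* **polarized-split**: 2–3 subgroups with headings separated by 120°,
  launched so their paths cross mid-segment and stay spatially interleaved,
  with weaker internal field (0.04) and more individual noise — the
  velocity network splits into blocks that the spatial network does not
  resolve, reproducing the lower alignment of multi-group polarized motion.

Each generated segment is self-checked against its polarization/rotation
box ($O_p \le 0.35, O_r \ge 0.65$ for milling, etc.; per-subgroup
polarization for the split regime) in at least 90% of frames, and
regenerated under a fresh derived seed otherwise (bounded retries).
Sessions concatenate segments with fresh agent sets; group size is drawn
per session (base 80–240, per-segment fluctuation within 15%, clipped to
70–280), so size is autocorrelated within a session — as when tracking one
school — while spanning the realistic range across sessions. Stored
velocities are backward differences of positions, so positions and
velocities are exactly consistent. Frame rate is fixed at 30 fps so a 2 s
lag is 60 frames.

What the fixtures do **not** model: behaviorally realistic interactions
(no attraction/repulsion/alignment forces), gradual regime morphing
(segments switch discretely), within-segment tracking gaps (gap handling
is tested separately with masked frames), and arena boundaries. Passing
the end-to-end tests therefore demonstrates that the pipeline separates
geometrically distinct collective modes at realistic group sizes and noise
levels — not that it would classify any particular empirical dataset at
the same accuracy.

## Numerical choices

* Eigenvector signs are fixed by making each column's largest-magnitude
  entry positive; eigenvalue ties keep the (stable) solver order after the
  descending sort.
* Duplicate points (zero kernel bandwidth) are a hard error naming the
  offending pair; a tolerant mode floors bandwidths at
  $10^{-12} \cdot \mathrm{median}(D)$. The pipeline enables the floor for
  the velocity metric, where near-identical profiles are genuinely common
  in highly organized frames.
* More than one eigenvalue within $10^{-10}$ of 1 means the affinity graph
  is numerically disconnected; the basis is flagged and a classed warning
  (`mapalign_disconnected`) is emitted rather than an error, since
  downstream statistics remain well defined.
* Row-stochasticity is enforced to $10^{-10}$, basis orthonormality to
  $10^{-8}$, and the spectral reconstruction of $\hat A^t$ matches direct
  matrix powers to $10^{-8}$ (in practice to machine precision).

## Problem sizes used in validation

The test suite and acceptance script validate at deliberately scaled
sizes chosen to exercise the same regimes as the original study protocols
at desk-scale cost: null calibration at $n = 200$, $k = 15$ with 5000
draws; spectral oracles on 50 random clouds of up to 50 points; the
flocking ramp at $N = 200$ agents over 600 steps and 10 seeds (low plateau
200 steps, ramp 200 steps, high plateau 200 steps); the null MAS over 200
independent geometry pairs; and macrostate recovery on five four-regime
sessions of 60 frames per segment, analyzed at a stride of 6. These sizes
are the package's own validation choices and are stated here so they can
be scaled up by users with more patience.

## Known limitations

* The scale-free kernel conflates extreme organization with pure noise:
  when a metric's point cloud collapses (all agents moving identically),
  the rescaled distances measure only stochastic fluctuations. Tracking a
  raw scale statistic (e.g. mean inter-agent distance) alongside $Z_k$ is
  advisable in applications.
* The analytic null covers the individual standardized summands, not the
  distribution of $Z_k$ itself; the gate treats $Z$ heuristically, and no
  multiple-testing control is applied across frames.
* Dense eigensolves limit practical frame sizes to a few thousand agents.
* The covariance-vector fingerprint is sensitive to $k$ only weakly, but
  cluster *identities* across different recordings are not comparable
  without aligning the cluster centers.
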