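# mapalign

Unsupervised detection and classification of collective behavior in agent
trajectory data (fish schools, bird flocks, and other interacting-agent
systems), using diffusion maps.

## The problem and the method

Deciding *when* a group of agents is behaving collectively — and *which* mode
of collective behavior it is in — usually requires knowing the right
macro-scale order parameters in advance. `mapalign` needs only two metrics on
the agents, typically spatial proximity

d⁽¹⁾(xᵢ, xⱼ; t) = ‖pᵢ(t) − pⱼ(t)‖₂

and a kernel-smoothed distance between recent velocity profiles

d⁽²⁾(xᵢ, xⱼ; t)² = Σₛ κₛ ‖vᵢ(t−s) − vⱼ(t−s)‖₂², κₛ ∝ e^(−s/τ),

optionally minimized over a time lag so leader–follower pairs register as
close. Each metric's frame is turned into a diffusion map: a scale-free
gaussian kNN kernel K(x, y) = exp(−d(x,y)² / d(x,k(x)) d(y,k(y))) is
density-normalized to a Markov (heat) operator Â whose orthonormal
eigenvectors φₖ and eigenvalues λₖ give the diffusion coordinates
ψₖ = λₖᵗ φₖ. The leading coordinates are data-driven macro-scale variables.

Two geometries are compared by the **map alignment statistic (MAS)**. Each
leading eigenvector of metric 1 is projected onto the span of metric 2's
leading k eigenvectors; under the null of unrelated geometries the squared
projection of a unit vector in Rⁿ is beta distributed with mean k/n and
variance 2(n−k)k/(n³+2n²), so the standardized projection

Pₖ(φ) = (‖Πₖφ‖² − k/n) · √((n³+2n²) / (2(n−k)k))

is centered with unit variance, and the eigenvalue-weighted sum

Zₖ = Σⱼ ûⱼ Pₖ(φⱼ⁽¹⁾),  û = (λ₁,…,λₖ)/‖·‖₂

measures how much of metric 1's macro-organization is captured by metric 2.
Z near 0 means no shared structure; values of several null standard
deviations indicate emergent, codetermined organization.

Frames that clear an incoherence gate (Z ≥ 3 by default) are fingerprinted by
the **covariance vector**: the k² inner products ξᵢⱼ = ⟨ψᵢ⁽¹⁾, ψⱼ⁽²⁾⟩,
magnitude-sorted to remove eigenvector sign and index ambiguity, then
clustered by k-means into macrostates. The classical polarization/rotation
order parameters (O_p, O_r) and their milling / swarming / polarized
demarcation are included as the reference classification.

The package also ships a Vicsek-type flocking simulator on the unit torus
(time-varying coupling radius, ramp and chirp protocols) and kinematic
fish-school fixture generators (milling, swarming, single- and
split-polarized regimes with known labels), so the entire pipeline is
testable without tracking data.

## Worked example

Generate a labeled synthetic schooling session (four regimes, 90 fish, 60
frames each) and run the full pipeline:

```r
library(mapalign)

specs <- list(
  regime_spec("milling",          n = 90, duration = 60),
  regime_spec("swarm",            n = 90, duration = 60),
  regime_spec("polarized-single", n = 90, duration = 60),
  regime_spec("polarized-split",  n = 90, duration = 60)
)
session <- make_session(specs, seed = 7)

cfg <- pipeline_config(k = 15, stride = 5)
result <- run_pipeline(session$trajectories, cfg)
print(result)
#> <pipeline_result> 44 frames analyzed, 3 skipped
#> # A tibble: 4 × 3
#>   label n_frames mean_z
#>   <chr>    <int>  <dbl>
#> 1 G1          11 50.1
#> 2 G2          11 23.2
#> 3 G3          11  9.06
#> 4 N           11  0.400
```

The four macrostates recover the ground truth exactly: milling frames land in
G1 (the most organized cluster, mean Z ≈ 50), single-group polarized frames
in G2, split-group polarized frames in G3 (coherent but less aligned — the
velocity network splits into subgroups that the spatial network does not
resolve), and every swarming frame is gated to the incoherent group N
(mean Z ≈ 0.4, below the Z < 3 gate):

```r
library(dplyr)
tidy(result) |>
  left_join(session$labels, by = "frame") |>
  count(true_regime, label)
#>   true_regime      label     n
#> 1 milling          G1       11
#> 2 polarized-single G2       11
#> 3 polarized-split  G3       11
#> 4 swarm            N        11
```

`autoplot(result)` draws the Z timeline colored by macrostate. For
simulation studies, `flock_config()` + `run_flock_experiment()` /
`flock_ensemble()` track Z₁₀(p, v) and the mean-velocity order parameter
through coupling-radius protocols. A thin command-line wrapper with
`simulate`, `fixtures`, `analyze`, `align` and `report` subcommands is
installed at `inst/scripts/mapalign`.

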