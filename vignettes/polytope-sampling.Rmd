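---
title: "Sampling densities on convex polytopes with chordwalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling densities on convex polytopes with chordwalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chordwalk)
```

## The sampling problem

Many models in systems biology — metabolic flux spaces above all — live on
a convex polytope: the set $P = \{\theta \in \mathbb{R}^n : A\theta \le b\}$
cut out by mass balances, capacity bounds, and sign constraints. The
inference target is a probability density $f$ supported on $P$, which may
be the uniform density (unbiased exploration of feasible fluxes), a
Gaussian or mixture, or an arbitrary user-supplied log-density such as a
posterior backed by a simulator. General-purpose MCMC engines handle this
setting poorly: proposals that ignore the geometry either step outside the
polytope (high rejection) or creep along it (slow mixing). chordwalk
implements the family of *Hit-and-Run* samplers, whose moves are confined
to the feasible chord of a random line through the current point, so every
candidate is feasible by construction.

A `sampling_problem` bundles three ingredients:

* a `polytope` (the space the chain moves in, possibly preprocessed),
* a model object with a `log_density` (and optional `log_gradient`,
  `log_curvature` — the curvature slot is validated but not consumed by any
  shipped proposal; it exists so that curvature-based kernels can plug in),
* an optional `transform_record`, an affine map `full = basis %*% z + shift`
  linking the preprocessed space to the original one. The model is always
  evaluated in *original* coordinates; proposals act in *reduced* ones.

## Preprocessing

**Feasibility.** `chebyshev_center()` solves the largest-inscribed-ball
linear program; a positive radius certifies a nonempty interior, while an
infeasible program is raised as an error — this is the feasibility check.
The LP solver behind it is an internal dense two-phase simplex with Bland's
rule, which reports `optimal` / `infeasible` / `unbounded` explicitly; at
the problem sizes of interest (tens of rows) a dense tableau is the most
robust choice.

**Equality embedding.** Implicit descriptions (e.g. stoichiometric
steady-state constraints $Sx = c$) are eliminated by
`embed_equalities()`: a particular solution $x_0$ and an orthonormal
null-space basis $N$ of $S$ (both via SVD, with the standard numerical
rank rule $\sigma > \max(m,n)\,\varepsilon\,\sigma_{\max}$) give the
full-dimensional reduced polytope $\{z : (AN)z \le b - Ax_0\}$. The
Birkhoff polytope factory is this pipeline applied to the row/column-sum
constraints of doubly stochastic matrices; `birkhoff_polytope(5)` yields
the 16-dimensional reduced body, $(n-1)^2$ in general.

**Redundancy removal.** Each row is tested by maximizing $a_i x$ subject
to all other retained rows; rows whose optimum stays below $b_i -$ `tol`
(default `1e-9`, above LP tolerance and below meaningful constraint
differences) are dropped. Exact duplicates bound each other in that test
and would all be kept, so repeated normalized rows are deduplicated first.

**Rounding.** Anisotropic polytopes ruin isotropic proposals, so
`round_polytope()` reparametrizes the body to near-isotropy. Two methods
share one interface:

* `ellipsoid` (default, deterministic): damped Newton iteration on the
  log-barrier finds the analytic center; the inscribed Dikin ellipsoid
  there — the inverse square root of $\sum_i a_i a_i^\top / s_i^2$ with
  slacks $s_i$ — is the constraint-weighted least-squares approximation of
  the maximum inscribed ellipsoid and becomes the new coordinate system.
* `covariance_svd` (stochastic): alternate short uniform runs of
  coordinate Hit-and-Run (50 steps per dimension per iteration) with
  recomputing $U\Sigma U^\top$ of the regularized sample covariance
  (ridge $10^{-12}\,\mathrm{tr}/n$ guards rank deficiency early on),
  composing the transform with $U\Sigma^{1/2}$, until the singular-value
  ratio changes by less than 5% between iterations (at most 10).

The first iteration always runs: the cheap enclosing-ball estimate used as
a quality gate (inscribed radius over the largest axis chord half-length,
threshold 0.2 — an engineering default) is blind to anisotropy that is not
axis-aligned, such as a rotated elongated box, so it only gates *extra*
iterations. The final transform is rescaled so the rounded body contains
the unit ball at the origin. Rounding never changes the point set — it is
an invertible affine change of variables, recorded and composed with any
earlier embedding, and all returned draws are mapped back to original
coordinates.

## The proposal marketplace

Proposals satisfy one minimal contract: `propose(rng, x)` returns a
candidate plus a log Hastings correction (the log ratio of reverse to
forward proposal densities, 0 for symmetric kernels); `advance(x)` is the
engine's after-step notification used by adaptive kernels;
`snapshot()`/`restore()` expose mutable state for checkpointing; tunable
kernels expose `step_size`. Registering a constructor under a name
(`register_proposal()`) makes any third-party kernel usable from the
engine, the tuner, and the CLI.

Shipped kernels:

* **`hit_and_run`** — direction uniform on the sphere, candidate uniform
  on the feasible chord. Because the chord is a property of the line, not
  of the point on it, the kernel is symmetric, and the Metropolis
  acceptance reduces to the density ratio; uniform targets accept every
  move.
* **`coordinate_hit_and_run`** — same, along a uniformly chosen coordinate
  axis; with rounding and thinning this is the CHRRT scheme standard in
  flux sampling.
* **`gaussian_hit_and_run`** — the step along the chord is
  $\mathcal{N}(0, s^2)$ truncated to the chord by rejection (100 tries,
  then the chain stays put and the event is counted). Truncation makes the
  kernel *asymmetric*: the truncated-normal mass $Z(x)$ differs between
  current and candidate point. The proposal therefore reports the exact
  correction $\log Z(x) - \log Z(y)$. We chose exactness over the common
  simplification of declaring the kernel symmetric: the bias of the
  uncorrected kernel concentrates near the boundary and is visible in
  long runs, while the correction costs two normal CDF evaluations. With
  the correction in place the 50-bin stationary law of a $10^6$-step 1D
  chain matches the quadrature-binned target to total variation
  $\approx 0.002$.
* **`over_relaxed_hit_and_run`** — reflects the current point through the
  chord midpoint, $\lambda' = \lambda_{\min} + \lambda_{\max}$:
  deterministic given the direction, self-inverse, and uniform-law
  preserving. The method is only correct for uniform targets, which is
  enforced at construction rather than silently wrong. The antithetic
  character is exact in one dimension (the reflection is $x \mapsto 1-x$
  on $[0,1]$, lag-1 autocorrelation $-1$) and shows up in higher dimension
  as a higher effective sample size than the plain chord-uniform kernel;
  per-coordinate lag-1 autocorrelations in a hypercube remain positive,
  because each reflection moves the state only along one random line.
* **`adaptive_svd`** — learns the target's shape instead of rounding up
  front: a Welford running mean/covariance of visited states feeds an SVD
  $U\Sigma U^\top$ every `update_interval` steps, and directions are drawn
  as $U\Sigma^{1/2}z$ (normalized). After `adaptation_horizon` total steps
  the transform is *frozen*; finite adaptation makes the post-freeze chain
  an honest Markov chain, and the engine reports the pre-freeze stretch as
  `burn_in_draws` rather than discarding anything silently. With a single
  observation the covariance is undefined and the kernel falls back to
  isotropic directions.

The precise over-relaxation and adaptive-SVD update rules are this
package's interpretations of methods known in the literature by name; the
chord-midpoint reflection was chosen because it is unambiguous,
self-inverse, and measure-preserving, and freeze-after-horizon because it
is simple and verifiably correct, unlike diminishing-adaptation schedules
whose validity is harder to audit.

## Engine, tempering, tuning, reproducibility

`metropolis_step()` applies the filter
$\log\alpha = \min(0, (f(y) - f(x))/T + \text{correction})$, rejecting
out-of-polytope candidates *before* any model evaluation. `-Inf` from a
model is a legal zero-density value; `NaN` raises an error naming the
offending point — the distinction separates intent from bugs.

`sample_polytope()` runs chains on independent PCG64 streams (64-bit
output, 128-bit state, period $2^{128}$; stream k of a seed drives chain
k), records every `thinning`-th state, and returns draws in original
coordinates together with per-chain acceptance rates. Determinism is
defined over (seed, stream), never over scheduling. Default starts jitter
the Chebyshev center inside a tenth of the inscribed ball. Normal deviates
use the inverse-CDF transform, so a chain's entire future is determined by
the 256-bit generator state — this is what makes checkpoints exact:
`checkpoint_chain()` serializes position, cached log-density, proposal
internals, counters and RNG state behind a schema tag and an Adler-32
checksum, and a restored chain reproduces the uninterrupted draw stream
bit for bit.

`parallel_tempering()` runs one chain per temperature against $f/T_k$ on
the *same* polytope — the support is never tempered, so even the hottest
chain stays feasible, and $T \to \infty$ tends to uniform-on-polytope.
Adjacent pairs (alternating even/odd offsets) swap with
$\log\alpha = (1/T_i - 1/T_j)(f(\theta_j) - f(\theta_i))$. Ladders are
validated as starting at 1 and non-decreasing; equal adjacent temperatures
are permitted (they swap with probability one) rather than rejected, which
keeps degenerate ladders usable in tests. A one-temperature ladder
reproduces `sample_polytope()` exactly, a useful equivalence check. The
geometric default ladder and adjacent-pair scheme are this package's
choices; on the shipped bimodal fixture (two Gaussians, sd 0.03, in the
unit square) the ladder $(1, 4, 16, 64)$ gives cold-chain mode occupancy
near 1/2 in $2 \times 10^4$ sweeps while the same kernel without
tempering, at the same total model-evaluation budget, never leaves its
starting mode.

`tune_step_size()` is Robbins–Monro on the log step size,
$\log s \leftarrow \log s + \gamma_k(\hat r_k - r^\*)$ with
$\gamma_k = 2/(k+1)$ over batches of 100 steps; the default target 0.234
is the classical random-walk optimum. Note that acceptance is bounded away
from zero for chord-truncated kernels — on a broad target the large-step
limit of `gaussian_hit_and_run` behaves like the chord-uniform kernel and
may accept well above the requested rate, in which case no step size
attains the target and the tuner drifts upward; pick targets compatible
with the target's peakedness.

## Diagnostics

`split_rhat()` is the classic split Gelman–Rubin statistic on half-chains
(the rank-normalized variant would be a straightforward extension; the
classic form is what the flux-sampling literature reports).
`effective_sample_size()` averages per-chain autocorrelations of centered
draws and truncates with Geyer's initial positive sequence, capped at the
total draw count. All-constant chains yield `NA`/1 with a `degenerate`
flag instead of an error. Calibration: iid chains recover
$\hat{R} \le 1.01$ and ESS $\approx N$; an AR(1) chain with
$\rho = 0.9$ at $N = 10^5$ matches the closed form
$N(1-\rho)/(1+\rho)$ within a few percent. `summary()` on a sample batch
gives per-dimension mean, sd, 2.5/50/97.5% quantiles, $\hat R$, ESS and
acceptance; draws are stored as (chain, draw, dimension) arrays, directly
consumable by standard MCMC-analysis tooling.

## Synthetic fixtures: what they do and do not show

`make_fixture()` generates every input the package is tested with:
hypercubes and simplices (closed-form moments), the Birkhoff polytope
(known intrinsic dimension), a seeded randomly *rotated* box with
anisotropy 100 (`stretched_box` — rotation matters, because an
axis-aligned box is a fixed point of coordinate Hit-and-Run and would hide
the benefit of rounding), a random half-space polytope built so that the
sampled probe points and the origin remain feasible (nonempty and bounded
by construction), and the bimodal Gaussian mixture. Each manifest records
analytic ground truth (dimension, Chebyshev data, moments) and is verified
against the library's own computation at generation time.

These fixtures exercise geometry, multimodality and anisotropy at desk
scale (dimensions up to ~16–25, constraint counts in the tens). They do
not emulate what makes real flux spaces hard: thousands of constraints,
extreme aspect ratios beyond $10^2$, nearly degenerate facets, or
expensive simulator-backed posteriors. Passing tests demonstrate
correctness of the machinery, not performance at genome scale.

## Numerical choices

* Strict-interior margin for chord origins and chain starts:
  slack $\ge 10^{-12}(1 + |b_i|)$, avoiding zero-length chords at facets.
* Membership filter tolerance $10^{-9}$; stored draws satisfy it always.
* Directions of norm below $10^{-300}$ are redrawn.
* Truncated-normal rejection is capped at 100 tries; exhaustion leaves the
  chain in place and increments a counter reported in the batch metadata.
* Problem sizes in the default test run: $2\times10^4$ draws for moment
  checks, $10^6$ steps for the 1D stationarity oracle, $2\times10^4$
  tempering sweeps, $10^4$ draws for the rounding comparison — chosen to
  hold Monte Carlo error near or below the tolerance being asserted.

## Limitations

* No vertex enumeration, volume computation, or exact rational arithmetic.
* No gradient/curvature-consuming (Riemannian) or reflective kernels;
  the interface slots exist, the algorithms do not.
* Plugin models are a library-level seam; the CLI constructs only the
  named built-ins.
* Integrability of a user-supplied log-density on the polytope is the
  user's responsibility and is not checked.
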