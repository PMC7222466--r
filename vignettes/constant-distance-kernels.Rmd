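---
title: "Constant-distance proposal kernels for relaxed-clock MCMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constant-distance proposal kernels for relaxed-clock MCMC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(constclock)
```

## The model and the problem the kernels solve

`constclock` samples the joint posterior of a rooted time tree $g$ (node
ages $\mathbf t$, contemporaneous or dated tips), per-branch evolutionary
rates $\mathbf r$, and substitution/clock hyperparameters
$\boldsymbol\Phi$, under an uncorrelated log-normal relaxed clock: each
branch rate is an independent draw from
$\mathrm{LogNormal}(m, s_1)$, usually with the real-space mean pinned at 1
($m = -s_1^2/2$).  The phylogenetic likelihood enters only through the
genetic distances $d_i = r_i \,\Delta t_i$ (expected substitutions per
site), because the per-branch transition matrix is $e^{\mathbf Q d_i}$.

Posterior draws of $(\mathbf t, \mathbf r)$ are therefore strongly and
negatively correlated branch by branch: the data pin $d_i$, while the
factorization into rate and duration is informed mainly by the priors.
Naive random-walk moves on a single age or rate fight this correlation
step by step.  The kernels in this package move *along* it: a node age is
perturbed and the adjacent rates are rescaled deterministically so that
every implied genetic distance is unchanged.  For a time-reversible
substitution model the likelihood is then exactly constant under the
move, so the proposal explores the rate-time ridge at no likelihood cost.

Four kernels cover the tree:

* **internal node** (`propose_internal_node`): $t_X' = t_X + a$,
  $a \sim U[-w, w]$, with the three adjacent rates rescaled by their old
  over new spans.  Green ratio
  $\alpha_{IN} = \frac{t_P - t_X}{t_P - t_X'} \cdot
  \frac{t_X - t_L}{t_X' - t_L}\cdot\frac{t_X - t_R}{t_X' - t_R}$,
  the Jacobian determinant of the map
  $(t_X, r_X, r_L, r_R)\mapsto(t_X', r_X', r_L', r_R')$.
* **simple distance** (`propose_simple_distance`): the same move on the
  root, rescaling the two root branch rates
  ($\alpha_{SD}$ drops the parent factor).
* **small pulley** (`propose_small_pulley`): at fixed ages, slides
  genetic distance between the two root branches,
  $d_L' = d_L + b$, $b \sim U[-v, v]$, keeping $D = d_L + d_R$.  The rate
  map has identity Jacobian, so $\alpha_{SP} = 1$ exactly.
* **big pulley** (`propose_big_pulley`): re-hangs the root onto a
  neighbouring branch of the underlying unrooted tree (changing the
  rooted topology) while proposing new ages for the root and its internal
  child and a new distance split; all tip-pairwise distances are
  conserved.  $\alpha_{BP} = \mu \prod_{i} \Delta t_i / \Delta t_i'$ over
  the four re-rated branches, with $\mu$ the reverse/forward
  topology-selection ratio.

Because a deterministic rate map accompanies each random displacement,
plain Hastings ratios do not apply; the acceptance uses the
Metropolis-Hastings-Green form with the Jacobian determinant of the map.
Every analytic ratio in the package is checked against a
finite-difference Jacobian in the test suite (relative error $\le
10^{-6}$ over a thousand random states per kernel).

### Reconstruction of the big-pulley selection rule

The selection among candidate re-rootings is implemented as follows.  On
a *symmetric* tree (both root children internal) each of the four
grandchild promotions is chosen with probability $1/4$.  On an
*asymmetric* tree (one root child a tip) the internal child $O$ has
grandchildren $G_1$ (elder) and $G_2$: if the proposed new age of $O$
falls below the elder grandchild's age, promoting $G_1$ is the only move
that can produce a valid tree and is selected with probability 1;
otherwise the two promotions are chosen with probability $1/2$ each.  The
reverse-selection probability is evaluated by the same rule on the
proposed tree (the restored age of the demoted node plays the role of the
proposed age), and $\mu$ is their ratio.  Note the forced branch can only
matter when the elder grandchild is older than age zero, i.e. an internal
node or a dated tip.  This rule is validated two ways: the
$\mu(g\to g')\,\mu(g'\to g) = 1$ and mirror-move round-trip identities,
and -- decisively -- the prior-sampling comparison below, which would
detect any selection-probability error as a biased stationary
distribution over the three rooted topologies.

There is no identity proposal in this reconstruction: the exchange step
always re-hangs the root, so even zero displacements produce a different
rooted tree.  Reversibility is therefore tested through mirror pairs
rather than a null move.

## Validating samplers against quadrature, and the two density conventions

The package ships five small fixtures (`make_fixture`) on the three-taxon
tree (tips A, B, C; internal node D; root E) with fixed genetic
distances, so that a prior-only chain driven by a single kernel lives on
a one- (or, for the big pulley, three-) dimensional manifold whose
stationary density can be computed by numerical integration
(`marginal_internal_node`, `marginal_root_time`, `marginal_small_pulley`,
`marginal_big_pulley`).  Chain and quadrature are compared by
`compare_chain_to_oracle` (mean within $3\times$ Monte-Carlo SE, plus a
Kolmogorov-Smirnov check on a subsample thinned to about two
autocorrelation times).

Two density conventions appear here, and conflating them is the easiest
way to "validate" a sampler incorrectly:

1. **Reference densities** (`change_of_var = FALSE`): the product of the
   log-normal rate densities evaluated at the implied rates
   $d_i/\Delta t_i$ of the varying branches (times the coalescent factor
   where the fixture records it).  These are densities *defined directly
   on the manifold coordinate* ($t_D$, $t_E$, or the distance split).  A
   Metropolis chain with symmetric moves on that coordinate and plain
   density-ratio acceptance samples exactly this law
   (`sample_fixture_prior(..., target = "reference")`), and its moments
   are the fixtures' recorded validation statistics.
2. **State densities** (`change_of_var = TRUE`): the stationary law of
   the full MHG kernel -- Green ratio included -- under the
   coalescent-times-rates prior on $(\mathbf t, \mathbf r)$.  Restricted
   to the manifold coordinate this acquires one $1/\Delta t_i$ factor per
   rescaled branch (the change of variable from rates to the
   coordinate).  The engine chains (`run_chain` in `"prior"` mode with
   the real operator objects) and
   `sample_fixture_prior(..., target = "state")` are tested against this
   variant.

Both comparisons are run in the test suite; the first validates the
fixtures' reference statistics and displacement logic, the second
validates the Green ratios *in distribution*, which is the strongest
whole-kernel check available.

Fixture particulars worth knowing:

* For the small pulley the conserved sum $D = 0.67$ splits across the two
  root branches with time spans $t_E - t_D = 9$ and $t_E = 10$; the
  recorded reference statistic (mean $0.3476$, sd $0.0494$) belongs to
  the span-$t_E$ branch, and `marginal_small_pulley` reports that branch
  by default (its mirror image is available via `variable = "d_D"`).
* The `big_pulley` fixture's reference distribution is defined with the
  coalescent factor active and a wider rate spread ($s = 0.5$), unlike
  the 1-D fixtures, whose reference distributions are defined by the
  rate prior alone ($s = 0.25$).  These settings are stored in the
  fixture object; the oracle and the chains both read them from there,
  so the two sides of every comparison always use the same density.

## Priors

* `lognormal_prior(m, s)`: parameters in log space.
* `coalescent_prior(N)`: constant population size; an interval with $k$
  lineages contributes rate $\binom{k}{2}/N$, e.g. for three taxa
  $p(t_E, t_D) = \frac1N e^{-(t_E-t_D)/N}\cdot\frac1N e^{-3 t_D/N}$.
* `yule_prior(lambda)`: pure birth over labelled histories; the interval
  with $k$ lineages is $\mathrm{Exp}(k\lambda)$.  Only relative densities
  matter in the chain; the simulator (`simulate_yule_tree`) draws from
  the same construction it scores.
* `clock_model(s1)` with a gamma hyperprior on $s_1$ (shape 0.5396,
  scale 0.3819 by default).

## The clock standard-deviation operator

`propose_stdev_and_rates` rescales $s_1$ by
$\mathrm{scale} = F + \xi(1/F - F)$, $\xi\sim U(0,1)$, and maps every
branch rate through quantile matching
$r_i' = \mathrm{icdf}_{s'}[\mathrm{cdf}_{s}(r_i)]$ so each rate keeps its
percentile under the mean-one clock.  The Hastings term is
$-\log(\mathrm{scale}) + \sum_i \log \partial r_i'/\partial r_i$, with the
product over the state's actual branch rates ($2n-2$ on a rooted binary
tree -- the Jacobian must match the dimension of the transformed
variables, which the finite-difference test enforces).  Under the
mean-one constraint the quantile map has the closed form
$\ln r' = -s'^2/2 + (s'/s)(\ln r + s^2/2)$; the generic cdf/icdf route is
required to agree with it to $10^{-10}$, a strong oracle for both.  The
operator rejects if any mapped rate is non-finite.

## Dating on a fixed unrooted tree

When branch lengths in substitutions are treated as known without error,
the unrooted tree *is* the data: `midpoint_root` places the root at the
midpoint of the diameter path (ties broken by the lexicographically
smallest taxon pair, for determinism), and
`init_times_rates_from_unrooted` assigns node ages proportional to depth
rank scaled into $(0, H]$ and derives rates as length over span, so every
branch product reproduces its input length exactly.  Any consistent
assignment is an equally valid chain start; the distances, not the
particular starting times, carry the information.  In the engine's
`"fixed-distances"` mode the likelihood term is omitted (it is constant
under distance-preserving kernels) and the run-configuration validator
refuses distance-changing operators.  This mode is restricted to
contemporaneous tips, since midpoint rooting has no natural definition
for dated tips.

## The scaled well-calibrated study

`well_calibrated_study` simulates parameters from the priors
($s_1 \sim$ gamma, $\lambda, \kappa \sim$ log-normal,
$\boldsymbol\pi \sim$ Dirichlet), a Yule tree, mean-one log-normal rates
and an HKY alignment; re-infers with the same model; and checks that the
true values fall in the 95% HPD intervals at the binomial rate.  Study
conditions: 20 taxa, 50 replicates, 100 sites, 32,000 steps per
chain sampled every 15 with a 25% burn-in.  The topology is held at
the truth during re-inference (no general topology moves are included;
the big pulley, which re-roots, is validated by the prior-sampling
oracles instead), so the study checks calibration of the continuous
parameters conditional on topology -- a valid conditional model.  The
analysis schedule mixes the constant-distance kernels with standard
helper moves (log-rate random walk sized to the replicate's clock
spread, node-age moves, an up-down scale that multiplies all ages and
divides all rates -- itself distance-preserving -- and two
$s_1$ operators: the quantile-matching one and a cheap plain scale).
Replicates whose tree-height ESS falls below 20 are flagged in the
output rather than silently pooled.

What the generator does *not* emulate: site-rate heterogeneity,
partitioned data, selection, indels/ambiguity, misspecified clocks, or
topology uncertainty.  Passing coverage therefore demonstrates the
internal consistency of the sampler under its own model at desk scale,
not robustness on real data.  The deliberate-miscalibration hook
(`misspecify_rate_mean`) provides a negative control: generating rates
with real-space mean 3 while analysing under the mean-one clock drives
tree-height coverage to essentially zero, confirming the study has power
to detect a broken sampler.

## Numerical choices

* Quadrature: adaptive 1-D integration at relative tolerance $10^{-10}$
  to $10^{-12}$; the unbounded root-age marginal is truncated where the
  integrand falls 14 orders of magnitude below its bulk and the
  truncation is doubled in tests without visible change.  The 3-D
  big-pulley density uses a tensor Gauss-Legendre rule (300 x 120 x 60
  nodes by default) whose moments are stable to grid refinement at
  $10^{-6}$.
* HKY transition probabilities use the closed-form eigenstructure with
  the generator normalized to one expected substitution per unit
  distance; they are tested against a generic scaling-and-squaring
  matrix exponential at $10^{-10}$.  Site independence, no rate
  heterogeneity across sites.  Ambiguity codes and gaps are
  full-uncertainty partials.
* The pruning engine caches per-node partials and recomputes only the
  ancestors of branches whose distance changed; re-rooting moves
  invalidate the cache without recomputing the (unchanged) likelihood.
  Partial rescaling is engaged only beyond 60 taxa, where underflow
  becomes possible.
* ESS uses $n / (1 + 2\sum\hat\rho_k)$ with the autocorrelation sum
  truncated at the first non-positive lag, clamped into $[1, n]$;
  constant series report 1 with a degenerate flag.
* Out-of-bounds proposals are rejected, never resampled; invalid
  proposals are tallied separately in the operator bookkeeping.
* HPD intervals are the shortest window containing 95% of the sorted
  draws.

## Known limitations

* No general topology samplers (subtree-slide, Wilson-Balding, ...): full
  topology inference is out of scope; the big pulley only relocates the
  root within a fixed unrooted tree.
* The kernels assume a binary rooted tree with strictly positive spans
  and rates; polytomies and zero-length branches are rejected by the
  validator.
* The pulley moves require a time-reversible substitution model; with a
  non-reversible model the likelihood would not be invariant under
  re-rooting.
* The specialized fixture chains exist for validation speed; for
  anything beyond the fixtures, use `run_chain` with operator objects.
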