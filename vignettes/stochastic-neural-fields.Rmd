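---
title: "Stochastic neural fields: from master equations to the Wilson–Cowan limit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic neural fields: from master equations to the Wilson-Cowan limit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuralfield)
```

## The models

This package simulates and cross-verifies three descriptions of the same
neural tissue, at three levels of resolution.

**Microscopic model.** A bounded spatial domain $D \subset \mathbb{R}^d$
is tiled by $P(n)$ convex cells $D_{k,n}$; cell $k$ holds a population of
$l(k,n)$ two-state (active/inactive) neurons, and $\Theta_t^k \in
\mathbb{N}_0$ counts its active neurons. Transitions are Markovian:
deactivation at constant rate $\tau^{-1}$ per active neuron, and
activation of population $k$ at rate
$$\tau^{-1}\, l(k)\, f\Big(\textstyle\sum_j \bar W_{kj}\,\theta_j/l(j) +
\bar I_k(t)\Big),$$
where $f$ is a bounded, Lipschitz, non-negative gain function, $\bar
W_{kj}$ is the double cell average of a connectivity kernel $w(x,y)$, and
$\bar I_k(t)$ the cell average of an input field $I(t,x)$. With
time-dependent input the chain is inhomogeneous; the space–time process
$(\Theta_t, t)$ is a piecewise deterministic Markov process whose only
continuous coordinate is time itself.

**Macroscopic limit.** The coordinate map $\nu^n(\theta) = \sum_k
(\theta_k/l(k))\,\mathbf 1_{D_k}$ embeds the state into $L^2(D)$ as a
field of active fractions. As the partition refines
($\delta_+(n) \to 0$) and populations grow ($\ell_-(n)\to\infty$), the
embedded process converges — uniformly on compacts in probability — to
the solution of the Wilson–Cowan equation
$$\tau\,\dot\nu(t,x) = -\nu(t,x) +
f\Big(\int_D w(x,y)\,\nu(t,y)\,dy + I(t,x)\Big).$$

**Fluctuations.** The compensated process
$M_t = \nu^n_t - \nu^n_0 - \int_0^t \tau^{-1}\big({-\nu^n_s} + \bar
F_n(\nu^n_s, s)\big)\,ds$ is a martingale carrying all of the
stochasticity. Rescaled by $\rho_n = \sqrt{\ell_-(n)/v_+(n)}$ it
converges (in dual Sobolev norms $H^{-\alpha}$, $\alpha > d$) to a
centred diffusion with covariance
$$\langle C(t)\varphi, \varphi\rangle = \int_0^t\!\!\int_D
\varphi(x)^2\, \tau^{-1}\big(\nu(s,x) + f(\textstyle\int w\,\nu\,dy +
I)\big)\,dx\,ds.$$
Substituting the limit back into the decomposition gives two stochastic
field equations with noise amplitude $\varepsilon_n = 1/\rho_n$: the
*linear-noise* approximation (diffusion coefficient frozen on the
deterministic solution; additive) and the *Langevin* approximation
(coefficient on the current state; multiplicative). Both collapse to the
Wilson–Cowan equation as $\varepsilon_n \to 0$, and neither reproduces
the mean of the jump model exactly unless the gain is affine.

## What the package verifies, and how

Each limit statement above is asymptotic; at desk scale the package
checks the three things that are checkable exactly or statistically:

1. **Exact finite-$n$ identities.** The Itô isometry
   $\mathrm{Var}[(M_T,\varphi)] = \mathbb E\,[\tau^{-1}\sum_k
   l(k)^{-2}(A_k + l(k)B_k)(\int_{D_k}\varphi)^2]$, with $A_k = \int_0^T
   \Theta^k_s\,ds$ and $B_k = \int_0^T \bar f_k(\Theta_s,s)\,ds$
   accumulated exactly by the simulator, holds at every $n$; likewise the
   affine-gain moment closures (the mean system is the spatially
   discretized Wilson–Cowan equation, solvable by matrix exponential).
2. **Distributional laws.** A single constant-gain population is an
   immigration–death process with Poisson$(l\,c)$ stationary law; the
   first waiting time from a frozen state is exponential at the total
   rate. These validate the thinning simulator's exactness.
3. **Trends.** Errors along a refining partition family must shrink:
   $\mathbb E \sup_t \|\nu^n_t - \nu(t)\|$ in $L^2$ and $H^{-1}$
   (`run_lln`), the long-horizon mean error (`run_longtime`), and the
   gap between the finite-$n$ quadratic variation and $\langle
   C(T)\varphi,\varphi\rangle$ (`run_clt`). Only gap shrinkage is
   asserted, not equality at fixed $n$ — the theorems are limits.

## Exact simulation by thinning

Between jumps the state is frozen, so the total rate
$\lambda(\theta, t) = \tau^{-1}\sum_k \theta_k + \sum_k a_k(\theta, t)$
is bounded by the majorant $\bar\lambda(\theta) = \tau^{-1}(\sum_k
\theta_k + \|f\|_0 \sum_k l(k))$, which uses only the declared supremum
of the gain. Candidates proposed at rate $\bar\lambda$ and accepted with
probability $\lambda/\bar\lambda$ give an exact sample of the
inhomogeneous chain (for time-constant input the acceptance test is
still performed; for constant gain it always accepts). Event selection
is inverse-CDF over the $2P$ events in a fixed order (deaths by cell,
then births by cell), so a trajectory is a deterministic function of the
seed. Every replicate runs on its own stream keyed by
`replicate_seed(seed, r)`, making ensembles reproducible
replicate-by-replicate.

The compiled core covers the gain presets and constant/sinusoidal
inputs; `engine = "r"` is the same algorithm in R consuming the
identical draw sequence (the suite asserts bitwise-identical
trajectories), and is the path for user-supplied closures. The per-cell
occupation and gain integrals $A_k, B_k$ are accumulated in closed form
between jumps (6-point Gauss–Legendre per constant-state interval when
the input varies in time), which is what makes the martingale
decomposition and its quadratic variation exact rather than
mesh-approximated.

## Numerical choices

* **Geometry.** Cells are axis-aligned boxes tiling the domain exactly,
  half-open except at the upper boundary, indexed lexicographically;
  $d \in \{1, 2\}$ with $d = 1$ the test dimension. Boxes make measures,
  diameters and convexity exact; partial tilings and unstructured cells
  would only add bookkeeping error terms to statements we want sharp.
* **Quadrature.** All cell averages and discrete weights use fixed-order
  Gauss–Legendre rules (order 6 per axis by default), deterministic
  across runs; adaptive rules would make trajectories depend on
  tolerance internals.
* **Deterministic solver.** Method of lines on a quadrature grid with an
  exponential-Euler default: the linear decay $-\nu/\tau$ is integrated
  exactly and only the gain term is frozen per step, mirroring the
  variation-of-constants form of the equation. Constant-gain problems
  are therefore solved exactly, the invariant region $[0, \|f\|_0]$ is
  preserved step by step, and self-convergence is first order in `dt`
  (classical RK4 is available for validation). For comparisons with the
  jump process the solver runs on a per-cell Gauss grid
  (`partition_grid`), so restriction to the partition is exact.
* **Dual norms.** $H^{-\alpha}(D)$ is realized as a spectral multiplier
  norm on the Neumann cosine basis of the box: mode $\kappa$ is weighted
  by $(1 + |\pi\kappa/\mathrm{ext}|^2)^{-\alpha}$, with $K = 256$ modes
  per axis by default ($K = 64$ inside the experiment drivers, enough to
  resolve partitions up to $n = 32$). Coefficients of partition fields
  are computed in closed form. Any equivalent norm changes constants but
  not convergence orders, and orders are what the suite measures;
  constants are therefore never compared against theory.
* **SPDE integration.** Euler–Maruyama with the same exponential-Euler
  drift step as the deterministic solver, so $\varepsilon = 0$
  reproduces it to machine precision. Space–time white noise is
  piecewise constant on a uniform midpoint grid: the increment at a node
  of width $h$ has variance $dt/h$, giving pairings the correct variance
  $dt \int \varphi^2 g^2\,dx$. Square-root arguments of the Langevin
  diffusion coefficient are clipped at zero with the clip fraction
  reported (the state may dip negative at finite step size; the
  well-posedness of the multiplicative equation is an open problem and
  the package makes no claim about it). Because each replicate owns an
  independent RNG stream, paths at different `dt` are not coupled;
  step-size quality is therefore checked through the damped
  Ornstein–Uhlenbeck closed form for the variance rather than through a
  pathwise strong-order fit.
* **Printed-form corrections adopted.** The drift of both field
  approximations is implemented as $\tau^{-1}(-U + F(U,t))$, matching
  the Wilson–Cowan drift and the martingale decomposition (some printed
  renderings drop the minus sign), and the rescalings carry the square
  root: $\rho_n = \sqrt{\ell_-/v_+}$ on paths, $\varepsilon_n =
  \sqrt{v_+/\ell_-}$ on noise, squares on variances — the only
  convention that is dimensionally consistent between the two.

## Scenario presets as study conditions

The three presets fix the conditions under which all statistical gates
run; they are not tuning knobs.

| preset | gain | kernel | input | role |
|---|---|---|---|---|
| `constant` | $f \equiv 0.5$ | all-to-all | 0 | every limit quantity in closed form; stationary from `nu0 = 0.5` |
| `affine` | $\min(1, \max(0, 0.4z + 0.3))$ | constant 0.5 | 0 | exact moment closure while the clip stays inactive |
| `sigmoid` | $(1 + e^{-(5z - 2)})^{-1}$ | Gaussian, width 0.2 | 0.3 | genuinely nonlinear smooth field |

The partition family is $n \in \{4, 8, 16, 32\}$ uniform cells on the
unit interval with $l(k,n) = 25n$: diameters shrink, populations grow,
and uniform cells with equal populations keep
$v_-\ell_-/(v_+\ell_+) = 1$, the balance the CLT rescaling assumes. The
clipped-affine gain exists so that Appendix-style exactness checks have
an affine gain on the visited states while the global
boundedness/non-negativity contract still holds. Default problem sizes
(200 replicates for pathwise trends, 500 for the CLT gate, 120 for the
long-horizon gate, horizon $T = 2\tau$ or $20\tau$) were chosen once as
the smallest ensembles whose standard errors separate the expected
trends from noise.

What the generator deliberately does **not** emulate: real tissue has
heterogeneous, correlated connectivity, conduction delays, refractory
dynamics and non-Markovian synapses. Passing gates here demonstrates
that the simulator, solvers and norms implement the stated mathematics
— not that the Wilson–Cowan equation describes any particular
preparation.

## Degenerate and edge inputs

Zero total rate (zero gain, empty state) is an absorbing state: the
simulator returns a jump-free trajectory, and
`transition_probabilities` refuses to normalize. The bounded rate
scheme multiplies activation by $\mathbf 1\{\theta_k < l(k)\}$; its
macroscopic limit $\tau\dot\nu = -\nu + (1-\nu)f(\cdot)$ is provided
(`solve_bounded_wc`, fixed point $c/(1+c)$ under constant gain), but no
convergence claim is made for it — the corresponding theorem is open —
so the suite only checks the hard count bound and the deterministic
equation itself. Ties in initial-state rounding go to the smaller
count; `K` below twice the cells per axis flags the dual norm as
underresolved rather than failing.

## Known limitations

* Convergence gates assert trends along one fixed family at desk scale;
  they cannot distinguish the theoretical rate constants.
* The $H^{-\alpha}$ realization is equivalent, not equal, to the dual
  Sobolev norm; only orders transfer.
* The sup over continuous time is evaluated on the recording mesh, an
  approximation from below.
* Moment closures beyond affine gain are mean-field only and labelled as
  such; no system-size corrections are attempted.
* `d = 2` is supported in geometry, norms and weights; the experiment
  drivers and SPDE integrator are one-dimensional.

## A compact session

```{r example, eval = FALSE}
nu0 <- function(x) 0.2 + 0.2 * cos(pi * x)
p <- uniform_partition(domain(), n = 16, pop_size = 400)
m <- micro_model(p, tau = 1, gain_sigmoid(5, -2),
                 kernel_gaussian(1, 0.2), input_constant(0.3))
theta0 <- make_initial_state(p, nu0)
traj <- simulate_pdmp(m, theta0, T = 2, seed = 1)

# macroscopic reference on the matching per-cell grid
mac <- solve_wilson_cowan(1, gain_sigmoid(5, -2), kernel_gaussian(1, 0.2),
                          input_constant(0.3), nu0 = nu0, T = 2,
                          grid = partition_grid(p))

# terminal L2 distance between the embedded path and the field equation
diff_fun <- function(x)
  field_eval(embed_state(p, traj$final), x) -
  field_eval(macro_field(mac, 2), x)
g <- partition_grid(p, 6)
sqrt(sum(g$weights * diff_fun(g$nodes[, 1])^2))

# the full empirical law-of-large-numbers table
sc <- scenario_preset("sigmoid", replicates = 50)
print(run_lln(sc, seed = 1))
```
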