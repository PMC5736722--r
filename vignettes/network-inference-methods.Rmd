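---
title: "Model-free inference of direct network interactions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free inference of direct network interactions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arni)
```

## The problem

Given only a multivariate time series $x_{i,m} = x_i(t_0 + m\,\Delta t)$
recorded from a network dynamical system
$\dot x_i = f_i(x) + \xi_i(t)$, we ask a deliberately restricted question:
*which units $j$ appear on the right-hand side of unit $i$'s equation of
motion?*  We do not attempt to identify $f_i$ itself, nor to predict the
trajectory; only the existence or absence of direct interactions is inferred.
This weaker goal is what makes the approach model-free: it needs neither a
parametric model of the dynamics nor sparsity of the dynamics in any
particular basis.

The object being estimated is, for each target unit $i$, the diagonal binary
matrix $\Lambda^i$ with $\Lambda^i_{jj} = 1$ iff
$\partial f_i / \partial x_j \not\equiv 0$.  `dependency_matrices()` returns
the ground-truth $\Lambda$ for every benchmark system in the package, read
off the equations symbolically; a finite-difference sensitivity oracle in the
test suite confirms each pattern against the simulated right-hand sides.

## From dynamics to a grouped regression

Each unit's dynamics is decomposed twice.  First into interaction orders —
pairwise terms $g^i_j(x_j)$, three-point terms $g^i_{jk}(x_j, x_k)$, and so
on — and then each unknown interaction function into $P$ basis functions
$h_p$ with unknown coefficients.  After estimating time derivatives
$\dot x_{i,m}$ by finite differences (`estimate_derivatives()`, forward
two-point or central three-point stencils that never straddle segment
boundaries), the reconstruction problem becomes a linear regression of
$\dot x_i$ on *groups* of regressor columns: one block of $P$ columns per
candidate interaction (`build_blocks()`).  An interaction is present iff its
whole block carries nonzero coefficients, so the inference is a grouped
variable-selection problem.

The basis families (a–f) range over powers and trigonometric functions of
$x_j - x_i$, monomials $x_i^{p_1} x_j^{p_2}$, inverse-quadratic radial basis
functions at data-drawn centers, and single-variable powers and Fourier
modes of $x_j$.  The family only needs to capture the *class* of the
coupling (pairwise versus single-variable versus higher order), not its
exact functional form.

Three design details deserve a note:

* **Normalisation.** Every block column is scaled to unit Euclidean norm
  before selection, making the greedy projections scale-free; the scales are
  recorded so fitted coefficients are reported on the original scale.
  Exactly zero columns are dropped.  Constant nonzero columns are *kept*,
  deliberately: the regression has no global intercept, so a constant column
  is the legitimate basis element absorbing constant intrinsic terms (the
  natural frequency $\omega_i$ of a phase oscillator, for instance).
* **Self block.** The candidate set includes the target itself.  Pair
  families fall back to their single-variable analogue for this block (their
  pairwise form is identically zero at $j = i$) and an intercept column is
  prepended, so intrinsic terms such as $-x_i$ or $\omega_i$ are absorbable
  without contaminating the ranking of genuine neighbours.  Self links are
  excluded from AUC scoring.
* **Multi-component units.** For units with several state components (the
  chaotic oscillators have three), the block of candidate unit $j$ stacks
  the basis evaluated on every component of $j$, so whole units are selected
  or rejected together.

## Greedy block orthogonal least squares

`infer_unit()` ranks candidate blocks greedily.  At each step every
unselected block is orthogonalised against the span of the already selected
blocks, and the block whose column space most reduces the squared training
residual is selected; the residual is deflated and the mean-squared fitting
cost $C_i(l)$ recorded on both data splits.  The implementation keeps the
per-step cost low by exploiting that the running residual is orthogonal to
the selected span: gains reduce to rank-guarded solves of $P \times P$
normal equations, with a single tall matrix product per step.  A test
verifies at tolerance $10^{-9}$ that every selection coincides with the
brute-force alternative — refitting ordinary least squares on (selected
$\cup$ candidate) for every candidate — and that the recursive costs equal
fresh nested OLS refits.

Numerical choices: modified Gram–Schmidt deflation applied twice
("twice is enough") against each newly added direction; a relative rank
tolerance of $10^{-10}$ on singular values inside blocks; ties in the gain
broken toward the lowest candidate key; final coefficients from one OLS
refit of the response on the union of the selected, unorthogonalised blocks
(pseudo-inverse with a warning if rank-deficient).

Stopping: at `L_max` selections (default
$\min(\#\text{candidates}, M_{\mathrm{eff}} / \max_j P_j)$), when the
relative training-cost decrease falls below `tol` ($10^{-4}$ by default), or
when the residual reaches a machine-level floor.  Both knobs are exposed;
the experiment driver `run_once()` additionally caps the ranking depth at
roughly three times the in-degree, since everything beyond that shares the
tied minimum score and cannot change the AUC ranking materially.

**Data splitting.** The recordings are split 60/40 into training and
validation *by whole segments*, never by individual samples, so that
adjacent (strongly dependent) time points cannot leak across the split.  A
single continuous recording is split into two contiguous blocks instead.
Selection uses training rows only; the validation curve is purely
diagnostic.

## Learning curves and the knee

For a basis family of the correct interaction order the validation cost
$C_i(l)$ is L-shaped: it drops steeply while genuine interactions are being
discovered and plateaus at the true in-degree.  `detect_knee()` locates the
plateau onset by the distance-to-chord construction on the log-cost curve
(both axes normalised to the unit box), with ties broken toward smaller
$l$.  A knee is flagged *confident* only when the interior deviation below
the chord exceeds 10% of the normalised box **and** the cost at the knee
sits at least one decade below the start of the curve.  The second condition
is what separates the two regimes observed in practice: matched families
drop the validation cost by orders of magnitude before flattening, while
mismatched single-variable families on pairwise-coupled data decay mildly
(often less than a factor of two) and frequently *rise* again through
overfitting — such curves must not, and under this flag do not, produce a
confident knee.

Because the self block is a genuine discovery (the intrinsic term), the raw
knee position estimates the number of *dependencies* including self;
`glance()` therefore also reports `knee_indegree`, the number of non-self
interactions discovered up to the knee, which is the quantity to compare
with the network's in-degree.

## Synthetic benchmark systems

The generator module is first-class, tested code; its defaults are the study
conditions used throughout the tests.

* **Gene-regulatory transients** (`simulate_mm`): Michaelis–Menten kinetics
  $\dot x_i = -x_i + n_i^{-1} \sum_j J_{ij}\, x_j / (1 + x_j)$, initial
  conditions U(0, 2), $\Delta t = 0.25$, short transients toward steady
  state ($m = 5$ samples per segment).  With homogeneous unit weights the
  network sits exactly at the critical coupling where relaxation toward zero
  is algebraic rather than exponential — useful for generating long
  informative transients; the `uniform_range` weight scheme gives
  subcritical, exponentially relaxing networks.
* **Phase-coupled oscillators** (`simulate_phase`): two Fourier modes,
  $\sin(x_j - x_i - 1.05) + 0.33 \sin(2(x_j - x_i))$, coupling scaled by
  $1/n_i$, natural frequencies i.i.d. standard normal (a plain choice given
  only that they are constant; configurable), initial phases U($-\pi, \pi$),
  $\Delta t = 0.05$, phases recorded unwrapped (a wrap option exists; the
  difference-based families are invariant either way).
* **Hypernetworks** (`random_hypernetwork` + `simulate_phase(hyper=)`): each
  of $n_i$ interactions is, with probability $p_h$, a genuine two-source
  pair $\{j, k\}$ acting through $x_j - x_k$, else a pairwise link encoded
  as the degenerate pair $\{j, i\}$ — an encoding chosen so the second-order
  coupling form reduces exactly to the pairwise model at $p_h = 0$.  For
  scoring, a selected single-unit block of target $i$ is mapped to its
  degenerate pair, so pairwise and three-point discoveries live in one
  candidate universe (all unordered pairs).
* **Chaotic oscillators** (`simulate_roessler`): three components per unit
  with coupling $n_i^{-1}\sum_j J_{ij}\sin(x_j^1)$ into the first
  component; the stiff third component uses a finer internal step
  ($\Delta t / 25$).
* **Biological oscillators** (`simulate_glycolysis`,
  `simulate_circadian`): the seven-species anaerobic yeast glycolysis model
  and the ten-variable PER–TIM circadian feedback oscillator, with standard
  literature parameter sets shipped as documented defaults
  (`glycolysis_params()`, `circadian_params()`) and fully overridable —
  these models are included for their fixed, known dependency structure.

**Integration.** All models are integrated with a fixed-step scheme batched
over segments: Heun's second-order method when the noise level $\eta$ is
zero (a convergence test verifies the order), and Euler–Maruyama with
additive noise of standard deviation $\eta\sqrt{\Delta t_{\mathrm{int}}}$
per substep otherwise, i.e. $\xi$ is read as white noise in the SDE sense
with diffusion amplitude $\eta$; a variance-scaling test pins this contract.
The internal step defaults to $\Delta t / 10$.  Divergence and negativity
guards abort on invalid settings rather than returning corrupt data.
"Distributed sampling" draws $S$ independent initial conditions and records
$m$ samples from each ($M = S \times m$); "continuous" records one long
trajectory.

What the generators deliberately do *not* emulate: measurement noise
distinct from dynamical noise, irregular sampling, delays, and event-driven
dynamics.  Passing tests on these benchmarks therefore demonstrate correct
recovery of direct couplings under additive dynamical noise and short-
transient sampling, not robustness to observation artefacts.

## Evaluation

`auc_score()` implements the Mann–Whitney formulation with midrank ties:
candidates never selected share one tied minimal score, all-tied scores give
exactly 1/2, and the AUC is invariant under strictly monotone transforms of
the scores.  Self pairs are excluded; in hidden-unit runs only pairs among
observed units are scored, making no statement about links mediated by
hidden units.  The ARNI score of a candidate is its discovery rank reversed
(earlier = higher); cost-decrease magnitudes would be an alternative score,
but discovery order is what the ranked-list output defines.

The baselines are deliberately standard: absolute Pearson correlation,
absolute partial correlation from the (optionally ridge-regularised) inverse
covariance, and plug-in transfer entropy with equal-frequency binning
(4 bins, lag 1, within segments only).  Multi-component units pool
component-level scores by maximum absolute value.

`run_experiment()` sweeps sample size, noise level, hypernetwork fraction or
observed fraction with seeded replicates, and bisects over $M$ for the
smallest sample size reaching mean AUC > 0.95.  Problem sizes used in the
shipped tests (e.g. $N = 100$ gene-regulation networks at $M = 1000$,
$N = 20$ oscillator networks at $M = 1000$–$2000$, 5–10 replicates) were
chosen as the smallest instances at which the replicate error bands are
narrow enough for the orderings and trends to be meaningful.

## Reproducibility

Every user-facing function takes an integer seed and derives independent
child seeds per unit / per role through a counter-based scheme, so
unit-level generation is order-independent and all outputs are bit-exact
reproducible from the seed; the command-line driver writes a manifest
echoing the fully resolved configuration next to every output file.

## Known limitations

* Synchronised, steady, or otherwise low-dimensional dynamics sample too
  little of the dynamics space to constrain the regression; the method needs
  transient, stochastic or otherwise rich trajectories.
* Interaction orders above two are representable by the same key mechanism
  but are not generated, inferred, or scored here.
* The basis family must be chosen by the user; the learning-curve diagnostic
  identifies a wrong choice but does not automate the search.
* Derivative estimation assumes $\Delta t$ small enough for the stencil
  error to sit well below the signal; the coefficient-recovery test uses a
  finer $\Delta t$ with the central stencil for exactly this reason.
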