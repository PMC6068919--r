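---
title: "Replicator dynamics of indirect reciprocity: model, numerics, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicator dynamics of indirect reciprocity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indirep)
```

## The model

A large population contains three fixed behavioural types: cooperators
($x_1$), who cooperate in every round; defectors ($x_2$), who never
cooperate; and discriminators ($x_3$), who copy their current partner's
publicly observed action from the previous round, cooperating with
probability $p$ in round 1 when no record yet exists. Each of the $N$
rounds pairs all players uniformly at random. Mutual cooperation pays
$\pi - c$ to each partner; unilateral cooperation pays $v - c$ to the
cooperating side and $v$ to the defecting side, with the cross benefit
parameterised as $v = \theta\pi$, $0 < \theta < 1$; mutual defection
pays nothing. The constraint $\pi > c > 0$ makes mutual cooperation
socially efficient.

Because a discriminator conditions on its partner's record, the
population-level fraction acting cooperatively in round $n$ follows

$$g_1 = x_1 + p x_3, \qquad g_n = x_1 + g_{n-1} x_3 \;(n \ge 2),$$

a contraction toward $x_1/(1 - x_3)$ at geometric rate $x_3$ with the
closed form $g_n = \tfrac{x_1}{1-x_3} + x_3^{\,n}\!\left(p -
\tfrac{x_1}{1-x_3}\right)$. Summing the per-round expected payoffs
gives the cumulative payoffs $R_1, R_2, R_3$ of the three types, in
which $\sum_{n=2}^{N} g_n$ and $\sum_{n=2}^{N} g_n^2$ are collapsed to
geometric-series closed forms. Selection acts on the payoffs relative
to the defector, $\hat R_1 = R_1 - R_2$, $\hat R_2 = 0$,
$\hat R_3 = R_3 - R_2$, through the replicator equations
$\dot x_i = x_i(\hat R_i - \bar R)$ with
$\bar R = x_1 \hat R_1 + x_3 \hat R_3$.

Two definitional points deserve note, because the expanded algebra can
be written in more than one way:

* `relative_payoffs()` defines $\bar R$ by the composition
  $x_1\hat R_1 + x_3\hat R_3$ rather than by any independently expanded
  polynomial; the composed form is the one under which
  $\sum_i \dot x_i = 0$ is an algebraic identity, and the test-suite
  verifies $\hat R_i$ against literal differences of the totals at
  every state it touches.
* The cooperator--discriminator edge analysis (`solve_edge_no_defector()`)
  solves a dedicated closed-form equation in $x_3$ stated for that edge.
  We note for transparency that this stated equation is *not*
  algebraically identical to $\hat R_1 = \hat R_3$ evaluated at
  $x_1 = 1 - x_3$ (the two differ in the sign of the
  $\theta\pi$-bracket and in the constant term; the consistent form's
  roots would be $-0.83$ and $0.99$). The stated form is implemented
  verbatim as the edge's defining equation and its residuals are
  reported against that definition. Either version places both roots
  outside the open interval $(0,1)$, so the qualitative conclusion —
  no interior rest point on that edge — does not depend on the choice.
  The defector--discriminator edge equation, by contrast, is exactly
  $\hat R_3(0, x_3)/p$ rearranged, and the package treats it as such.

## Parameters and defaults

| parameter | meaning | default | units |
|---|---|---|---|
| $N$ | rounds per game | 100 | count |
| $\pi$ | mutual-cooperation benefit | $10^6$ | payoff |
| $c$ | cooperation cost | $0.5 \times 10^6$ | payoff |
| $\theta$ | cross-benefit ratio, $v = \theta\pi$ | 0.75 | — |
| $p$ | round-1 discriminator cooperation probability | 0.5 | — |

The defaults are the reference parameterisation used by every worked
example and by `scripts/acceptance.R`. All payoff expressions are
homogeneous of degree 1 in $(\pi, c)$ jointly, so solvers and
residual checks normalise by $\pi$; reported residuals are therefore
dimensionless and independent of the payoff scale.

## Equilibrium analysis

$\hat R_1$ is exactly linear in $x_1$ with coefficient
$N(1 - 2\theta)\pi$, so the interior system $\hat R_1 = \hat R_3 = 0$
reduces to one dimension: `solve_interior()` eliminates
$x_1(x_3)$ in closed form, scans the substituted $\hat R_3$ for sign
changes on a 3000-point grid over $x_3 \in [-1.5, 1.5]$, and polishes
every bracket with Brent's method to $10^{-12}$. The scan range
deliberately extends beyond the simplex: whether a mathematical root is
*admissible* (all coordinates in $[0,1]$) is the scientific question,
so roots must be found before they can be rejected. At $\theta = 1/2$
the linear coefficient vanishes and the reduction is undefined; the
solver raises a distinct condition rather than silently switching
method. The two edge equations are solved by the same bracketed scan,
with the poles at $x_3 = \pm 1$ excluded by a $10^{-6}$ margin and any
bracket straddling a pole discarded.

With the reference parameters the interior system has exactly two real
solutions, $(x_1, x_3) = (0.2448, -0.5209)$ and $(0.6650, 0.3367)$;
the first has $x_3 < 0$ and the second has $x_2 = 1 - x_1 - x_3 < 0$,
so neither is admissible. The defector--discriminator edge has roots at
$x_3 = -0.88$ and $1.017$, the cooperator--discriminator edge at
$-0.92$ and $1.03$ — none in $(0,1)$. The only admissible rest point
away from the vertices is the cooperator--defector face point
$x_1 = (c - \theta\pi)/((1-2\theta)\pi)$, which is $(0.5, 0.5, 0)$
here; its tangent-plane eigenvalues are $-12.5$ and $+6.19$ (in
$\pi$-normalised time), a saddle: stable to invasion along the face,
invadable by discriminators. Together these computations give the
machine-checkable form of the headline claim: the dynamics admit no
admissible stable equilibrium, so the three types cycle rather than
settle.

```{r equilibria}
params <- game_parameters(N = 100, pi = 1e6, c = 0.5e6, theta = 0.75, p = 0.5)
equilibrium_report(params)
```

Stability is operationalised as the eigenvalue test on the
$2 \times 2$ central-difference Jacobian of the flow restricted to the
simplex tangent plane (coordinates $(x_1, x_3)$, step $10^{-6}$), with
threshold $10^{-8}$ on the real parts; when the real parts straddle the
threshold the label is `center/inconclusive` rather than a guess. The
one-shot game is classified separately by best responses: `mixed` when
$v > \pi - c$ and $v > c$, `all_defect` when defection dominates, and
`all_cooperate` otherwise — the latter covering both the
dominance case and the coordination case, where the payoff-dominant
(cooperate, cooperate) equilibrium is selected. Ties are resolved
toward defection and flagged `boundary`. Note the face-ratio rule and
the best-response rule agree wherever the mixed regime exists but can
differ in the coordination corner ($v < \pi - c$, $v < c$): there the
face point $x_1 = (c-\theta\pi)/((1-2\theta)\pi)$ may lie in $(0,1)$
yet be unstable within the face, and the one-shot classifier's
`all_cooperate` is the meaningful label.

## Numerical choices

* **Singularities.** The closed forms divide by $1 - x_3$ (and the
  squared sum by $1 - x_3^2$). Within $10^{-9}$ of either pole all
  sums are computed by the recursion, which is finite everywhere;
  elsewhere the closed forms are used and the test-suite pins the two
  branches together to $10^{-12}$ per round and $10^{-10}$ on the sums.
* **Integration.** Trajectories use fixed-step classical RK4 on the
  $\pi$-normalised field (a pure time reparameterisation; orbits are
  unchanged). After each step the state's drift off the simplex is
  asserted below $10^{-9}$ (in practice it is at rounding level,
  $\sim 10^{-16}$, because the field components sum to zero
  identically), then clamped to $[0,1]$ and renormalised. Any
  coordinate exceeding $1.1$ before clamping aborts with a diagnostic
  rather than continuing a diverged solution. Step-halving agreement
  of terminal states ($< 10^{-4}$ at step $2\times10^{-3}$ over unit
  time) is part of the test-suite.
* **Scan robustness.** Doubling the root-scan grid does not change the
  root count; this is asserted in the tests.

## The agent-based oracle

`run_abm()` simulates the behavioural rules directly: $M$ agents of
fixed type (largest-remainder rounding of $M x_i$), a fresh uniform
random perfect matching every round, cooperators always C, defectors
always D, discriminators copying their current partner's recorded
action from the previous round (independent $p$-coin flips in round 1),
payoffs per the stage game, every agent's acted choice becoming its
public record. Random matching is chosen because the mean-field algebra
implicitly assumes uniform mixing; type frequencies are frozen within a
run — frequency change is the replicator module's job, and mixing the
two would confound the check. One master seed spawns per-replicate
streams, all recorded, so identical configurations are bit-identical.

What the oracle does and does not validate: under random matching the
per-round expectations of the cooperation fraction and of the
cooperator's and defector's payoffs are exactly the mean-field
expressions, so those comparisons carry z-scores of order 1 (at
$M = 10^4$ and 20 replicates, $|z| \approx 1$ for the payoffs, and the
per-round $g_n$ z-scores are unit-normal across rounds — bear in mind
that the extreme of $\sim$100 per-round z-scores is *expected* to
approach 3 even when the model is exact). The discriminator's
mean-field round-$n$ payoff, by contrast, treats the partner's record
as independent of the partner's type, whereas in the simulation a
defector's record is always D from round 2 onward; the simulation
accordingly shows a large, systematic discriminator payoff gap
(z-magnitude of order $10^3$ at the scale above).
`compare_abm_analytic()` therefore reports the discriminator block with
`agreement_expected = FALSE`: the gap is measured and surfaced, and the
package takes no position on which formula is "right". Because the
replicator analysis only ever uses payoff *differences from the
defector* of the cooperator and discriminator, conclusions that rest on
$\hat R_1$ (the interior elimination, the face point) are unaffected;
conclusions involving $\hat R_3$ inherit the mean-field simplification.

The simulation emulates exactly the model's idealisations — fixed
types, global random matching, error-free public records. Real
behavioural data involve assortative interaction, perception errors,
and strategy switching, none of which are represented; passing
cross-validation shows the algebra is a correct account of the model,
not that the model is a correct account of any particular population.

## Problem sizes

The validation suite uses 50 random simplex states for the algebraic
identities, recursion depths to $n = 200$, trajectories of $10^3$ RK4
steps, and one agent-based run at $M = 10^4$ agents with 20 replicates
of the full 100-round game; the equilibrium scans use the default
3000-point grid. These sizes were chosen to estimate every Monte-Carlo
quantity to well under a percent while keeping the whole suite at the
scale of seconds.

## Known limitations

* Stability labels rest on finite-difference eigenvalues; eigenvalues
  within $10^{-8}$ of the imaginary axis are reported as inconclusive,
  and no Lyapunov-exponent or center-manifold analysis is attempted, so
  the package reports the absence of *hyperbolically* stable rest
  points rather than any stronger statement about long-run behaviour.
* The edge analyses implement their stated closed-form equations; as
  noted above, the cooperator--discriminator edge equation's provenance
  relative to $\hat R_1 = \hat R_3$ is unresolved, and both variants
  are inside the package's test surface only through the stated form.
* Discriminators with longer memories (conditioning on the last two
  rounds or more) are out of scope: the one-round public record is
  structural to every closed form here.
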