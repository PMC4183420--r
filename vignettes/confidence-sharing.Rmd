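---
title: "Confidence sharing: model, algorithms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence sharing: model, algorithms, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confshare)
```

## The model

A population of anonymous agents estimates a fixed, unknown environmental
target value $\theta$ (a location, a direction of motion).  Each agent $x$
carries an external state $X_x(t)$ — its current estimate, which we call its
*position* — and possibly a small internal memory.  Positions are
initialised by drawing from per-agent distributions centred on $\theta$;
each agent knows the variance of its own initial distribution.

Information moves through pairwise interactions.  When agent $x$ observes
agent $y$ it obtains

* a **passive** measurement of their relative distance,
  $d = X_y - X_x + \eta$, with additive noise $\eta$ drawn from a known
  noise distribution of variance $\sigma^2$ (sign convention: $X_x + d$ is
  an unbiased estimate of $X_y$'s position); and
* an **active** message exposing part of $y$'s internal memory.

Agents are scored by the mean squared error of their positions about
$\theta$, and every update is required to keep positions unbiased.
Environmental cues are modelled by immobile *environment agents* pinned at
$\theta$ (plus a fixed offset) that can be observed but never move.

## The interaction algorithms

**Confidence sharing (`conf`).**  The compact algorithm stores a single
memory scalar $w_x$, the agent's *confidence*, initialised to the
reciprocal of its initial variance.  The active message is $w_y$.  The
observer forms the effective observation weight

$$w_{\mathrm{obs}} = \frac{w_y}{1 + \sigma^2 w_y},$$

the inverse variance of $X_x + d$ as an estimator of $\theta$, and fuses by
inverse-variance weighted averaging:

$$\Delta X_x = d\,\frac{w_{\mathrm{obs}}}{w_x + w_{\mathrm{obs}}},\qquad
  w_x \leftarrow w_x + w_{\mathrm{obs}}.$$

If the observer's error and the observation's error are independent, the
updated position is unbiased with variance exactly $1/w_x$ — confidence
stays *calibrated*, which is the property all the package's optimality
checks measure.

**The unrestricted Bayes algorithm (`opt_grid`).**  With no limits on
memory or communication, each agent maintains a full probability density
$f_x(z)$ of the target's position relative to itself, here tabulated on a
uniform grid.  An interaction multiplies the prior by the likelihood

$$L(z) = \int f_y(s)\, g(d - z + s)\, ds$$

(the cross-correlation of the partner's density with the noise density
$g$), normalises, moves the agent to the posterior mean, and re-centres the
stored density so its mean returns to zero.  `opt_gaussian` is the
closed-form special case for Gaussian densities and is algebraically
identical to `conf` under $w = 1/\mathrm{var}$ — confidence sharing is
*optimal* when everything is Gaussian.

**Constant linear combinations (`linear`).**  The memoryless passive-only
rule $\Delta X_x = \alpha d$.  Its mean-field steady-state dispersion is
the fixed point of $V' = (1-\alpha)^2 V + \alpha^2 (V + \sigma^2)$, i.e.
$V^* = \alpha\sigma^2 / (2(1-\alpha))$, reached on a timescale
$\sim 1/\alpha$: the speed–accuracy tradeoff that motivates keeping a
confidence memory at all.

**Extensions.**  `transmit_confidence()` models noisy active messages as a
zero-truncated multiplicative Gaussian factor $\max(0,\xi)$,
$\xi \sim N(1, \sigma_a^2)$ — truncation is the minimal reading of
"multiplicative noise that preserves non-negativity".
`conf_update_dynamic()` adds one freshness bit for changing environments
(below).  `correlation_corrected_fusion()` replaces the independence
assumption with the optimal linear fusion of correlated estimators, with
the error correlation $\rho$ supplied exactly by the provenance tracker.
`perceive()` applies a per-agent multiplicative distance-perception bias
for heterogeneous populations; in the engine the bias multiplies the whole
measured displacement (distance plus its noise), since a misperceiving
agent misreads what it measures, not just the true part.

## The Fisher-information framework

For a translation family with density $f$, the Fisher information is
$J = \int f'(x)^2/f(x)\,dx$; the Cramér–Rao inequality bounds any unbiased
estimator's variance by $1/J$.  The package computes $J$ for closed-form
cases exactly and otherwise by central differences on the tabulation grid.

* **Fisher-deviation** of a distribution: variance $\times$ Fisher
  information, $\geq 1$ always, $= 1$ exactly for Gaussians.  The
  **initial Fisher-deviation** $F_0$ is its supremum over all initial and
  noise distributions and bounds the competitiveness of confidence sharing
  against the unrestricted optimum; the test suite checks the conservative
  bound $F_0^2$ and in practice measures ratios far below it.
* **Fisher channel capacity** $C$: the Fisher information of the noise
  distribution.  One observation can raise an agent's information by at
  most $\min(J_{\mathrm{partner}}, C)$ — an agent can obtain neither more
  information than its partner holds nor a measurement more precise than
  the channel allows.
* **Convergence-time bound**: to enter a window of half-width
  $\varepsilon$ around $\theta$, a typical agent's information must exceed
  $1/\varepsilon^2$, so at least
  $(1/\varepsilon^2 - J_{\mathrm{median}})/C$ observations are needed.
  With a noiseless channel the additive cap is vacuous and the binding
  constraint is the **doubling bound**: additivity of Fisher information
  means the best per-agent information can at most double per synchronous
  round, giving $\log_2(J_{\mathrm{target}}/J_{\mathrm{max,init}})$
  rounds.

## Meeting patterns and the independence assumption

The optimality proofs assume *independent meeting patterns*: the memories
of any two interacting agents are statistically independent.  Literally
evolving disposable partner populations to guarantee this is exponentially
expensive in the number of rounds, so the `oracle_independent` pattern
realises the property by construction: the partner's index is drawn
uniformly, and its state is synthesised as a fresh unbiased Gaussian draw
with that partner's current exact variance $1/w_y$.  This keeps the
calibration identity $\mathrm{Var}(X_x) = 1/w_x$ exact by induction at
every round, which is precisely what the optimality-ratio experiments
measure.  It is restricted to the confidence-sharing family, whose updates
depend on partner states only through their first two moments.

`well_mixed` (uniform random partner) and `round_robin_pairs` (a fresh
random perfect matching per round, both members observing each other) are
the dependent patterns used everywhere else.  The `hypercube` pattern is a
deterministic complementary schedule — in round $t$, agent $i$ meets
$i \oplus 2^{t \bmod \log_2 n}$ — under which interacting partners always
carry information about disjoint halves of the population.

## Exact dissemination and the corrected rule

In a uniformly informed, noiseless population the correlation-corrected
rule should end with every agent holding exactly the population's total
initial information $n J_0$: all information disseminated, no
over-confidence.  Whether that happens depends on the meeting schedule.
Under *random* matchings the population reaches consensus on a common
estimate whose weights over the initial positions are close to, but not
exactly, uniform — pairwise fusion can only combine the two estimates it
sees, and the uniform combination is generically outside their span.  The
package's simulations show steady states around $0.99\,n J_0$ for random
perfect matchings (and lower for `well_mixed`), always bounded by $n J_0$:
the corrected rule never over-counts.  Under the `hypercube` schedule the
pairs are always complementary, each fusion is an exact half-half average,
and the population reaches exactly $n J_0$ (to machine precision) in
$\log_2 n$ rounds.  The exact-dissemination experiment therefore runs on
the hypercube schedule, and the random-matching shortfall is reported as a
property of the schedule, not of the rule.

## Dynamic environments

Accumulated confidence makes plain confidence sharing unresponsive to a
target shift.  The dynamic extension stores one extra bit, on while an
agent holds post-change information: environment agents switch their bit
on when the target moves; a stale observer meeting a fresh partner
discards its obsolete confidence (reset to its initial value), fuses, and
turns its bit on, inheriting the partner's timestamp; bits expire after an
obsolescence horizon $\tau$.  A fresh observer conversely *ignores* stale
partners — we found this complementary branch is required, not optional:
without it, the enormous confidence accumulated before the change drags
freshly updated agents straight back to the obsolete target (the
population settles at a stale/fresh compromise instead of tracking).  In
stable periods all bits are off and the rule coincides exactly with plain
confidence sharing.

## The provenance auditor

For every linear update rule (`conf`, `opt_gaussian`, `linear`,
`conf_corrected`), each position is an exact affine combination of the
initial positions and the accumulated noise draws.  With
`track_provenance = TRUE` the engine carries these coefficient vectors, so
exact variances, pairwise correlations, and per-interaction information
gains are available with *no Monte-Carlo error* — this is what feeds the
corrected rule's $\rho$, the capacity audit, and the reconstruction check
(simulated positions equal the affine reconstruction to $10^{-9}$).

## Numerical choices

* **Grids**: uniform, centred on the distribution mean, default half-width
  8 standard deviations with 2048 points for Fisher computations (1024 for
  population runs of the grid algorithm).  8$\sigma$ keeps the truncated
  Gaussian mass below $10^{-10}$ and bounds convolution aliasing; the
  constructor refuses tabulation when the outermost cells hold mass
  $\geq 10^{-6}$.
* **Fisher information**: central differences, density floored at
  $10^{-300}$ inside the quotient.  For the Laplace density the kink at 0
  costs $\sim 1\%$ accuracy (tested at that tolerance); the uniform
  density is non-regular (discontinuous), its translation-family
  information is not finite, and no closed form is stored for it.
* **Cross-correlation**: FFT with zero padding to at least twice the
  combined length (no circular aliasing), evaluated off-lattice by linear
  interpolation; verified against a direct $O(n^2)$ summation to
  $10^{-10}$.
* **Re-centring** of the stored pdf uses linear interpolation and
  renormalises; it biases the variance by $O(dx^2)$, which is two orders
  below the tolerances used anywhere.
* **Degenerate inputs**: a zero-confidence pair produces no movement and
  no error; an infinitely confident partner over a noiseless channel moves
  the observer exactly onto it; two infinitely confident agents over a
  noiseless channel are rejected.  In the corrected rule the fusion weight
  is clipped to $[0,1]$ and the fused variance is evaluated at the applied
  weight, so fusing never increases variance.
* **Linear steady state at finite $n$**: the mean-field fixed point
  $\alpha\sigma^2/(2(1-\alpha))$ ignores the $O(1/n)$ coupling between an
  observer and its partner.  The exact fixed point of the pair-moment
  recursion (derived from the joint dynamics of $E[X_i^2]$ and
  $E[X_iX_j]$) is
  $$V^*_n = \frac{\alpha^2\sigma^2}
    {2\alpha(1-\alpha)\left(1+\tfrac{1}{n-1}\right)
     + \alpha^2\tfrac{n-2}{(n-1)^2}},$$
  about 1 % below the mean-field value at $n = 128$; both are available
  from `linear_steady_state_variance()`.  Because the population mean
  performs a random walk under the memoryless rule (MSE about $\theta$
  grows without bound), "steady-state variance" is measured as the
  within-population dispersion about the replicate mean.  The mean-field
  comparison is run at a replicate count whose Monte-Carlo resolution
  (4 SE $\approx$ 4 %) matches what the mean-field description can predict
  at this population size; the finite-$n$ fixed point is additionally
  verified at 2000 replicates.
* **Rumor convergence window**: all agents within
  $6\sqrt{\mathrm{var}_{\mathrm{informed}}}$ of the target — six standard
  deviations of the steady-state optimum, so the informed agent itself
  lies inside the window with overwhelming probability (a 3$\sigma$ window
  would spuriously fail $\approx 0.3\%$ of seeds on the informed agent's
  own initial draw).

## What the synthetic populations do and do not emulate

The generator produces the study conditions behind every experiment:
Gaussian, Laplace, bimodal (double-Gaussian) and uniform initial beliefs;
Gaussian or Laplace passive noise; a noiseless channel as a point mass;
single-informed-agent "rumor" populations; log-uniform perception-bias
heterogeneity; and step schedules for a moving target.  Default study
conditions are: unit-variance Gaussians with $n = 32$ and 2000 replicates
for the optimality runs; $n = 128$, $\sigma^2 = 1$ for the linear
tradeoff; the bimodal family at $c = 1$, $s^2 = 0.25$ (variance 1.25,
Fisher information $\approx 2.9$ versus $0.8$ for its variance-matched
Gaussian).  These populations deliberately omit spatial structure
(interaction graphs are fully mixed or matched, never metric), interactions
of more than two agents, multidimensional state, heavy-tailed beliefs
without finite variance, and objectives other than mean squared error —
so passing tests demonstrate the information-theoretic claims under the
model's own assumptions, not robustness of real animal groups to their
violation.

## Problem sizes

The shipped experiments use $n \le 128$ agents, at most 2000 replicates,
and at most 150 rounds; the grid algorithm runs at $n = 16$, 100
replicates, 1024 grid points.  These sizes put every Monte-Carlo tolerance
(4 standard errors throughout) well below the effect sizes being measured
while keeping the full suite fast; all of them are plain `sim_config()`
arguments, so larger studies are one override away.

## Known limitations

* The grid algorithm assumes all agents share one lattice and symmetric
  initial densities (the stored density of $\theta - X$ then coincides
  with the position density); asymmetric initial families would need a
  mirrored tabulation.
* `oracle_independent` synthesises Gaussian partner states; for
  non-Gaussian initial families it preserves the partner's variance but
  not its shape, so it is deliberately unavailable for the grid algorithm.
* The corrected rule requires exact correlations and is therefore only
  available with provenance tracking, i.e. for moderate problem sizes and
  populations whose updates are linear.
* Convergence-time bounds are stated per synchronous round; event-driven
  (Poisson-clock) scheduling is out of scope.
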