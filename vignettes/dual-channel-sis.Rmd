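---
title: "A dual-channel SIS model of competing sales channels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-channel SIS model of competing sales channels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualsis)
```

## The model and its assumptions

`dualsis` treats the diffusion of purchasing through two competing sales
channels (offline = channel 1, online = channel 2) as a two-population
susceptible–infected–susceptible process. The analogy: a potential
customer is "susceptible", a purchaser is "infected", and lapsing
(stopping to buy, with no immunity) is "recovery" at rate $\gamma_i$, so
consumers can purchase again later. The modelling assumptions are those of
the classical SIS framework adapted to a market:

* the two channels sell an identical (substitutable) product;
* at any time a consumer either has demand or has purchased, and buys
  through exactly one channel;
* channel preference can switch, which is what the cross-channel
  transmission terms express;
* there is no birth/death demography; demand sizes change only through
  the logistic growth and cross-channel competition terms.

The customer bases $N_1, N_2$ evolve independently of the purchase counts
(a skew-product structure that the stability machinery exploits, see
below):

$$\dot N_1 = r_1 N_1\Big(1 - \frac{N_1}{K_1}\Big) + m\,\frac{N_1 N_2}{K_2},
\qquad
\dot N_2 = r_2 N_2\Big(1 - \frac{N_2}{K_2}\Big) + n\,\frac{N_1 N_2}{K_1},$$

with signed cross-influence rates $m, n$ (competition when both are
negative). Purchases spread by mass-action contact,

$$\dot I_i = (\beta_{ii} I_i + \beta_{ij} I_j)(N_i - I_i) - \gamma_i I_i
+ g_i I_i,$$

where $g_i$ is channel $i$'s per-capita demand growth. The last
(demographic) term carries purchasers along with the growing or shrinking
customer base. It is a configuration switch
(`demographic_coupling`, default on) because the coupling between the
demand and purchase layers admits two natural readings; the switch makes
both available. The choice never moves an equilibrium or threshold:
$g_i$ vanishes identically at every studied equilibrium (at the interior
demand equilibrium by definition, and on the boundary faces because the
surviving channel sits at its carrying capacity). With the term on, the
admissible region $G' = \{0 \le I_i \le N_i \le K_i\}$ is forward
invariant: on the face $I_i = N_i$ one has
$\dot I_i - \dot N_i = -\gamma_i N_i \le 0$.

The right-hand sides are pinned by their printed consequences: the
per-capita nullclines $r_1(1 - N_1/K_1) + m N_2/K_2 = 0$ (and
symmetrically) reproduce the closed-form interior demand equilibrium

$$M = (N_{1E}, N_{2E}) = \Big(\frac{(m+r_1) r_2 K_1}{r_1 r_2 - mn},\;
\frac{(n+r_2) r_1 K_2}{r_1 r_2 - mn}\Big),$$

and on the face $N_1 = K_1,\ N_2 = I_2 = 0$ the purchase equation reduces
exactly to $\beta_{11} I_1 (K_1 - I_1) - \gamma_1 I_1$, whose nonzero root
is the endemic offline level $I_{1E} = K_1(1 - 1/R_1)$. The test suite
asserts both reductions.

## Parameters

| parameter | meaning | units |
|---|---|---|
| $r_1, r_2 > 0$ | intrinsic demand growth rates | 1/time |
| $K_1, K_2 > 0$ | channel carrying capacities | persons |
| $m, n$ | signed cross-influence of the other channel's base | 1/time (per scaled density) |
| $\beta_{ij} \ge 0$ | transmission influence rates (purchasers of channel $j$ converting potential customers of channel $i$) | 1/(person · time) |
| $\gamma_1, \gamma_2 > 0$ | purchase-termination (recovery) rates | 1/time |

Time is abstract, as in the source model; no calendar mapping is
attempted. Derived quantities: reproduction numbers
$R_i = \beta_{ii} K_i / \gamma_i$; invasion balance terms
$A = \gamma_1 - r_1(1 - N_{1E}/K_1) - m N_{2E}/K_2$ and the symmetric $B$
(identically $\gamma_1$ and $\gamma_2$ at $M$ — evaluated in full as a
built-in self-check); invasion ratios
$\Pi_1 = (A - \beta_{11} N_{1E})/(\beta_{12} N_{1E})$,
$\Pi_2 = \beta_{21} N_{2E}/(B - \beta_{22} N_{2E})$.

## Demand regimes and equilibria

With $m, n < 0$ the demand system falls into one of four regimes, decided
by strict inequalities on $(r_1 r_2 - mn,\ r_1 + m,\ r_2 + n)$:
coexistence ($M$ attracting), bistable ($M$ a saddle), and two
channel-dominant regimes (three boundary equilibria only). Values within
$10^{-12}$ of a regime boundary are reported as `degenerate`, never
silently assigned; parameter sets with $m \ge 0$ or $n \ge 0$ are labelled
`noncompetitive`. When $r_1 r_2 = mn$ the interior equilibrium is reported
as nonexistent with an explicit flag rather than an exception, since only
the nondegenerate denominator case is specified.

The four-dimensional system has up to seven equilibria. P0 (extinction),
P1 and P3 (single-channel demand, purchase-free) always exist. P2 and P4
(single-channel endemic) exist iff $R_1 > 1$ resp. $R_2 > 1$; the
channel-2 endemic level is $K_2(1 - 1/R_2)$ — its printed form contains a
transcription slip ($K_1$ for $K_2$), repaired here because the companion
expression $(\beta_{22} K_2 - \gamma_2)/\beta_{22}$ forces $K_2$. P5 (both
demands positive, purchase-free) exists with $M$. P6 (interior purchase
equilibrium) has no closed form; see below.

## Numerical choices

* **P6 solver.** At $N = M$ the two purchase balances form a
  two-dimensional root problem. Channel 1's balance is a downward-opening
  quadratic in $I_1$ with a unique root in $[0, N_{1E}]$ for any given
  $I_2$, so the solver eliminates $I_1$ analytically and scans the
  channel-2 residual on a 1024-point grid over $(0, N_{2E})$ for a sign
  change, polishing with `uniroot` at tolerance $10^{-12}$. This is
  deterministic, derivative-free and needs no initial guess. Existence is
  decided by the solve itself; absence of a sign change is reported as
  nonexistence together with the threshold verdict ($\Pi_1 \ge \Pi_2$).
  The two agree whenever $A - \beta_{11} N_{1E} > 0$ and
  $B - \beta_{22} N_{2E} > 0$ (the case the condition table covers); the
  solve additionally handles sign-flipped cases such as fully decoupled
  channels, where closed forms exist and are tested.
* **Stability.** Jacobians are analytic (finite-difference-validated in
  the tests at $10^{-6}$ relative). Because the demand equations never
  depend on $I$, every Jacobian is block lower-triangular in the
  $(N, I)$ grouping and its spectrum is the union of the demand block and
  the purchase block. Eigenvalue verdicts use a nonhyperbolicity
  threshold of $10^{-8} \max(r_1, r_2, \gamma_1, \gamma_2)$; a real part
  within it yields `nonhyperbolic`, never a silent classification.
* **Region-conditional claims.** The condition table claims stability
  of some equilibria only on subregions of $G'$ (basins, or the
  separatrix itself). For basin-restricted rows, trajectories from seeded
  states inside the claimed region are required to converge to the
  claimed point. For the separatrix-confined regions (Ω12/Ω13) the
  demand motion converges to $M$ along the stable manifold, so the
  decisive spectrum is the purchase block evaluated at $N = M$; the
  cross-validation compares against that block and simulates the purchase
  subsystem with demand pinned at $M$. The full spectrum at P5/P6 in the
  bistable regime necessarily contains the demand saddle's positive
  eigenvalue, and is reported as computed. Relatedly, the source text
  calls $M$ a saddle in both regimes while its condition table makes
  P5/P6 attracting in the coexistence regime; the package reports
  computed eigenvalues ($M$ is a saddle only in the bistable regime,
  where the demand-block determinant
  $N_{1E} N_{2E} (r_1 r_2 - mn)/(K_1 K_2)$ is negative) and does not
  impose either reading.
* **Integration.** `deSolve::lsoda` (adaptive, stiffness-switching),
  relative tolerance $10^{-9}$, absolute $10^{-12}$, dense output on a
  1000-point grid by default. States that drift out of $G'$ by less than
  $10^{-6} \max(K_1, K_2)$ (the usual tiny negative overshoot of a
  decaying component) are clipped; larger violations raise a flag and are
  never clipped silently. Halving the tolerances moves scenario terminal
  states by less than $10^{-5}$ relative (tested).
* **Separatrix.** The saddle's stable manifold is traced by integrating
  the *unit-speed reversed* demand flow from $M \pm \varepsilon v_s$
  ($\varepsilon = 10^{-4} \max K$, $v_s$ the stable eigendirection).
  Arc-length parameterisation avoids the finite-time blowups of the raw
  reversed logistic flow and yields a uniformly spaced polyline; a branch
  ends at the admissible-region boundary, at an arc-length cap, or where
  the flow speed stalls (a demand equilibrium, typically the origin).
  Basin membership is a crossing count of the joined polyline against a
  reference point deep in the offline basin; points within
  $10^{-6} \max K$ of the curve are reported as on the separatrix.
  "Nonzero" coordinate conditions in the Ω-region predicates are tested
  against $10^{-9} \max K$.
* **Convergence detection** requires the whole final 10% of a trajectory
  to stay within a relative tolerance (default $10^{-3}$) of a candidate
  equilibrium. In the trajectory leg of the cross-validation the horizon
  is keyed to the target's slowest contraction rate ($30/\lambda_{\min}$,
  capped at $10^5$); claims whose slowest rate is below
  $3 \times 10^{-4}$ per unit time are skipped as numerically degenerate,
  since no finite-time simulation can resolve them.

## The parameter sampler

`sample_parameters()` is the package's synthetic-condition generator,
used by the property tests and the cross-validation. It draws
$r \sim U(0.5, 2)$, $K \sim U(500, 2000)$, $m, n \sim U(-2, -0.05)$,
$\beta \sim \log U(10^{-6}, 10^{-1})$, $\gamma \sim U(0.005, 0.1)$ and
rejects draws whose demand inequalities miss the requested regime by less
than $10^{-3}$, so every returned set satisfies its regime strictly with
margin. The ranges bracket the published scenario values (rates of order
one, capacities of order $10^3$, transmission rates spanning the
sub- and supra-threshold sides of $R_i = 1$) — what a modeller in this
area would call realistic magnitudes. The sampler emulates *parameter*
heterogeneity only: it does not emulate observation noise, demand
seasonality, finite-population stochasticity or any data-generating
process, so passing property tests demonstrate internal mathematical
consistency of the implementation, not fit to real sales data.

## The shipped scenarios

Three sweep configurations reproduce the published simulation settings
(`scenario_config("s51")` etc., and `inst/extdata/*.yaml`):

* **s51** — bistable regime ($m = -1.2$, $n = -1.5$), sweep
  $\beta_{11} \in \{5\times10^{-6}, 3\times10^{-5}, 6\times10^{-5},
  9\times10^{-5}\}$, horizon 300. The first value gives $R_1 = 0.5$;
  the rest cross the threshold and settle at $K_1(1 - 1/R_1)$ (within 1%
  at the horizon, tested).
* **s52** — channel-2-dominant regime ($n = -0.5$), sweep $\beta_{22}$
  over the same list, horizon 10.
* **s53** — coexistence regime ($m = -0.8$, $n = -0.5$), joint sweep of
  $\beta_{12}$ and $\beta_{21}$ over their printed lists, horizon 10.

Two readings had to be fixed. First, the published lists assign
"$\gamma_1 = \gamma_2 = 1$" and "$\gamma_1 = \gamma_2 = 0.01$" in the same
breath; the first assignment is read as $r_1 = r_2 = 1$ (the growth rates
are otherwise never assigned, and the printed check $R_1 = 0.5$ requires
$\gamma_1 = 0.01$). Second, the s53 list prints a second "$\beta_{22}$"
value list for what its prose describes as the $\beta_{21}$ sweep; it is
swept as $\beta_{21}$, with $\beta_{22}$ held at its stated $10^{-5}$.
Both readings are recorded as comments in the shipped configs. Initial
purchaser counts are not published; the default is one seed purchaser per
channel ($I_i(0) = 1$, configurable), since an SIS system started at
$I = 0$ stays purchase-free and no sweep could show growth. Because the
seed is a choice, the scenario checks assert orderings and threshold
behaviour (terminal total sales nondecreasing in the swept rate;
sub-threshold offline sales decaying to the purchase-free point,
supra-threshold ones settling at the endemic level), not point-for-point
curve overlays.

At the published s51 horizon ($t = 300$) the sub-threshold run is still
in transient decay: its offline purchase count shrinks at rate
$\gamma_1 - \beta_{11} K_1 = 0.005$ per unit time, so it reaches the
purchase-free attractor only on a horizon an order of magnitude longer
(the suite verifies convergence to P1 at $t = 4000$). The package reports
what the model actually does rather than forcing "near zero" at $t=300$.

## Problem sizes

The test suite and the acceptance script use seeded samples of 25–100
parameter sets per regime (up to 400 for the rarest sub-case of the
invasion-criterion check), 200–500-point output grids, and horizons of
10–4000 time units chosen to exceed each target's slowest contraction
time. These sizes were chosen so that every property is exercised across
all regimes while a full run stays interactive (tens of seconds).

## Known limitations

* Stochastic (agent-based or jump-process) variants, demographic
  birth/death beyond the logistic term, and more than two channels are
  out of scope.
* Basins and the separatrix are computed in the two-dimensional demand
  projection only, which is exact for this model because the demand
  subsystem is autonomous; no four-dimensional invariant-manifold
  computation is attempted.
* No symbolic closed form for P6 and no continuation/bifurcation tracing
  beyond evaluating the threshold surfaces.
* No fitting of $\beta, \gamma, m, n$ to sales data, and no pricing or
  contract optimisation.
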