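---
title: "The antibiotic prescribing game: model, equilibria, and dynamics"
author: "abxgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The antibiotic prescribing game: model, equilibria, and dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abxgame)
```

## The model

A well-defined population of `n >= 2` doctors repeatedly decides whether to
prescribe antibiotics to symptomatic patients. Each doctor's mixed strategy
is the probability `p` of prescribing (p = 1 is the pure strategy T,
"treat"; p = 0 is U, "do not treat"); the population state is the treated
fraction `q` of symptomatic patients. Doctors are assumed to care only
about morbidity in their own patients, so payoffs are (negative) expected
morbidity risks. Two ingredients drive everything:

* `phi` in (0, 1] — the probability that a symptomatic patient truly has a
  bacterial infection. Untreated infected patients face morbidity risk
  `r_U > 0`, so the payoff of U is `-phi * r_U` regardless of `q`.
* the relative morbidity risk `r_q` of treated patients — antibiotic use
  selects for resistant bacteria, so the risk of treated patients grows
  with `q`. Since bacterial mutation accumulates at a roughly constant
  per-generation rate, the baseline model takes the growth to be linear,
  `r_q = q`: treatment is riskless at `q = 0` and exactly as risky as no
  treatment at `q = 1`.

Dividing all payoffs by `r_U` (payoffs are von Neumann–Morgenstern
utilities on an interval scale, so this changes nothing strategically)
gives the normalized mixed-strategy payoff

```
pi(p, q) = phi * (p * (1 - r_q) - 1),
```

so that for the baseline model the pure payoffs are `pi_T(q) = -phi * q`
and `pi_U(q) = -phi`.

```{r payoffs}
g <- prescribing_game(phi = 0.5)
payoff_table(params = g, q_steps = 5)
```

### Variants

The package implements three deliberate departures from the baseline,
selected by the `variant` field of [prescribing_game()]:

* `scaled_k` (`r_q = k q`, `0 < k < 1`): resistance never fully destroys
  efficacy. T remains strictly dominant and the dynamics are qualitatively
  unchanged.
* `residual_lambda` (`pi_T(q) = -lambda q` with `0 < lambda < phi`):
  antibiotics retain residual efficacy even at `q = 1`. We define the
  relative risk as `(lambda/phi) q` so that the pure-T payoff is exactly
  `-lambda q` while the Eq-5 structure of the payoff stays intact.
* `crossing`: efficacy is exhausted at some `q' < 1`. The package commits
  to the concrete form `pi_T(q) = -phi * min(q/q', 1) - c`, where
  `c = side_effect_cost >= 0` represents adverse side effects; the curves
  meet at `q'` when `c = 0` and cross (T strictly below U) when `c > 0`.
  This is a design choice, not the only admissible shape — any monotone
  curve that meets U before `q = 1` behaves the same way, which is why the
  crossing solver [crossing_point()] accepts arbitrary payoff curves as
  functions rather than hard-coding the formula.

## Equilibrium and evolutionary stability

The dominance gap is `pi_T(q) - pi_U(q) = phi * (1 - q)`, strictly
positive for every `q < 1`: whatever everyone else does, treating is never
worse and almost always strictly better. T is therefore a dominant
strategy, and the unique symmetric Nash equilibrium is `p* = 1`.

```{r equilibrium}
find_symmetric_nash(g)
classify_dilemma(g)
```

One boundary subtlety deserves honesty rather than silence. At the
equilibrium state `q = 1` all strategies earn exactly `-phi`, so the Nash
condition holds with equality there, not strictly; strictness holds
against every resident state `q < 1`. [find_symmetric_nash()] therefore
reports `p* = 1` as strict in the limit-of-strict-best-responses sense
(it is the unique best response at every interior resident state), while
[check_ess()] reports the tie as it finds it: `strict = FALSE`, with the
second (tie-breaking) stability condition and the invasion condition both
passing. Both routes certify evolutionary stability; they differ only in
which inequality does the work at the boundary.

```{r ess}
check_ess(1, g)
```

The invasion check evaluates, for each mutant strategy `p` and each
invading fraction `eps`, the payoffs of resident and mutant in the mixed
population `q = eps * p + (1 - eps) * p*`. The reported
`barrier_estimate` is the largest tested `eps` below which every tested
mutant loses — a numerically certified lower bound for the true invasion
barrier, never a claim about its exact value. Defaults: 21 equally spaced
mutants, `eps` on the logarithmic ladder 1e-6 … 1e-1, payoff-equality
tolerance 1e-12 in normalized units.

How the treated fraction relates to a finite strategy profile is a
modelling choice the equilibrium analysis itself never needs: we define
`q` as the mean prescribing probability over all `n` doctors
([profile_state()]), the mean-field reading under which the mixture state
above is literal. Under a strictly finite-population reading in which a
doctor's own deviation feeds back into `q`, a unilateral deviation from
all-treat would raise the deviator's payoff by `phi * p(1-p)/n`, and the
all-treat profile would not be an equilibrium at all; the model's claims
are mean-field claims, and the package says so rather than blending the
two readings.

## The tragedy of the commons

If all doctors prescribe at the same rate `q`, each earns the symmetric
payoff `phi * (q(1 - q) - 1)`, maximized at `q = 1/2` with value
`-3 phi/4`. The dominant strategy drives the population to `q = 1` and
payoff `-phi` instead — strictly worse for every doctor. That conjunction
(a dominant strategy whose equilibrium is strictly Pareto-dominated by an
attainable symmetric outcome) is what [classify_dilemma()] labels a
tragedy of the commons.

The residual-efficacy variant shows the classification is not vacuous:
when `lambda < phi/2` the average payoff `-lambda q^2 - phi (1 - q)` is
maximized at `q = 1`, the equilibrium and the cooperative optimum
coincide, and `is_tragedy` is `FALSE` even though T is still strictly
dominant.

```{r residual}
classify_dilemma(prescribing_game(phi = 0.5, variant = "residual_lambda",
                                  lambda = 0.2))
```

## Replicator dynamics

Strategy frequencies evolve by adaptive learning: the frequency of T grows
in proportion to its payoff advantage over the population average,

```
dq/dt = q * (pi_T(q) - avg(q)) = q (1 - q) (pi_T(q) - pi_U(q)),
```

which with the baseline payoffs reduces to `dq/dt = phi q (1 - q)^2`.
(One printed intermediate form of this derivation circulating with the
model contains a sign slip that does not reduce to the final equation; the
package implements the definition, and a regression test pins
[replicator_from_payoffs()] to the closed form on a dense grid.)

Key structural facts, each of which is a test:

* the velocity is nonnegative, zero exactly at `q = 0`, `q = 1` (or
  `phi = 0`, where every state rests);
* `phi` factors out — infection probability only rescales time;
* the velocity peaks at `q = 1/3` regardless of `phi`, with height
  `4 phi / 27`;
* `q = 0` is unstable (linearization `+phi`), `q = 1` attracts from the
  whole interior. At `q = 1` the linearization vanishes, so
  [classify_rest_point()] resolves the degenerate case by one-sided sign
  probes at `q +- h` (default `h = 1e-6`): inward flow from every occupied
  side means a degenerate attractor.

```{r dynamics}
find_rest_points(phi = 0.5)$points
peak_velocity(1)
```

### Numerical choices

Integration uses `deSolve`'s adaptive lsoda with absolute and relative
tolerances 1e-9 by default, on a logarithmically spaced output grid
(400 points), with the state clamped to `[0, 1]`; a fixed-step RK4
integrator written in the package serves as a second opinion in the test
suite. A trajectory is declared converged when the terminal velocity is
below 1e-10 and the terminal state is within 1e-6 of a rest point.

The flow approaches `q = 1` only algebraically: near the attractor
`du/dt ≈ -phi u^2` for `u = 1 - q`, so `u(t) ≈ 1/(phi t)`. Reaching
`|q - 1| < 1e-6` therefore needs horizons of order `1e6/phi`; the default
`t_max = 1e4` leaves a visible gap (`q ≈ 0.9998` from `q0 = 0.1` at
`phi = 0.5`), which the package reports as-is rather than rounding away.
The global-attraction checks in the test suite integrate to `t_max = 1e8`
over a 10 × 10 grid of starts — about a hundred cheap adaptive solves.

The separable equation has the closed-form first integral
`log(q/(1-q)) + 1/(1-q) - phi t`, used as an independent oracle for the
integrator ([first_integral()]). Its `q`-derivative is `1/(q (1-q)^2)`,
so solver error is amplified without bound as `q` approaches 1; the
conservation tests accordingly tighten the solver to 1e-12 and check the
invariant on the well-conditioned window `q < 0.99`, where it is held to
1e-6.

Tie-breaking: at a payoff tie the best response is reported as the full
interval `[0, 1]`, never an arbitrary point. Crossing points are located
by a sign-change scan refined by bisection to 1e-10. Closed-form argmaxes
(quadratic vertices, the `1/3` peak) are always cross-validated against
brute-force grid searches at step 1e-6 in the tests.

## What the randomized checks do and do not show

The property tests on evolutionary stability draw random games with
*affine* pure-strategy payoff curves (coefficients uniform on [-1, 1],
fixed seed), because that is the class the prescribing game lives in; the
verified implications (strict Nash resists invasion; a tight Nash
condition plus the tie-breaking condition resists invasion; invasion
resistance on a shrinking ladder implies the Nash condition) are proved
facts for this class, so a failure would indicate an implementation
defect, not new science. The model itself idealizes heavily — identical
patient-focused doctors, a deterministic mean-field dynamic, no
within-host or bacterial population genetics — so passing tests certify
the mathematics of the model, not the behaviour of real prescribers.

## Reporting

[full_report()] aggregates the dilemma classification, Nash set, ESS
check, rest points, cooperative optimum and peak-velocity summary into
one JSON-ready document. The command-line interface (`abxgame`, installed
under `exec/`) exposes subcommands `payoff-table`, `equilibrium`,
`ess-check`, `simulate`, `vector-field`, `rest-points` and `report`, with
`--config` key = value files, flag overrides, CSV or JSON output (CSV:
comma-separated, header row, 12 significant digits), and a
`.manifest.json` sidecar recording the effective parameters, seed and
package version next to every file it writes. Data files contain no
timestamps, so identical runs are byte-identical; the wall clock lives in
the manifest only.
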