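# abxgame

Antibiotic over-prescription is widely described as a tragedy of the
commons: each doctor, acting in the best interest of their own patients,
prescribes antibiotics whenever a bacterial infection is plausible, and the
aggregate of those individually rational choices breeds resistance that
leaves every doctor's patients worse off. `abxgame` turns that claim into
checkable mathematics. It is aimed at modellers in health behaviour,
antimicrobial-resistance policy, and evolutionary game theory who want the
prescribing game as a tested, scriptable library rather than a one-off
calculation.

## The model

A population of `n ≥ 2` doctors repeatedly chooses between two pure
strategies for symptomatic patients — T (treat with antibiotics) and U (do
not treat) — with mixed strategy `p ∈ [0, 1]`, the probability of
prescribing. With `φ ∈ (0, 1]` the probability that a symptomatic patient
truly has a bacterial infection, `q` the fraction of patients currently
treated, and relative morbidity risk `r_q = q` (resistance grows linearly
with prescribing), the normalized payoff to a doctor is

    π(p, q) = φ [ p (1 − r_q) − 1 ],    so  π_T(q) = −φq,  π_U(q) = −φ.

T strictly dominates for every `q < 1`, making all-treat (`p* = 1`) the
unique symmetric Nash equilibrium and an evolutionarily stable strategy —
yet the symmetric payoff `φ[q(1−q) − 1]` is maximized at `q = 1/2`, so the
equilibrium payoff `−φ` is strictly worse than the attainable cooperative
payoff `−3φ/4`: a tragedy of the commons. The replicator dynamic

    dq/dt = φ q (1 − q)²

carries every interior state to `q = 1`, fastest at `q = 1/3`. Model
variants (partial resistance `r_q = kq`, residual efficacy
`π_T = −λq`, efficacy exhausted at `q′ < 1` with side-effect costs)
probe when the dilemma persists and when it dissolves; see the methods
vignette in `vignettes/prescribing-game.Rmd`.

## Worked example

```r
library(abxgame)
g <- prescribing_game(phi = 0.5)

classify_dilemma(g)
#> Dilemma classification
#>   dominant strategy: T (p = 1)
#>   equilibrium:  q = 1, payoff = -0.5
#>   cooperative:  q = 0.5, payoff = -0.375
#>   tragedy of the commons: YES

integrate_replicator(0.1, phi = 0.5, t_max = 1e8)
#> Replicator trajectory: phi = 0.5, q(0) = 0.1 -> q(1e+08) = 0.99999998 (converged)

find_rest_points(phi = 0.5)$points
#>   q_star derivative        classification
#> 1      0        0.5              UNSTABLE
#> 2      1        0.0 DEGENERATE_ATTRACTING
```

Read: with a 50% infection probability, treating is dominant; the
population equilibrates at universal prescribing with payoff −0.5 (in
units of the untreated morbidity risk), although uniform half-rate
prescribing would give everyone −0.375. The dynamic confirms it: from 10%
treated, the population flows to all-treat (the no-treat state is an
unstable rest point, the all-treat state a degenerate attractor — its
linearization vanishes, so stability is resolved by sign probes). Under
residual efficacy the dilemma disappears:

```r
classify_dilemma(prescribing_game(phi = 0.5, variant = "residual_lambda",
                                  lambda = 0.2))$is_tragedy
#> [1] FALSE
```

## Command line

The installed script `exec/abxgame` exposes the analyses as subcommands:

```sh
abxgame payoff-table --phi 0.5 --steps 101 --out payoffs.csv
abxgame report --phi 0.5 --out report.json
abxgame simulate --phi 0.5 --q0 0.1 --t-max 10000 --out traj.csv
```

Each `--out` file gets a `.manifest.json` sidecar with the effective
parameters, seed, and package version; a plain-text `key = value` config
file (`--config`) can supply model parameters, with flags taking
precedence.

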