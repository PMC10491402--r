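# motifid

Structural identifiability analysis of biomolecular controller motifs in R.

## What it is for

Controller motifs are small negative-feedback reaction networks that hold a
controlled species *A* at a set point: the *basic* motifs use one controller
species *E*, the *antithetic* motifs an annihilating pair *E1*, *E2*
(integral feedback, `ja = ka*E1*E2`). Modellers who want to fit such motifs
to data face the question of **which measurements make the rate and binding
constants identifiable at all**. `motifid` answers it structurally: it builds
the complete library of 128 motif model structures

```
dA/dt = di - do ± jc        di = ki,  do = ko*A
dE/dt = js - jd             (basic; antithetic uses dE1 = js1 - ja, dE2 = js2 - ja)
```

across 8 wirings × complexity cases (one/both disturbances, first-order vs
saturable activation `f_a(X) = X` or `X/(K_aX + X)`, zero/first-order/
Michaelis–Menten degradation of *E*), attaches any combination of one or two
concentration and/or flow measurements as outputs, and decides local
structural identifiability by the rank test on the generalized
observability–identifiability matrix

```
OI(x~) = [ d/dx~ (g), d/dx~ (L_f g), d/dx~ (L_f^2 g), ... ]     x~ = (x, p)
```

built from successive Lie derivatives of the outputs, with full rank
`N = n + q` meaning identifiable and observable. Flow measurements enter
either by promoting the flow to a state (method 1, rate constant eliminated
so `N` is unchanged) or by placing the flow expression in the output
(method 2); both give identical verdicts. Ranks are evaluated at generic
points either exactly over a prime field ("symbolic" mode) or with the
randomized `U(0.5, 1.5)` / 10-draw protocol ("numeric" mode), with the
standard early-stopping rules (full rank, rank plateau, order `N - 1`).

On top of single-instance analysis the package sweeps the whole corpus
(3648 instances), classifies measurement patterns as always
sufficient / always insufficient / case-and-motif dependent, diagnoses which
individual parameters and states are identifiable (column-deletion
analysis), verifies Lie symmetry generators that certify unidentifiability,
and aggregates identifiability scores per case, motif, controller type and
family. User-defined rational ODE models can be supplied through a small
plain-text grammar or JSON.

## Worked example

```r
library(motifid)

m  <- buildModel("basic", 3, "B8")     # two disturbances, A inhibits js, jd = kd*E
om <- buildOutputModel(m, c("E", "di"), method = 2)
assess(om, mode = "symbolic", seed = 1)
#> <rank result: basic motif 3 case B8, y = {E,di}, method 2>
#>   rank 7 of N = 8 -> structurally unidentifiable/unobservable
#>   mode symbolic, Lie orders 0..6, stop: rank_plateau

elementIdentifiability(om, mode = "symbolic", seed = 1)
#> <element diagnosis: rank 7 of 8>
#>   identifiable parameters:   ki, ko, kd
#>   unidentifiable parameters: kc, ks, KiA
#>   observable states:         E
#>   unobservable states:       A
```

Measuring the controller concentration together with the inflow disturbance
is not enough: the compensatory gain `kc`, the sensing parameters `ks`,
`KiA` and the trajectory of `A` itself remain undetermined. Measuring both
concentrations instead gives full rank 8. The corresponding unidentifiability
certificate for the simpler case B7 is a translational symmetry, which the
package can verify:

```r
om7 <- buildOutputModel(buildModel("basic", 3, "B7"), c("A", "js"), 2)
checkSymmetry(om7, list(E = -1, ki = quote(kc)), mode = "symbolic", seed = 1)
#> symmetry confirmed: OI(x~) v = 0 (rank 7 of 8)
# i.e. E -> E - eps, ki -> ki + eps*kc leaves both outputs invariant
```

Corpus-level sweeps:

```r
rec <- runSweep(mode = "symbolic", seed = 1)     # all 3648 instances, ~2 min
identifiabilityScore(crossSpeciesSubset(rec))    # 0.80 over 1568 instances
classifyCombos(rec[rec$family == "basic", ])     # pattern classes
aggregateTables(rec)$caseScores                  # per-case score table
```

A thin command-line wrapper is installed with the package:

```sh
motif-ident() { Rscript "$(Rscript -e 'cat(system.file("scripts","motif-ident",package="motifid"))')" "$@"; }
motif-ident analyze --family basic --motif 3 --case B8 --measurements di
motif-ident sweep --family basic --cases B8 --combos dependent --out b8.csv
```

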