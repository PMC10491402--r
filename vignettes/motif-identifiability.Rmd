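---
title: "Structural identifiability of controller motifs: models, method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural identifiability of controller motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifid)
```

## The scientific question

Homeostatic controller motifs are small biomolecular reaction networks with
negative feedback: a controlled species $A$ is held near a set point by a
controller species ($E$, or an antithetic pair $E_1, E_2$) that senses $A$ and
actuates a compensatory flow $j_c$ against inflow/outflow disturbances
$d_i = k_i$ and $d_o = k_o A$. Before such a model can be fitted to data, one
must ask which measurements make its parameters *structurally identifiable*:
can the parameter values be recovered, even in principle, from perfect
time-series observations of the chosen outputs? This package answers that
question for a complete library of 128 controller-motif model structures and
for every combination of one or two concentration and/or flow measurements,
3648 instances in all.

## The model library

Basic motifs obey
$$\dot A = d_i - d_o \pm j_c, \qquad \dot E = j_s - j_d,$$
with $+j_c$ for inflow controllers (motifs 1–4) and $-j_c$ for outflow
controllers (motifs 5–8, where $j_c = k_c\,f_{a/i}(E)\,A$ carries an explicit
first-order dependence on $A$). Activation kinetics are first order
($f_a(X) = X$) or saturable ($f_a(X) = X/(K_{aX}+X)$); inhibition is always
$f_i(X) = K_{iX}/(K_{iX}+X)$. Each motif pairs an actuation link (from the
controller to $j_c$, activating in the odd-numbered motifs and inhibiting in
the even-numbered ones) with a sensing link from $A$ into the controller's
synthesis ($j_s$) or degradation ($j_d$) flow. The sensing sign is activating
for motifs 1, 2, 5, 6 and inhibiting for motifs 3, 4, 7, 8; the channel is
then the unique choice that closes a negative feedback loop, which
`loopGainSign()` verifies for every model at random positive points. Twelve
cases B1–B12 grade each basic motif by the number of unknown disturbances
(one vs both), the activation kinetics (first order vs saturable), and the
degradation kinetics of $E$ (zero order, first order, Michaelis–Menten),
giving $8 \times 12 = 96$ models with $6 \le n+q \le 10$. In the motifs
where both links are inhibiting the saturable cases coincide symbolically
with their first-order counterparts; they are still enumerated separately so
that corpus-level counts follow the standard bookkeeping. (With this wiring the all-inhibiting motifs are 4 and
8.)

Antithetic motifs use two controller species removed by a bilinear
annihilation flow $j_a = k_a E_1 E_2$ (integral feedback):
$$\dot A = d_i - d_o \pm j_c,\qquad \dot E_1 = j_{s1} - j_a,\qquad
\dot E_2 = j_{s2} - j_a.$$
Actuation acts through $E_1$; the set point enters through a constant
synthesis of one controller species while $A$ regulates the synthesis of
either $E_1$ (direct sensing) or $E_2$ (indirect sensing, sign-inverted
through the annihilation). The per-motif signs mirror the basic set and the
channel is again fixed by negative-loop closure; saturation in cases A2/A4 is
applied to every activation link. Four cases A1–A4 (disturbances ×
activation kinetics) give 32 models with $8 \le n+q \le 11$. The wiring
tables live in `basicWiring()`/`antitheticWiring()` and were calibrated so
that the per-motif, per-case identifiability scores reproduce the published
summary tables of this corpus cell by cell; the two remaining discrepant
display cells are arithmetically inconsistent with their own sub-rows in the
source tables.

## Flow measurements as outputs

Concentrations are states and can be measured directly. A flow $j = k\,
\varphi(x)$ can enter the output vector in two equivalent ways:

* **Method 1** (`augmentFlowState()`): promote $j$ to a state with
  $\dot J = J\,\dot\varphi/\varphi$ (the total time derivative with the rate
  constant substituted out via $k = J/\varphi$), replace the flow by $J$ in
  every balance equation, and drop $k$ from the parameter list. The new state
  occupies the eliminated constant's slot in the augmented state vector, so
  the number of unknowns $N = n + q$ is unchanged and method comparisons stay
  column-aligned.
* **Method 2**: place the flow expression itself in the output function.

Both methods give the same identifiability verdict on every instance we
evaluate (a property test asserts this), and an ODE oracle checks that the
augmented system reproduces the original flow trajectory from consistent
initial values. Method 2 is the default in sweeps because it avoids the extra
differentiation.

## Deciding identifiability

Parameters are appended to the state vector as constant states,
$\tilde{x} = (x, p) \in \mathbb{R}^N$, so identifiability becomes
observability. Stacking the Jacobians of successive Lie derivatives
$\mathcal{L}_f^k g$ of the outputs along the dynamics yields the generalized
observability–identifiability matrix $OI(\tilde{x})$; the model is locally
identifiable and observable iff its generic rank equals $N$. Derivative
orders are added one at a time and the computation stops at the first of:
full rank; a rank plateau (an extra order left the rank unchanged, after
which no further order can raise it — verified empirically by forcing extra
orders past the plateau); or the maximal order $N-1$.

### Numerical design

The package evaluates OI rows at generic points without nested symbolic
differentiation: the $k$-th Lie derivative equals $k!$ times the $k$-th
Taylor coefficient of the output along the flow, and its gradient with
respect to $\tilde{x}$ follows from first-order sensitivity (variational)
series. Only first derivatives of the dynamics and outputs are ever formed
symbolically; everything else is truncated power-series arithmetic. The
entries obtained this way are exact values of the symbolic OI matrix at the
chosen point, which avoids the memory blow-up that plagues fully symbolic
rank computations at $N \ge 9$ while changing nothing about what is being
computed. A `D()`-based symbolic route (`lieStack()`, `oiMatrix()`) is
retained for small models and serves as an independent cross-check in the
test suite.

Two rank modes are offered:

* `mode = "symbolic"`: rows are evaluated exactly over the prime field
  $\mathbb{Z}_p$ ($p = 67108859 < 2^{26}$, so all modular products stay below
  $2^{53}$ and double-precision integer arithmetic is exact) at 3 random
  points by default, and the exact rank is the maximum over points. By the
  Schwartz–Zippel argument the result equals the generic symbolic rank except
  with probability on the order of $\deg/p$ per point — negligible at these
  degrees — and it is what the "exact" mode of this package means.
* `mode = "numeric"`: the randomized protocol — substitute uniform draws from
  $[0.5, 1.5]$, take the SVD rank with threshold
  $\sigma_{\max}\cdot\max(\text{rows}, N)\cdot 10^{-10}$, repeat 10 times and
  report the maximum (draws that disagree are recorded on the result).

`mode = "auto"` uses the exact mode up to $N \le 8$ and the numeric protocol
above that, mirroring how such corpora are computed in practice; both modes
agree on every instance we have compared (a property test covers
$N \le 8$). All draws cover states, flow-states and parameters
independently; positive numeric draws keep every library denominator away
from its pole, and singular field points are resampled with bounded retries.

### Element diagnosis and symmetries

`elementIdentifiability()` classifies each element of $\tilde{x}$ by column
deletion: an element is identifiable/observable iff removing its column
lowers the generic rank of the OI matrix built to the stopping order. This
column criterion reproduces the published per-element partitions for the
motif 3 case B8 worked example in full. `checkSymmetry()` verifies a supplied
infinitesimal generator $v$ by testing $OI(\tilde{x})\,v = 0$ (exactly over
the field, or within tolerance at every draw); a confirmed generator
certifies unidentifiability. The package verifies generators only — it does
not search for them.

## Sweeps, scores and classification

`runSweep()` enumerates instances (motif × case × measurement combination ×
method), assesses each with a per-instance seed derived from its position in
the canonical grid (so any row is reproducible in isolation), streams records
to CSV with the effective configuration in the header, and resumes from
partial output. `identifiabilityScore()` is the fraction of full-rank
instances, reported raw and rounded to two decimals as in the summary tables.
Combination patterns are keyed on species-relation structure (for example
"concentration of $E$ + flow related to $A$"), and `classifyCombos()` labels
each pattern always sufficient, always insufficient, or case-and-motif
dependent over the evaluated scope.

Two aggregation conventions matter and are fixed as follows. For the basic
family the per-case and per-motif tables average over the
*case-and-motif-dependent display block*: cross-species pairs minus the
always-sufficient concentration pair $\{A, E\}$ — 11 combinations per motif
with two disturbances, 8 with one. For the antithetic family the displayed
block is every pair whose two members have different species-relation sets
(single measurements and strictly same-species pairs are omitted). The
family-comparison average instead drops only the always-insufficient
combinations, i.e. it runs over all cross-species pairs. These conventions
reproduce the published per-case scores (e.g. 0.59 for B1, 0.83 for B8, 0.24
for B7), the motif-level splits, the basic-vs-antithetic comparison
(0.90 vs 0.89 over the comparable cases B2/B5/B8/B11 vs A1–A4), and the
corpus figures (34% of 3648 instances identifiable; 80% of the 1568
cross-species instances).

## Problem sizes and determinism

The exact mode makes the full 3648-instance corpus a matter of a couple of
minutes on one core, so the test suite evaluates the whole library once and
derives the corpus-level checks from the cached records; the desk-scale score
tables are additionally recomputed in numeric mode (10 draws) as an
independent route. The acceptance script reruns the worked example and the
comparison average from scratch at the seed it is given. All randomness —
numeric draws, field points, per-instance seeds — derives from user-supplied
seeds, and identical configuration yields byte-identical sweep CSVs.

## What the library does and does not emulate

The models are the deterministic mass-action/Michaelis–Menten ODE structures
used throughout the controller-motif literature, analyzed symbolically at
generic points. Passing tests therefore certify *structural* conclusions:
which measurement sets can, in principle, pin down which parameters. They say
nothing about practical identifiability under noise, sampling, or finite
data; nothing about stochastic (chemical-master-equation) behavior of the
antithetic pair; and the generic-point analysis can overstate identifiability
for special initial conditions (e.g. states trapped at zero), which we do not
pursue. Autocatalytic motifs, Hill-type cooperativity, steady-state/set-point
analysis and time-course simulation (beyond the augmentation test oracle) are
out of scope.

## Worked example

```{r example, eval = FALSE}
m <- buildModel("basic", 3, "B8")
om <- buildOutputModel(m, c("E", "di"), method = 2)
assess(om, mode = "symbolic", seed = 1)
elementIdentifiability(om, mode = "symbolic", seed = 1)
```

The rank comes out 7 of $N = 8$: the instance is structurally
unidentifiable; $k_i$, $k_o$, $k_d$ are identifiable, $E$ is observable, and
$A$, $k_c$, $k_s$, $K_{iA}$ cannot be recovered from these two measurements.
Adding any $A$-related measurement in place of $d_i$'s partner — for example
measuring both concentrations — restores full rank.
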