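---
title: "Smallest minimal cut sets by dualization and MILP enumeration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smallest minimal cut sets by dualization and MILP enumeration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcuts)
```

## Model and assumptions

A metabolic network is a stoichiometric matrix $N \in \mathbb{R}^{m
\times n}$ over $m$ internal metabolites and $n$ reactions.  All
analysis in this package rests on the steady-state cone

$$ \{\, r \in \mathbb{R}^n : N r = 0,\; r_i \ge 0 \text{ for } i \in
\mathrm{Irrev} \,\}, $$

i.e. purely stoichiometric, time-free reasoning: no kinetics, no
regulation (a user-supplied list of regulation-disabled reactions can be
applied as zero bounds, but regulatory logic is never computed).
External metabolites are not part of $N$; exchange reactions appear as
one-sided columns.

Two linear-inequality systems over the fluxes complete an intervention
problem:

* the **target polyhedron** $T r \le b$ — the undesired behaviours, all
  of which the knockouts must eliminate.  It must not contain the zero
  flux vector (nothing can knock out "doing nothing");
  `validate_target()` checks this and also reports, via one LP, whether
  the target region is reachable at all;
* optionally the **desired polyhedron** $D r \le d$ — at least one
  element must stay feasible after the cuts (constrained cut sets).

Finite flux bounds (an SBML model's medium bounds, say) are deliberately
*not* part of the cut-set semantics: the dual construction below covers
the homogeneous cone plus the inhomogeneous target rows, so capacity
limits that should shape the target or desired behaviour must be written
as constraint rows.  This keeps one canonical polyhedron per question
and makes the LP self-validation exactly consistent with the
enumeration.  Flux variability analysis and the strain-performance
metrics, by contrast, do honour model bounds — they answer questions
about the bounded model.

## From cut sets to shortest dual modes

Adding the constraints $r = 0$ (one equality per reaction) to the target
system makes it infeasible.  The minimal subsets of these zero-rate
equalities that already induce infeasibility are exactly the minimal cut
sets.  By the Farkas lemma, infeasibility certificates live in the dual
system, assembled by `build_dual_system()`:

* one free variable $u_j$ per metabolite (dual to $N r = 0$),
* one split pair $vp_i, vn_i \ge 0$ per reaction (dual to $r_i = 0$;
  the unsplit $v_i$ is sign-free and both signs must be indicator-visible),
* one variable $w_k \ge 0$ per target row,
* one structural row per reaction: $(N^T u + vp - vn + T^T w)_i \ge 0$
  for irreversible, $= 0$ for reversible reactions,
* the inhomogeneity row $b^T w \le -c$ with a constant $c > 0$.

A feasible dual point whose $v$-support is $S$ certifies that cutting
$S$ blocks the target; support-minimal dual solutions are the MCSs.
Reaction membership is read off the indicators by collapsing
$z_i = zp_i + zn_i$.

Three design points deserve a note:

* **Sign conventions are property-gated, not trusted.**  Published sign
  conventions for dual constructions are notoriously easy to
  mistranscribe, so the construction is accepted only because every
  enumerated support passes the self-validation LP — cutting the support
  makes the primal target system infeasible and every single-member
  deletion restores feasibility.  `smallest_mcs(verify = TRUE)` (the
  default) applies this gate to each returned set; the test-suite
  additionally asserts a 100% pass rate on toy and random networks.
* **The inhomogeneity row is an inequality.**  After rewriting, either
  an equality or an inequality satisfies the self-validation property;
  the inequality $b^T w \le -c$ is used because it leaves the
  certificate cone full-dimensional.  $c$ merely fixes the certificate
  scale: the returned family is identical for any $c > 0$ (checked for
  $c \in \{0.5, 1, 10\}$), and $c = 1$ is the default.
* **Reversible reactions touched by the target are split** into
  forward/backward parts before dualization, each with its own
  $vp$/$vn$ pair, but grouped so that the objective, the size row and
  the integer cuts count the *reaction* once and results are reported on
  the unsplit identifier.  For structural rows this loses nothing: a
  certificate never needs both directions of one reaction, because the
  two split rows constrain their $v$ parts only one-sidedly.

## The MILP engine

Both elementary-mode search (primal) and cut-set search (dual) are one
engine: a linear system with designated non-negative columns, one binary
indicator per designated column with the link semantics
$z = 1 \Leftrightarrow x \ge c$ and $z = 0 \Leftrightarrow x = 0$
(threshold $c = 1$; solutions are rays, so the threshold does not select
against any support), mutual-exclusion rows $z_s + z_t \le 1$ for
forward/backward and $vp$/$vn$ pairs, a row $\sum z \ge 1$ excluding the
zero solution, and a size-control row $sz_{lb} \le \sum z \le sz_{ub}$.

Two enumeration schemes return identical families:

* `enumerate_iterative()`: minimize $\sum z$, record the optimal
  support, add its integer cut, repeat.  The k-th round yields the k-th
  shortest support; termination by infeasibility, size, count or time.
* `enumerate_fixed_size()`: one minimization finds the smallest size
  $s$; each size class is then processed with the size row fixed
  ($sz_{lb} = sz_{ub} = s$) and no objective, as a sequence of pure
  feasibility problems.  The bundled backend has no native solution
  pool, so a class is exhausted by repeated feasibility solves with one
  integer cut per found support — the documented pool-less fallback.
  All cuts are kept for every later size class, which both prevents
  supersets and guarantees that any support found at size $s$ is
  support-minimal (its subsets would have been found at smaller sizes).

Within a size class the solution order is backend-dependent and carries
no meaning; families are compared as sets.  With one thread the engine
is fully deterministic (branch variable: the unfixed binary with the
largest linked continuous value, ties by index; the $z = 1$ child is
explored first).

### Indicator versus big-M mode

Indicator semantics are exact in `mode = "indicator"`: links act through
variable bounds as binaries are fixed during branch and bound, and a
node is accepted only once every binary is fixed.  `mode = "bigM"`
emulates the links inside the LP relaxation with rows $x \le M z$ and
$x \ge c z$, the classic fallback for solvers without indicator support;
integral relaxation solutions are then accepted directly.  Both modes
are exercised by the test-suite and must (and do) return identical
families.

The big-M constant must exceed the dynamic range of the dual
certificates, i.e. the largest $vp/vn$ value after scaling the
certificate so its smallest active value is $c = 1$.  The default is
$M = 10^3$: on the dense simplex backend bundled here, every extra order
of magnitude in $M$ costs about one decimal digit of conditioning in the
link rows, and $10^3$ is comfortably beyond the certificate ranges of
the networks this backend is sized for while keeping the relaxations
numerically clean.  $M$ is configurable (`big_m =`) for models with more
extreme stoichiometric ratios.

### The LP backend

No LP or MILP solver library is assumed.  The package bundles a dense
two-phase primal simplex (C++): general bounds and free variables by
substitution, row equilibration, Dantzig pricing with a switch to
Bland's rule under degeneracy, an extended-precision (`long double`)
tableau, and periodic exact refactorization of the tableau from the
current basis by Gaussian elimination — dual systems are almost entirely
homogeneous and hence massively degenerate, and plain tableau updates
accumulate error along long degenerate pivot walks.  A phase's optimum
is only accepted after a refactorize-and-reprice confirmation.
Tolerances: pivot admission $10^{-9}$, phase-1 feasibility $10^{-9}$,
reduced-cost threshold $10^{-9}$; zero-snapping at $10^{-14}$.  The LP
layer is cross-checked in the tests against an independent
implementation (`boot::simplex`) on random instances.

## Preprocessing

* **Blocked reactions** (`fva_blocked_reactions()`): a reaction whose
  minimal and maximal steady-state flux are both within $10^{-6}$ of
  zero can never carry flux; two LPs per reaction with an early exit on
  a nonzero witness, each objective bounded at $\pm 10^6$ so unbounded
  models still give finite witnesses.
* **Compression** (`compress_network()`): reactions whose kernel-basis
  rows are proportional are fully coupled (fixed flux ratio at steady
  state) and are lumped into one column, the ratio-weighted sum of the
  members.  Coupling is detected on a right-nullspace basis of $N$ with
  proportionality tolerance $10^{-9}$.  Parallel reactions (identical
  columns) are *not* merged — they are alternative cut candidates, not
  coupled fluxes — which is why parallel routes legitimately appear as
  separate members of larger cut sets.  Lump orientation follows the
  irreversible members; a lump is knockable iff a member is.  Cut sets
  found in compressed space expand by Cartesian product over each
  lump's knockable members (`decompress_cutsets()`), and the test-suite
  checks that the compressed path returns exactly the uncompressed
  family.
* **Desired-essential exclusion** (`desired_essential_reactions()`):
  knockable reactions whose single knockout already empties the desired
  polyhedron can never appear in a cMCS and are removed from the search
  space up front.

## Constrained cut sets and strain metrics

`is_cmcs()`/`filter_cmcs()` test each MCS with one feasibility LP
(steady state + desired rows + cut rates at zero); filtering runs after
enumeration, where its cost is negligible next to the MILP.
`evaluate_cutset()` reports, on the bounded model, the mutant's maximal
growth rate, the guaranteed (minimal) product yield at the stated
maximal substrate uptake, and the substrate-specific productivity
(SSP = growth × yield).  SSP is evaluated at the mutant's maximum-growth
flux state, taking the guaranteed yield at that growth rate — the
convention is recorded here because the product-of-quantities definition
leaves the flux state open.  Yield floors are linearized as
$\mathit{product} - Y_{\min}\,\mathit{uptake} \ge 0$ rows
(`yield_constraint()`), with uptake measured as a non-negative
uptake-direction flux.

## What the synthetic fixtures do and do not show

The named toys (chain, diamond, branch, a reversible cycle) are
hand-checkable and anchor the worked examples.  Random fixtures
(`make_random()`) draw 8–12 reactions over 4–5 metabolites with small
integer coefficients, a fixed import and export, about 2–3 metabolites
per reaction and a configurable reversible fraction, resampled until the
network carries nonzero steady-state flux — sized so that the
*independent* ground truths (exhaustive support enumeration by subset
LPs; Berge minimal hitting sets of the target modes) stay tractable,
with the tests and the acceptance script running 10–20 instances in a
few minutes.  Passing on them demonstrates the correctness of the
dualization, the enumeration schemes, both indicator modes and the
compression round-trip.  It does not demonstrate genome-scale
performance: real reconstructions bring thousands of reactions, wide
stoichiometric ranges (biomass coefficients), and MILP instances whose
practical solvability rests on industrial solver machinery (solution
pools, presolve, parallel search) that the bundled backend intentionally
does not replicate.  The hitting-set ground truth is also only valid for
homogeneous targets (ray-scalable behaviours); inhomogeneous targets —
maintenance demands, uptake limits — are therefore validated through the
LP soundness/minimality property instead, which applies universally.

## Degenerate inputs and edge conventions

* A target already unreachable under steady state yields an empty family
  with status `complete` (there is nothing to cut) — reported, not an
  error.
* A target containing the zero flux vector is an error: no knockout can
  ever block it.
* Empty cut sets are valid cMCS *candidates* only in the trivial sense;
  the enumeration never returns the empty support (excluded by
  $\sum z \ge 1$).
* `max_size` is capped at the number of knockable units after
  preprocessing.
* Within-class ties, as noted, are unordered; all outputs are sorted by
  size and then lexicographically for stable files.

## Known limitations

Gene–protein–reaction mapping is out of scope (cut sets are reaction
sets); regulatory rules are consumed only as a disable list; the bundled
MILP engine targets desk-scale validation and method work, not
genome-scale production runs; and SBML support covers the Level 2/3 core
plus FBC flux bounds, not the full breadth of SBML extensions.
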