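# fluxcuts

Enumeration of the smallest minimal cut sets (MCSs) and constrained
minimal cut sets (cMCSs) in stoichiometric metabolic networks.

## The problem

A metabolic network with stoichiometric matrix **N** (m internal
metabolites × n reactions) operates at steady state:

```
N r = 0,      r_i ≥ 0  for irreversible reactions i
```

A *target flux polyhedron* collects the undesired behaviours as linear
inequalities **T r ≤ b** — for instance "biomass formation above a
viability threshold" (synthetic lethality) or "product yield below a
floor" (strain design).  A **minimal cut set** is an inclusion-minimal
set of reaction knockouts that makes the target polyhedron infeasible; a
**constrained MCS** additionally leaves a *desired* polyhedron
**D r ≤ d** non-empty, so the organism keeps at least one wanted mode of
operation (growth, maintenance).  Enumerating the smallest such sets is
the core computation of rational knockout-based strain design.

## The method

Computing MCSs through the full set of elementary modes (EMs) is
infeasible beyond small networks.  Instead, `fluxcuts` exploits the
duality between cut sets and elementary modes:

1. The system "steady state + irreversibility + target rows + all rates
   forced to zero" is infeasible by construction (the zero flux vector
   is not in the target polyhedron).  By the Farkas lemma its dual
   system is feasible, and the support-minimal dual solutions in the
   multipliers **v** of the per-reaction zero-rate constraints
   correspond one-to-one to the MCSs of the primal network.
2. The shortest elementary modes of that dual system — the smallest
   MCSs — are enumerated by a mixed-integer linear program: binary
   indicators `zp_i`/`zn_i` report whether the split dual variables
   `vp_i`/`vn_i` are active, the objective `min Σ (zp_i + zn_i)` finds
   the smallest support, and *integer cuts*
   `Σ_{i∈S} (zp_i + zn_i) ≤ |S| − 1` remove each found support S and all
   of its supersets.  Two schemes are provided: an iterative
   minimize–cut loop, and a faster fixed-size scheme that walks the size
   classes s, s+1, … as pure feasibility problems.
3. cMCSs are obtained by one feasibility LP per MCS against the desired
   polyhedron.

Preprocessing shrinks the search space before dualization: blocked
reactions are removed by flux variability analysis, and fully coupled
reaction subsets (fixed flux ratios at steady state) are lumped into
single reactions, with cut sets expanded back afterwards.  Every
returned set is gated by an LP self-validation: cutting it makes the
target system infeasible, and dropping any single member restores
feasibility.

The MILP is solved by a bundled branch-and-bound engine over a dense
two-phase simplex (extended-precision tableau with periodic basis
refactorization), with exact indicator semantics by default and a big-M
emulation as an alternative link mode.

## Worked example

The "branch" toy network (`R1: → A; R2: A → B; R3: A → C; R4: B →;
R5: C →`): block every flux state that exports C (target `r5 ≥ 1`)
while keeping export of B possible (desired `r4 ≥ 1`).

```r
library(fluxcuts)

net     <- make_toy("branch")
target  <- parse_constraints("1 R5 >= 1")
desired <- parse_constraints("1 R4 >= 1", label = "desired")

validate_target(net, target)
#> target validation:
#>   zero flux vector in target polyhedron: FALSE
#>   target polyhedron non-empty under steady state: TRUE

res <- enumerate_mcs(net, target, desired = desired, max_size = 2)
cutset_table(res$cutsets, cmcs = res$cmcs)
#>   members size cmcs
#> 1      R3    1    1
#> 2      R5    1    1
```

The unconstrained MCSs for this target are {R1}, {R3} and {R5}, but
cutting R1 (the substrate uptake) also kills the desired export of B, so
only {R3} and {R5} survive as constrained MCSs — each a single knockout
that abolishes C export while leaving the A → B → export pathway intact.

The same machinery on the "diamond" network (parallel routes `R2`,`R3`
between the substrate and the product) for target `r4 ≥ 1`:

```r
prob <- intervention_problem(make_toy("diamond"),
                             parse_constraints("1 R4 >= 1"), max_size = 3)
r2 <- smallest_mcs(prob)
cutset_table(r2$cutsets)
#>   members size cmcs
#> 1      R1    1   NA
#> 2      R4    1   NA
#> 3   R2|R3    2   NA
```

Cutting the uptake or the export alone suffices; the parallel interior
routes must be cut together.

A command-line front end covering the whole pipeline (model reading —
SBML Level 3/FBC or a tabular dialect — preprocessing, enumeration,
filtering, TSV/JSON output) is installed as `inst/scripts/fluxcuts`:

```sh
Rscript inst/scripts/fluxcuts cmcs --model branch.tsv --target target.txt \
        --desired desired.txt --max-size 2 --out run
```

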