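# progpot

Coarse-level interaction **rules**, compiled into smooth **switching
functions**, assembled into a low-dimensional **N-body potential**, and
simulated.

Many meso-scale processes — an inhibitor blocking a receptor, a
bond-breaking exchange reaction, templated sequential assembly — are known
at the level of logic ("the AB bond turns off when C comes within R of A")
long before anyone can write down an accurate potential.  `progpot` is for
modelers who want to turn exactly that knowledge into a simulable
Hamiltonian: it takes pairwise potentials plus Boolean interaction rules
and produces an approximate N-body potential that respects the rules, with
analytic forces and reproducible Langevin / velocity-Verlet dynamics.

## The model

The assembled potential is a switched sum of pairwise terms,

```
U(x) = U_bonds(x) + Σ_{p ∈ P} Σ_{j=1..m(p)}  S_{p,j}(x) · φ_{p,j}(‖x_p1 − x_p2‖)
```

* `φ_{p,j}` — an ordinary 1-D pair potential (Morse
  `D(1 − e^{−a(r−r_eq)})² − D`, its repulsive branch for transition-state
  repulsion, harmonic, tabulated); `m(p)` is the pair's multiplicity
  (a pair can carry a stable bond *and* a repulsion term).
* `S_{p,j} ∈ [0,1]` — the **encoding function**: the smoothed form of a
  Boolean **logic function** built from proximity predicates
  `near(i, j, R)` ≡ χ_[0,R)(‖x_i − x_j‖) with AND (`a·b`), OR
  (`a + b − ab`), NOT (`1 − a`).  A rule may never reference the distance
  of its own pair.
* Smoothing replaces each indicator with
  `h_{α,n}(r) = 1 / (1 + (r²/α²)ⁿ)` at `α = R`: `h(0) = 1`,
  `h(α) = 1/2` for every `n ≥ 1`, strictly decreasing, sharper with
  larger `n`, and smooth in Cartesian coordinates even at coincidence.

Forces are exact gradients — including the chain-rule terms through every
switch, which is how an approaching molecule pays a bond's dissociation
energy to turn it off — or, optionally, the frozen-switch approximation
that treats the switches as locally constant.

## Worked example: the inhibitor mechanism

Three two-site rods in the plane: receptor **A**(1,2), active molecule
**B**(3,4), inhibitor **C**(5,6).  Either inhibitor bond — C taking A's
site (2,5) or B's site (3,6) — switches the receptor–substrate bond (2,3)
off, and the two inhibitor bonds exclude each other.

```r
library(progpot)

lg <- inhibitor_logic()
truth_table(lg$exprs, lg$conditions)
#>   c25 c36 L23 L36 L25
#> 1   0   0   1   1   1
#> 2   0   1   0   1   0
#> 3   1   0   0   0   1
#> 4   1   1   0   0   0

sys <- build_inhibitor()
sys
#> <system> 6 particles in d=2 (reduced units), 3 entities, 3 switched terms
#>   AB             (2,3) j=1  morse             L = not(or(near(2,5,3), near(3,6,3)))
#>   AC             (2,5) j=1  morse             L = not(near(3,6,3))
#>   BC             (3,6) j=1  morse             L = not(near(2,5,3))
#>   confinement: flat-bottom well, radius 6, k = 50
effective_dimension(sys)   # the switched potential sees 4 of the 6 sites
#> $reduced
#> [1] 8
#> $full
#> [1] 12
```

The truth table is the designed bond logic: with everything far apart
(row `0 0`) all three bonds are available; each formed inhibitor bond
(rows `0 1`, `1 0`) turns the AB bond off and excludes the other; row
`1 1` is forbidden dynamically.  A realization shows the mechanism at
work — AB is pre-formed, the inhibitor arrives and displaces it:

```r
tr <- run_fixture(sys, seed = 1)          # Langevin, frozen-switch forces
round(c(AB = bond_occupancy(tr, c(2,3), 2.4),
        AC = bond_occupancy(tr, c(2,5), 2.4),
        BC = bond_occupancy(tr, c(3,6), 2.4)), 3)
#>    AB    AC    BC
#> 0.170 0.351 0.340

head(event_sequence(tr, r_on = 2.4, r_off = 4), 5)
#>   i j   kind time frame
#> 1 2 3 formed  0.0     1
#> 2 3 6 formed  6.6    34
#> 3 2 3 broken  9.6    49
#> 4 2 3 formed 28.4   143
#> 5 2 3 broken 30.8   155
```

The receptor–substrate bond spends the least time formed (the inhibitor
bonds together hold C on one of the two sites about 70% of the time), and
the event log shows the designed grammar: the BC inhibitor bond forms at
t = 6.6 and the AB bond, switched off by it, breaks just after.

The bond-breaking reaction fixture quantifies what switching costs: with a
bond of depth `D = 100` held at equilibrium, dragging the third molecule
quasi-statically into the switch-off radius takes

```r
rx <- build_reaction(bias = 1)
w  <- dissociation_work(rx, reaction_scan_geometry(rx, 2, 9.5),
                        particle = 5, target = 2, from = 9.5, to = 2)
round(as.numeric(w), 2)
#> [1] 98.47
```

— the dissociation energy, up to the smoothing tails (1.5% here).

Other fixtures: `build_signaling()` (single-switch motivating system),
`build_reaction(bias)` (AB + C ⇌ AC + B with transition-state repulsion;
`bias` is the well-depth ratio D_AC/D_AB), `build_dna()`
(rule-programmed transcription of a four-base template with strict
binding order and terminal release).  See the vignette in `vignettes/`
for the model, parameter meanings and design rationale.

## Command line

A thin wrapper is installed with the package:

```sh
Rscript inst/scripts/progpot build inhibitor -o inhibitor.yaml
Rscript inst/scripts/progpot run inhibitor.yaml -o out --seed 3
Rscript inst/scripts/progpot analyze out_terms.csv
Rscript inst/scripts/progpot check inhibitor.yaml     # rule validation + gradient audit
```

`run` writes an XYZ trajectory plus per-frame energy and per-term switch
CSVs; configs round-trip losslessly through `read_run_config()` /
`write_run_config()`.

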