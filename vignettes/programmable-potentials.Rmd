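---
title: "Programmable pairwise potentials: from interaction rules to dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Programmable pairwise potentials: from interaction rules to dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progpot)
```

## The model

Many meso-scale processes — signal transduction, bond-breaking reactions,
templated assembly — are naturally described by coarse rules ("the AB bond
turns off when C comes close") rather than by a quantum-accurate potential.
`progpot` compiles such rules into a smooth, low-dimensional N-body
potential and simulates its dynamics.

The potential is a switched sum of ordinary pairwise terms,

$$U(x) \;=\; U_b(x) \;+\; \sum_{p \in \mathcal{P}} \sum_{j=1}^{m(p)}
S_{p,j}(x)\,\varphi_{p,j}(\lVert x_{p_1} - x_{p_2}\rVert),$$

where $U_b$ collects the permanent harmonic constraint bonds holding each
entity (rod, strand, nucleotide) together, $\mathcal{P}$ is the set of
interacting pairs, $m(p)$ is the number of distinct potentials a pair
interacts through (multiplicity: a pair may carry a stable bond *and* a
transition-state repulsion), $\varphi_{p,j}$ is a 1-D pair potential
(Morse, its repulsive branch, harmonic, or tabulated), and $S_{p,j} \in
[0,1]$ is an *encoding function* that switches its term on and off.

Each encoding function is the smoothed twin of a Boolean *logic function*
built from elementary proximity predicates
$E_{q,R}(x) = \chi_{[0,R)}(\lVert x_{q_1}-x_{q_2}\rVert)$ ("particles
$q_1, q_2$ are within $R$") combined with AND, OR, NOT in their algebraic
forms $a\wedge b = ab$, $a\vee b = a+b-ab$, $\neg a = 1-a$.  On $\{0,1\}$
these coincide with every standard definition (including min/max), and
unlike min/max they remain smooth after the replacement below.  One
structural rule is enforced everywhere: a term's logic may not reference
its own pair distance, since the radial dependence of the term is the
business of $\varphi$, not of its switch.  `validate_logic()` checks this
and `add_term()` refuses violations.

## The replacement procedure

Smoothing replaces each proximity indicator with

$$h_{\alpha,n}(r) \;=\; \frac{1}{1 + (r^2/\alpha^2)^n},
\qquad h_{0,n}\equiv 0,\quad h_{\infty,n}\equiv 1 .$$

$\alpha$ is the transition point and $n$ the sharpness: $h(0)=1$,
$h(\alpha)=\tfrac12$ for every $n \ge 1$, $h$ decreases strictly to 0, and
the transition steepens as $n$ grows.  To smooth a predicate with threshold
$R$ one takes $\alpha = R$; at the threshold itself the smoothed predicate
takes the regularizing value $\tfrac12$.  Because $h$ depends on $r$ only
through $r^2$, every encoding function is smooth in Cartesian coordinates,
including at particle coincidence, where its gradient vanishes without
special-casing.  The exponent form was chosen as the simplest closed form
satisfying all of the properties above; any form with these properties
yields the same discrete logic in the sharp limit.

The default sharpness is $n = 6$: sharp enough that "far" ($r > 2\alpha$)
drives a leaf below $2\times10^{-3}$, soft enough that the induced forces
integrate stably at the default time steps.

## Forces, and what the switches cost

`forces()` offers two modes.  `full` is the exact negative gradient,
including the chain-rule terms through every encoding function; these terms
are physically meaningful — they are how an approaching molecule must *pay*
for switching a deep bond off.  `dissociation_work()` makes this
quantitative: dragging the third particle quasi-statically into the switch
radius of a bond of depth $D$ requires work equal to $D$ (up to the
smoothing tails, about 1.5% at the defaults), because the term's energy
rises from $-D$ to $\approx 0$ as its switch closes.  `frozen_switch` mode
drops the encoding gradients (treats the switches as locally constant,
which they are almost everywhere in the sharp limit); it is the
qualitative mode used for the inhibitor and DNA fixtures, where the
mechanism rather than the energy bookkeeping is of interest.

Integration is velocity-Verlet for NVE checks (`run_verlet()`; symplectic,
time-reversible, energy drift about $10^{-5}$ relative over $10^4$ steps on
the reaction fixture at its default step) and BAOAB-discretized Langevin
dynamics at constant temperature (`run_langevin()`) for production runs.
BAOAB was chosen for its configurational accuracy at large steps; with
friction and temperature sent to zero it reduces exactly to Verlet, which
the tests exploit.  One seed drives two deterministically split streams
(Maxwell–Boltzmann initialization, thermostat noise), so every run is
bitwise reproducible.

## Units and default parameters

The fixtures use a reduced unit system: $k_B = 1$ (temperatures are energy
units), lengths in the unit of the Morse equilibrium distance scale, masses
arbitrary.  A `real` preset (kcal/mol, Å, g/mol, $k_B = 0.0019872$; time
unit $\approx 48.9$ fs) is available for users with calibrated potentials.
Defaults shared by the fixtures, each overridable:

| parameter | default | meaning |
|---|---|---|
| $D$ | 100 | Morse depth (energy) |
| $a$ | 1 | Morse width (1/length) |
| $r_{eq}$ | 2 | Morse equilibrium distance (length) |
| $R$ | 3 | proximity threshold for "close" (length) |
| $n$ | 6 | smoothing sharpness |
| mass | 10 | per site |
| $k_{rod}$ | 12500 | constraint-bond stiffness (<2% length fluctuation at $k_BT=20$) |
| $k_BT$ | 20 | run temperature (energy) |
| $\gamma$ | 0.5 | Langevin friction (1/time) |
| $dt$ | 0.002 (0.001 for the reaction) | integrator step |

The run temperature is one fifth of the bond depth: high enough that
switching events occur at observable rates (each realization shows many
exchanges), low enough that bonds are persistent between events.  Each
fixture carries a flat-bottom confining well (radius 6–8, stiffness 50),
the analogue of a simulation box, so that entities keep re-encountering
each other; it is excluded from energy-surface scans and the work probe,
which characterize the interaction potential itself.  The reaction fixture
uses half the default time step because its full-gradient forces include
the stiff switch terms whose curvature sets the NVE accuracy.

## The example systems

**Signaling switch** (`build_signaling()`): three rods, one switched bond —
the (2,3) potential is on exactly while site 5 is far from site 2.

**Inhibitor mechanism** (`build_inhibitor()`): bonds (2,3), (2,5), (3,6)
with logic $L_{(2,3)} = \neg(E_{(2,5)} \vee E_{(3,6)})$,
$L_{(2,5)} = \neg E_{(3,6)}$, $L_{(3,6)} = \neg E_{(2,5)}$: either
inhibitor bond suppresses the receptor–substrate bond, and the two
inhibitor bonds exclude each other.  `truth_table()` reproduces the
4-row bond-logic table, and trajectories never show the excluded bonds
stably formed together.  The potential depends on four of the six
particles: 8 effective dimensions out of 12.

**Bond-breaking reaction** (`build_reaction(bias)`): models
AB + C ⇌ AC + B with multiplicity 2 on each reactive pair: a stable Morse
bond switched off when the competitor enters the switch-off radius
($R_{off} = 1.5\,r_{eq}$ of the partner bond, so a bond turns off before
the incomer reaches its own equilibrium length), plus the repulsive Morse
branch — same $D$, $a$, $r_{eq}$, spliced $C^1$-continuously to zero at
$r_{eq}$ — switched on in exactly the complementary condition,
representing transition-state electron repulsion.  With `bias = 1`
($D_{AC} = D_{AB}$) the energy surface over the two bond lengths is
exactly transposition-symmetric and long Langevin runs split their bound
time evenly between AB and AC; with `bias = 2` the AC well is twice as
deep and realizations spend most of their bound time as AC.

**DNA transcription** (`build_dna()`): a 20-site model — template strand
with promoter, a polymerase rod, and four free base–sugar–phosphate
nucleotides — whose nine switched bonds are gated so that nothing binds
before the polymerase docks, the base pairs A–U, C–G, T–A, G–C form
strictly in template order interleaved with the backbone links, and the
finished transcript and the polymerase release (the polymerase may later
re-dock; the transcript cannot re-attach while its backbone is complete).

Three concretizations in the DNA rules deserve explanation, because the
obvious encodings fail in instructive ways:

* *Predicate radii follow their meaning.*  Conditions of the form "the X–Y
  bond has formed" use radius 2.4 with $n = 8$ — just above the bond
  length, so only a genuinely formed bond (held at $r_{eq} = 2$,
  fluctuating $\pm 0.16$ under the narrowed wells, $a = 2$) satisfies
  them.  With reach-type radii ($R = 3$) a transient passage of two sites
  is indistinguishable from a bond, and pilot runs assembled backbones
  abiotically.  The polymerase-docked predicate, by contrast, asks whether
  the polymerase is on station and keeps the generous radius 3: a docked
  polymerase momentarily stretched to $2.5$ must still read as docked,
  otherwise the *complement* of this predicate leaks into the persistence
  clauses below.
* *Persistence needs the detached-state signature.*  "A backbone link stays
  on once the backbone is complete" cannot be encoded as a bare conjunction
  of the other backbone proximities: such a clause is memoryless and fires
  on any transient sugar–phosphate contact, scrambling the designed order
  (and for the last link the bare clause logically absorbs its own gating
  rule).  Each persistence clause is therefore the own-pair-excluded
  backbone conjunction AND "polymerase released AND no base pair formed" —
  false throughout transcription, true exactly in the post-release state
  the clause exists for.
* *Deep wells, slow diffusion.*  The DNA bonds use $D = 200$
  ($10\,k_BT$): a formed rung must persist for the whole cascade, and
  release is by switching, never by thermal escape.  Friction is $\gamma =
  2$ and the template is anchored at the center with the polymerase
  starting near the promoter, so binding is resolved, sequential diffusion
  rather than simultaneous capture of pre-positioned molecules.

## Analysis conventions

Bond occupancy is read off distance traces exactly as one reads a
realization's distance-trace plot: the fraction of frames with $r < r_{on}$
($r_{on} = 1.2\,r_{eq} = 2.4$ by default).  Discrete formed/broken events
use two-threshold (Schmitt-trigger) detection, $r_{on} = 2.4$ and $r_{off}
= 2\,r_{eq} = 4$, which debounces Langevin jitter and makes events
alternate structurally.  For *mechanism* checks in the logic-gated
fixtures, a bond counts as formed only when its pair is close **and** its
own encoding exceeds $\tfrac12$ — a close pair whose switch is off is a
passive flyby, not a bond.  Polymerase release at the end of transcription
is likewise read from its switch turning off (the designed signal); how
far the released polymerase then diffuses before re-docking is incidental.

## What the synthetic systems do and do not show

The fixtures are the designed study conditions, not data: they demonstrate
that the compiled potentials *reproduce the coarse behavior that was
programmed into them* — the truth tables, the exclusion grammar, the
occupancy symmetry and bias, the transcription order — and that the
numerics (gradients, integrators, event detection) are correct.  Passing
them says nothing about whether a particular real molecular system is well
described by switched pairwise potentials: angles, many-body sterics,
hydrodynamics, and excluded volume are all absent.  The absence of excluded
volume matters even inside the model: unswitched particles can pass
through each other, which is why "bond formed" must be measured jointly
with the switch value, and why the DNA fixture needed the design choices
above.

## Numerical choices and degenerate inputs

* Thresholds are strict ($r = R$ gives 0; smoothed value $\tfrac12$).
* Coincident particles in a smoothed leaf are regular ($h$ is a function
  of $r^2$); the crisp elementary predicate at $r = 0$ is 1 for any
  $R > 0$.
* $n$-ary AND/OR fold left over the binary forms (associative, so the
  fold order is irrelevant); compiled encodings evaluate a postfix tape
  with a reverse (adjoint) sweep for exact leaf sensitivities.
* The compiled engine covers the closed-form potentials; systems with
  tabulated terms evaluate through the pure-R path (monotone cubic
  interpolation, clamped flat outside the table) and cannot be integrated
  in time.
* Integration aborts with the first offending step on non-finite
  coordinates (time step too large).
* Problem sizes in the shipped checks: random-system audits use up to 8
  particles; ensemble checks use 10 seeds per condition with $5\times10^5$
  to $2\times10^6$ steps per realization — enough that every fixture shows
  its designed behavior many times per run.

## Known limitations

Rules are limited to pairwise-distance predicates (no angles, velocities,
or history); the logic is memoryless, so "remains on" semantics can only
be approximated by state signatures as described above; no periodic
boundaries, cutoffs or neighbor lists (all fixtures are small); and the
`real` unit preset performs no unit conversion beyond $k_B$ — consistent
inputs are the user's responsibility.
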