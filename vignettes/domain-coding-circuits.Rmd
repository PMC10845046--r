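---
title: "Domain-coded strand-displacement circuits: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-coded strand-displacement circuits: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsdcircuit)
```

## The signal model

In most DNA strand-displacement (DSD) logic architectures a wire's Boolean
value is encoded in the *concentration* of a species, which makes NOT gates
unstable (an inverter can fire before its upstream gate has produced
anything) and forces dual-rail designs that double the gate count.  The
domain-coding strategy implemented here encodes the value *structurally*:
every signal is a single 7-domain strand

```
flank – code(left) – flank – T – flank – code(right) – flank
```

split by a central toehold `T`.  The left code domain is what an upstream
gate hybridizes with; the right code domain *is* the logic value of the
strand.  The four code pairs (0,0), (0,1), (1,0), (1,1) are the variants
A0–A3 of a wire.  Flank and code domains are wire-specific, so signals on
different wires cannot cross-react; this is what makes a multi-wire circuit
well-posed even though all species share one solution.

```{r}
make_signal_strand("X0", 0, 1)$variant   # A1: left code 0, logic value 1
```

## Mapping modules: the truth table is the coding

An n-input *mapping module* is a bank of `2^n` gate duplexes, one per input
combination.  The duplex for combination `x` binds the inputs sequentially
(the first input wire is consumed first; each intermediate exposes exactly
one new toehold, so no ordering ties can arise) and finally releases an
output strand whose logic value is the module's coding bit `k[index(x)+1]`.
The coding vector `k_1..k_{2^n}` is therefore literally the truth-table
column: one module family realizes all `2^(2^n)` n-input Boolean functions
— 4 at one input (SET0, SET1, YES, NOT), 16 at two, 256 at three:

```{r}
enumerate_realizable_functions(1)$names
enumerate_realizable_functions(3)$count
```

Negation costs nothing: NOT is the coding `(1, 0)` on the same two duplexes
a YES gate uses.  A mismatched encounter (an input whose logic value is not
the one the exposed position accepts) is modelled as unreactive — consuming
the duplex would disable the module for later inputs, and the net effect of
a reversible toehold touch with no branch-migration pathway is nil.

## Auxiliary gates

* **Fan-out** (`make_fanout_gate`): per logic value, `m` duplexes each
  release one copy strand onto its own output wire; a fuel strand displaces
  the input back out of each post-displacement intermediate, so the input
  acts catalytically.  Both branches are implemented symmetrically.  Fuel
  concentration is twice the summed same-path duplex concentration.
* **Amplifier** (`make_amplifier`): the same catalytic motif with one
  duplex per logic value; an attenuated input cycles until the output
  plateau reaches the duplex concentration (fuel at 2x).
* **Reporter** (`make_reporter`): two fluorophore/quencher duplexes; Rep0
  converts logic-0 strands into the fluorescence species `Y_<label>1`, Rep1
  converts logic-1 strands into `Y_<label>2`, irreversibly, so
  fluorescence is monotone.  The reporter duplex concentration is not
  prescribed by the architecture; the default is the circuit unit (1X),
  configurable per netlist.

## Compilation

`compile_netlist()` expands gates in wire-topological order, tracking which
signal variants are *producible* on each wire under the given input
assignment.  All initially-present material (inputs, every gate duplex,
fuels, reporters) enters the network whether or not it can react;
intermediates and wastes are created only along reachable pathways.  Each
productive toehold-mediated displacement is one irreversible bimolecular
reaction at `k_bind = 3.0e-4 /nM/s`.  An optional two-step mode makes the
toehold encounter explicit (bind at `k_bind`, unbind at
`k_unbind = 0.1126 /s`, then irreversible branch migration at
`k_migrate`, default 10 /s).  One-step is the default: the architecture
specifies the two DSD rate constants but not the enumeration depth, and the
one-step network reproduces the observed timescales with far fewer species.
`k_migrate` has no prescribed value anywhere; 10 /s is a typical branch-
migration resolution rate for ~15 nt domains and only matters in two-step
mode.

Every species is identified by its canonical structure — the sorted multiset
of elementary strands it contains — so equality is structural, names are
only for reporting, and every reaction necessarily conserves each
elementary-strand count (`check_strand_conservation()` verifies this on
every compiled network).

Duplex top strands are row-specific species: a duplex's output strand is
complementary to part of its row-specific template, so two rows of the same
module carry structurally distinct tops even when their output codes agree.
Functionally all of a wire's variants with the same right code are
interchangeable, and downstream expansion treats them so.

### Wiring discipline and literal buses

Each wire has exactly one driver.  A wire consumed by more than one
downstream gate must normally be driven through a fan-out gate — compiling
such a netlist without one is an error.  A netlist may, however, declare a
wire a *shared bus* (`shared_wires`): the consumers then compete for one
strand pool.  The prebuilt exponentiation circuit uses this for its decoder
literals: each input `X_i` passes a fan-out-two (one branch to its
inverter, one branch the shared positive-literal bus of the AND array), and
each inverter output is likewise a shared negative-literal bus.  The
competition attenuates the AND outputs (each module's first-stage duplexes
take an equal share of the bus pool), which is exactly what the amplifier
stage is for: attenuation is restored to full concentration before
reporting, and decoding uses plateau *ratios*, so correctness is
unaffected.

### Species accounting

Two conventions are implemented because they answer different questions:

* `count_initial_species(crn)` — every distinct species with nonzero
  initial concentration (the full mixed inventory; 139 for the
  exponentiation circuit).
* `count_initial_species(crn, involved_only = TRUE)` — the initially
  present species that participate in at least one reaction for the given
  input: the species *involved in the calculation*.  For the
  exponentiation circuit this is 71, for every input word: 3 inputs, 9
  fan-out species on the taken paths (2 duplexes + 1 fuel per input), 3
  matching inverter duplexes, 32 AND duplexes (4 prefix-matching rows per
  module), 16 amplifier species and 8 reporter duplexes.
* `count_component_strands(crn, "core")` — distinct elementary strands
  over inputs, mapping-module duplexes and fan-out gates (a duplex
  contributes its two component strands).  The square-root circuit's
  computational core counts 64: 4 inputs + 2 fan-out-twos at 10 strands
  each + 8 strands for the two-input module + 32 for the four-input
  module.

## Simulation and decoding

`simulate()` integrates the mass-action ODEs with `deSolve::lsodes`
(sparse, stiff-capable), `rtol = 1e-8`, `atol = 1e-6` nM, on a fixed output
grid (default 0.1 s).  Concentrations are in nM, time in s, bimolecular
rates in 1/(nM s).  The settle time is the earliest grid time after which
every tracked fluorescence output stays within a 5% band of its final
value; the band has an absolute floor equal to the solver `atol` so
identically-zero outputs settle at t = 0.  The 5% criterion is a package
choice — the architecture only speaks of reaching a stable state — and
`epsilon` is an argument everywhere.

Decoding compares the two fluorophores of each reported wire: bit 1 if
`Y_<x>2` exceeds `Y_<x>1` tenfold, bit 0 in the symmetric case, and an
error otherwise — an ambiguous ratio signals a malfunction and is never
guessed.  Ratios are used instead of absolute thresholds because absolute
fluorescence scales with the circuit unit (10^4 nM for the square-root
circuit, 10^3 nM for exponentiation).

## The prebuilt circuits

* **Four-bit square root** (`build_sqrt4_netlist`): `Y1 = OR(X2, X3)` as a
  two-input module and `Y0` as a four-input module coded from the
  floor-square-root column, with fan-out-twos on the shared inputs `X2`,
  `X3` and reporters on both outputs, at 1X = 10,000 nM.  This is the
  minimal mapping-module realization of the function.
* **Exponentiation 2^x** (`build_exponentiation_netlist`): the decoder
  netlist — 3 one-input NOT modules, 8 three-input AND modules, fan-outs,
  8 amplifiers, 8 reporters — at 1X = 1,000 nM.  The mapping-module family
  could absorb the inverters (a module matches both codes natively), but
  the explicit-inverter decoder is the reference structure and is kept.

Simulation horizons are 300 s (grid 0.1 s) for the square-root circuit and
3,000 s (grid 1 s) for exponentiation — roughly an order of magnitude
beyond the observed settle scales (~4 s and ~280 s), so the plateau used by
the settle detector is a genuine steady state.  `verify_truth_table()`
compiles and simulates one input assignment per run, decodes, and compares
against the defining table; all 16 square-root rows and all 8
exponentiation rows decode correctly under the defaults, and flipping any
single coding bit corrupts exactly the rows that coding position encodes
(`inject_fault()`).

## Sequence design

The circuits are complete at the domain level; `assign_sequences()` exists
to hand an experimentalist concrete strands.  It draws each base domain
(toeholds 6 nt, long domains 15 nt, GC in [0.3, 0.7], optional three-letter
toeholds) under a *canonical-orientation* constraint: every 6-nt window
must be strictly smaller, base-wise, than its reverse complement.  Exactly
one of a k-mer and its reverse complement can satisfy this (palindromes
never do), so no hexamer and its complement can both occur anywhere in the
pool — unintended complementary runs of ≥ 6 nt between non-partner domains
are excluded *by construction*, for any number of domains.  This matters
because plain rejection sampling cannot work at circuit scale: a compiled
exponentiation circuit carries thousands of hexamer windows against only
4,096 possible hexamers, so collisions are guaranteed by pigeonhole and a
resampling loop never converges.  A k-mer screen still verifies the final
pool.  The design is deterministic given its seed; `write_fasta()` emits
one record per elementary strand.  What this does **not** do:
thermodynamics.  There is no partition-function or minimum-free-energy
check, no secondary-structure screening beyond the complementarity rule —
domain-level design is heuristic support, not a lab-ready guarantee.

## What the simulations do and do not show

The deterministic mass-action model reproduces the architecture's logic,
counting, catalysis and timescale claims.  It deliberately omits leak
reactions, spurious remote-toehold interactions, 4-way branch migration,
fluorophore photochemistry and thermal fluctuations; a decoded word from
`simulate()` shows the *design* is consistent, not that a wet-lab
implementation is.  Dual-rail baseline circuits are out of scope throughout;
their published figures are context, not reimplementation targets.

## Numerical choices, degenerate inputs, limitations

* Tolerances `rtol 1e-8 / atol 1e-6` nM keep plateau shifts under halved
  tolerances below 0.1% on both prebuilt circuits; agreement with an
  independent fixed-step RK4 integrator on small sub-networks is < 1e-4.
* Empty netlists compile to empty (valid) networks and export valid empty
  SBML; zero inputs yield identically-zero fluorescence and a decoding
  error rather than a guess.
* Compilation is deterministic: identical netlists give byte-identical
  species tables and decode reports.
* SBML L3V2 export/import is implemented directly over `xml2` and
  round-trips species, initial concentrations, stoichiometries and rate
  constants through its own reader.
* Mass-action rates assume a well-mixed, isothermal solution; there is no
  spatial or stochastic mode (a fixed-step deterministic oracle is used in
  the test suite only).
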