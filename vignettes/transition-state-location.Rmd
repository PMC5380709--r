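---
title: "Locating and validating transition states with biased replica pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating and validating transition states with biased replica pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tslocate)
```

## The problem

A chemical reaction on a potential energy surface (PES) connects two
minima — reactant and product — through a first-order saddle point, the
transition state: a stationary point with exactly one negative Hessian
eigenvalue whose eigenvector points along the reaction. Minima are easy to
find with standard geometry optimization; saddles are not, because they are
maxima along one direction and minima along all others, and
gradient-following methods started far from the saddle either fall into a
minimum or fail outright. For enzyme-sized systems (thousands of atoms,
very flat conformational energy landscapes) the problem is harder still:
almost all coordinates are spectators, and any method must tolerate large
floppy displacements that cost almost no energy.

`tslocate` implements a double-ended answer. Both endpoint structures are
treated as replicas on the same PES and relaxed *simultaneously* under a
combined objective

$$ E(A') + E(G') + c\,R^2_{A'G'}, $$

where $R_{A'G'}$ is the plain (non-mass-weighted) Cartesian distance
between the replicas and $c$ a bias constant. Each evaluation involves
three quantities — the two energies and the squared distance — and the
bias pulls the replicas toward each other, up opposite sides of the
barrier. Stepwise growth of $c$ walks both replicas to the saddle region;
averaging the final pair gives the transition-state guess.

## The ascent and its failure mode

At a given bias the relaxed pair balances the surface gradient against the
bias force, so the two unbiased gradients point in nearly opposite
directions: their angle stays near 180°. Close to the saddle the profile
becomes parabolic and a further bias increase can push one replica through
to the other side, after which both replicas would slide into the same
basin — a catastrophic collapse. `ascend_barrier()` therefore monitors the
gradient angle and terminates on any significant drop (default floor
150°), or when the separation falls under `r_stop`. A collapse that
happens *inside* one relaxation (so the angle monitor never saw it coming)
is detected after the fact — the pair merged at a point that relaxes
downhill — rolled back to the last stable pair, and retried with a gentler
bias increment; if no increment is gentle enough, the ascent terminates on
the instability signal and the last stable pair is averaged.

A merged pair is not always a failure: if the two endpoints actually share
a basin there is no barrier at all. The two cases are distinguished by
probing the merged point — small displacements along the last inter-replica
direction are relaxed, and if both probes fall back onto the merged point it
is a minimum (no barrier, a distinct signal, not an error); if they roll
away it is the saddle itself and the run has simply converged.

Defaults: `c_initial = 2` kcal/mol/Å² (the productive initial range is
roughly 1–3: large enough to move the floppy coordinates, small enough not
to climb), geometric growth ×1.5 per step (the growth law is a design
choice; geometric growth keeps step counts logarithmic in the final bias,
and the rollback logic adapts it near the top), `r_stop = 3.0` Å for
protein-scale problems. On the desk-scale test surfaces we instead scale
`r_stop` to about 1 % of the initial separation, since 3 Å would be larger
than the whole problem. `locate_ts()` applies that scaling automatically.

On the strongly asymmetric Müller–Brown surface the stable straddling
branch of the biased pair disappears at moderate separation, so the ascent
usually ends on the instability monitor with the replicas a few tenths of
a unit apart. The averaged guess is then not yet at the saddle — it does
not need to be: it reliably lies inside the refinement's convergence
region, and the refined saddles agree with an independent grid+Newton
catalogue to ~1e-8 in position.

## Partitioned refinement

The guess is refined by `refine_saddle()`, which partitions the atoms into
a small *active* set — those making and breaking bonds, found by diffing
the covalent topologies of the two endpoints (`diff_topology()`, typically
2–4 atoms) — and the environment. It alternates (i) stationary-point
refinement of the active atoms with the environment frozen and (ii) energy
minimization of the environment with the active atoms frozen. Each stage
induces small forces on the other set; the alternation converges rapidly,
normally in two to five rounds (a warning fires beyond five).

Stage (i) is a damped Newton iteration on the active-subspace Hessian
(central differences of the analytic gradient, step `h = 5e-3` Å,
symmetrized), with an eigenvalue pseudo-inverse so that indefinite
Hessians are followed *toward* the saddle, and steps accepted only when
they reduce the active gradient norm — a descent on $|g|^2$ that stays
robust far from the quadratic region, where plain eigenvector-following
methods fail. Near-null directions (overall translations/rotations of the
active set, or the inert third coordinate of the 2-D surfaces) are
projected out of the Newton step.

For heats of formation precise enough to difference, `exhaustive_minimize()`
continues descent until the energy fails to improve over a window of 100
consecutive cycles, and never moves frozen atoms (bit-identical, by
construction — they are simply not parameters of the optimization). After
the environment of a refined transition state has been exhaustively relaxed
with the reactive atoms frozen, releasing those atoms for a residual
gradient minimization must change the energy by under 0.2 kcal/mol and
positions by under 0.001 Å; `check_release()` measures exactly that, and
the test suite enforces those thresholds on the fixtures.

## Vibrational validation

A candidate saddle is accepted only if it has exactly one imaginary normal
mode, large in magnitude and localized on the reactive atoms. Because
reaction-coordinate modes are necessarily well separated from the real
spectrum, the analysis can be restricted to the reactive subset:
`partial_hessian()` builds the subset Hessian, `normal_modes()`
mass-weights and diagonalizes it, and `validate_ts()` applies the three
checks. Wavenumbers are reported as signed cm⁻¹ (negative = imaginary)
via the conversion $\tilde\nu = \sqrt{\lambda}/(2\pi c)$ computed from
physical constants — 1 kcal/mol/Å² over 1 amu is 108.59 cm⁻¹, which the
suite checks against the closed form. Defaults `min_imag = 50` cm⁻¹ and
localization ≥ 0.5 are deliberately permissive: genuine reaction modes on
the fixtures (and in published enzyme work) sit far above both. The
"intensity" of a mode on a set of atoms is defined here as its squared
mass-weighted amplitude fraction.

## Intrinsic reaction coordinate

`displace_along_mode()` nudges the validated saddle by 0.05 mass-weighted
Å along the imaginary mode (the Cartesian image $v_i/\sqrt{m_i}$,
renormalized), in both signs; `follow_irc()` then runs damped
mass-weighted steepest descent with a fixed 0.02 step, terminating when
the per-step energy drop falls below 1e-4 kcal/mol (the step and limit are
ours — configurable — as is the displacement). Positions on the path are
reported as signed cumulative arc length in mass-weighted coordinates
(monotone by construction), alongside the straight-line mass-weighted
distance from the saddle, which is the quantity used for barrier-width
bookkeeping; on a curved path the two differ. PES *distances* elsewhere in
the package are never mass-weighted; mass enters only here.

The endpoint is polished by a descent whose per-cycle displacement is
capped at 0.1 Å. The cap exists because unconstrained quasi-Newton
optimization from the end of a shallow downhill path can take unexpectedly
large steps and land on the *other* branch, reversing the apparent
terminus; the suite checks across 20 seeded perturbations that the capped
polish never flips the branch. `classify_terminus()` accepts a terminus
only when a unique candidate intermediate lies within tolerance;
`barrier_base()` finds where the slope first collapses past the steepest
segment, which measures barrier width while excluding the essentially flat
plain between the barrier bottom and the exact minima.

For reactions not expected to have a barrier at all (e.g. a product
diffusing out of a binding site), `drag_toward()` pulls the system toward
a target under a stepwise-tightened distance constraint with step-capped
relaxation, recording the unbiased energy of every accepted substep; the
maximum upward fluctuation estimates any barrier met on the way (within
~1 % of the oracle barrier height on the test surface when the pull
constant dominates the surface slopes), and a large fluctuation triggers
advice to run the full double-ended search.

## Test surfaces and the synthetic fixtures

Two built-in engines make the whole pipeline testable at desk scale:

* **Müller–Brown** (`mb_engine()`): the standard four-term exponential
  2-D surface (three minima, two saddles), wrapped as a one-atom
  pseudo-geometry with unit mass so every downstream operation applies
  unchanged. Units are treated as kcal/mol and Å for coherence. The
  exponent is clamped at 40 so far-field probe points stay finite. Its
  stationary-point catalogue is *computed*, never hand-typed: Newton
  refinement (analytic gradient and Hessian) from a dense grid of starts,
  deduplicated and classified by eigenvalue spectrum
  (`mb_stationary_points()`).
* **Proton transfer** (`proton_engine()`): donor–H–acceptor with two
  Morse bonds competing for the hydrogen, an exponential donor–acceptor
  repulsion, and seeded spectator atoms held by harmonic tethers. Default
  parameters (well depth 110 kcal/mol, r₀ = 1.0 Å, stiffness 3.5 Å⁻¹,
  repulsion 1.5e8·exp(−6.0 R)) were chosen once so that the *relaxed*
  system keeps a genuine double well — softer parameter sets collapse into
  a centered, shared-proton single well, which is chemically interesting
  but useless as a barrier fixture. The resulting barrier is ≈ 13.6
  kcal/mol with an imaginary mode ≈ 2500i cm⁻¹, in the range typical of
  proton transfers.

What the fixtures emulate: a localized bond rearrangement embedded in an
indifferent environment, consistent endpoint atom ordering, and an
engine whose gradient is exact. What they do *not* emulate: engine noise
and SCF convergence failures, the 10³–10⁴-dimensional flatness of real
protein landscapes, solvation, or conformational multiplicity — so green
tests here demonstrate the correctness of the algorithms, not the
hardness of real enzyme applications. Likewise, the published enzyme
numbers shipped with the package (heats of formation, residue charges for
the chymotrypsin catalytic cycle) are consumed as *inputs* to the
thermodynamic-cycle arithmetic; recomputing them would require a
semiempirical quantum engine on a 4,586-atom system, far outside desk
scale. The `external_engine()` adapter documents the plain-text protocol
(`ENERGY`/`GRAD` lines, a reuse flag for frozen internal state) through
which such an engine can drive this package on real systems, including the
single-expensive-evaluation-per-bias-step state-reuse contract.

## Thermodynamic cycles

The energetics module is pure, exact bookkeeping. For two charged sites A
and B, four systems (both ionized; each singly neutralized; both
neutralized) give the interaction energy as the double difference
$E = \Delta H_f(A) + \Delta H_f(D) - \Delta H_f(B) - \Delta H_f(C)$
(`electrostatic_interaction()`); neutralizations are designed with
`mutate_for_neutralization()` — delete a proton, replace a side chain, or
delete a donor hydrogen and promote the donor element to the next atomic
number (N→O, O→F) so no radical is left. Hydrogen-bond energy changes use
the analogous H/X double difference (`hbond_energy_change()`), mutation
effects on a reaction step use `mutation_delta()`, and `charge_audit()`
totals per-residue charge changes at a site. Printed-table comparisons in
the tests use a 0.02 kcal/mol tolerance where the sources are 2-decimal
rounded inputs, and exact equality where the arithmetic is exact. The
shipped chymotrypsin tables flag one quirk of their source: two
consecutive four-system blocks describe different cycles under similar
headings, so the tables are keyed by system descriptions, not captions.
Hydrogen-bond energies are not additive — the three individual oxyanion-
site bonds sum to 33.97 kcal/mol against 32.06 when deleted jointly — and
the package reports both rather than hiding the 1.9 kcal/mol discrepancy.

## Numerical choices, sizes, limitations

* Inner minimizations use L-BFGS-B (`stats::optim`); contract: monotone
  objective decrease. Finite-difference Hessian step 5e-3 Å; bond
  detection at 1.2 × covalent-radius sum (the connectivity criterion is a
  standard heuristic — the method itself never defines one).
* Conformability demands identical element sequences; no atom matching is
  attempted. Distances are plain Cartesian; only the IRC mass-weights.
* Problem sizes used throughout the suite: 2-D surfaces and a 7-atom
  proton system; the ascent takes ~10–15 bias steps and the whole
  locate–refine–validate–IRC chain runs in under a second per fixture.
* Not covered (deliberately): synchronous-transit/NEB/dimer methods,
  higher-order IRC integrators, full 3N vibrational analysis with
  rotational projection, thermochemistry, solvation, and any electronic-
  structure machinery.

## A worked run

```{r}
fx <- make_proton_transfer(fixture_spec("proton", seed = 1))
pes <- proton_engine(fx$params, fx$donor, fx$h, fx$acceptor,
                     g0 = fx$reactant)
res <- locate_ts(pes, fx$reactant, fx$product)
res$validation
irc <- irc_both_ways(pes, res$ts,
                     candidates = list(reactant = res$reactant,
                                       product = res$product),
                     tol = 0.2)
c(barrier = res$ts$energy - pes_evaluate(pes, res$reactant)$energy,
  forward = irc$forward$terminus, reverse = irc$reverse$terminus)
```
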