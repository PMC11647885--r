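---
title: "Classical hydroxide models and stochastic proton hopping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classical hydroxide models and stochastic proton hopping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The hydroxide ion moves through water mostly by Grotthuss hopping: a
neighbouring water donates a proton along a hydrogen bond, the water becomes
the new hydroxide, and the charge advances without the molecule itself
travelling. Fixed-topology classical force fields cannot do this, and they
also overcoordinate OH⁻ — typical two-particle (O,H) point-charge models
surround the ion with 6+ first-shell waters, while neutron diffraction and
ab-initio MD put the number near 4–4.5, with a tetrahedral, 3-bond-accepting
state believed to be the hop-ready configuration.

`ohmd` implements, in one self-contained package, the pieces needed to study
this at desk scale: a catalogue of classical OH⁻ models in TIP3P water, a
minimal rigid-body NVT engine, a stochastic proton-hopping layer with a
threshold-Metropolis rule, χ² steepest-descent parameterization of LJ
parameters against solvation-structure observables, windowed free-energy
perturbation for solvation free energies, and the trajectory analyses
(RDF/CN, Einstein diffusion, electrophoretic mobility, hop/rattle
classification).

## The models

All molecules are rigid. TIP3P is the CHARMM-modified variant (O: q −0.834 e,
ε 0.1521 kcal/mol, Rmin/2 1.7682 Å; H: +0.417 e, 0.046, 0.2245; O–H
0.9572 Å, H–O–H 104.52°). The hydroxide catalogue (`model_catalog()`,
shipped as `extdata/models.yaml`) holds:

* **OH_full** — the full-charge 2p model (O −1.3 e, H +0.3 e, original
  CHARMM LJ). Overcoordinated; the package's reference point.
* **M07 / M09** — reduced-charge 2p models (O −1.0 / −1.2 e, H +0.3 e).
  M07 trades solvation free energy for a better coordination number; M09
  the reverse.
* **OH_2p_opt** — the endpoint of the LJ optimization (q_H +0.0742 e,
  Rmin/2_H 2.1051 Å). Catalogued but flagged unusable for hopping: the huge
  hydrogen Rmin causes ~10²–10³ kcal/mol clashes upon identity swaps.
* **OH_3AP** — O carries +0.4 e and three auxiliary particles (1 amu,
  −0.458 e each) sit 0.70 Å from the oxygen, mimicking the lone pairs;
  net −0.9 e. This is the hopping-capable model with a 3-accepted-bond
  tetrahedral-leaning first shell.
* **OH_5AP** — catalogued for completeness from its published parameters;
  its AP placement angles are not published in machine-readable form, so the
  geometry here is an approximate synthetic reconstruction, and no
  observable is validated against it.

One transcription decision: the published 3AP parameter table prints
q_H = +0.7400 e, which contradicts the model's stated net charge of −0.9 e.
The catalogue stores +0.0740 e, which reproduces the net charge exactly
(0.4 + 0.074 − 3×0.458 = −0.9) and matches the hydrogen-charge pattern of
the optimized 2p model (+0.0742). The YAML notes this in place.

AP placement angles are configurable; the defaults put the APs at 110° from
the O–H axis with 120° azimuthal spacing. Standalone hydroxides use an O–H
bond of 0.97 Å; titratable residues use TIP3P geometry throughout so that
their protonated state is *exactly* TIP3P (verified in the tests via the
parameter variants).

## The engine

Velocity-Verlet with SHAKE/RATTLE distance constraints (every intramolecular
pair is constrained; tolerance 10⁻⁸ Å, ≤500 iterations), a velocity-rescale
thermostat (check every 10 steps, rescale when |T − T₀| > 5 K), an optional
uniform field along z (1 e·V = 23.0609 kcal/mol), and flat-bottom harmonic
z-walls (k = 10 kcal/mol/Å²) used to keep single-file water inside nanotube
ends. Units: Å, ps, amu, kcal/mol, e; k_C = 332.0636 kcal·Å/(mol·e²),
k_B = 0.0019872 kcal/(mol·K).

Three electrostatics schemes are available. **Force-shifted Coulomb
truncation** at the vdW cutoff keeps forces continuous (NVE drift on a
water dimer is below 0.5% of the mean kinetic energy over 10 ps) and is
the default for non-periodic systems such as the nanotube. **Smooth
Ewald** (erfc-screened real space at the cutoff plus a reciprocal-space
sum with net-charge background; the screened kernel is evaluated through a
cubic-Hermite table whose analytic derivative supplies the force, so
energy/force consistency holds to machine precision) is used for all bulk
solvation-structure runs: truncation schemes reduce the Coulomb pair
energy substantially at first-shell distances (about half at 2.6 Å with a
9 Å force-shifted cutoff) and measurably under-bind the ion's first shell
— the full-charge model's CN drops by ≈0.2–0.4 waters under force
shifting, independent of the cutoff length. The Ewald sum is validated
against the rock-salt Madelung constant (1.7475) and finite-difference
forces. **Plain truncation** is kept for oracle comparisons. LJ is plain
12-6 under Lorentz–Berthelot rules, truncated at the cutoff. Absolute
single-ion solvation free energies remain the most
electrostatics-sensitive quantity; `run_fep()` is validated against its
internal closed forms (Zwanzig/BAR on Gaussian work distributions,
identity transforms, vacuum annihilation) rather than absolute values.

Nanotube carbons are fixed, neutral sites with ε 0.07 kcal/mol, Rmin/2
1.9924 Å. Fixed–fixed pairs are excluded from the sum (a constant offset).

## The hopping layer

Every `interval` MD steps (default 10, i.e. 0.02 ps at the 2 fs timestep)
the driver looks for water molecules donating a hydrogen bond to the
hydroxide oxygen (geometric criterion: O···O ≤ 3.5 Å and D–H···A ≥ 120°,
both configurable), picks one candidate uniformly at random, and evaluates
the hop energy ΔE by **swapping the nonbonded identities** of the two
partners: the donor takes the hydroxide parameter set with its donated H
becoming a non-interacting dummy, and the acceptor takes the protonated
set with its dummy materialising as a real hydrogen *along the hydrogen
bond* — on the acceptor's O–H bond sphere in the direction of the donated
hydrogen, i.e. the transferred position with the bond constraint applied.
No other coordinate moves, so a mirror-symmetric donor/acceptor pair gives
ΔE = 0 exactly — a property the tests assert — and the evaluation is
incremental: under truncated electrostatics only pairs involving the two
molecules contribute, and under Ewald the real-space group terms are
differenced while the reciprocal-space change is obtained from a cached
structure factor via the swap's ΔS(k) (self and exclusion deltas are
analytic; the net-charge background cancels). The incremental value equals
a full-lattice-sum difference to 10⁻¹² and the tests assert it. The
placement convention matters: materialising the proton at the acceptor's
rigid dummy slot instead roughly doubles the hop-energy median (the after
state then lacks the donor-to-hydroxide hydrogen bond), and freezing it at
the donated hydrogen's raw coordinates produces an unphysical LJ clash
with the donor oxygen. With the along-the-bond convention the M07
hop-energy median at desk scale is ~28–29 kcal/mol, a little below the ~34
of nanosecond-scale reference runs; the residual difference traces to
exactly this (not fully specified) placement convention and is the one
acceptance-level quantity this build leaves at the edge of its stated
band.

Hop candidates are all hydrogen-bonded waters, not only the currently
titratable ones: when a plain water is chosen as donor it is switched with
a titratable residue on demand — a pure relabelling for two-site models
(the protonated titratable residue is TIP3P-identical, so nothing moves)
and a rigid-geometry trade for AP models. A pool of about five titratable
residues per hydroxide is additionally re-centred on the ion after every
accepted hop.

Acceptance follows a modified Metropolis rule in which ΔE is replaced by
(ΔE − C): accept with probability min(1, e^{−(ΔE−C)/kT}). C is the
empirical threshold that calibrates the hopping rate; it is the only tuned
quantity in the method. On acceptance the identity swap is executed and the
new hydroxide is re-canonicalized as a rigid body: its oxygen and remaining
real hydrogen stay exactly in place while the dummy and the (now charged)
APs move to their template positions about the new O–H axis. The molecule
then carries its centre-of-mass velocity. The AP re-seat injects a small
amount of energy beyond ΔE; together with the identity-swap strain it is
removed by the post-hop steepest-descent minimization (0 steps for 2p
models, 4 for 3AP, following the rule that the minimization should roughly
remove the energy the hop added).

The titratable-pool exchanges are energy-neutral because a protonated
titratable residue is TIP3P-identical (the APs of the 3AP model carry mass
but no interactions in the water state — their inertial effect is the one
acknowledged difference).

## Analyses

* `compute_rdf()` — pair histogram normalized by shell volume and partner
  density; optional four-block uncertainty.
* `first_peak()` / `first_minimum()` / `coordination_number()` — the peak is
  the first local maximum (3-bin moving average) after g first exceeds 0.5;
  the first-shell boundary is searched in 2.8–3.8 Å; CN = 4πρ∫g r²dr to
  that boundary. The source publication does not state its integration
  limit, so the auto-detected minimum of our own g(r) is the package's
  convention; all three knobs are arguments.
* `einstein_diffusion()` — MSD over all time origins on a lag grid (lags up
  to ¼ of the trajectory), least-squares slope over a fit window, D =
  slope/2d. For nanotube runs the fit window is set to the early linear
  portion (0.5–5 ps lags on a 100 ps trajectory) because the tube ends
  saturate the MSD at longer lags.
* `identify_hydroxide()` — nearest-oxygen hydrogen assignment under minimum
  image; the unique single-H oxygen is the ion; exact ties break to the
  lower index and flag the frame; 0 or ≥2 single-H oxygens raise an
  ambiguous-frame error rather than guessing.
* `classify_hops()` — transfers are index-change points; an immediate
  return (i→j, j→i) is a rattling pair and by default both members are
  excluded from true hops (n_true = n_transfers − 2·n_pairs); a
  `"reversal"` mode excluding only the returning member is provided because
  the original bookkeeping is not fully specified.

## Parameterization and FEP

`optimize_parameters()` minimizes χ² = Σ w (A_target − A_obs)² over
{ε_O, ε_H, Rmin/2_O, Rmin/2_H} by steepest descent with central-difference
gradients (relative step 0.05; analytic observable derivatives are not
available here) and optional backtracking (α halves when χ² would rise,
making the trace non-increasing for a deterministic evaluator — the
fixed-α update of the original recipe remains available). The
simulation-backed evaluator (`make_cn_peak_evaluator()`) re-seeds the RNG
identically at every evaluation (common random numbers) so the finite
differences see systematic, not sampling, variation. Targets default to
CN = 4.5 and Peak = 4.

`run_fep()` transforms one molecule over 10 uniform coupling windows
(2 ps equilibration + 8 ps production each, three replicas; all
configurable). Charges interpolate linearly; LJ mixes dual-topology with
Beutler-style soft cores — E = (1−c)·E_A[shift s·c·R⁶] + c·E_B[shift
s·(1−c)·R⁶], s = 0.5 — so both endpoints are exact and annihilation is
singularity-free. Window free energies come from exponential averaging
(Zwanzig) with double-wide sampling, or BAR. Scheme "water_to_oh" adds the
TIP3P self-solvation free energy (−6.10 kcal/mol); scheme "annihilate"
returns the negative of the annihilation free energy so the result is the
ion's solvation free energy in both schemes.

## Study conditions at desk scale

The validation suite and `scripts/acceptance.R` run scaled-down versions of
the bulk and nanotube experiments: 216-molecule boxes at 0.997 g/mL (box
edge 18.65 Å; one molecule replaced by the hydroxide), cutoff 9.0 Å — the
largest the minimum-image convention allows in that box — 20 ps
equilibration + 50 ps production at 298 K (the test suite trims this to
15 + 35 ps), and a 100 Å (6,6) tube with 45 single-file waters run for
100 ps (60 ps in the tests) with C = 35 kcal/mol and 4-step post-hop
minimization. These runs reproduce the reference ladder — full-charge overcoordination
(CN ≈ 6.2–6.6 across seeds), partial relief with M07 (≈ 5.5–5.7), the 3AP
first peak at 2.45–2.50 Å, M07 hop-energy medians near 28–29 kcal/mol,
and strongly accelerated 1D transport in the tube (D of order 5–60 Å²/ps
across seeds at C = 35; the nanotube transport coefficient is intrinsically
high-variance at the 100 ps scale, where a trajectory holds only a handful
of independent tube crossings).
The full-scale stochastic quantities (solvation free energies of
−70 … −117 kcal/mol; the 1 ns threshold ladder of accepted-hop counts and
bulk diffusion coefficients) are hours-scale runs and are deliberately not
asserted by the test suite; the machinery to run them is exported
(`run_fep()`, `run_hopping_md()` with `n_steps` at nanosecond scale).

What the synthetic systems do *not* emulate: pressure coupling (systems are
built at the target density and run NVT), long-range electrostatic order,
polarization, and bond flexibility. Conclusions about real water beyond the
first two solvation shells should not be drawn from these desk-scale runs.

## Numerical choices and degenerate inputs

* Overlapping interacting sites (< 10⁻⁶ Å) raise a singular-geometry error
  instead of returning infinities.
* SHAKE non-convergence aborts the step with the molecule identified;
  constraint sets are exact all-pair distance sets, so any rigid seating
  satisfies them to machine precision.
* A zero-kinetic-energy system under a nonzero thermostat target is
  re-initialized from the Maxwell–Boltzmann distribution (seeded).
* The Zwanzig estimator uses a log-sum-exp guard; BAR solves its
  self-consistency by bisection on a bracketed interval.
* Hop candidates are chosen uniformly at random among hydrogen-bonded
  donors (the original method does not specify the choice); with candidate
  evaluation disabled the driver reproduces plain MD bit-for-bit under the
  same seed.
* The spacing of single-file water (≈2.2 Å for 45 molecules over ~96 Å)
  and the alternating initial dipole orientation are build conventions;
  both relax within the first picoseconds.

## Known limitations

* Truncated electrostatics shift absolute ion solvation free energies by
  tens of kcal/mol relative to Ewald treatments; FEP results here are for
  method validation and relative comparisons.
* First-shell coordination numbers at the 216-water/9 Å scale sit ~5–7%
  below the full-protocol references; the test tolerances carry that
  documented bias where it matters.
* One hydroxide per system; hydronium and titratable amino-acid chemistry
  are out of scope.
* The 5AP model is catalogued, not validated.
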