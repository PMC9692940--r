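---
title: "Methods: time-averaged NMR restraints and conformer population analysis in mdoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-averaged NMR restraints and conformer population analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Solution NMR parameters of flexible small molecules are averages over a
conformer equilibrium. Residual dipolar couplings (RDCs) average over both
overall orientation and internal states; NOE intensities average interproton
distances as r⁻⁶; vicinal ³J couplings average the Karplus curve over the
intervening dihedral. `mdoc` implements the orientational-constraint strategy:
a single all-atom molecule in vacuum is simulated with pseudo-forces that push
the *time averages* of back-calculated observables toward the experimental
targets. Because a time average, not a snapshot, is constrained, the molecule
is free — indeed obliged — to visit several conformers whenever the data are
averages over several, and conformer populations can then be read off torsion
trajectories.

## Physical model and integrator

The physical force field is deliberately minimal: harmonic bonds and angles
(`E = k (x − x₀)²`, Amber-style constant without the ½), cosine torsion
series `V (1 + cos(nφ − γ))`, 12-6 Lennard-Jones (Lorentz–Berthelot
combination) and Coulomb with fixed user-supplied charges, 1-2/1-3 pairs
excluded and 1-4 pairs scaled (defaults 0.5 / 0.833). One molecule in vacuum:
no cutoffs, no periodic boundaries, no solvent; the influence of the
surroundings enters only through the NMR constraints. Polarizable or
charge-recalculating electrostatics are intentionally out of scope; fixed
charges are sufficient because the restraint mechanics do not depend on the
charge model.

Integration is velocity Verlet at a default 0.5 fs — explicit hydrogens with
unconstrained X–H bonds need that step — with a Berendsen weak-coupling
thermostat (coupling time 100 fs by default; per-step scale factor clamped to
[0.8, 1.25] for robustness). Degrees of freedom are counted as 3N − 3
(center-of-mass momentum is removed at initialization). A symplectic check:
without thermostat and restraints, total energy shows no secular drift
(the suite asserts < 10⁻⁴ relative between the first and last 10% of a
10⁴-step run). Temperatures default to 306.3 K, the average at which the
simulated NMR data sets of interest were recorded and simulated.

## Observables

* **Dipolar tensor.** `D = D_max(r)(3 e eᵀ − I)/2`,
  `D_max(r) = −(μ₀/4π) γᵢ γⱼ ħ/(2π r³)` in Hz (CODATA 2018 constants;
  γ values per element: ¹H, ¹³C, ¹⁵N, ¹⁹F, ³¹P). Sign convention: negative
  `D_max` for pairs with same-sign γ. The measured coupling is the projection
  `bᵀ D b` onto the unit field direction (laboratory z by default).
  Conventions in the literature differ by factors of 2 and sign, so this one
  is stated explicitly and tested (a ¹³C–¹H pair at 1.09 Å gives
  |D_max| ≈ 23.3 kHz). Vibrational corrections to effective bond lengths are
  *not* applied — a documented limitation.
* **NOE effective distance.** `r_eff = ⟨r⁻⁶⟩^(−1/6)`; r⁻³ averaging is
  deliberately not offered, as it can produce unpredictable errors. Power-mean
  bounds (min ≤ r_eff ≤ arithmetic mean) are asserted property-style.
* **³J couplings.** Generalized Karplus (Haasnoot–Altona):
  `J = P1 cos²φ + P2 cosφ + P3 + Σᵢ Δχᵢ [P4 + P5 cos²(ξᵢφ + P6 |Δχᵢ|)]`,
  with group electronegativities corrected for β-substituents
  (`Δχ = Δχ_α − P7 Σ Δχ_β`). The standard 1980 six-parameter set and Huggins
  electronegativities ship as a data file (`inst/extdata/haasnoot_altona.tsv`)
  and can be overridden. The orientation signs ξᵢ are resolved geometrically
  from the reference structure: a substituent found at +120° from the coupled
  proton (about the C–C axis, IUPAC sense) gets ξ = +1 on the near carbon and
  the mirrored convention on the far carbon. This is a package convention —
  the generator and the back-calculation share it, which is what consistency
  requires.

## Time-averaged restraints

Every restraint keeps an exponential-memory average,
`⟨O⟩ ← (1 − λ) O(t) + λ ⟨O⟩`, `λ = exp(−Δt/τ)`. The memory constant τ
defaults to 10 ps: long enough to bridge conformer interconversion on the toy
systems, short enough that the average responds within a desk-scale run. The
accumulators are initialized from the observables of the start structure
(not zero), which avoids an artificial initial violation of tensor scale.

Pseudo-energies:

* RDC: `E = w Σ_αβ (⟨D⟩_αβ − T_αβ)²` over all nine elements. The target
  tensor `T` is reconstructed as axially symmetric about the field with its
  field component equal to the measured coupling
  (`T = D_exp (3bbᵀ − I)/2`). This reconstruction is a documented choice,
  isolated in `build_target_tensor()` and swappable.
* NOE and ³J: flat-bottom harmonics, zero within the experimental error and
  quadratic outside. Rationale: the success criterion of the method is the χ²
  quality `n/χ² > 1`, i.e. agreement *within* error; deviations inside the
  error window should cost nothing. Error defaults follow the standard rules:
  0.5 Hz for RDCs; 0.05 Å for NOE distances below 2.8 Å and 0.11 Å up to the
  ~4.5 Å detection limit; 1.25 Hz for ³J (0.65 Hz experimental + 0.6 Hz
  Altona-curve uncertainty). Pro-R and pro-S methylene protons are restrained
  individually; methyl groups are out of scope.

**Gradient convention.** Only the current-step term `(1 − λ) ∂O(t)/∂x` of the
memory average is differentiated — differentiating the full history is
intractable and unphysical for pseudo-forces. The suite verifies every
pseudo-force as the exact negative gradient of its pseudo-energy under this
convention (memory frozen except the current step, central finite differences,
relative error < 10⁻⁵). Scalar restraints exert zero net force; tensorial
restraints exert zero net translational force but a net torque — the handle
by which they reorient the molecule — and both facts are asserted numerically.

Two consequences of the (1 − λ) factor deserve emphasis. First, usable force
constants are numerically large (defaults: RDC 10⁻⁴, NOE 10⁶, ³J
2×10⁵ kcal mol⁻¹ per squared observable unit), because the factor
`(1 − λ) = Δt/τ ≈ 10⁻⁴` suppresses the instantaneous gradient; the defaults
were calibrated so that an active restraint's torque exceeds the toy rotor's
barrier slope. Second, pseudo-*energies* are bookkeeping quantities on a
different scale from the physical energy; diagnostics report them per class
but they should not be summed with the potential energy.

**Force cap.** When a time-averaged restraint engages far outside its
tolerance (e.g. immediately after a conformer flip), the instantaneous
gradient can be impulsive. Each restraint's per-step force set is therefore
rescaled so that no atom receives more than `force_cap`
(default 20 kcal mol⁻¹ Å⁻¹; 40 in the recovery configuration). This is a
numerical safeguard in the MD loop only; the single-evaluation functions used
by the gradient tests are uncapped. Restraint force constants also ramp
linearly from zero over `ramp_steps` (default 10⁴ steps) to avoid initial
shocks.

## Quality statistics and conformer analysis

`chi2_report()` computes `χᵢ = (qᵢ_exp − qᵢ_calc)/eᵢ`, per-item `(1/χᵢ)²`
(< 1 flags an outlier), totals `χ²`, and the quality `n/χ²` (+∞ for a perfect
fit). `resolve_assignment()` resolves interchangeable (ambiguous) assignments
by scoring every within-group permutation and returning the χ²-minimizing
one, breaking ties by the lexicographically smallest permutation so results
are deterministic.

Torsion trajectories are classified into ±gauche states by sign (boundary 0°
by default, configurable per torsion for states that straddle 0°, and an
optional three-state variant with a trans class exists but is off by
default). Joint state tuples are counted into a conformer table whose
probabilities sum to 100% before rounding; `aggregate_flip()` sums all rows
with a given label at a given torsion. Reported percentages use decimal
half-up rounding (`round_half_up()`): two decimals in tables, one in
aggregates — plain IEEE rounding can drop a stored x.x5 to the even side.
Histogram bins default to 2°.

## The synthetic two-state scenario

`two_state_scenario()` builds an 8-atom butane-like chain whose terminal
methyls are replaced by halogen-like caps, so the monitored central torsion
is the *only* rotor (no methyl spinning) and the ³J/NOE network across it is
exactly the four vicinal H–H pairs. The soft torsion gets the potential
`A (cosφ − cosφ₀)²` (minima at ±φ₀, default ±60°; barrier over φ = 0 set by
the `barrier` argument, default 6 kcal/mol; trans strongly penalized) plus a
sin-phase tilt. Three design choices matter:

1. **Boltzmann-consistent asymmetry.** The two wells are offset by
   `ΔE = kT ln((1−p)/p)` for ground-truth minor population p. Observables
   generated from an equilibrium mixture presuppose a molecule with that
   equilibrium; with a symmetric rotor the flat-bottom windows would let the
   trajectory drift toward 50/50 within tolerance, biasing any recovery
   upward by construction. With the default barrier, unrestrained vacuum MD
   essentially never crosses (≈ 6 kcal/mol ≳ 10 kT), so the equilibrium is
   unreachable without the restraints: the pseudo-forces supply the
   transitions, the landscape supplies the ratio, and the recovered
   population tests both together.
2. **Order parameter 1 for synthetic RDCs.** RDC targets are the
   population-weighted mixture of the per-state lab-frame dipolar tensors
   scaled by a single axial order parameter. The default is 1 — a notionally
   fully aligned sample — because that is the simplest model under which the
   toy's four C–H tensors carry usable conformer information: at a realistic
   weak-alignment scale (10⁻³ – 10⁻⁴) the target couplings are a few Hz,
   and a lone vacuum molecule cannot tumble fast enough for its memory-averaged
   tensor ever to reach that scale, so the constraints would be pure noise.
   The cost of the convention is cosmetic: scored against the 0.5 Hz error
   rule, the toy's kHz-scale RDC targets are "outliers" even when orientation
   and conformer weighting are essentially right; the scalar classes carry the
   quantitative χ² statement.
3. **A stiff frame.** Bending constants are deliberately high
   (150 kcal mol⁻¹ rad⁻²) so each torsional state stays near the rigid
   geometry its reference observables were computed from; with soft angles,
   thermal libration shifts the state-average ³J by about one error window
   and washes out the two-state contrast.

Noise defaults mirror the error magnitudes (RDC σ = 0.5 Hz, NOE σ =
0.05/0.11 Å, ³J σ = 0.65 Hz), all drawn from the single scenario seed.

**What the scenario does *not* emulate:** solvent and spin diffusion (NOE
intensities are taken as exact distances), vibrational averaging in the
generator (rigid per-state values), realistic weak alignment (see above),
methyl rotors, and multi-well landscapes beyond two states (a two-torsion
template, `chain2`, exists for joint-state analysis but not for recovery).
Passing tests therefore demonstrate that the machinery recovers populations
when its model assumptions hold — not that it would on raw experimental data,
where assignment errors, spin diffusion and alignment-model mismatch all
enter.

## Population recovery: sizes and expectations

`population_recovery_experiment()` runs the full pipeline: generate reference
tables → resolve restraints → 4×10⁵ MD steps (200 ps) at 306.3 K with
τ = 5 ps memory (shorter than the general default so that a 200 ps run
contains tens of restraint-driven flip cycles), 10 ps ramp, snapshots every
50 fs → discard the ramp plus two memory constants → classify by sign →
block-bootstrap uncertainty (50 contiguous blocks, 200 resamples). These
sizes keep a single experiment under ~10 s on one CPU while giving a
bootstrap standard error of ~3–4 percentage points. The test suite verifies:
recovery of a 20% minor population to ±5 points at zero noise, monotonicity
across ground truths {5%, 20%, 40%}, < 10-point spread across five seeds, and
< 2% recovered for a stiff-well scenario with no minor-state signal. With the
full noise defaults the recovery degrades markedly (a 1σ shift of one ³J
target moves the feasible population window by roughly 8 points on this toy);
the zero-noise condition isolates the dynamics from target noise.

## Degenerate inputs and numerical details

Collinear dihedral atoms raise an undefined-torsion error (threshold 10⁻¹⁸ on
the squared normal); coincident atoms in bonded, nonbonded or spin pairs
raise singularity errors; non-finite kinetic energy aborts integration with
the step number. Angle gradients guard sin θ ≈ 0. Torsions follow the IUPAC
(Klyne–Prelog) sign convention, validated against a constructed-geometry case
and a mirror-symmetry property; the Z-matrix builder and the bond-rotation
scanner share that convention, so built conformers re-measure to their input
torsions to 10⁻⁶ degrees. Memory accumulators are updated exactly once per
force evaluation, and runs are bit-reproducible given (config, seed) — the
only RNG draw is the Maxwell–Boltzmann velocity initialization (plus the
generator's noise), both R-seeded.

## Known limitations

Single-molecule vacuum dynamics with a weak-coupling thermostat (no canonical
ensemble guarantees); no SHAKE (0.5 fs step instead); no alignment-tensor
(Saupe SVD) fitting; no spin-diffusion modelling; no vibrational corrections
to RDC-effective bond lengths; fixed charges; the axial target-tensor
reconstruction and the geometric ξ convention are package choices that other
implementations may make differently; and equivalence with any particular
legacy implementation of the pseudo-force functional form cannot be asserted —
the construction here is documented, tested against its own gradients, and
isolated behind small functions so each piece can be swapped.
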