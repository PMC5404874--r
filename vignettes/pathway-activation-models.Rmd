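---
title: "Simulating axonal pathway activation by deep brain stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating axonal pathway activation by deep brain stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamsim)
```

# The model

Pathway-activation models (PAMs) predict which axonal pathways fire in
response to deep brain stimulation (DBS). `pamsim` implements the full
chain for voltage-regulated monopolar stimulation:

1. **Stimulus waveform.** An equivalent electrical circuit of the
   implanted system — output blocking capacitor, extension and lead wire
   resistance, electrode–tissue interface (double-layer capacitance
   parallel to a Faradaic resistance), the access resistance of the static
   field solution, and a parasitic RC branch across the load — is
   integrated through the four switching topologies of a stimulation
   period (cathodic drive; source disconnected; parasitics also
   disconnected; passive recovery with the load grounded). The voltage
   across the tissue resistance, normalized to unit cathodic peak, is the
   *tissue waveform* `V_tissue(t)`.
2. **Static unit field.** The extracellular potential for −1 V at the
   active contact, `Φ(x, y, z)`, from an analytic surrogate or an imported
   structured grid.
3. **Separable composition.** Because the static problem is linear and
   tissue capacitance is negligible next to the double-layer capacitance,
   the space–time potential factorizes as
   `Φ(x, y, z, t) = Φ(x, y, z) · A · V_tissue(t)` with stimulus amplitude
   `A`.
4. **Axons.** Corticofugal trajectories (tractography-style streamlines,
   smoothed and resampled) carry double-cable myelinated axon models;
   hyperdirect axons additionally branch a thin collateral into the
   subthalamic nucleus (STN). The composed potential drives every
   compartment's extracellular node.
5. **Thresholds and population analysis.** Binary search for the lowest
   amplitude that elicits a one-to-one distal response to a short pulse
   train, exclusion rules, bootstrap recruitment curves, and
   strength-duration / charge-duration summaries.

# Circuit

Component defaults are the implanted-system values for a standard
four-contact lead: 10 µF blocking capacitance, 55 Ω combined wire
resistance, a lumped interface of 1.8 µF ∥ 2.5 kΩ (from 30 µF/cm² and
150 Ω cm² over the ~0.06 cm² contact), and a 3 nF + 20 kΩ parasitic
branch. Two wiring details are not fixed by the component values alone
and were resolved as follows:

* **Parasitic topology.** The parasitic capacitance and resistance are
  modeled *in series* with each other, the pair in parallel with the load.
  This is the only arrangement in which "connecting the parasitic
  capacitance and resistance to each other" during passive recovery is a
  meaningful switch change, and it reproduces the clinically probed
  dynamic impedance (≈1450 Ω at 70 µs into an 80 µs pulse with a 1373 Ω
  access resistance) to a few ohms, whereas a parallel pair does not.
* **Interpulse topology.** All switches open; the interface and parasitic
  capacitances relax through their own leak resistances and the blocking
  capacitor holds its charge until the next recovery phase.

The switched circuit is integrated with forward Euler at an internal step
of 0.1 µs (the wire-resistance × parasitic-capacitance time constant is
≈0.17 µs, so 1 µs would be unstable); exported waveforms are decimated to
the protocol step. The two open-circuit phases have identically zero
tissue voltage and exactly exponential internal state decay, which is
applied in closed form. Because the recovery time constant
(≈2 ms against 3.686 ms of recovery) does not fully drain the blocking
capacitor each period, the circuit approaches its periodic steady state
with a contraction of ≈0.88 per period; charge balance across the
blocking capacitor holds to <1% per period only at that limit cycle
(≈40 pulses), which is how the property is tested.

# Static field surrogates

The finite-element volume conductor is out of scope; its two products that
the rest of the workflow consumes — a unit potential evaluator and an
access resistance — are provided by a spherical-equivalent analytic model:
the active cylindrical contact (1.5 mm × 1.27 mm diameter) is replaced by
a sphere of equal area (radius 0.69 mm) wrapped in a 0.5 mm encapsulation
shell, giving

```
R_access = (1/4π) [ (1/σ_enc)(1/a − 1/b) + 1/(σ_t b) ]
```

with −1 V on the equivalent surface, continuity at the shell boundary and
1/r decay outside. An anisotropic variant uses the point-source closed
form `Φ ∝ 1/sqrt(rᵀ σ̃⁻¹ r)` with the unit-determinant shape tensor σ̃ and
the geometric-mean conductivity in the access resistance. Inactive
contacts are ignored. Externally solved potentials can be imported on a
structured grid (trilinear interpolation; queries outside the grid return
0 and are flagged). Diffusion-tensor fields map to conductivity tensors by
eigenvector preservation with eigenvalues rescaled so their geometric mean
equals a reference isotropic conductivity ("volume/load preservation";
every output tensor then has determinant σ_iso³).

The encapsulation conductivity is calibrated by bisection so that the
dynamic impedance of the full circuit, with the tissue resistance set to
the field model's access resistance, matches a clinically measured
impedance — mirroring clinical programming-device measurements.

# Pathways

`generate_streamlines()` emulates probabilistic tractography output for a
corticofugal bundle: a bowed centerline from a cortical cap to a brainstem
cap past the electrode, a per-streamline Gaussian lateral offset
(default SD 1.5 mm), and independent per-point Gaussian jitter (default
SD 0.3 mm, sub-voxel, mimicking per-step sampling noise at the typical
0.5 mm step). It does **not** emulate anatomically curved fascicle
geometry, fanning into cortex, crossing-fiber artifacts, or
false-positive streamlines; passing tests therefore validate the
machinery, not tractography fidelity on real data.

**Smoothing.** Point jitter barely moves a streamline but wrecks the
*second spatial differences* of the sampled potential — the effective
driving term of extracellular stimulation — so each streamline is smoothed
before compartments are placed. The default smoother projects each
coordinate (as a function of arc length) onto a cubic B-spline basis with
knots every 6 mm: well below anatomical curvature scales (centimetres)
and well above the jitter scale. Projection was chosen over penalized
smoothing because it is (near-)idempotent — re-smoothing an already
smoothed streamline is a no-op to within a few microns — whereas a
penalized smoother shrinks the curve a little more on every application.
The few-micron residual is the floor set by representing the curve as a
0.5 mm arc-length-resampled polyline. Knot grids are anchored at
multiples of the spacing, endpoints are pinned, and arc length is
re-measured on a cubic interpolant to avoid chord-sum bias. A `spar`
based penalized mode and an interpolating mode remain available.

**Collaterals.** A hyperdirect collateral branches at a node of Ranvier
drawn uniformly among the main-path nodes lying within the axial bounds of
the STN mask (its extent along the electrode axis — the electrode defines
the axial frame), and terminates at a voxel drawn uniformly from the mask.
The connecting arc is a planar circular arc in the plane spanned by the
chord and the electrode axis, bulging away from the electrode with a
sagitta of 0.25 × chord by default; a straight-line fallback is
available.
Arcs intersecting the electrode shaft trigger a redraw of the voxel, up to
100 attempts.

**Compartments.** The double-cable repeat (node, MYSA, FLUT, 6 × STIN,
FLUT, MYSA) is walked along the arc length starting from the cortical end
(the choice of end is configurable; nothing in the workflow depends on
it), truncating at the last complete node. Collaterals start with a node
shortened to 0.5 µm and are truncated to end on a node of Ranvier, which
is passive — terminal nodes are otherwise hyperexcitable loci. Geometry
for the 5.7 µm corticofugal fiber comes from the published double-cable
table; the 1.8 µm collateral lies below the published range (5.7–16 µm),
where linear extrapolation of the table turns negative, so diameters,
segment lengths and lamellae counts scale proportionally with fiber
diameter while the node (1 µm) and MYSA (3 µm) lengths keep their
table-constant values.

# Axon biophysics and integration

Nodes of Ranvier carry fast Na⁺ (3.0 S/cm²), persistent Na⁺ (0.01 S/cm²)
and slow K⁺ (0.08 S/cm²) conductances plus leak (0.007 S/cm², reversal
−90 mV); the persistent Na⁺ current balances the leak so nodes rest near
−80 mV. MYSA/FLUT/STIN axolemma is passive (0.001/0.0001/0.0001 S/cm²,
resting at −80 mV) under a myelin sheath whose conductance and capacitance
scale as 0.001 S/cm² and 0.1 µF/cm² per membrane over twice the lamellae
count. Axoplasmic and periaxonal resistivities are 70 Ω cm with the
published periaxonal space widths. The published gating rate equations
are taken as 36 °C values with Q10 factors (2.2, 2.9, 3.0) applied
relative to 36 °C; the alternative reading (20 °C base values) makes
activation kinetics unphysiologically fast (τ_m ≈ 3 µs) and destroys
one-to-one following at 130 Hz, so it was rejected.

The discretized system has two unknowns per compartment — intracellular
and periaxonal potential, with the periaxonal layer shorted to the
extracellular potential at nodes — and is advanced by backward Euler
(the cable system is stiff, and compartmental simulators conventionally
default to implicit methods), solving a symmetric 2×2-block tridiagonal tree system by Hines
elimination at each step, with gating advanced by exponential Euler at
the previous potential (staggered scheme). The extracellular potential
enters as each compartment's external node via the separable composition
above.

Two numerical conveniences follow from the scheme. First, the backward
Euler fixed point is the exact equilibrium of the equations regardless of
step size, so resting states are computed once at a coarse 25 µs step
(`settle_axon()`, drift tolerance 10⁻⁴ mV/ms) and reused as the initial
condition for any production step size. Second, the same settled state
serves every amplitude probe of a threshold search.

An independently coded route — the same published model assembled directly
from its geometry table in R and integrated as a plain ODE system with
`deSolve::lsoda` — is used in the test suite to cross-check conduction
velocity (within 5%) and the full nonlinear membrane response under
extracellular drive (within 5%).

# Thresholds, recruitment, strength–duration

Activation requires every monitored distal node (the 2nd–4th active nodes
from each corticofugal end) to fire exactly once per pulse over a 3-pulse
train at 130 Hz, detected as upward 0 mV crossings in per-pulse windows.
The threshold search brackets from below: amplitudes grow geometrically
from 1 V until activation, then bisection refines the lowest activating
amplitude to 0.01 V. A plain bisection against the 150 V cap is unsafe
here because the one-to-one criterion is *not monotone* in amplitude —
far above threshold axons block or fire doublets — and a [0, cap]
bisection can converge onto the upper edge of the activated region
instead of the threshold. Axons are excluded if no amplitude up to the
cap activates them (reported as reason `"cap"`, without resolving where
within the non-activating range they fail) or if the action potential
initiates within 3 nodes of either corticofugal end (distal initiation).

Recruitment curves resample the surviving thresholds into bootstrap
populations (default 100 populations of 1000, with replacement) and
report mean ± SD percent activation on an amplitude grid; each
population's curve is a non-decreasing step function, so the mean is
monotone by construction. Strength–duration points invert the recruitment
curve (linear interpolation between grid amplitudes) to the band reaching
a target activation (e.g. 15 ± 5%); charge–duration attaches the
trapezoidal integral of the cathodic-phase current through the tissue
resistance (`A·V_tissue(t)/R_tissue`), in µC.

# Problem sizes and determinism

The test-suite and acceptance analyses run at desk scale by design:
synthetic fibers of 12–15 mm (25–30 internodes, ≈300 compartments) a few
millimetres from the contact, 3-pulse protocols (≈23 ms simulated at
1 µs), populations of 3–10 axons for search-consistency and
convergence checks, and pipelines of a handful of axons. The
step-halving analysis uses a finer 0.0025 V search resolution so that
amplitude quantization (≈0.7% at these thresholds) does not alias into
the time-step comparison. All randomness flows through explicit seeds;
identical configurations rerun to bit-identical result files.

# Worked example

```{r example, eval = FALSE}
params <- circuit_params()                       # implanted-system defaults
dynamic_impedance(params)                        # ~1444 Ohm

field <- build_analytic_field(electrode_spec(), sigma_tissue_S_m = 0.2,
                              sigma_enc_S_m = 0.1)
protocol <- stimulus_protocol(amplitude_V = 1, pulse_width_us = 60)
waveform <- simulate_tissue_waveform(params, protocol)

streamline_pts <- cbind(2.5, 0, seq(-7, 7, length.out = 60))
axon <- build_axon(compartmentalize(axon_trajectory(
  streamline(streamline_pts))))
find_threshold(axon, field, waveform, protocol)  # ~1.83 V at 2.5 mm
```

# Limitations

* The analytic field is a spherical-equivalent surrogate: no head
  geometry, no inactive-contact effects, no tissue heterogeneity beyond
  the encapsulation shell. Imported grids can carry an external solution
  where fidelity matters.
* The synthetic streamline generator reproduces the statistical character
  of tractography noise, not anatomy; absolute recruitment fractions from
  synthetic bundles are not comparable to patient results.
* Below the published 5.7 µm fiber-geometry row, dimensions are a
  proportional extrapolation.
* One collateral per hyperdirect axon, no terminal arborization, no
  synapses, no network effects.
* The propagating action potential of this parameterization has a modest
  overshoot; detection relies on 0 mV crossings at distal monitors, which
  the tests exercise at the geometries used here.
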