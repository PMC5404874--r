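# pamsim — pathway-activation models of deep brain stimulation

`pamsim` simulates the direct axonal response to deep brain stimulation
(DBS). It is aimed at computational neuroscientists and neural engineers
who want a self-contained, scriptable implementation of the
pathway-activation-model (PAM) workflow: given an implanted electrode, a
stimulus protocol and a set of axonal trajectories, which axons fire?

The workflow rests on the separable field approximation for
voltage-regulated stimulation,

    Φ(x, y, z, t) = Φ(x, y, z, t = 0) · A · V_tissue(t)

where `Φ(x, y, z, t = 0)` is the static extracellular potential for −1 V
at the active contact, `A` is the stimulus amplitude, and `V_tissue(t)` is
the normalized voltage waveform across the tissue resistance, computed
from an equivalent circuit of the implanted system (blocking capacitor,
lead wires, electrode–tissue interface, parasitics, access resistance).
The composed potential drives double-cable myelinated axon models — nodes
of Ranvier with fast Na⁺, persistent Na⁺ and slow K⁺ channels; passive
MYSA/FLUT/STIN internodes under myelin — whose trajectories come from
tractography-style streamlines (smoothed, resampled, optionally with a
thin collateral branching into the subthalamic nucleus). Activation
thresholds are found by binary search under a 1-to-1 distal-response
criterion, then aggregated into bootstrap recruitment curves and
strength-duration / charge-duration relationships.

Everything runs at synthetic scale out of the box: a built-in generator
produces corticofugal-like streamline bundles, an STN-like voxel mask and
an analytic volume-conductor surrogate, so no imaging data is required.
Externally solved potential grids, user streamlines and voxel masks can be
substituted at every interface.

## Worked example

```r
library(pamsim)

## implanted-system circuit with the standard component values
params <- circuit_params()
dynamic_impedance(params)
#> [1] 1444.194     # Ohm, probed 70 us into an 80 us pulse

## analytic field surrogate: 0.2 S/m tissue, 0.1 S/m encapsulation
field <- build_analytic_field(electrode_spec(), 0.2, 0.1)
field$access_resistance_ohm
#> [1] 818.7865

## normalized tissue waveform for a 60 us, 130 Hz, 3-pulse train
protocol <- stimulus_protocol(amplitude_V = 1, pulse_width_us = 60)
waveform <- simulate_tissue_waveform(params, protocol)

## a straight 14 mm, 5.7 um fiber passing 2.5 mm from the active contact
axon <- build_axon(compartmentalize(axon_trajectory(
  streamline(cbind(2.5, 0, seq(-7, 7, length.out = 60))))))
find_threshold(axon, field, waveform, protocol)
#>   threshold_V excluded reason initiation_node n_sims
#> 1    1.828125    FALSE                    155      9
```

The threshold (1.83 V) is the lowest amplitude at which every monitored
distal node of Ranvier fires exactly once per pulse; `initiation_node` is
the compartment where the action potential starts (here a central node —
distal initiation would flag the axon for exclusion), and `n_sims` counts
the simulations the bracketing-plus-bisection search used.

A complete synthetic run — fixtures, waveform, field, pathway
construction, thresholds, recruitment — is one call pair:

```r
paths <- make_fixtures("fixtures", seed = 1)
res <- run_pipeline(read_run_config(paths$config))
```

which writes `thresholds.csv`, `recruitment.csv` and a `manifest.json`
(configuration echo, input hashes, stage timings, exclusion counts) under
the configured output directory. A thin command-line wrapper with the
same entry points ships in `inst/cli/pamsim`.

## Package layout

| Area | Functions |
| --- | --- |
| Circuit | `circuit_params`, `stimulus_protocol`, `simulate_tissue_waveform`, `dynamic_impedance`, `calibrate_encapsulation` |
| Field | `electrode_spec`, `build_analytic_field`, `load_field_grid`/`save_field_grid`, `sample_potentials`, `compose_spacetime`, `conductivity_from_diffusion` |
| Pathways | `generate_streamlines`, `fit_smoothing_spline`, `build_collateral`, `compartmentalize`, `sample_population`, `fiber_geometry` |
| Axon | `membrane_dynamics`, `build_axon`, `settle_axon`, `integrate_axon`, `detect_activation` |
| Analysis | `find_threshold`, `apply_exclusions`, `bootstrap_recruitment`, `strength_duration`, `charge_duration` |
| Orchestration | `make_fixtures`, `read_run_config`, `run_pipeline` |

The methods vignette (`vignettes/pathway-activation-models.Rmd`) documents
the model assumptions, parameter choices, numerical scheme and known
limitations in detail.
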