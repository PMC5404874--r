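# shared builders for simulation tests; heavyweight objects are cached per
# session so independent tests do not repeat identical work
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

test_field <- function() cached("field", build_analytic_field(electrode_spec(), 0.2, 0.1))

test_params <- function() cached("params", circuit_params())

test_protocol <- function(dt_us = 1, pulse_width_us = 60, n_pulses = 3) {
  stimulus_protocol(amplitude_V = 1, pulse_width_us = pulse_width_us,
                    frequency_hz = 130, n_pulses = n_pulses, dt_us = dt_us)
}

test_waveform <- function(dt_us = 1, pulse_width_us = 60, n_pulses = 3) {
  key <- sprintf("wave_%g_%g_%d", dt_us, pulse_width_us, n_pulses)
  cached(key, simulate_tissue_waveform(
    test_params(), test_protocol(dt_us, pulse_width_us, n_pulses)))
}

# straight corticofugal-like fiber parallel to the electrode at lateral
# offset x_off (mm), length L (mm)
straight_axon <- function(x_off, L = 12, diameter = 5.7) {
  key <- sprintf("ax_%g_%g_%g", x_off, L, diameter)
  cached(key, {
    pts <- cbind(x_off, 0, seq(-L / 2, L / 2, length.out = max(9, round(4 * L))))
    build_axon(compartmentalize(axon_trajectory(streamline(pts)),
                                main_geom = fiber_geometry(diameter)))
  })
}

settled <- function(ax, key) cached(paste0("st_", key), settle_axon(ax))

# small jittered synthetic bundle close to the electrode (thresholds of a
# few volts); used by the search-consistency and convergence tests
synthetic_axons <- function(n, seed, jitter_sd_mm = 0.2) {
  sl <- generate_streamlines(n, bundle_spec = list(
    start = c(2.0, -0.6, 7), end = c(2.6, 0.8, -7), bow_mm = 0.8,
    bundle_sd_mm = 0.4, n_points = 41), jitter_sd_mm = jitter_sd_mm,
    seed = seed)
  lapply(sl, function(s)
    build_axon(compartmentalize(axon_trajectory(fit_smoothing_spline(s)))))
}

# exhaustive ascending amplitude sweep: lowest activating amplitude on a
# fixed grid, as the independent oracle for the binary search
sweep_threshold <- function(ax, field, waveform, protocol, step_V = 0.01,
                            max_V = 10, init_state = NULL) {
  phi <- sample_potentials(field, ax$midpoints)
  if (is.null(init_state)) init_state <- settle_axon(ax)
  dur <- (length(waveform$values) - 1) * waveform$dt_us
  for (a in seq(step_V, max_V, by = step_V)) {
    rec <- integrate_axon(ax, phi, waveform, a, waveform$dt_us, dur,
                          init_state = init_state)
    if (detect_activation(rec, protocol, ax$monitor)$activated) return(a)
  }
  NA_real_
}

# long pulse train at the clinical setting, for charge-balance checks at
# the circuit's periodic steady state (contraction ~0.88 per period)
steady_waveform <- function() cached("wave_steady", {
  simulate_tissue_waveform(test_params(),
                           stimulus_protocol(amplitude_V = 1.7,
                                             n_pulses = 40))
})

charge_balance_ratio <- function(w, pulse) {
  log <- w$state_log
  v_end <- log$v_cblock[log$pulse == pulse & log$phase == "interpulse"]
  v_start <- log$v_cblock[log$pulse == pulse - 1 & log$phase == "interpulse"]
  swing <- log$v_cblock[log$pulse == pulse & log$phase == "drive"] - v_start
  abs(v_end - v_start) / abs(swing)
}

# a normalized waveform object from raw values, for hand-built drives
fake_waveform <- function(values, dt_us, pulse_onsets_us = 0) {
  structure(list(times_us = (seq_along(values) - 1) * dt_us, values = values,
                 raw_peak_V = 1, dt_us = dt_us,
                 pulse_onsets_us = pulse_onsets_us, protocol = NULL),
            class = "tissue_waveform")
}

# a hand-made sim_record for detector unit tests
fake_record <- function(traces, dt_us, record_idx) {
  structure(list(potentials = traces,
                 times_ms = (seq_len(ncol(traces)) - 1) * dt_us * 1e-3,
                 record_idx = record_idx, dt_us = dt_us, state = NULL),
            class = "sim_record")
}
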