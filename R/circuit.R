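.default_contact_area <- function() contact_area_cm2(electrode_spec())

#' Lumped electrode-tissue interface values from distributed densities
#'
#' The electrode-tissue interface (ETI) is modeled as a double-layer
#' capacitance in parallel with a Faradaic resistance. Their lumped values
#' follow from distributed surface densities scaled by the geometric area of
#' the active contact: a 30 uF/cm^2 double layer and 150 Ohm cm^2 Faradaic
#' resistivity over a ~0.06 cm^2 cylindrical contact give approximately
#' 1.8 uF and 2.5 kOhm.
#'
#' @param contact_area_cm2 Geometric contact area (cm^2).
#' @param c_dl_density_uF_cm2 Double-layer capacitance density (uF/cm^2).
#' @param r_f_density_ohm_cm2 Faradaic resistivity (Ohm cm^2).
#' @return List with `c_dl_uF` and `r_faradaic_ohm`.
#' @export
#' @examples
#' lumped_eti(contact_area_cm2(electrode_spec()))
lumped_eti <- function(contact_area_cm2,
                       c_dl_density_uF_cm2 = 30,
                       r_f_density_ohm_cm2 = 150) {
  stopifnot(contact_area_cm2 > 0)
  list(c_dl_uF = c_dl_density_uF_cm2 * contact_area_cm2,
       r_faradaic_ohm = r_f_density_ohm_cm2 / contact_area_cm2)
}

#' Equivalent-circuit parameters of the implanted DBS system
#'
#' Component values of the voltage-regulated monopolar stimulation circuit:
#' output blocking capacitor, extension-plus-lead wire resistance, lumped
#' electrode-tissue interface (double-layer capacitance parallel to a
#' Faradaic resistance), the access (tissue) resistance of the static field
#' solution, and a series parasitic RC branch in parallel with the load that
#' reproduces the interphase decay of measured pulse-generator output.
#'
#' If `c_dl_uF`/`r_faradaic_ohm` are omitted they are derived from
#' `contact_area_cm2` via [lumped_eti()]. When both lumped values and an
#' area are supplied they must agree with the distributed densities within
#' 1%.
#'
#' @param c_block_uF Blocking capacitance (uF).
#' @param r_wires_ohm Extension plus lead wire resistance (Ohm).
#' @param c_dl_uF Lumped double-layer capacitance (uF).
#' @param r_faradaic_ohm Lumped Faradaic resistance (Ohm).
#' @param r_tissue_ohm Access resistance of the static field model (Ohm).
#' @param c_parasitic_nF Parasitic capacitance (nF); `Inf` allowed.
#' @param r_parasitic_ohm Parasitic resistance (Ohm); `Inf` removes the branch.
#' @param contact_area_cm2 Active contact area (cm^2) used to derive or
#'   validate the lumped ETI values.
#' @return Object of class `circuit_params`.
#' @export
circuit_params <- function(c_block_uF = 10,
                           r_wires_ohm = 55,
                           c_dl_uF = NULL,
                           r_faradaic_ohm = NULL,
                           r_tissue_ohm = 1373,
                           c_parasitic_nF = 3,
                           r_parasitic_ohm = 20e3,
                           contact_area_cm2 = .default_contact_area()) {
  eti <- lumped_eti(contact_area_cm2)
  if (is.null(c_dl_uF)) c_dl_uF <- eti$c_dl_uF
  if (is.null(r_faradaic_ohm)) r_faradaic_ohm <- eti$r_faradaic_ohm

  vals <- c(c_block_uF, r_wires_ohm, c_dl_uF, r_faradaic_ohm, r_tissue_ohm,
            c_parasitic_nF, r_parasitic_ohm, contact_area_cm2)
  if (any(vals <= 0)) stop("all circuit parameters must be strictly positive")
  if (is.finite(c_dl_uF) && abs(c_dl_uF - eti$c_dl_uF) / eti$c_dl_uF > 0.01)
    stop("lumped c_dl inconsistent with 30 uF/cm^2 over the contact area (> 1%)")
  if (is.finite(r_faradaic_ohm) &&
      abs(r_faradaic_ohm - eti$r_faradaic_ohm) / eti$r_faradaic_ohm > 0.01)
    stop("lumped r_faradaic inconsistent with 150 Ohm cm^2 over the contact area (> 1%)")

  structure(list(c_block_uF = c_block_uF, r_wires_ohm = r_wires_ohm,
                 c_dl_uF = c_dl_uF, r_faradaic_ohm = r_faradaic_ohm,
                 r_tissue_ohm = r_tissue_ohm, c_parasitic_nF = c_parasitic_nF,
                 r_parasitic_ohm = r_parasitic_ohm,
                 contact_area_cm2 = contact_area_cm2),
            class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("DBS equivalent-circuit parameters\n")
  cat(sprintf("  C_block    %8.3g uF   R_wires    %8.4g Ohm\n",
              x$c_block_uF, x$r_wires_ohm))
  cat(sprintf("  C_dl       %8.3g uF   R_Faradaic %8.4g Ohm\n",
              x$c_dl_uF, x$r_faradaic_ohm))
  cat(sprintf("  R_tissue   %8.4g Ohm  C_par      %8.3g nF  R_par %8.4g Ohm\n",
              x$r_tissue_ohm, x$c_parasitic_nF, x$r_parasitic_ohm))
  invisible(x)
}

#' Stimulation protocol
#'
#' Timing and amplitude of a voltage-regulated rectangular pulse train. Each
#' period consists of a cathodic phase (`pulse_width_us`), a two-part
#' interphase interval during which first the voltage source
#' (`interphase_a_us`) and then also the parasitic branch
#' (`interphase_b_us`) are disconnected, a passive charge-recovery phase
#' (`recovery_ms`), and the remaining interpulse interval.
#'
#' @param amplitude_V Cathodic amplitude magnitude (V).
#' @param pulse_width_us Cathodic phase duration (us).
#' @param frequency_hz Pulse repetition rate (Hz).
#' @param n_pulses Number of pulses simulated.
#' @param interphase_a_us First interphase segment (us).
#' @param interphase_b_us Second interphase segment (us).
#' @param recovery_ms Passive recovery duration (ms).
#' @param dt_us Output sampling interval (us); must be <= 1.
#' @param pulse_width_range_us Admissible pulse-width range (us).
#' @return Object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(amplitude_V = 1.7,
                              pulse_width_us = 60,
                              frequency_hz = 130,
                              n_pulses = 3,
                              interphase_a_us = 10,
                              interphase_b_us = 70,
                              recovery_ms = 3.686,
                              dt_us = 1,
                              pulse_width_range_us = c(20, 120)) {
  stopifnot(amplitude_V >= 0, pulse_width_us > 0, frequency_hz > 0,
            n_pulses >= 1, dt_us > 0)
  if (dt_us > 1) stop("dt_us must be <= 1 us")
  if (pulse_width_us < pulse_width_range_us[1] ||
      pulse_width_us > pulse_width_range_us[2])
    stop(sprintf("pulse width %g us outside configured range [%g, %g] us",
                 pulse_width_us, pulse_width_range_us[1], pulse_width_range_us[2]))
  period_us <- 1e6 / frequency_hz
  phases_us <- pulse_width_us + interphase_a_us + interphase_b_us +
    recovery_ms * 1e3
  if (period_us < phases_us)
    stop("phase durations exceed the stimulation period")
  structure(list(amplitude_V = amplitude_V, pulse_width_us = pulse_width_us,
                 frequency_hz = frequency_hz, n_pulses = n_pulses,
                 interphase_a_us = interphase_a_us,
                 interphase_b_us = interphase_b_us,
                 recovery_ms = recovery_ms, dt_us = dt_us,
                 period_us = period_us),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "Stimulus protocol: %g V, %g us pulse, %g Hz, %d pulse(s), dt %g us\n",
    x$amplitude_V, x$pulse_width_us, x$frequency_hz, x$n_pulses, x$dt_us))
  invisible(x)
}

# One forward-Euler phase of the switched circuit.
# topology: "drive", "interphase_a" (source off), "interphase_b" (source and
# parasitic branch off), "recovery" (load grounded through blocking cap,
# parasitic C and R joined), "interpulse" (all switches open, leakage decay).
.circuit_phase <- function(state, p, topology, v_applied, n_steps, dt_s,
                           keep = TRUE) {
  vcb <- state[1]; vdl <- state[2]; vpar <- state[3]
  Cb <- p$c_block_uF * 1e-6; Rw <- p$r_wires_ohm
  Cdl <- p$c_dl_uF * 1e-6; Rf <- p$r_faradaic_ohm; Rt <- p$r_tissue_ohm
  Cp <- p$c_parasitic_nF * 1e-9; Rp <- p$r_parasitic_ohm
  vt <- if (keep) numeric(n_steps) else NULL

  if (topology == "interphase_b" || topology == "interpulse") {
    # open-circuit phases: tissue voltage is identically zero and the
    # remaining state decays through closed internal loops (exact update)
    t_end <- n_steps * dt_s
    vdl <- vdl * exp(-t_end / (Rf * Cdl))
    if (topology == "interpulse") vpar <- vpar * exp(-t_end / (Rp * Cp))
    return(list(state = c(vcb, vdl, vpar), v_tissue = vt))
  }

  for (k in seq_len(n_steps)) {
    if (topology == "drive") {
      v1 <- ((v_applied - vcb) / Rw + vdl / Rt + vpar / Rp) /
        (1 / Rw + 1 / Rt + 1 / Rp)
      iw <- (v_applied - vcb - v1) / Rw
      il <- (v1 - vdl) / Rt
      ip <- (v1 - vpar) / Rp
      vcb <- vcb + dt_s * iw / Cb
      vdl <- vdl + dt_s * (il - vdl / Rf) / Cdl
      vpar <- vpar + dt_s * ip / Cp
    } else if (topology == "interphase_a") {
      v1 <- (vdl / Rt + vpar / Rp) / (1 / Rt + 1 / Rp)
      il <- (v1 - vdl) / Rt
      ip <- (v1 - vpar) / Rp
      vdl <- vdl + dt_s * (il - vdl / Rf) / Cdl
      vpar <- vpar + dt_s * ip / Cp
    } else if (topology == "recovery") {
      il <- -(vcb + vdl) / (Rw + Rt)
      vcb <- vcb + dt_s * il / Cb
      vdl <- vdl + dt_s * (il - vdl / Rf) / Cdl
      vpar <- vpar + dt_s * (-vpar / (Rp * Cp))
    } else stop("unknown topology")
    if (keep) vt[k] <- il * Rt
  }
  if (!all(is.finite(c(vcb, vdl, vpar))))
    stop("circuit integration unstable (non-finite state); use a smaller dt")
  list(state = c(vcb, vdl, vpar), v_tissue = vt)
}

#' Simulate the tissue voltage waveform
#'
#' Integrates the switched equivalent circuit with forward Euler through the
#' four per-pulse topologies (drive; source disconnected; parasitics also
#' disconnected; passive recovery with the load grounded and the parasitic
#' capacitance and resistance joined) over `n_pulses` periods, and returns
#' the voltage across the tissue resistance normalized to unit cathodic
#' peak. The pre-normalization cathodic peak is recorded in `raw_peak_V`.
#'
#' @param params [circuit_params()].
#' @param protocol [stimulus_protocol()].
#' @param dt_internal_us Internal forward-Euler step (us). The circuit is
#'   stiff (wire resistance times parasitic capacitance is about 0.17 us),
#'   so integration runs at a finer step than the exported sampling and is
#'   then decimated to `protocol$dt_us`.
#' @return Object of class `tissue_waveform` with `times_us`, `values`
#'   (dimensionless, unit cathodic peak), `raw_peak_V`, `dt_us`,
#'   `pulse_onsets_us`, a `state_log` data frame recording the circuit
#'   state (blocking-capacitor, double-layer and parasitic voltages) at
#'   the end of every phase, and the generating protocol.
#' @export
#' @examples
#' w <- simulate_tissue_waveform(circuit_params(), stimulus_protocol(1))
#' max(abs(w$values))
simulate_tissue_waveform <- function(params, protocol, dt_internal_us = 0.1) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(protocol, "stimulus_protocol"))
  if (dt_internal_us <= 0) stop("dt_internal_us must be positive")
  dec <- protocol$dt_us / dt_internal_us
  if (abs(dec - round(dec)) > 1e-8)
    stop("protocol dt_us must be an integer multiple of dt_internal_us")
  dec <- round(dec)

  dt_s <- dt_internal_us * 1e-6
  n_per <- function(d_us) {
    n <- d_us / dt_internal_us
    if (abs(n - round(n)) > 1e-6)
      stop("dt must divide every phase duration")
    round(n)
  }
  n_pw <- n_per(protocol$pulse_width_us)
  n_ia <- n_per(protocol$interphase_a_us)
  n_ib <- n_per(protocol$interphase_b_us)
  n_rec <- n_per(protocol$recovery_ms * 1e3)
  # the period is quantized to the exported sampling grid; the interpulse
  # interval absorbs the (sub-sample) remainder
  n_period <- round(protocol$period_us / protocol$dt_us) * dec
  n_ipi <- n_period - n_pw - n_ia - n_ib - n_rec

  state <- c(0, 0, 0)
  raw <- numeric(protocol$n_pulses * n_period)
  pos <- 0L
  state_log <- vector("list", protocol$n_pulses * 5L)
  li <- 0L
  for (pulse in seq_len(protocol$n_pulses)) {
    for (ph in list(list("drive", n_pw), list("interphase_a", n_ia),
                    list("interphase_b", n_ib), list("recovery", n_rec),
                    list("interpulse", n_ipi))) {
      res <- .circuit_phase(state, params, ph[[1]], protocol$amplitude_V,
                            ph[[2]], dt_s)
      state <- res$state
      if (!is.null(res$v_tissue)) raw[pos + seq_len(ph[[2]])] <- res$v_tissue
      pos <- pos + ph[[2]]
      li <- li + 1L
      state_log[[li]] <- data.frame(pulse = pulse, phase = ph[[1]],
                                    v_cblock = state[1], v_dl = state[2],
                                    v_par = state[3])
    }
  }
  state_log <- do.call(rbind, state_log)

  raw <- c(0, raw) # sample at t = 0, before the first step
  keep <- seq(1, length(raw), by = dec)
  raw <- raw[keep]
  times <- (keep - 1) * dt_internal_us

  period_out_us <- n_period * dt_internal_us
  cathodic <- times %% period_out_us <= protocol$pulse_width_us
  raw_peak <- max(raw[cathodic], 0)
  values <- if (raw_peak > 0) raw / raw_peak else raw * 0

  structure(list(times_us = times, values = values, raw_peak_V = raw_peak,
                 dt_us = protocol$dt_us,
                 pulse_onsets_us = (seq_len(protocol$n_pulses) - 1) *
                   period_out_us,
                 state_log = state_log, protocol = protocol),
            class = "tissue_waveform")
}

#' @export
print.tissue_waveform <- function(x, ...) {
  cat(sprintf(
    "Tissue waveform: %d samples at dt = %g us, raw cathodic peak %.4g V\n",
    length(x$values), x$dt_us, x$raw_peak_V))
  invisible(x)
}

#' Dynamic load impedance of the implanted system
#'
#' Applies a single rectangular voltage pulse to the drive topology of the
#' equivalent circuit and returns applied voltage divided by source current
#' at `probe_time_us` into the pulse. Clinical programming devices report
#' this quantity; with the standard component values and an access
#' resistance of 1373 Ohm, probing 70 us into an 80 us pulse gives
#' approximately 1450 Ohm.
#'
#' @param params [circuit_params()].
#' @param probe_time_us Probe time into the pulse (us).
#' @param pulse_width_us Pulse duration (us); must exceed `probe_time_us`.
#' @param dt_us Forward-Euler step (us).
#' @return Impedance (Ohm).
#' @export
#' @examples
#' dynamic_impedance(circuit_params())
dynamic_impedance <- function(params, probe_time_us = 70, pulse_width_us = 80,
                              dt_us = 0.01) {
  stopifnot(inherits(params, "circuit_params"))
  if (probe_time_us >= pulse_width_us)
    stop("probe_time_us must be smaller than pulse_width_us")
  p <- params
  dt_s <- dt_us * 1e-6
  n <- round(probe_time_us / dt_us)
  vcb <- 0; vdl <- 0; vpar <- 0
  Cb <- p$c_block_uF * 1e-6; Rw <- p$r_wires_ohm
  Cdl <- p$c_dl_uF * 1e-6; Rf <- p$r_faradaic_ohm; Rt <- p$r_tissue_ohm
  Cp <- p$c_parasitic_nF * 1e-9; Rp <- p$r_parasitic_ohm
  iw <- NA_real_
  for (k in seq_len(n)) {
    v1 <- ((1 - vcb) / Rw + vdl / Rt + vpar / Rp) / (1 / Rw + 1 / Rt + 1 / Rp)
    iw <- (1 - vcb - v1) / Rw
    il <- (v1 - vdl) / Rt
    ip <- (v1 - vpar) / Rp
    vcb <- vcb + dt_s * iw / Cb
    vdl <- vdl + dt_s * (il - vdl / Rf) / Cdl
    vpar <- vpar + if (is.finite(Cp)) dt_s * ip / Cp else 0
  }
  if (!is.finite(iw) || iw <= 0)
    stop("non-physical source current in impedance probe")
  1 / iw
}

#' Calibrate the encapsulation layer conductivity against a clinical impedance
#'
#' Bisection on the encapsulation conductivity so that the dynamic load
#' impedance of the implanted-system circuit, with the tissue resistance set
#' to the access resistance of the field model produced by `field_factory`,
#' matches the clinically measured impedance.
#'
#' @param field_factory Function sigma_enc (S/m) -> field model exposing
#'   `$access_resistance_ohm`.
#' @param params [circuit_params()]; its `r_tissue_ohm` is overridden.
#' @param clinical_impedance_ohm Target impedance (Ohm).
#' @param bounds Conductivity search interval (S/m).
#' @param tol_ohm Acceptable impedance mismatch (Ohm).
#' @param probe_time_us,pulse_width_us Impedance probe timing, as in
#'   [dynamic_impedance()].
#' @return Calibrated conductivity (S/m), with attributes `impedance_ohm`
#'   and `access_resistance_ohm`.
#' @export
calibrate_encapsulation <- function(field_factory, params,
                                    clinical_impedance_ohm,
                                    bounds = c(0.05, 0.2), tol_ohm = 1,
                                    probe_time_us = 70, pulse_width_us = 80) {
  z_of <- function(sigma) {
    fm <- field_factory(sigma)
    p <- params
    p$r_tissue_ohm <- fm$access_resistance_ohm
    dynamic_impedance(p, probe_time_us, pulse_width_us)
  }
  z_lo <- z_of(bounds[1]) # impedance decreases with conductivity
  z_hi <- z_of(bounds[2])
  if (clinical_impedance_ohm > z_lo + tol_ohm ||
      clinical_impedance_ohm < z_hi - tol_ohm)
    stop(sprintf(
      "clinical impedance %.4g Ohm outside achievable range [%.4g, %.4g] Ohm",
      clinical_impedance_ohm, z_hi, z_lo))
  lo <- bounds[1]; hi <- bounds[2]
  for (iter in 1:100) {
    mid <- (lo + hi) / 2
    z <- z_of(mid)
    if (abs(z - clinical_impedance_ohm) <= tol_ohm) break
    if (z > clinical_impedance_ohm) lo <- mid else hi <- mid
  }
  fm <- field_factory(mid)
  structure(mid, impedance_ohm = z,
            access_resistance_ohm = fm$access_resistance_ohm)
}

#' Write / read a tissue waveform as two-column delimited text
#'
#' Column 1 is time (us), column 2 the normalized value; the raw cathodic
#' peak and sampling interval are stored in `#`-prefixed header lines.
#'
#' @param waveform A `tissue_waveform`.
#' @param path File path.
#' @return `write_waveform` returns `path` invisibly; `read_waveform`
#'   returns a `tissue_waveform` (without the generating protocol).
#' @export
write_waveform <- function(waveform, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pamsim tissue waveform v1",
               sprintf("# raw_peak_V: %.17g", waveform$raw_peak_V),
               sprintf("# dt_us: %.17g", waveform$dt_us),
               sprintf("# pulse_onsets_us: %s",
                       paste(waveform$pulse_onsets_us, collapse = " "))), con)
  utils::write.table(data.frame(waveform$times_us, waveform$values), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    if (!length(ln)) stop("malformed waveform header: missing ", key)
    as.numeric(strsplit(sub(paste0("^# ", key, ": *"), "", ln[1]), " ")[[1]])
  }
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")])
  structure(list(times_us = tab[[1]], values = tab[[2]],
                 raw_peak_V = get("raw_peak_V"), dt_us = get("dt_us"),
                 pulse_onsets_us = get("pulse_onsets_us"), protocol = NULL),
            class = "tissue_waveform")
}
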