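#' Membrane dynamics of the double-cable myelinated axon
#'
#' Channel densities, passive parameters and kinetics of the established
#' double-cable myelinated axon model: nodes of Ranvier carry fast Na+,
#' persistent Na+ and slow K+ conductances plus leak; MYSA/FLUT/STIN
#' compartments are passive on the axolemma and are wrapped by a myelin
#' sheath whose capacitance and conductance scale inversely with twice the
#' lamellae count (two membranes per lamella). Gating kinetics are the
#' published rate functions with Q10 temperature scaling.
#'
#' @param gnaf_S_cm2 Fast Na+ maximum conductance (S/cm^2).
#' @param gnap_S_cm2 Persistent Na+ maximum conductance (S/cm^2).
#' @param gks_S_cm2 Slow K+ maximum conductance (S/cm^2).
#' @param gl_S_cm2 Nodal leak conductance (S/cm^2).
#' @param ena_mV,ek_mV,el_mV Reversal potentials (mV).
#' @param cm_uF_cm2 Axolemmal capacitance (uF/cm^2), nodes and internodes.
#' @param g_mysa_S_cm2,g_flut_S_cm2,g_stin_S_cm2 Passive axolemmal
#'   conductances (S/cm^2).
#' @param xg_S_cm2,xc_uF_cm2 Myelin conductance and capacitance per
#'   membrane (divided by 2 x lamellae for the sheath).
#' @param rho_axial_ohm_cm Axoplasmic resistivity (Ohm cm).
#' @param rho_periaxonal_ohm_cm Periaxonal-space resistivity (Ohm cm).
#' @param v_rest_mV Rest potential (mV).
#' @param celsius Temperature (degrees C).
#' @return Object of class `membrane_dynamics`.
#' @export
membrane_dynamics <- function(gnaf_S_cm2 = 3.0,
                              gnap_S_cm2 = 0.01,
                              gks_S_cm2 = 0.08,
                              gl_S_cm2 = 0.007,
                              ena_mV = 50, ek_mV = -90, el_mV = -90,
                              cm_uF_cm2 = 2,
                              g_mysa_S_cm2 = 0.001,
                              g_flut_S_cm2 = 0.0001,
                              g_stin_S_cm2 = 0.0001,
                              xg_S_cm2 = 0.001, xc_uF_cm2 = 0.1,
                              rho_axial_ohm_cm = 70,
                              rho_periaxonal_ohm_cm = 70,
                              v_rest_mV = -80,
                              celsius = 36) {
  if (any(c(gnaf_S_cm2, gnap_S_cm2, gks_S_cm2, gl_S_cm2) < 0))
    stop("conductances must be non-negative")
  structure(as.list(environment()), class = "membrane_dynamics")
}

#' Assemble a double-cable axon model from a morphology
#'
#' Builds the per-compartment electrical discretization consumed by the
#' implicit cable integrator: axolemmal and myelin capacitances and
#' conductances from membrane areas, intracellular and periaxonal axial
#' conductances from compartment geometry, and channel conductances at
#' active nodes. The collateral root couples to its branch node on the
#' main path. Nodal leak (and the passive terminal node of a collateral)
#' reverses at the rest potential so that an unstimulated fiber holds rest.
#'
#' @param morph An [compartmentalize()] result (`axon_morphology`).
#' @param dyn [membrane_dynamics()].
#' @return Object of class `axon_model` holding the discretization, the
#'   compartment table, node bookkeeping, and default monitor nodes
#'   (2nd-4th active main-path node from each end).
#' @export
build_axon <- function(morph, dyn = membrane_dynamics()) {
  stopifnot(inherits(morph, "axon_morphology"),
            inherits(dyn, "membrane_dynamics"))
  df <- morph$compartments
  n <- nrow(df)
  if (any(df$length_um <= 0)) stop("zero-length compartment in morphology")
  is_node <- df$type == "node"
  active <- df$active

  geom_of <- function(section) if (section == "main") morph$main_geom else morph$coll_geom
  peri_um <- vapply(seq_len(n), function(i)
    geom_of(df$section[i])$periaxonal_um[[df$type[i]]], numeric(1))
  lamellae <- vapply(seq_len(n), function(i)
    geom_of(df$section[i])$n_lamellae, numeric(1))

  area_cm2 <- pi * (df$diameter_um * 1e-4) * (df$length_um * 1e-4)
  c_axo_nF <- dyn$cm_uF_cm2 * area_cm2 * 1e3
  g_pas_S_cm2 <- ifelse(is_node, dyn$gl_S_cm2,
                        ifelse(df$type == "mysa", dyn$g_mysa_S_cm2,
                               ifelse(df$type == "flut", dyn$g_flut_S_cm2,
                                      dyn$g_stin_S_cm2)))
  g_pas_uS <- g_pas_S_cm2 * area_cm2 * 1e6
  # active nodal leak reverses at el (-90 mV); the persistent Na+ current
  # balances it so the node rests near v_rest. Passive compartments
  # (internodal axolemma, passive terminal nodes) rest at v_rest directly.
  e_pas_mV <- ifelse(is_node & active, dyn$el_mV, dyn$v_rest_mV)

  c_my_nF <- ifelse(is_node, 0,
                    dyn$xc_uF_cm2 / (2 * lamellae) * area_cm2 * 1e3)
  g_my_uS <- ifelse(is_node, 0,
                    dyn$xg_S_cm2 / (2 * lamellae) * area_cm2 * 1e6)

  gnaf_uS <- ifelse(active, dyn$gnaf_S_cm2 * area_cm2 * 1e6, 0)
  gnap_uS <- ifelse(active, dyn$gnap_S_cm2 * area_cm2 * 1e6, 0)
  gks_uS <- ifelse(active, dyn$gks_S_cm2 * area_cm2 * 1e6, 0)

  # half-compartment axial resistances (Ohm): intracellular and periaxonal
  rh_axial <- dyn$rho_axial_ohm_cm * (df$length_um * 1e-4 / 2) /
    (pi * (df$diameter_um * 1e-4 / 2)^2)
  rh_peri <- dyn$rho_periaxonal_ohm_cm * (df$length_um * 1e-4 / 2) /
    (pi * (df$diameter_um * 1e-4) * (peri_um * 1e-4))

  parent <- c(-1L, seq_len(n - 1) - 1L) # 0-based chain
  n_main <- sum(df$section == "main")
  if (!is.na(morph$branch_parent) && n_main < n) {
    parent[n_main + 1] <- morph$branch_parent - 1L
  }
  ga_uS <- numeric(n); gp_uS <- numeric(n)
  for (i in 2:n) {
    pi_ <- parent[i] + 1
    ga_uS[i] <- 1e6 / (rh_axial[i] + rh_axial[pi_])
    gp_uS[i] <- 1e6 / (rh_peri[i] + rh_peri[pi_])
  }

  node_idx <- which(is_node)
  main_nodes <- which(is_node & df$section == "main" & active)
  k <- length(main_nodes)
  monitor <- unique(c(main_nodes[pmin(k, 2:4)], main_nodes[pmax(1, k - (1:3))]))

  structure(list(n = n, parent = as.integer(parent),
                 is_node = as.integer(is_node), active = as.integer(active),
                 c_axo_nF = c_axo_nF, c_my_nF = c_my_nF, g_my_uS = g_my_uS,
                 g_pas_uS = g_pas_uS, e_pas_mV = e_pas_mV,
                 ga_uS = ga_uS, gp_uS = gp_uS,
                 gnaf_uS = gnaf_uS, gnap_uS = gnap_uS, gks_uS = gks_uS,
                 ena_mV = dyn$ena_mV, ek_mV = dyn$ek_mV,
                 v_rest_mV = dyn$v_rest_mV, celsius = dyn$celsius,
                 node_idx = node_idx, main_node_idx = main_nodes,
                 monitor = monitor,
                 midpoints = as.matrix(df[, c("x", "y", "z")]),
                 compartments = df, dynamics = dyn),
            class = "axon_model")
}

#' @export
print.axon_model <- function(x, ...) {
  cat(sprintf("Double-cable axon model: %d compartments, %d nodes (%d active)\n",
              x$n, length(x$node_idx), sum(x$active[x$node_idx])))
  invisible(x)
}

#' Settle an axon model to its resting state
#'
#' Runs the integrator with zero extracellular drive until the maximum
#' membrane-potential drift falls below `tol_mV_ms` (mV/ms) or `max_ms` is
#' reached, and returns the packed state vector for use as `init_state`.
#' Because the backward-Euler fixed point is the exact equilibrium of the
#' cable equations regardless of step size, settling runs at a coarse step
#' by default; the resulting state is valid as the initial condition for
#' any subsequent integration step size.
#'
#' @param model An [build_axon()] result.
#' @param dt_us Integration step (us).
#' @param max_ms Maximum settling time (ms).
#' @param tol_mV_ms Drift tolerance (mV/ms).
#' @return Packed state vector (attribute `drift_mV_ms` records the final
#'   drift).
#' @export
settle_axon <- function(model, dt_us = 25, max_ms = 500, tol_mV_ms = 1e-4) {
  dt_ms <- dt_us * 1e-3
  state <- numeric(0)
  chunk_ms <- 50
  n_steps <- round(chunk_ms / dt_ms)
  drift <- Inf
  elapsed <- 0
  while (elapsed < max_ms) {
    res <- .cable_integrate(model, numeric(model$n), rep(0, n_steps + 1), 0,
                            dt_ms, n_steps, model$node_idx,
                            max(1L, n_steps %/% 2), state,
                            0L, 0, 0, 0, TRUE)
    prev <- res$potentials[, ncol(res$potentials) - 1]
    last <- res$potentials[, ncol(res$potentials)]
    drift <- max(abs(last - prev)) / (chunk_ms / 2)
    state <- res$state
    elapsed <- elapsed + chunk_ms
    if (drift < tol_mV_ms) break
  }
  attr(state, "drift_mV_ms") <- drift
  state
}

#' Integrate an axon model under extracellular stimulation
#'
#' Implicit (backward-Euler) integration of the double-cable equations with
#' the extracellular potential applied at each compartment's external node.
#' The drive is the separable composition of the unit static potential at
#' the compartment midpoints, the stimulus amplitude, and the normalized
#' tissue waveform.
#'
#' @param model An [build_axon()] result.
#' @param phi Unit-field potentials (V) at the compartment midpoints (e.g.
#'   from [sample_potentials()]); recycled scalar 0 means no field.
#' @param waveform A [simulate_tissue_waveform()] result, or `NULL` for
#'   zero drive; its sampling interval must equal `dt_us`.
#' @param amplitude_V Stimulus amplitude (V).
#' @param dt_us Time step (us).
#' @param duration_us Simulated duration (us).
#' @param record Compartment indices to record (default: all nodes of
#'   Ranvier).
#' @param init_state Packed state from [settle_axon()] (default: analytic
#'   rest initialization).
#' @param iinj Optional intracellular step current: list with `comp`,
#'   `nA`, `start_us`, `dur_us`.
#' @return Object of class `sim_record`: `potentials` (mV, one row per
#'   recorded compartment), `times_ms`, `record_idx`, `dt_us`, and `state`.
#' @export
integrate_axon <- function(model, phi = 0, waveform = NULL, amplitude_V = 0,
                           dt_us = 1, duration_us, record = NULL,
                           init_state = NULL, iinj = NULL) {
  stopifnot(inherits(model, "axon_model"))
  dt_ms <- dt_us * 1e-3
  n_steps <- round(duration_us / dt_us)
  phi <- rep_len(as.numeric(phi), model$n)
  if (is.null(waveform)) {
    wave <- rep(0, n_steps + 1)
    amplitude_V <- 0
  } else {
    if (abs(waveform$dt_us - dt_us) > 1e-9)
      stop("waveform sampling interval must equal the integration step")
    wave <- waveform$values
    if (length(wave) < n_steps + 1)
      stop("waveform shorter than the requested duration")
  }
  if (is.null(record)) record <- model$node_idx
  if (is.null(init_state)) init_state <- numeric(0)
  ii <- list(comp = 0L, nA = 0, start_us = 0, dur_us = 0)
  if (!is.null(iinj)) ii[names(iinj)] <- iinj
  res <- .cable_integrate(model, phi, wave, amplitude_V, dt_ms, n_steps,
                          as.integer(record), 1L, as.numeric(init_state),
                          as.integer(ii$comp), ii$nA, ii$start_us * 1e-3,
                          ii$dur_us * 1e-3, TRUE)
  structure(list(potentials = res$potentials, times_ms = res$times_ms,
                 record_idx = as.integer(record), dt_us = dt_us,
                 state = res$state),
            class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat(sprintf("Simulation record: %d compartments x %d samples (%.2f ms)\n",
              nrow(x$potentials), ncol(x$potentials), max(x$times_ms)))
  invisible(x)
}

# upward crossings of `thr` within a trace; returns index of first sample
# above threshold for each crossing
.crossings <- function(trace, thr) {
  above <- trace > thr
  which(above[-1] & !above[-length(above)]) + 1L
}

#' Detect 1-to-1 activation in a simulation record
#'
#' Counts upward threshold crossings of the membrane potential in each
#' inter-pulse window at each monitored distal node. The axon counts as
#' activated if and only if every monitored node fires exactly once per
#' stimulus pulse. The initiation node is the recorded node with the
#' earliest crossing.
#'
#' @param rec A [integrate_axon()] record containing the monitor nodes.
#' @param protocol The [stimulus_protocol()] that produced the drive.
#' @param monitor Compartment indices of the monitored distal nodes.
#' @param threshold_mV Crossing level (mV).
#' @return Object of class `activation_result`: `activated`,
#'   `spikes_per_pulse` (monitor x pulse counts), `initiation_node`
#'   (compartment index or NA).
#' @export
detect_activation <- function(rec, protocol, monitor,
                              threshold_mV = 0) {
  stopifnot(inherits(rec, "sim_record"), inherits(protocol, "stimulus_protocol"))
  period_us <- round(protocol$period_us / rec$dt_us) * rec$dt_us # sample grid
  if (max(rec$times_ms) * 1e3 + rec$dt_us + 1e-6 <
      protocol$n_pulses * period_us)
    stop("record shorter than the stimulation protocol")
  rows <- match(monitor, rec$record_idx)
  if (anyNA(rows)) stop("monitor nodes were not recorded")
  onsets_ms <- (seq_len(protocol$n_pulses) - 1) * period_us * 1e-3
  window_of <- function(t_ms) findInterval(t_ms, onsets_ms)

  counts <- matrix(0L, length(monitor), protocol$n_pulses,
                   dimnames = list(paste0("comp", monitor), NULL))
  first_t <- Inf; init_node <- NA_integer_
  all_rows <- seq_len(nrow(rec$potentials))
  for (r in all_rows) {
    cr <- .crossings(rec$potentials[r, ], threshold_mV)
    if (length(cr)) {
      t_cr <- rec$times_ms[cr]
      if (t_cr[1] < first_t) {
        first_t <- t_cr[1]
        init_node <- rec$record_idx[r]
      }
      if (r %in% rows) {
        w <- window_of(t_cr)
        w <- w[w >= 1 & w <= protocol$n_pulses]
        mi <- which(rows == r)
        for (wi in w) counts[mi, wi] <- counts[mi, wi] + 1L
      }
    }
  }
  structure(list(activated = all(counts == 1L),
                 spikes_per_pulse = counts,
                 initiation_node = init_node),
            class = "activation_result")
}

#' @export
print.activation_result <- function(x, ...) {
  cat(sprintf("Activation: %s (initiation at compartment %s)\n",
              if (x$activated) "1-to-1" else "no",
              ifelse(is.na(x$initiation_node), "-", x$initiation_node)))
  invisible(x)
}
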