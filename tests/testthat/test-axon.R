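test_that("model assembly is deterministic and respects passive terminals", {
  el <- electrode_spec()
  main <- streamline(cbind(3, 0, seq(-14, 14, by = 0.25)))
  anat <- anatomy_context(rbind(c(1.2, 1.2, 0), c(1.4, 1.0, 0.4)), 0.5, el)
  set.seed(9); traj <- build_collateral(main, fiber_geometry(5.7), anat)
  morph <- compartmentalize(traj)
  ax1 <- build_axon(morph)
  ax2 <- build_axon(morph)
  expect_identical(ax1[setdiff(names(ax1), "dynamics")],
                   ax2[setdiff(names(ax2), "dynamics")])

  # passive terminal node of the collateral: leak + capacitance only
  term <- which(ax1$compartments$section == "collateral" &
                  ax1$compartments$type == "node")
  term <- term[length(term)]
  expect_equal(ax1$gnaf_uS[term], 0)
  expect_equal(ax1$gks_uS[term], 0)
  expect_gt(ax1$g_pas_uS[term], 0)
  expect_gt(ax1$c_axo_nF[term], 0)
  # collateral root couples to the branch node on the main path
  n_main <- sum(ax1$compartments$section == "main")
  expect_equal(ax1$parent[n_main + 1] + 1L, morph$branch_parent)

  # axial conductance reciprocity: edge value matches the two-half-resistor
  # formula computed by hand for a node/MYSA pair
  df <- ax1$compartments
  rh <- function(i) 70 * (df$length_um[i] * 1e-4 / 2) /
    (pi * (df$diameter_um[i] * 1e-4 / 2)^2)
  expect_equal(ax1$ga_uS[2], 1e6 / (rh(2) + rh(1)), tolerance = 1e-12)

  bad <- morph
  bad$compartments$length_um[3] <- 0
  expect_error(build_axon(bad), "zero-length")
})

test_that("a settled axon holds its resting state for 50 ms", {
  ax <- straight_axon(2.5, 12)
  st <- settled(ax, "rest12")
  rec <- integrate_axon(ax, duration_us = 50000, dt_us = 1, init_state = st)
  drift <- abs(rec$potentials - rec$potentials[, 1])
  expect_lt(max(drift), 0.1)
})

test_that("an intracellular stimulus propagates to both fiber ends", {
  ax <- straight_axon(2.5, 12)
  st <- settled(ax, "rest12")
  mid <- ax$node_idx[ceiling(length(ax$node_idx) / 2)]
  rec <- integrate_axon(ax, duration_us = 3000, dt_us = 1, init_state = st,
                        iinj = list(comp = mid, nA = 3, start_us = 100,
                                    dur_us = 100))
  n <- length(ax$node_idx)
  second <- rec$potentials[2, ]
  second_last <- rec$potentials[n - 1, ]
  expect_gt(max(second), 0)
  expect_gt(max(second_last), 0)
  # symmetric geometry: both ends fire at the same time
  expect_equal(which.max(second), which.max(second_last), tolerance = 2)
})

test_that("conduction velocity agrees with the independent ODE route within 5%", {
  skip_if_not_installed("deSolve")
  fib <- oracle_fiber(n_nodes = 11)
  o <- oracle_run(fib, inj_node = 3, inj_nA = 3, inj_start_ms = 0.1,
                  inj_dur_ms = 0.1, t_end_ms = 2)
  cv_oracle <- cv_between(o$t_ms, o$Vm[, 5], o$Vm[, 9], 4 * 0.5)

  L <- (11 - 1) * 0.5 + 0.002
  pts <- cbind(0, 0, seq(0, L, length.out = 160))
  ax <- build_axon(compartmentalize(axon_trajectory(streamline(pts))))
  st <- settle_axon(ax)
  rec <- integrate_axon(ax, duration_us = 2000, dt_us = 0.5, init_state = st,
                        iinj = list(comp = ax$node_idx[3], nA = 3,
                                    start_us = 100, dur_us = 100))
  cv_pkg <- cv_between(rec$times_ms, rec$potentials[5, ], rec$potentials[9, ],
                       4 * 0.5)
  expect_lt(abs(cv_pkg - cv_oracle) / cv_oracle, 0.05)
})

test_that("membrane response matches the ODE route under extracellular drive", {
  skip_if_not_installed("deSolve")
  # same fiber, driven by a rectangular extracellular pulse from a point
  # source; compares the full nonlinear response of the two routes
  fib <- oracle_fiber(n_nodes = 9)
  phi_o <- -0.2 / sqrt(2^2 + (fib$mids_um / 1000 - 2)^2)

  L <- (9 - 1) * 0.5 + 0.002
  pts <- cbind(2, 0, seq(-2, L - 2, length.out = 160))
  ax <- build_axon(compartmentalize(axon_trajectory(streamline(pts))))
  phi_p <- -0.2 / sqrt(rowSums(ax$midpoints^2))
  nsteps <- 2000
  vals <- as.numeric(seq_len(nsteps + 1) * 1 > 100 &
                       seq_len(nsteps + 1) * 1 <= 160)
  w <- fake_waveform(vals, dt_us = 1)
  st <- settle_axon(ax)

  for (amp in c(8, 25)) {
    rec <- integrate_axon(ax, phi_p, w, amp, 1, nsteps, init_state = st)
    o <- oracle_run_extracellular(fib, phi_o, amp, on_ms = 0.1, off_ms = 0.16,
                                  t_end_ms = 2)
    pk_p <- max(rec$potentials)
    pk_o <- max(o$Vm)
    expect_lt(abs(pk_p - pk_o) / (abs(pk_o) + 1), 0.05)
  }
})

test_that("the activation detector implements the 1-to-1 rule", {
  pr <- test_protocol(n_pulses = 3)
  period_ms <- pr$period_us * 1e-3
  n <- round(3 * period_ms / 0.01)
  t_ms <- (seq_len(n + 1) - 1) * 0.01
  base <- rep(-80, n + 1)
  spike_at <- function(trace, t0) {
    i <- which.min(abs(t_ms - t0))
    trace[i + 0:5] <- c(10, 30, 20, 5, -10, -40)
    trace
  }
  mk <- function(traces) fake_record(traces, dt_us = 10, record_idx = c(5L, 9L))

  sub <- mk(rbind(base, base))
  res <- detect_activation(sub, pr, monitor = c(5L, 9L))
  expect_false(res$activated)
  expect_true(all(res$spikes_per_pulse == 0))
  expect_true(is.na(res$initiation_node))

  one_per <- base
  for (k in 0:2) one_per <- spike_at(one_per, k * period_ms + 0.5)
  good <- mk(rbind(one_per, one_per))
  res <- detect_activation(good, pr, monitor = c(5L, 9L))
  expect_true(res$activated)
  expect_true(all(res$spikes_per_pulse == 1))
  expect_equal(res$initiation_node, 5L)

  doublet <- spike_at(one_per, 0.9)
  res <- detect_activation(mk(rbind(doublet, one_per)), pr,
                           monitor = c(5L, 9L))
  expect_false(res$activated)
  expect_equal(unname(res$spikes_per_pulse[1, 1]), 2L)

  # a monitored node missing one pulse also fails
  two_of_three <- base
  for (k in 0:1) two_of_three <- spike_at(two_of_three, k * period_ms + 0.5)
  res <- detect_activation(mk(rbind(one_per, two_of_three)), pr,
                           monitor = c(5L, 9L))
  expect_false(res$activated)

  short <- fake_record(rbind(base[1:100], base[1:100]), 10, c(5L, 9L))
  expect_error(detect_activation(short, pr, monitor = c(5L, 9L)), "shorter")
  expect_error(detect_activation(good, pr, monitor = c(1L)), "not recorded")
})

test_that("refractoriness permits 1-to-1 following at 130 Hz but not at 1 kHz", {
  ax <- straight_axon(2.0, 12)
  st <- settled(ax, "rest12b")
  f <- test_field()
  phi <- sample_potentials(f, ax$midpoints)
  two_pulse <- function(gap_us) {
    n <- round((gap_us + 3000) / 1)
    vals <- numeric(n + 1)
    tt <- (seq_len(n + 1) - 1)
    vals[(tt > 0 & tt <= 60) | (tt > gap_us & tt <= gap_us + 60)] <- 1
    w <- fake_waveform(vals, dt_us = 1)
    rec <- integrate_axon(ax, phi, w, 3, 1, n, init_state = st)
    sum(apply(rec$potentials[c(3, length(ax$node_idx) - 2), , drop = FALSE],
              1, function(v) length(which(v[-1] > 0 & v[-length(v)] <= 0)))) / 2
  }
  expect_lt(two_pulse(1000), 2)     # second pulse inside the refractory period
  expect_equal(two_pulse(7692), 2)  # 130 Hz spacing follows 1-to-1
})
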