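test_that("an axon in a zero field is excluded at the cap", {
  ax <- straight_axon(2.5, 12)
  null_field <- structure(list(kind = "analytic-isotropic",
                               phi = function(p) numeric(nrow(matrix(p, ncol = 3))),
                               access_resistance_ohm = 1373,
                               sigma_enc_S_m = 0.1,
                               electrode = electrode_spec()),
                          class = "field_model")
  pr <- test_protocol()
  res <- find_threshold(ax, null_field, test_waveform(), pr,
                        init_state = settled(ax, "rest12"))
  expect_true(is.na(res$threshold_V))
  expect_true(res$excluded)
  expect_equal(res$reason, "cap")
})

test_that("thresholds scale as 1/k when the field is scaled by k", {
  ax <- straight_axon(2.5, 12)
  st <- settled(ax, "rest12")
  pr <- test_protocol()
  w <- test_waveform()
  f <- test_field()
  th1 <- find_threshold(ax, f, w, pr, init_state = st)$threshold_V
  th2 <- find_threshold(ax, scale_field(f, 2), w, pr, init_state = st)$threshold_V
  expect_false(is.na(th1))
  expect_lt(abs(th2 - th1 / 2), 0.02)
})

test_that("a 0.25 mm grid import reproduces analytic-field thresholds within 2%", {
  ax <- straight_axon(2.5, 12)
  st <- settled(ax, "rest12")
  pr <- test_protocol()
  w <- test_waveform()
  f <- test_field()
  path <- withr::local_tempfile(fileext = ".txt")
  save_field_grid(f, path, origin_mm = c(1, -2, -7.5), spacing_mm = 0.25,
                  dims = c(13, 17, 61))
  g <- load_field_grid(path)
  th_a <- find_threshold(ax, f, w, pr, init_state = st)$threshold_V
  th_g <- find_threshold(ax, g, w, pr, init_state = st)$threshold_V
  expect_lt(abs(th_g - th_a) / th_a, 0.02)
})

test_that("the search is monotone-consistent at its own threshold", {
  ax <- straight_axon(2.0, 12)
  st <- settled(ax, "rest12b")
  pr <- test_protocol()
  w <- test_waveform()
  f <- test_field()
  res <- find_threshold(ax, f, w, pr, init_state = st)
  phi <- sample_potentials(f, ax$midpoints)
  dur <- (length(w$values) - 1) * 1
  probe <- function(a) {
    rec <- integrate_axon(ax, phi, w, a, 1, dur, init_state = st)
    detect_activation(rec, pr, ax$monitor)$activated
  }
  expect_true(probe(res$threshold_V))
  expect_false(probe(res$threshold_V - 0.01))
})

test_that("exclusion rules drop capped and distally initiating axons", {
  res <- data.frame(threshold_V = c(1.2, NA, 0.8, 2.0),
                    excluded = c(FALSE, TRUE, TRUE, FALSE),
                    reason = c("", "cap", "distal", ""),
                    initiation_node = c(40L, NA, 2L, 52L),
                    n_sims = 10L)
  out <- apply_exclusions(res)
  expect_equal(nrow(out), 2)
  counts <- attr(out, "exclusion_counts")
  expect_equal(as.integer(counts[c("cap", "distal")]), c(1L, 1L))
  all_in <- res[!res$excluded, ]
  expect_equal(nrow(apply_exclusions(all_in)), 2)
})

test_that("bootstrap recruitment reproduces degenerate and binomial limits", {
  amps <- seq(0, 5, by = 0.1)
  # identical thresholds: a 0 -> 100% step with zero spread
  set.seed(30)
  rc <- bootstrap_recruitment(rep(2, 50), amps, n_pop = 40, pop_size = 100)
  expect_true(all(rc$mean_pct[rc$amplitude_V < 2] == 0))
  expect_true(all(rc$mean_pct[rc$amplitude_V >= 2] == 100))
  expect_true(all(rc$sd_pct == 0))

  # no axon under the cap: flat 0 +/- 0
  rc0 <- bootstrap_recruitment(rep(NA_real_, 20), amps, n_pop = 10,
                               pop_size = 50)
  expect_true(all(rc0$mean_pct == 0) && all(rc0$sd_pct == 0))

  # bootstrap mean within 2 SE of the empirical proportion
  set.seed(31)
  th <- runif(400, 0.5, 4.5)
  rc <- bootstrap_recruitment(th, amps, n_pop = 100, pop_size = 1000)
  for (a in c(1, 2.5, 4)) {
    p_emp <- mean(th <= a)
    se <- sqrt(p_emp * (1 - p_emp) / 1000) * 100
    expect_lt(abs(rc$mean_pct[rc$amplitude_V == a] - 100 * p_emp), 2 * se + 1e-9)
  }
  # monotone mean, non-negative spread
  expect_true(all(diff(rc$mean_pct) >= 0))
  expect_true(all(rc$sd_pct >= 0))
  expect_error(bootstrap_recruitment(numeric(0)), "no thresholds")
})

test_that("strength-duration inversion finds the target band when crossed", {
  amps <- seq(0, 10, by = 0.1)
  # Weiss-law synthetic population: threshold = rheobase (1 + chronaxie/pw)
  set.seed(32)
  rheo <- runif(300, 0.8, 3)
  curves <- list()
  for (pw in c(20, 60, 120)) {
    th <- rheo * (1 + 100 / pw)
    curves[[as.character(pw)]] <-
      bootstrap_recruitment(th, amps, n_pop = 50, pop_size = 500)
  }
  sd_pts <- strength_duration(curves, target_pct = 15, tol_pct = 5)
  expect_true(all(sd_pts$reachable))
  expect_true(all(sd_pts$amp_lo_V <= sd_pts$amp_hi_V))
  expect_true(all(diff(sd_pts$amp_lo_V) < 0))   # non-increasing with pw
  expect_true(all(diff(sd_pts$amp_hi_V) < 0))

  # unreachable target is flagged
  sd_hi <- strength_duration(curves["120"], target_pct = 300, tol_pct = 5)
  expect_false(sd_hi$reachable)
})

test_that("cathodic charge integrates exactly for known waveforms", {
  r_t <- 1373
  # ideal rectangular unit waveform: Q = V * pw / R
  rect_factory <- function(pw) {
    tt <- 0:200
    fake_waveform(as.numeric(tt <= pw), dt_us = 1)
  }
  sd_pts <- data.frame(pulse_width_us = c(60, 120),
                       amp_lo_V = c(2, 1), amp_hi_V = c(3, 1.5),
                       reachable = TRUE)
  out <- charge_duration(sd_pts, rect_factory, r_t)
  expect_equal(out$charge_lo_uC, c(2 * 60, 1 * 120) / r_t, tolerance = 1e-3)
  expect_equal(out$charge_hi_uC, c(3 * 60, 1.5 * 120) / r_t, tolerance = 1e-3)

  # trapezoid vs closed form on an exponential decay, dt = 1 us
  tau <- 40
  exp_factory <- function(pw) {
    tt <- 0:200
    fake_waveform(ifelse(tt <= pw, exp(-tt / tau), 0), dt_us = 1)
  }
  out <- charge_duration(sd_pts[1, ], exp_factory, r_t)
  exact <- 2 * tau * (1 - exp(-60 / tau)) / r_t
  expect_lt(abs(out$charge_lo_uC - exact) / exact, 0.001)

  # charge grows with pulse width along an SD curve even as amplitude falls
  sd_w <- data.frame(pulse_width_us = c(20, 60, 120),
                     amp_lo_V = c(6, 2.7, 1.8), amp_hi_V = c(7, 3.2, 2.2),
                     reachable = TRUE)
  out <- charge_duration(sd_w, rect_factory, r_t)
  expect_true(all(diff(out$charge_lo_uC) > 0))
})
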