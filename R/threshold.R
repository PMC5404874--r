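#' Binary search for the activation threshold amplitude
#'
#' Binary search on the stimulus amplitude between 0 V (never activating)
#' and `cap_V`, using the 1-to-1 distal-response criterion of
#' [detect_activation()] on a short pulse train: the upper bracket is grown
#' geometrically until an activating amplitude is found, then bisection
#' refines the lowest activating amplitude to within `resolution_V`. The axon is settled to
#' rest once and every probe starts from that state. Axons that do not
#' activate at the cap are flagged excluded (reason `"cap"`); axons whose
#' action potential initiates within `guard` nodes of either end of the
#' corticofugal axon are flagged excluded (reason `"distal"`).
#'
#' @param axon An [build_axon()] model.
#' @param field A `field_model` (analytic or grid).
#' @param waveform Normalized `tissue_waveform` sampled at `dt_us`.
#' @param protocol The [stimulus_protocol()] describing the pulse train
#'   (its `n_pulses` governs the activation criterion; default 3 pulses).
#' @param resolution_V Amplitude resolution of the search (V).
#' @param cap_V Upper search bracket and exclusion cap (V).
#' @param dt_us Integration step (us); must match the waveform sampling.
#' @param guard Distal-initiation guard width (nodes from either end).
#' @param monitor Monitor compartments (default: the model's 2nd-4th
#'   active nodes from each corticofugal end).
#' @param init_state Optional pre-settled state (computed if missing).
#' @return A one-row data.frame of class `threshold_result`: `threshold_V`
#'   (NA if not found), `excluded`, `reason`, `initiation_node`,
#'   `n_sims`.
#' @export
find_threshold <- function(axon, field, waveform, protocol,
                           resolution_V = 0.01, cap_V = 150,
                           dt_us = protocol$dt_us, guard = 3,
                           monitor = axon$monitor, init_state = NULL) {
  stopifnot(inherits(axon, "axon_model"), resolution_V > 0, cap_V > 0)
  phi <- sample_potentials(field, axon$midpoints)
  duration_us <- (length(waveform$values) - 1) * dt_us
  if (is.null(init_state)) init_state <- settle_axon(axon)

  probe <- function(amp) {
    rec <- integrate_axon(axon, phi, waveform, amp, dt_us, duration_us,
                          record = axon$node_idx, init_state = init_state)
    detect_activation(rec, protocol, monitor)
  }

  # The 1-to-1 response is not monotone in amplitude: far above threshold
  # the axon blocks or fires doublets. A plain bisection started at the cap
  # can therefore converge onto the upper edge of the activated region. The
  # upper bracket is instead grown geometrically from the search resolution
  # until the first activating amplitude is found, which the bisection then
  # refines downward to the lowest activating amplitude.
  n_sims <- 0L
  lo <- 0; hi <- NA_real_; init_node <- NA_integer_
  a <- resolution_V * 100
  repeat {
    a <- min(a, cap_V)
    act <- probe(a)
    n_sims <- n_sims + 1L
    if (act$activated) {
      hi <- a
      init_node <- act$initiation_node
      break
    }
    lo <- a
    if (a >= cap_V) break
    a <- a * 2
  }
  if (is.na(hi)) {
    res <- data.frame(threshold_V = NA_real_, excluded = TRUE, reason = "cap",
                      initiation_node = NA_integer_, n_sims = n_sims)
    class(res) <- c("threshold_result", class(res))
    return(res)
  }
  while (hi - lo > resolution_V) {
    mid <- (lo + hi) / 2
    act <- probe(mid)
    n_sims <- n_sims + 1L
    if (act$activated) {
      hi <- mid
      init_node <- act$initiation_node
    } else lo <- mid
  }

  main_nodes <- axon$main_node_idx
  pos <- match(init_node, main_nodes)
  distal <- !is.na(pos) && (pos <= guard || pos > length(main_nodes) - guard)
  res <- data.frame(threshold_V = hi, excluded = distal,
                    reason = if (distal) "distal" else "",
                    initiation_node = init_node, n_sims = n_sims)
  class(res) <- c("threshold_result", class(res))
  res
}

#' Apply the population exclusion rules
#'
#' Drops axons whose threshold reached the cap or whose action potential
#' initiated in the distal nodes, and reports counts per reason.
#'
#' @param results Data.frame of stacked [find_threshold()] rows (one axon
#'   per row, any extra id columns preserved).
#' @return The surviving rows; attribute `exclusion_counts` holds a named
#'   count per reason.
#' @export
apply_exclusions <- function(results) {
  stopifnot(nrow(results) >= 1)
  excl <- results$excluded
  counts <- table(factor(results$reason[excl], levels = c("cap", "distal")))
  out <- results[!excl, , drop = FALSE]
  attr(out, "exclusion_counts") <- counts
  out
}

#' Bootstrap recruitment curve
#'
#' Resamples the per-axon thresholds into `n_pop` populations of `pop_size`
#' axons (with replacement) and evaluates, on an amplitude grid, the
#' percentage of each population with threshold at or below the amplitude.
#' Returns mean and standard deviation over populations.
#'
#' @param thresholds_V Numeric vector of per-axon thresholds (NA = never
#'   activated; such axons never count as active).
#' @param amplitudes_V Amplitude grid (V).
#' @param n_pop Number of bootstrap populations.
#' @param pop_size Axons per population.
#' @return Object of class `recruitment_curve`: data.frame with
#'   `amplitude_V`, `mean_pct`, `sd_pct`; attributes `n_populations`,
#'   `population_size`.
#' @export
bootstrap_recruitment <- function(thresholds_V, amplitudes_V = seq(0, 10, 0.1),
                                  n_pop = 100, pop_size = 1000) {
  if (!length(thresholds_V)) stop("no thresholds supplied")
  th <- thresholds_V
  act <- matrix(0, n_pop, length(amplitudes_V))
  for (b in seq_len(n_pop)) {
    smp <- th[sample.int(length(th), pop_size, replace = TRUE)]
    smp <- sort(smp[!is.na(smp)]) # NA thresholds never activate
    act[b, ] <- 100 * findInterval(amplitudes_V, smp) / pop_size
  }
  out <- data.frame(amplitude_V = amplitudes_V,
                    mean_pct = colMeans(act),
                    sd_pct = apply(act, 2, stats::sd))
  attr(out, "n_populations") <- n_pop
  attr(out, "population_size") <- pop_size
  class(out) <- c("recruitment_curve", class(out))
  out
}

# amplitude at which the recruitment mean first reaches `pct`, by linear
# interpolation between grid amplitudes; NA if never reached
.inverse_recruitment <- function(curve, pct) {
  m <- curve$mean_pct
  a <- curve$amplitude_V
  at <- which(m >= pct)
  if (!length(at)) return(NA_real_)
  i <- at[1]
  if (i == 1 || m[i] == m[i - 1]) return(a[i])
  a[i - 1] + (pct - m[i - 1]) / (m[i] - m[i - 1]) * (a[i] - a[i - 1])
}

#' Strength-duration points at a target activation band
#'
#' For each pulse width, inverts the recruitment curve to the amplitude
#' interval whose mean activation lies within `target_pct` plus/minus
#' `tol_pct` (e.g. 15 +/- 5% for the hyperdirect pathway, 10 +/- 5% for
#' fibers of passage).
#'
#' @param recruitment_by_pw Named list of [bootstrap_recruitment()] curves;
#'   names are pulse widths in us.
#' @param target_pct Target activation percentage.
#' @param tol_pct Band half-width (percentage points).
#' @return Data.frame of class `sd_curve`: `pulse_width_us`, `amp_lo_V`,
#'   `amp_hi_V`, `reachable`.
#' @export
strength_duration <- function(recruitment_by_pw, target_pct = 15,
                              tol_pct = 5) {
  pw <- as.numeric(names(recruitment_by_pw))
  if (anyNA(pw)) stop("recruitment_by_pw must be named by pulse width (us)")
  rows <- lapply(seq_along(pw), function(i) {
    cv <- recruitment_by_pw[[i]]
    lo <- .inverse_recruitment(cv, target_pct - tol_pct)
    hi <- .inverse_recruitment(cv, target_pct + tol_pct)
    reach <- !is.na(lo)
    if (is.na(hi)) hi <- max(cv$amplitude_V) # band upper edge never reached
    data.frame(pulse_width_us = pw[i],
               amp_lo_V = lo, amp_hi_V = hi, reachable = reach)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pulse_width_us), ]
  rownames(out) <- NULL
  class(out) <- c("sd_curve", class(out))
  out
}

#' Cathodic charge for strength-duration points
#'
#' Converts each strength-duration amplitude into the total charge injected
#' during the cathodic phase: the trapezoidal integral of the current
#' through the tissue resistance (amplitude times the normalized waveform
#' divided by the tissue resistance) over the cathodic phase.
#'
#' @param sd_points A [strength_duration()] result.
#' @param waveform_factory Function pulse_width_us -> `tissue_waveform`.
#' @param r_tissue_ohm Tissue resistance (Ohm).
#' @return `sd_points` with added `charge_lo_uC`, `charge_hi_uC` columns.
#' @export
charge_duration <- function(sd_points, waveform_factory, r_tissue_ohm) {
  stopifnot(r_tissue_ohm > 0)
  charge <- function(pw, amp) {
    if (is.na(amp)) return(NA_real_)
    w <- waveform_factory(pw)
    sel <- w$times_us <= pw & w$times_us >= 0
    # V / Ohm integrated over us gives uC directly
    pracma::trapz(w$times_us[sel], amp * w$values[sel] / r_tissue_ohm)
  }
  sd_points$charge_lo_uC <- mapply(charge, sd_points$pulse_width_us,
                                   sd_points$amp_lo_V)
  sd_points$charge_hi_uC <- mapply(charge, sd_points$pulse_width_us,
                                   sd_points$amp_hi_V)
  sd_points
}
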