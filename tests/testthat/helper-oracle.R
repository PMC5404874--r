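# Independent reference route for the double-cable axon: the same published
# model assembled from its geometry table directly in R and integrated as a
# plain ODE system with deSolve::lsoda. Shares no code with the package's
# compiled backward-Euler path.

oracle_fiber <- function(n_nodes = 9) {
  axonD <- 3.4; nodeD <- 1.9; paraD1 <- 1.9; paraD2 <- 3.4
  deltax <- 500; pl1 <- 3; pl2 <- 35; nodeL <- 1; nl <- 80
  stinL <- (deltax - nodeL - 2 * pl1 - 2 * pl2) / 6
  types <- c("node", rep(c("mysa", "flut", rep("stin", 6), "flut", "mysa",
                           "node"), n_nodes - 1))
  lens <- c(nodeL, rep(c(pl1, pl2, rep(stinL, 6), pl2, pl1, nodeL),
                       n_nodes - 1))
  diams <- ifelse(types == "node", nodeD,
                  ifelse(types == "mysa", paraD1,
                         ifelse(types == "flut", paraD2, axonD)))
  space <- ifelse(types %in% c("node", "mysa"), 0.002, 0.004)
  n <- length(types)
  area <- pi * (diams * 1e-4) * (lens * 1e-4)
  gpas_d <- ifelse(types == "node", 0.007,
                   ifelse(types == "mysa", 0.001, 1e-4))
  Rha <- 70 * (lens * 1e-4 / 2) / (pi * (diams * 1e-4 / 2)^2)
  Rhp <- 70 * (lens * 1e-4 / 2) / (pi * (diams * 1e-4) * (space * 1e-4))
  list(n = n, types = types, is_node = types == "node",
       mids_um = cumsum(lens) - lens / 2,
       Cax = 2 * area * 1e3, Gpas = gpas_d * area * 1e6,
       Cmy = ifelse(types == "node", 0, 0.1 / (2 * nl) * area * 1e3),
       Gmy = ifelse(types == "node", 0, 0.001 / (2 * nl) * area * 1e6),
       ga = 1e6 / (Rha[-n] + Rha[-1]), gp = 1e6 / (Rhp[-n] + Rhp[-1]))
}

oracle_rates <- function(v) {
  vt <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 + x / (2 * y)),
                              x / (1 - exp(-x / y)))
  list(am = 6.57 * vt(v + 20.4, 10.3), bm = 0.304 * vt(-(v + 25.7), 9.16),
       ah = 0.34 * vt(-(v + 114), 11),
       bh = 12.6 / (1 + exp(-(v + 31.8) / 13.4)),
       ap = 0.0353 * vt(v + 27, 10.2), bp = 0.000883 * vt(-(v + 34), 10),
       as = 0.3 / (1 + exp(-(v + 53) / 5)),
       bs = 0.03 / (1 + exp(-(v + 90) / 1)))
}

# integrate with an intracellular current step at node `inj_node`;
# returns node potential traces on a regular output grid
oracle_run <- function(fib, inj_node, inj_nA, inj_start_ms, inj_dur_ms,
                       t_end_ms, dt_out_ms = 0.005) {
  n <- fib$n; nid <- which(fib$is_node); nn <- length(nid)
  gNa <- 3.0 * (fib$Gpas[nid] / 0.007)
  gNp <- 0.01 * (fib$Gpas[nid] / 0.007)
  gKs <- 0.08 * (fib$Gpas[nid] / 0.007)
  epas <- ifelse(fib$is_node, -90, -80)
  inj_comp <- nid[inj_node]

  deriv <- function(t, y, parms) {
    Vm <- y[1:n]; Vw <- y[n + (1:n)]
    mm <- y[2 * n + (1:nn)]; hh <- y[2 * n + nn + (1:nn)]
    pp <- y[2 * n + 2 * nn + (1:nn)]; ss <- y[2 * n + 3 * nn + (1:nn)]
    w <- ifelse(fib$is_node, 0, Vw)   # zero extracellular potential
    u <- Vm + w
    Iion <- fib$Gpas * (Vm - epas)
    r <- oracle_rates(Vm[nid])
    gna <- gNa * mm^3 * hh; gnp <- gNp * pp^3; gk <- gKs * ss
    Iion[nid] <- Iion[nid] + (gna + gnp) * (Vm[nid] - 50) + gk * (Vm[nid] + 90)
    Iax <- numeric(n); du <- diff(u)
    Iax[-n] <- Iax[-n] + fib$ga * du
    Iax[-1] <- Iax[-1] - fib$ga * du
    Ipx <- numeric(n); dw <- diff(w)
    Ipx[-n] <- Ipx[-n] + fib$gp * dw
    Ipx[-1] <- Ipx[-1] - fib$gp * dw
    if (t > inj_start_ms && t <= inj_start_ms + inj_dur_ms)
      Iax[inj_comp] <- Iax[inj_comp] + inj_nA
    dVm <- (Iax - Iion) / fib$Cax
    Imem <- fib$Cax * dVm + Iion
    dVw <- ifelse(fib$is_node, 0,
                  (Imem + Ipx - fib$Gmy * Vw) / pmax(fib$Cmy, 1e-12))
    r0 <- r
    list(c(dVm, dVw,
           r0$am * (1 - mm) - r0$bm * mm, r0$ah * (1 - hh) - r0$bh * hh,
           r0$ap * (1 - pp) - r0$bp * pp, r0$as * (1 - ss) - r0$bs * ss))
  }

  r0 <- oracle_rates(-80)
  y0 <- c(rep(-80, n), rep(0, n),
          rep(r0$am / (r0$am + r0$bm), nn), rep(r0$ah / (r0$ah + r0$bh), nn),
          rep(r0$ap / (r0$ap + r0$bp), nn), rep(r0$as / (r0$as + r0$bs), nn))
  s <- deSolve::ode(y0, c(0, 150, 300), deriv, NULL, method = "lsoda",
                    rtol = 1e-6, atol = 1e-6)
  y0 <- s[nrow(s), -1]
  out <- deSolve::ode(y0, seq(0, t_end_ms, by = dt_out_ms), deriv, NULL,
                      method = "lsoda", rtol = 1e-7, atol = 1e-7)
  list(t_ms = out[, 1], Vm = out[, 1 + nid, drop = FALSE])
}

# same ODE route driven by a rectangular extracellular pulse: phi_V is the
# unit potential (V) at each compartment, applied between on_ms and off_ms
oracle_run_extracellular <- function(fib, phi_V, amp, on_ms, off_ms,
                                     t_end_ms, dt_out_ms = 0.005) {
  n <- fib$n; nid <- which(fib$is_node); nn <- length(nid)
  gNa <- 3.0 * (fib$Gpas[nid] / 0.007)
  gNp <- 0.01 * (fib$Gpas[nid] / 0.007)
  gKs <- 0.08 * (fib$Gpas[nid] / 0.007)
  epas <- ifelse(fib$is_node, -90, -80)

  deriv <- function(t, y, parms) {
    Vm <- y[1:n]; Vw <- y[n + (1:n)]
    mm <- y[2 * n + (1:nn)]; hh <- y[2 * n + nn + (1:nn)]
    pp <- y[2 * n + 2 * nn + (1:nn)]; ss <- y[2 * n + 3 * nn + (1:nn)]
    e <- 1000 * amp * phi_V * (t > on_ms && t <= off_ms)
    w <- ifelse(fib$is_node, e, Vw + e)
    u <- Vm + w
    Iion <- fib$Gpas * (Vm - epas)
    r <- oracle_rates(Vm[nid])
    gna <- gNa * mm^3 * hh; gnp <- gNp * pp^3; gk <- gKs * ss
    Iion[nid] <- Iion[nid] + (gna + gnp) * (Vm[nid] - 50) + gk * (Vm[nid] + 90)
    Iax <- numeric(n); du <- diff(u)
    Iax[-n] <- Iax[-n] + fib$ga * du
    Iax[-1] <- Iax[-1] - fib$ga * du
    Ipx <- numeric(n); dw <- diff(w)
    Ipx[-n] <- Ipx[-n] + fib$gp * dw
    Ipx[-1] <- Ipx[-1] - fib$gp * dw
    dVm <- (Iax - Iion) / fib$Cax
    Imem <- fib$Cax * dVm + Iion
    dVw <- ifelse(fib$is_node, 0,
                  (Imem + Ipx - fib$Gmy * Vw) / pmax(fib$Cmy, 1e-12))
    list(c(dVm, dVw,
           r$am * (1 - mm) - r$bm * mm, r$ah * (1 - hh) - r$bh * hh,
           r$ap * (1 - pp) - r$bp * pp, r$as * (1 - ss) - r$bs * ss))
  }

  r0 <- oracle_rates(-80)
  y0 <- c(rep(-80, n), rep(0, n),
          rep(r0$am / (r0$am + r0$bm), nn), rep(r0$ah / (r0$ah + r0$bh), nn),
          rep(r0$ap / (r0$ap + r0$bp), nn), rep(r0$as / (r0$as + r0$bs), nn))
  s <- deSolve::ode(y0, c(0, 150, 300), deriv, NULL, method = "lsoda",
                    rtol = 1e-6, atol = 1e-6)
  y0 <- s[nrow(s), -1]
  out <- deSolve::ode(y0, seq(0, t_end_ms, by = dt_out_ms), deriv, NULL,
                      method = "lsoda", rtol = 1e-7, atol = 1e-7)
  list(t_ms = out[, 1], Vm = out[, 1 + nid, drop = FALSE])
}

# conduction velocity (m/s) between two nodes from 0 mV upward crossings
cv_between <- function(t_ms, v_a, v_b, dist_mm) {
  t_cross <- function(v) {
    i <- which(v[-1] > 0 & v[-length(v)] <= 0)[1]
    t_ms[i] + (0 - v[i]) / (v[i + 1] - v[i]) * (t_ms[i + 1] - t_ms[i])
  }
  dist_mm / (t_cross(v_b) - t_cross(v_a))
}
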