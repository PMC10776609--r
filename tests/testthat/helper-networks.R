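# Shared builders for reactor-level tests.

# A closed (no-flow) single mixed cell with the default feeds, started from
# an unmixed 50/50 solution/water charge at 25 degC.
closed_cell <- function(cfg_mod = identity) {
  cfg <- default_config()
  cfg$template <- "mixed_cell"
  cfg <- cfg_mod(cfg)
  net <- build_network(cfg)
  net$flows$Q <- 0
  net
}

closed_cell_y0 <- function(net, T0 = 298.15) {
  y0 <- numeric(8 + net$grid$n)
  y0[1] <- 0.5
  y0[2] <- 0.5
  y0[8] <- T0
  y0
}

integrate_closed <- function(net, y0, times, rtol = 1e-10) {
  deSolve::lsoda(y0, times, reactor_rhs, net, rtol = rtol, atol = 1e-12)
}

# Total dissolved + crystalline solute along a closed-cell trajectory.
closed_solute_total <- function(sol, net) {
  phi1 <- jetcryst:::inlet_phi(net$inlets[[1]], net$const)
  phi2 <- jetcryst:::inlet_phi(net$inlets[[2]], net$const)
  w <- jetcryst:::mass_weights(net$grid, net$const$rho_crystal,
                               net$const$k_v)
  n <- net$grid$n
  vapply(seq_len(nrow(sol)), function(i) {
    sol[i, 2] * phi1[1] + sol[i, 3] * phi2[1] + sol[i, 6] +
      sum(w * pmax(sol[i, 10:(9 + n)], 0))
  }, numeric(1))
}
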