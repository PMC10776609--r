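#' Build a compartment-network crystallizer model
#'
#' Constructs a flow-balanced network of well-mixed compartments from a run
#' configuration (see [default_config()] / [load_config()]).  Three
#' templates are available:
#' \describe{
#'   \item{`mixed_cell`}{one compartment fed by both inlets.}
#'   \item{`pfr_chain`}{`n_compartments` equal cells in series, both inlets
#'     feeding the first cell (plug flow with cell-to-cell mixing).}
#'   \item{`impinging_jet`}{an impingement compartment fed by the two
#'     opposed jets followed by a chain of chamber compartments to the
#'     outlet, with turbulence strongest at the impingement point and
#'     decaying downstream.}
#' }
#' Inlet volumetric flows are derived from `velocity * nozzle_area` or
#' `mass_flow / density` (mutually exclusive per inlet).  Unless every
#' compartment's turbulence is prescribed in the config, the per-compartment
#' turbulence frequency `eps/k` is the template profile scaled by
#' `v_mean / 1.5` (engulfment proportional to the jet velocity over the
#' nozzle scale).
#'
#' @param config run configuration list; missing entries take defaults.
#' @return object of class `compartment_network`.
#' @export
build_network <- function(config = list()) {
  cfg <- resolve_config(config)
  const <- do.call(physical_constants, cfg$constants)
  grid <- size_grid(cfg$grid$r_min, cfg$grid$r_max, cfg$grid$n_classes)

  inlets <- lapply(cfg$inlets, function(inl) {
    C <- if (!is.null(inl$S_inlet)) {
      feed_concentration(inl$S_inlet, inl$w_as, inl$T_K)
    } else inl$C
    rho <- mixture_density(C, inl$w_as, const)
    has_v <- !is.null(inl$velocity)
    has_m <- !is.null(inl$mass_flow)
    if (has_v && has_m) stop("inlet: give velocity or mass_flow, not both")
    if (!has_v && !has_m) stop("inlet: needs velocity or mass_flow")
    Q <- if (has_v) inl$velocity * cfg$geometry$nozzle_area
         else inl$mass_flow / rho
    v <- Q / cfg$geometry$nozzle_area
    list(env = inl$env, C = C, w_as = inl$w_as, T_K = inl$T_K,
         Q = Q, velocity = v, rho = rho, mdot = Q * rho)
  })

  n_comp <- switch(cfg$template,
                   mixed_cell = 1L,
                   pfr_chain = as.integer(cfg$n_compartments),
                   impinging_jet = 1L + as.integer(cfg$n_chamber),
                   stop("unknown template: ", cfg$template))
  vol <- rep(cfg$geometry$total_volume / n_comp, n_comp)

  # turbulence frequency profile, scaled with mean inlet velocity
  v_mean <- mean(vapply(inlets, `[[`, numeric(1), "velocity"))
  eok <- cfg$turbulence$eps_over_k
  if (is.null(eok)) {
    # jet-scale turbulence frequency: eps ~ v^3/d, k ~ (0.2 v)^2 gives
    # eps/k of order 1e4 1/s at 1.5 m/s in the impingement zone
    prof <- if (cfg$template == "impinging_jet") {
      c(2e4, 5e3, 2e3, 1e3, rep(5e2, max(0, n_comp - 4)))[seq_len(n_comp)]
    } else rep(5e3, n_comp)
    eok <- prof * v_mean / 1.5
  } else {
    eok <- rep_len(eok, n_comp)
  }
  D_t <- rep_len(cfg$turbulence$D_t, n_comp)

  Q_total <- sum(vapply(inlets, `[[`, numeric(1), "Q"))
  # serial chain: both inlets -> compartment 1 -> ... -> n -> out
  flows <- data.frame(
    from = c(paste0("inlet", seq_along(inlets)),
             if (n_comp > 1) seq_len(n_comp - 1), n_comp),
    to = c(rep(1, length(inlets)),
           if (n_comp > 1) 2:n_comp, "out"),
    Q = c(vapply(inlets, `[[`, numeric(1), "Q"),
          rep(Q_total, n_comp)),
    stringsAsFactors = FALSE
  )

  net <- list(
    config = cfg, const = const, grid = grid, inlets = inlets,
    n_comp = n_comp, volumes = vol, eps_over_k = eok, D_t = D_t,
    flows = flows, Q_total = Q_total,
    micromixing = isTRUE(cfg$micromixing),
    kinetics = cfg$kinetics, energy = cfg$energy, solver = cfg$solver
  )
  class(net) <- "compartment_network"
  check_flow_balance(net)
  net
}

#' @export
print.compartment_network <- function(x, ...) {
  cat(sprintf(
    "compartment_network (%s): %d compartment(s), V = %.3g mL, Q = %.3g mL/s\n",
    x$config$template, x$n_comp, sum(x$volumes) * 1e6, x$Q_total * 1e6))
  cat(sprintf("  residence time %.3g s; grid %d classes, dr = %.3g um\n",
              sum(x$volumes) / x$Q_total, x$grid$n, x$grid$dr * 1e6))
  invisible(x)
}

# Flow balance at every compartment (sum in = sum out), 1e-12 relative.
check_flow_balance <- function(net) {
  for (i in seq_len(net$n_comp)) {
    q_in <- sum(net$flows$Q[net$flows$to == as.character(i)])
    q_out <- sum(net$flows$Q[net$flows$from == as.character(i)])
    if (abs(q_in - q_out) > 1e-12 * max(q_in, q_out)) {
      stop("flow imbalance at compartment ", i)
    }
  }
  invisible(TRUE)
}

# Fixed environment compositions as concentration vectors
# (solute, methanol, water) in kg per m^3 of that environment's fluid.
inlet_phi <- function(inl, const) {
  rho <- inl$rho
  msolv <- rho / (1 + inl$C)      # solvents kg per m^3
  c(solute = msolv * inl$C,
    methanol = msolv * (1 - inl$w_as / 100),
    water = msolv * inl$w_as / 100)
}

# State vector layout per compartment:
# P1, P2, P3, q3 (=P3*xi3), sS, sM, sW (kg/m^3, env-3 weighted), T, f[1..n]
.n_scalar <- 8L

state_index <- function(net) {
  per <- .n_scalar + net$grid$n
  list(per = per,
       off = function(i) (i - 1L) * per)
}

#' Initial state vector of a network
#'
#' Compartments start filled with quiescent anti-solvent (environment 2) at
#' the configured initial temperature, with no crystals; with micromixing
#' disabled they start as fully mixed anti-solvent.
#'
#' @param net a [build_network()] result.
#' @return numeric state vector.
#' @export
initial_state <- function(net) {
  n <- net$grid$n
  rho_w <- net$const$rho_water
  per <- .n_scalar + n
  y <- numeric(net$n_comp * per)
  T0 <- net$config$initial$T_K
  for (i in seq_len(net$n_comp)) {
    o <- (i - 1L) * per
    if (net$micromixing) {
      y[o + 2] <- 1                      # P2 = 1, water environment
    } else {
      y[o + 3] <- 1                      # P3 = 1, premixed
      y[o + 7] <- rho_w                  # water content
    }
    y[o + 8] <- T0
  }
  y
}

# Environment composition entering a compartment from an inlet, expressed in
# the transported variables.
inlet_state_vector <- function(net, inl) {
  n <- net$grid$n
  y <- numeric(.n_scalar + n)
  phi <- inlet_phi(inl, net$const)
  if (net$micromixing && inl$env %in% c(1, 2)) {
    y[inl$env] <- 1                      # pure environment fluid
  } else {
    y[3] <- 1                            # enters fully mixed
    y[4] <- if (identical(inl$env, 2)) 0 else
      if (identical(inl$env, 1)) 1 else 0.5
    y[5:7] <- phi
  }
  y[8] <- inl$T_K
  y
}

#' Time derivatives of the full network state
#'
#' Assembles, for every compartment: inter-compartment flow exchange,
#' micromixing sources (with the spurious-dissipation correction inactive in
#' 0-D cells), the size-discretized PBE growth flux divergence and
#' nucleation source evaluated at the environment-3 supersaturation, the
#' solute sink equal to the total crystal mass production rate (mass
#' closure), and the enthalpy source from heats of mixing and
#' crystallization.
#'
#' @param t time, s (unused; autonomous system).
#' @param y state vector (see [initial_state()]).
#' @param net a [build_network()] result.
#' @return list with the derivative vector (deSolve convention) and
#'   diagnostics attribute.
#' @export
reactor_rhs <- function(t, y, net) {
  n <- net$grid$n
  per <- .n_scalar + n
  const <- net$const
  en <- net$energy
  dy <- numeric(length(y))

  phi1 <- phi2 <- c(0, 0, 0)
  for (inl in net$inlets) {
    if (identical(inl$env, 1)) phi1 <- inlet_phi(inl, const)
    if (identical(inl$env, 2)) phi2 <- inlet_phi(inl, const)
  }

  # upstream state for every flow edge
  comp_state <- function(i) y[((i - 1L) * per + 1L):(i * per)]
  rho_comp <- function(s) {
    s[1] * sum(phi1) + s[2] * sum(phi2) + sum(s[5:7])
  }

  for (i in seq_len(net$n_comp)) {
    o <- (i - 1L) * per
    s <- comp_state(i)
    P1 <- s[1]; P2 <- s[2]; P3 <- s[3]; q3 <- s[4]
    sS <- s[5]; sM <- s[6]; sW <- s[7]; T_K <- s[8]
    f <- pmax(s[9:(8 + n)], 0)
    V <- net$volumes[i]
    rho_i <- max(rho_comp(s), 1)

    d <- numeric(per)

    ## ---- flow exchange -------------------------------------------------
    edges_in <- net$flows[net$flows$to == as.character(i), , drop = FALSE]
    edges_out <- net$flows[net$flows$from == as.character(i), , drop = FALSE]
    for (k in seq_len(nrow(edges_in))) {
      from <- edges_in$from[k]; Q <- edges_in$Q[k]
      up <- if (grepl("^inlet", from)) {
        idx <- as.integer(sub("inlet", "", from))
        inlet_state_vector(net, net$inlets[[idx]])
      } else comp_state(as.integer(from))
      d[1:7] <- d[1:7] + Q / V * up[1:7]
      d[9:per] <- d[9:per] + Q / V * up[9:per]
      # enthalpy inflow: mass-based, against compartment thermal mass
      rho_up <- if (grepl("^inlet", from)) {
        net$inlets[[as.integer(sub("inlet", "", from))]]$rho
      } else max(rho_comp(up), 1)
      d[8] <- d[8] + Q * rho_up / (rho_i * V) * (up[8] - T_K)
    }
    Q_out <- sum(edges_out$Q)
    d[1:7] <- d[1:7] - Q_out / V * s[1:7]
    d[9:per] <- d[9:per] - Q_out / V * s[9:per]

    ## ---- micromixing ---------------------------------------------------
    mix_solvent_rate <- 0
    if (net$micromixing) {
      xi3 <- env3_mixture_fraction(q3, max(P3, 1e-300))
      src <- micromixing_sources(min(max(P1, 0), 1), min(max(P2, 0), 1),
                                 min(max(P3, 0), 1), as.numeric(xi3),
                                 eps_over_k = net$eps_over_k[i],
                                 phi1 = phi1, phi2 = phi2,
                                 D_t = net$D_t[i], grad_xi3 = 0)
      d[1] <- d[1] + src$dP1
      d[2] <- d[2] + src$dP2
      d[3] <- d[3] + src$dP3
      d[4] <- d[4] + src$dxi3_content
      d[5:7] <- d[5:7] + src$ds3
      mix_solvent_rate <- src$ds3[2] + src$ds3[3]   # solvents into env 3
    }

    ## ---- crystallization in environment 3 ------------------------------
    crys_rate <- 0
    m_solv <- sM + sW
    if (net$kinetics$mode == "constant") {
      # imposed rates (kinetics stubbed, e.g. MSMPR verification)
      B <- net$kinetics$B; G <- net$kinetics$G
      if (G > 0 || B > 0) {
        dfdt <- numeric(n)
        if (G > 0) dfdt <- dfdt + growth_flux_divergence(
          f, G, net$grid, "growth", net$solver$theta)
        dfdt <- dfdt + nucleation_source(P3 * B, net$grid)
        d[9:per] <- d[9:per] + dfdt
      }
    } else if (m_solv > 1e-9 && P3 > 1e-9) {
      C3 <- max(sS, 0) / m_solv
      w3 <- min(max(100 * sW / m_solv, 0), 100)
      S3 <- C3 / solubility(w3, T_K, net$kinetics$branch_mode)
      if (S3 > 1) {
        B <- nucleation_rate(S3)$B
        G <- growth_rate(S3)
        dfdt <- growth_flux_divergence(f, G, net$grid, "growth",
                                       net$solver$theta)
        dfdt <- dfdt + nucleation_source(P3 * B, net$grid)
        d[9:per] <- d[9:per] + dfdt
        crys_rate <- sum(mass_weights(net$grid, const$rho_crystal,
                                      const$k_v) * dfdt)
        d[5] <- d[5] - crys_rate        # solute sink: mass closure
      }
    }

    ## ---- enthalpy source -----------------------------------------------
    if (en$adiabatic) {
      S_h <- mix_solvent_rate * (-en$dH_mix) + crys_rate * (-en$dH_crys)
      d[8] <- d[8] + S_h / (rho_i * en$cp)
    }

    dy[(o + 1):(o + per)] <- d
  }
  list(dy)
}

#' Run a network to a time horizon or to steady state
#'
#' Integrates the coupled compartment ODE system with a stiffness-switching
#' solver (`deSolve::lsoda`).  With `t_end = NULL` the integration proceeds
#' in chunks of one residence time until the maximum relative state change
#' per residence time falls below `steady_tol`, or `max_chunks` is reached.
#'
#' @param net a [build_network()] result.
#' @param t_end fixed horizon in seconds, or `NULL` for steady-state mode.
#' @param steady_tol steady-state declaration tolerance (relative change per
#'   residence time).
#' @param max_chunks maximum number of residence-time chunks.
#' @param y0 optional initial state (defaults to [initial_state()]).
#' @return object of class `crystallizer_run`: list with the final `state`,
#'   `net`, elapsed `time`, `converged` flag, `residual`, negativity `clips`
#'   count, and a `trace` data.frame of per-chunk diagnostics.
#' @export
run_network <- function(net, t_end = NULL, steady_tol = NULL,
                        max_chunks = 400, y0 = NULL) {
  if (is.null(steady_tol)) steady_tol <- net$solver$steady_tol
  y <- if (is.null(y0)) initial_state(net) else y0
  n <- net$grid$n
  per <- .n_scalar + n
  tau <- sum(net$volumes) / net$Q_total
  atol <- rep(c(1e-10, 1e-10, 1e-10, 1e-10, 1e-7, 1e-7, 1e-7, 1e-7,
                rep(1e4, n)), net$n_comp)

  step_to <- function(y, dt) {
    sol <- deSolve::lsoda(y, c(0, dt), reactor_rhs, net,
                          rtol = net$solver$rtol, atol = atol,
                          maxsteps = 50000)
    if (nrow(sol) < 2 || any(!is.finite(sol[nrow(sol), -1]))) {
      stop("integration failure: non-finite state (diagnostics: t = ",
           sol[nrow(sol), 1], ")")
    }
    as.numeric(sol[nrow(sol), -1])
  }

  clips <- 0L
  trace <- list()
  if (!is.null(t_end)) {
    y <- step_to(y, t_end)
    fidx <- as.vector(outer(9:per, (seq_len(net$n_comp) - 1L) * per, `+`))
    clips <- clips + sum(y[fidx] < 0)
    y[fidx] <- pmax(y[fidx], 0)
    res <- NA_real_
    conv <- NA
    t_done <- t_end
  } else {
    t_done <- 0
    conv <- FALSE
    res <- Inf
    for (ch in seq_len(max_chunks)) {
      y_new <- step_to(y, tau)
      fidx <- as.vector(outer(9:per, (seq_len(net$n_comp) - 1L) * per, `+`))
      clips <- clips + sum(y_new[fidx] < 0)
      y_new[fidx] <- pmax(y_new[fidx], 0)
      t_done <- t_done + tau
      # per-type reference scales so near-empty size classes do not dominate
      f_scale <- max(abs(y_new[fidx]), 1)
      scale_ref <- rep(c(rep(1, 4), rep(1e3, 3), 300, rep(f_scale, n)),
                       net$n_comp)
      res <- max(abs(y_new - y) / pmax(abs(y_new), scale_ref))
      trace[[ch]] <- data.frame(t = t_done, residual = res)
      y <- y_new
      if (res < steady_tol) { conv <- TRUE; break }
    }
    if (!conv) {
      warning("steady state not reached: residual ", signif(res, 3),
              " after ", t_done, " s")
    }
  }
  out <- list(state = y, net = net, time = t_done, converged = conv,
              residual = res, clips = clips,
              trace = if (length(trace)) do.call(rbind, trace) else NULL)
  class(out) <- "crystallizer_run"
  out
}

# Extract the state of one compartment as a named list.
compartment_view <- function(run, i = run$net$n_comp) {
  net <- run$net
  per <- .n_scalar + net$grid$n
  s <- run$state[((i - 1L) * per + 1L):(i * per)]
  list(P1 = s[1], P2 = s[2], P3 = s[3],
       xi3 = as.numeric(env3_mixture_fraction(s[4], max(s[3], 1e-300))),
       sS = s[5], sM = s[6], sW = s[7], T_K = s[8],
       f = pmax(s[9:length(s)], 0))
}

# Environment-3 supersaturation of a compartment view.
view_supersaturation <- function(v, net) {
  m_solv <- v$sM + v$sW
  if (m_solv <= 1e-12) return(0)
  C3 <- max(v$sS, 0) / m_solv
  w3 <- min(max(100 * v$sW / m_solv, 0), 100)
  C3 / solubility(w3, v$T_K, net$kinetics$branch_mode)
}

#' Outlet summary of a crystallizer run
#'
#' Condenses a run into the quantities reported for crystallizer operating
#' studies: number- and mass-weighted mean crystal size and standard
#' deviation at the outlet (um), outlet crystal mass flow (mg/s),
#' volume-weighted network averages of the supersaturation ratio and of the
#' nucleation and growth rates, and the outlet temperature.
#'
#' @param run a [run_network()] result.
#' @return one-row data.frame.
#' @export
outlet_summary <- function(run) {
  net <- run$net
  out_comp <- net$n_comp
  v <- compartment_view(run, out_comp)
  cs <- csd_summary(v$f, net$grid, net$const$rho_crystal, net$const$k_v)
  Q_out <- sum(net$flows$Q[net$flows$to == "out"])

  wS <- wB <- wG <- 0
  for (i in seq_len(net$n_comp)) {
    vi <- compartment_view(run, i)
    S <- view_supersaturation(vi, net)
    if (net$kinetics$mode == "constant") {
      B <- net$kinetics$B; G <- net$kinetics$G
    } else {
      B <- nucleation_rate(S)$B; G <- growth_rate(S)
    }
    w <- net$volumes[i] / sum(net$volumes)
    wS <- wS + w * S; wB <- wB + w * B; wG <- wG + w * G
  }

  data.frame(
    mean_num_um = cs$mean_num * 1e6, sd_num_um = cs$sd_num * 1e6,
    mean_mass_um = cs$mean_mass * 1e6, sd_mass_um = cs$sd_mass * 1e6,
    total_number_per_m3 = cs$total_number,
    total_mass_kg_per_m3 = cs$total_mass,
    outlet_mass_flow_mg_s = Q_out * cs$total_mass * 1e6,
    avg_S = wS, avg_B = wB, avg_G = wG,
    outlet_T_K = v$T_K, P3_outlet = v$P3,
    converged = run$converged
  )
}

#' Sweep an operating parameter across values
#'
#' Repeats a steady-state run per value of one operating parameter and
#' collects [outlet_summary()] rows, mirroring operating-condition study
#' tables.  Parameters: `inlet_supersaturation` (solution-stream S),
#' `inlet_velocity` (both inlets, m/s), `ms_ma_ratio` (solution mass flow as
#' a multiple of the fixed anti-solvent mass flow), `n_classes`, `dr` (um).
#' Individual run failures are recorded (`error` column) and the sweep
#' continues.
#'
#' @param config base run configuration.
#' @param param one of the names above.
#' @param values numeric vector of parameter values.
#' @return data.frame with one row per value.
#' @export
parameter_sweep <- function(config, param, values) {
  param <- match.arg(param, c("inlet_supersaturation", "inlet_velocity",
                              "ms_ma_ratio", "n_classes", "dr"))
  rows <- lapply(values, function(val) {
    res <- tryCatch({
      cfg <- resolve_config(config)
      cfg <- apply_sweep_value(cfg, param, val)
      run <- run_network(build_network(cfg))
      cbind(data.frame(param = param, value = val), outlet_summary(run),
            data.frame(error = NA_character_))
    }, error = function(e) {
      data.frame(param = param, value = val, mean_num_um = NA, sd_num_um = NA,
                 mean_mass_um = NA, sd_mass_um = NA,
                 total_number_per_m3 = NA, total_mass_kg_per_m3 = NA,
                 outlet_mass_flow_mg_s = NA, avg_S = NA, avg_B = NA,
                 avg_G = NA, outlet_T_K = NA, P3_outlet = NA,
                 converged = NA, error = conditionMessage(e))
    })
    res
  })
  do.call(rbind, rows)
}

apply_sweep_value <- function(cfg, param, val) {
  if (param == "inlet_supersaturation") {
    for (k in seq_along(cfg$inlets)) {
      if (identical(cfg$inlets[[k]]$env, 1)) cfg$inlets[[k]]$S_inlet <- val
    }
  } else if (param == "inlet_velocity") {
    for (k in seq_along(cfg$inlets)) {
      cfg$inlets[[k]]$velocity <- val
      cfg$inlets[[k]]$mass_flow <- NULL
    }
  } else if (param == "ms_ma_ratio") {
    ma <- NULL
    for (k in seq_along(cfg$inlets)) {
      if (identical(cfg$inlets[[k]]$env, 2)) {
        if (is.null(cfg$inlets[[k]]$mass_flow)) {
          stop("ms_ma_ratio sweep needs a mass_flow-defined anti-solvent inlet")
        }
        ma <- cfg$inlets[[k]]$mass_flow
      }
    }
    for (k in seq_along(cfg$inlets)) {
      if (identical(cfg$inlets[[k]]$env, 1)) {
        cfg$inlets[[k]]$mass_flow <- val * ma
        cfg$inlets[[k]]$velocity <- NULL
      }
    }
  } else if (param == "n_classes") {
    cfg$grid$n_classes <- as.integer(val)
  } else if (param == "dr") {
    span <- cfg$grid$r_max - cfg$grid$r_min
    cfg$grid$n_classes <- as.integer(round(span / (val * 1e-6)))
  }
  cfg
}
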