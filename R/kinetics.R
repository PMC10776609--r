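#' Physical constants for the lovastatin / methanol / water system
#'
#' Returns the fixed physical properties used throughout the simulator.
#' Densities and kinematic viscosities are for the pure components at the
#' operating temperature; `rho_crystal` is the lovastatin crystal density.
#' `k_v` is the volume shape factor relating crystal volume to the cube of
#' the characteristic size (default `pi/6`, volume-equivalent spheres).
#' `dH_mix` (J per kg of solvents mixed into the crystallizing environment)
#' and `dH_crys` (J per kg of crystal formed) are negative for exothermic
#' processes; `dH_mix` is calibrated, not measured (see the package
#' vignette), `cp` is a representative methanol/water mixture specific heat.
#'
#' @param ... named overrides for any constant (e.g. `k_v = 0.5`).
#' @return A named list of constants.
#' @examples
#' physical_constants()$rho_crystal
#' physical_constants(k_v = 1)$k_v
#' @export
physical_constants <- function(...) {
  const <- list(
    rho_water    = 997.1,    # kg/m^3
    rho_methanol = 782,      # kg/m^3
    rho_crystal  = 1273,     # kg/m^3
    nu_water     = 8.976e-7, # m^2/s
    nu_methanol  = 6.87e-7,  # m^2/s
    T_ref        = 296,      # K, reference for the solubility correlation
    k_v          = pi / 6,   # volume shape factor
    dH_mix       = -3.9e4,   # J/kg solvents mixed (calibrated, ~+10 K rise)
    dH_crys      = -30,      # J/kg crystal (small for lovastatin)
    cp           = 3400      # J/(kg K), methanol/water mixture
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(const))
    if (length(bad)) {
      stop("unknown physical constant(s): ", paste(bad, collapse = ", "))
    }
    const[names(over)] <- over
  }
  const
}

#' Solubility of lovastatin in methanol/water mixtures
#'
#' Closed-form solubility correlation in kg of lovastatin per kg of solvents
#' (methanol + water), as a function of the anti-solvent (water) weight
#' percent on a solute-free basis and temperature.  The correlation is a
#' temperature factor `0.001 * exp(15.45763 * (1 - 1/theta))` with
#' `theta = T/296`, multiplying a composition polynomial: a cubic in `w_as`
#' below 45.67 wt% water and a linear form above.
#'
#' As printed, the upper linear branch (`1.7884 w + 1.7888`) is
#' discontinuous with the cubic by a factor of ~85 at the boundary; with the
#' slope read as `-1.7884e-2` the two branches agree to 0.034%, which
#' strongly suggests a sign/exponent misprint.  `branch_mode =
#' "continuity_restored"` (default) uses the continuous form;
#' `"as_printed"` reproduces the literal coefficients.
#'
#' @param w_as anti-solvent (water) weight percent of the solvent blend,
#'   0--100.
#' @param T_K temperature in kelvin.
#' @param branch_mode `"continuity_restored"` (default) or `"as_printed"`.
#' @return Solubility in kg lovastatin per kg solvents (vectorized).
#' @examples
#' solubility(0, 296)         # 0.033089
#' solubility(50, 298.15)     # water-rich branch
#' @export
solubility <- function(w_as, T_K,
                       branch_mode = c("continuity_restored", "as_printed")) {
  branch_mode <- match.arg(branch_mode)
  if (any(!is.finite(w_as)) || any(w_as < 0) || any(w_as > 100)) {
    stop("w_as must be within [0, 100]")
  }
  if (any(!is.finite(T_K)) || any(T_K <= 0)) {
    stop("T_K must be positive")
  }
  theta <- T_K / 296
  tfac <- 0.001 * exp(15.45763 * (1 - 1 / theta))
  poly_lo <- -2.7455e-4 * w_as^3 + 3.3716e-2 * w_as^2 - 1.6704 * w_as + 33.089
  slope_hi <- if (branch_mode == "as_printed") 1.7884 else -1.7884e-2
  poly_hi <- slope_hi * w_as + 1.7888
  poly <- ifelse(w_as <= 45.67, poly_lo, poly_hi)
  tfac * poly
}

#' Mixture state: concentration, composition, solubility, supersaturation
#'
#' Builds a `mixture_state` from the solute concentration (kg lovastatin per
#' kg solvents), the anti-solvent weight percent and temperature, filling in
#' the local solubility `C_star` and the supersaturation ratio `S = C /
#' C_star` that drives nucleation and growth.
#'
#' @inheritParams solubility
#' @param C solute concentration, kg lovastatin / kg solvents, `>= 0`.
#' @return An object of class `mixture_state`: list with fields `C`, `w_as`,
#'   `T_K`, `C_star`, `S`.
#' @examples
#' st <- supersaturation(C = 0.3255, w_as = 0, T_K = 298.15)
#' st$S   # ~8.8
#' @export
supersaturation <- function(C, w_as, T_K,
                            branch_mode = c("continuity_restored",
                                            "as_printed")) {
  if (any(!is.finite(C)) || any(C < 0)) stop("C must be non-negative")
  C_star <- solubility(w_as, T_K, branch_mode)
  st <- list(C = C, w_as = w_as, T_K = T_K, C_star = C_star, S = C / C_star)
  class(st) <- "mixture_state"
  st
}

#' @export
print.mixture_state <- function(x, ...) {
  cat(sprintf(
    "mixture_state: C = %.5g kg/kg, w_as = %.4g %%, T = %.2f K\n",
    x$C[1], x$w_as[1], x$T_K[1]))
  cat(sprintf("  C* = %.5g kg/kg, S = %.4g\n", x$C_star[1], x$S[1]))
  invisible(x)
}

#' Primary nucleation rate of lovastatin
#'
#' Total primary nucleation rate `B = B_hom + B_het` in number per m^3 of
#' suspension per second, from the 23 degC correlations
#' `B_hom = 6.97e14 exp(-15.8 / (ln S)^2)` and
#' `B_het = 2.18e8 exp(-0.994 / (ln S)^2)`.  Both rates tend to zero as
#' `S -> 1+`; for `S <= 1` the rates are zero (their limiting value), since
#' a non-positive `ln S` is unphysical for primary nucleation.
#'
#' @param S supersaturation ratio, `>= 0` (vectorized).
#' @return data.frame with columns `B_hom`, `B_het`, `B` in 1/(m^3 s).
#' @examples
#' nucleation_rate(exp(1))   # B_hom ~ 9.56e7
#' nucleation_rate(1)$B      # 0
#' @export
nucleation_rate <- function(S) {
  if (any(!is.finite(S)) || any(S < 0)) stop("S must be non-negative")
  lnS2 <- ifelse(S > 1, log(S)^2, NA_real_)
  B_hom <- ifelse(S > 1, 6.97e14 * exp(-15.8 / lnS2), 0)
  B_het <- ifelse(S > 1, 2.18e8 * exp(-0.994 / lnS2), 0)
  data.frame(B_hom = B_hom, B_het = B_het, B = B_hom + B_het)
}

#' Crystal growth rate of lovastatin
#'
#' Linear (size-independent) growth rate at 23 degC,
#' `G = 8.33e-30 * (2.46e3 * ln S)^6.7` m/s for `S > 1`, zero otherwise.
#'
#' @inheritParams nucleation_rate
#' @return Growth rate in m/s (vectorized).
#' @examples
#' growth_rate(exp(1))   # ~4.36e-7 m/s
#' @export
growth_rate <- function(S) {
  if (any(!is.finite(S)) || any(S < 0)) stop("S must be non-negative")
  ifelse(S > 1, 8.33e-30 * (2.46e3 * log(S))^6.7, 0)
}

#' Combined kinetic rates at a supersaturation ratio
#'
#' @inheritParams nucleation_rate
#' @return data.frame with columns `B_hom`, `B_het`, `B` (1/(m^3 s)) and
#'   `G` (m/s).
#' @export
kinetic_rates <- function(S) {
  out <- nucleation_rate(S)
  out$G <- growth_rate(S)
  out
}

#' Density of a lovastatin/methanol/water liquid mixture
#'
#' Ideal-volume mixing of the pure components: 1 kg of solvents (split by
#' `w_as`) carrying `C` kg of dissolved lovastatin, whose partial volume is
#' taken at the crystal density.
#'
#' @inheritParams supersaturation
#' @param const physical constants, see [physical_constants()].
#' @return density, kg/m^3.
#' @export
mixture_density <- function(C, w_as, const = physical_constants()) {
  w <- w_as / 100
  mass <- 1 + C
  vol <- (1 - w) / const$rho_methanol + w / const$rho_water +
    C / const$rho_crystal
  mass / vol
}

#' Blend two feed streams into a single mixture state
#'
#' Mass-conserving blend of two streams, each given as a list with fields
#' `mdot` (total mass flow, kg/s), `C` (kg solute / kg solvents), `w_as`
#' (anti-solvent weight percent) and `T_K`.  The blended `w_as` is computed
#' on a solute-free solvents basis, `C` on the combined-solvents basis, and
#' temperature as the mass-weighted average (equal specific heats).
#'
#' @param stream_a,stream_b lists with fields `mdot`, `C`, `w_as`, `T_K`.
#' @return list with the blended `C`, `w_as`, `T_K`, the `mixture_state`
#'   (`state`), and mass flows `mdot` (total) and `mdot_solvents` (kg/s).
#' @examples
#' sol <- list(mdot = 1e-3, C = 0.3255, w_as = 0, T_K = 298.15)
#' water <- list(mdot = 0.754e-3, C = 0, w_as = 100, T_K = 298.15)
#' mix_streams(sol, water)$w_as
#' @export
mix_streams <- function(stream_a, stream_b) {
  chk <- function(s, nm) {
    need <- c("mdot", "C", "w_as", "T_K")
    if (!all(need %in% names(s))) {
      stop(nm, " must have fields ", paste(need, collapse = ", "))
    }
    if (s$mdot < 0) stop(nm, "$mdot must be >= 0")
  }
  chk(stream_a, "stream_a"); chk(stream_b, "stream_b")
  if (stream_a$mdot == 0 && stream_b$mdot == 0) {
    stop("at least one stream must have positive mass flow")
  }
  # per-stream solvent / solute / water mass flows
  part <- function(s) {
    msolv <- s$mdot / (1 + s$C)         # solvents kg/s
    c(solv = msolv, solute = msolv * s$C, water = msolv * s$w_as / 100)
  }
  pa <- part(stream_a); pb <- part(stream_b)
  solv <- pa["solv"] + pb["solv"]
  solute <- pa["solute"] + pb["solute"]
  water <- pa["water"] + pb["water"]
  C <- as.numeric(solute / solv)
  w_as <- as.numeric(100 * water / solv)
  T_K <- (stream_a$mdot * stream_a$T_K + stream_b$mdot * stream_b$T_K) /
    (stream_a$mdot + stream_b$mdot)
  list(C = C, w_as = w_as, T_K = T_K,
       state = supersaturation(C, w_as, T_K),
       mdot = stream_a$mdot + stream_b$mdot,
       mdot_solvents = as.numeric(solv))
}

#' Feed concentration realizing a target inlet supersaturation
#'
#' Concentration `C = S * C_star(w_as, T)` for a feed stream defined by its
#' supersaturation ratio relative to the solubility at its own composition
#' and temperature.
#'
#' @param S_inlet target supersaturation ratio of the stream.
#' @inheritParams solubility
#' @return concentration kg solute / kg solvents.
#' @export
feed_concentration <- function(S_inlet, w_as = 0, T_K = 298.15) {
  if (S_inlet < 0) stop("S_inlet must be >= 0")
  S_inlet * solubility(w_as, T_K)
}
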