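#' Three-environment micromixing state
#'
#' Validates and assembles the state of the presumed-PDF micromixing model:
#' environment probabilities `P1` (pure solution feed), `P2` (pure
#' anti-solvent) and `P3` (mixed, where crystallization occurs), the
#' environment-3 weighted composition vector `s3` (species concentration
#' times probability), and the environment-3 mixture fraction `xi3`
#' (conserved scalar equal to 1 in the solution feed, 0 in the
#' anti-solvent).
#'
#' @param P1,P2,P3 environment probabilities; must sum to 1 within 1e-12.
#' @param xi3 mixture fraction of environment 3, in `[0, 1]`.
#' @param s3 named numeric vector of weighted species concentrations.
#' @param phi1,phi2 fixed species concentrations of environments 1 and 2.
#' @return object of class `environment_state`.
#' @export
environment_state <- function(P1, P2, P3 = 1 - P1 - P2, xi3 = 0.5,
                              s3 = numeric(0), phi1 = numeric(0),
                              phi2 = numeric(0)) {
  P <- c(P1, P2, P3)
  if (any(P < -1e-12) || any(P > 1 + 1e-12)) {
    stop("probabilities must be in [0, 1]")
  }
  if (abs(sum(P) - 1) > 1e-12) stop("P1 + P2 + P3 must equal 1")
  if (xi3 < 0 || xi3 > 1) stop("xi3 must be in [0, 1]")
  st <- list(P1 = P1, P2 = P2, P3 = P3, xi3 = xi3,
             s3 = s3, phi1 = phi1, phi2 = phi2)
  class(st) <- "environment_state"
  st
}

#' Mixture-fraction variance of the three-environment PDF
#'
#' `<xi'^2> = P1 (1 - P1) - 2 P1 P3 <xi>3 + P3 (1 - P3) <xi>3^2`, the
#' sub-grid variance of the conserved mixing scalar implied by the
#' three-delta PDF (environment 1 at `xi = 1`, environment 2 at `xi = 0`).
#'
#' @param P1,P3 environment probabilities.
#' @param xi3 environment-3 mixture fraction.
#' @return variance `<xi'^2>` (clamped at 0 against roundoff).
#' @examples
#' mixture_fraction_variance(0.25, 0.5, 0.5)  # 0.125
#' @export
mixture_fraction_variance <- function(P1, P3, xi3) {
  v <- P1 * (1 - P1) - 2 * P1 * P3 * xi3 + P3 * (1 - P3) * xi3^2
  pmax(v, 0)
}

#' Scalar dissipation rate
#'
#' `eps_xi = C_phi <xi'^2> eps / k` with `C_phi = 2`: the decay rate of
#' mixture-fraction variance for a fully developed scalar spectrum, driven
#' by the turbulence frequency `eps / k`.
#'
#' @param xi_var mixture-fraction variance.
#' @param eps_over_k turbulence frequency `eps / k`, 1/s (`k > 0`).
#' @param C_phi mixing-model constant (default 2).
#' @return scalar dissipation rate, 1/s.
#' @export
scalar_dissipation <- function(xi_var, eps_over_k, C_phi = 2) {
  if (any(eps_over_k < 0)) stop("eps/k must be >= 0 (k > 0)")
  C_phi * xi_var * eps_over_k
}

#' Micromixing source terms of the three-environment model
#'
#' Engulfment sources for the probabilities and the environment-3 weighted
#' composition, plus the spurious-dissipation corrections that matter only
#' where resolved mixture-fraction gradients exist:
#' \describe{
#'   \item{probabilities}{`G(P1) = -gamma P1 (1 - P1)`, `G(P2) = -gamma P2
#'     (1 - P2)`, `G(P3) = gamma (P1 (1 - P1) + P2 (1 - P2))`, with
#'     corrections `(+gamma_s P3, +gamma_s P3, -2 gamma_s P3)`.}
#'   \item{weighted composition}{`M(s3) = gamma (P1 (1 - P1) phi1 + P2 (1 -
#'     P2) phi2)` and `M_s(s3) = -gamma_s P3 (phi1 + phi2)`.}
#' }
#' where `gamma = eps_xi / (P1 (1 - P1)(1 - xi3^2) + P2 (1 - P2) xi3^2)`
#' and `gamma_s = 2 D_t / ((1 - xi3)^2 + xi3^2) * |grad xi3|^2`.  When the
#' `gamma` denominator vanishes (nothing left to engulf) all sources are
#' zero.  The sources conserve probability and the species means exactly.
#'
#' @param P1,P2,P3 environment probabilities.
#' @param xi3 environment-3 mixture fraction.
#' @param eps_over_k turbulence frequency, 1/s.
#' @param phi1,phi2 species concentrations of environments 1 and 2 (same
#'   length).
#' @param D_t turbulent diffusivity, m^2/s.
#' @param grad_xi3 magnitude of the resolved `xi3` gradient, 1/m (0 in
#'   well-mixed compartments).
#' @return list with `dP1`, `dP2`, `dP3` (1/s), `ds3` (per-species rates),
#'   `dxi3_content` (rate of the transported `P3 * xi3` scalar), `gamma`,
#'   `gamma_s`.
#' @examples
#' micromixing_sources(0.25, 0.25, 0.5, xi3 = 0.5, eps_over_k = 1,
#'                     phi1 = 1, phi2 = 0)
#' @export
micromixing_sources <- function(P1, P2, P3, xi3, eps_over_k,
                                phi1 = numeric(0), phi2 = numeric(0),
                                D_t = 0, grad_xi3 = 0) {
  if (length(phi1) != length(phi2)) {
    stop("phi1 and phi2 must have the same length")
  }
  a1 <- P1 * (1 - P1)
  a2 <- P2 * (1 - P2)
  denom <- a1 * (1 - xi3^2) + a2 * xi3^2
  if (denom < 0) stop("invalid state: negative gamma denominator")
  zero <- list(dP1 = 0, dP2 = 0, dP3 = 0,
               ds3 = numeric(length(phi1)),
               dxi3_content = 0, gamma = 0, gamma_s = 0)
  if (denom < 1e-14) return(zero)
  xi_var <- mixture_fraction_variance(P1, P3, xi3)
  eps_xi <- scalar_dissipation(xi_var, eps_over_k)
  gamma <- eps_xi / denom
  gamma_s <- 2 * D_t / ((1 - xi3)^2 + xi3^2) * grad_xi3^2
  list(
    dP1 = -gamma * a1 + gamma_s * P3,
    dP2 = -gamma * a2 + gamma_s * P3,
    dP3 = gamma * (a1 + a2) - 2 * gamma_s * P3,
    ds3 = gamma * (a1 * phi1 + a2 * phi2) - gamma_s * P3 * (phi1 + phi2),
    # the transported scalar P3*xi3 engulfs xi = 1 from env 1, 0 from env 2
    dxi3_content = gamma * a1 * 1 - gamma_s * P3 * (1 + 0),
    gamma = gamma, gamma_s = gamma_s
  )
}

#' Mean species composition of the three-environment mixture
#'
#' `Phi = P1 phi1 + P2 phi2 + s3`: the Favre-mean species concentrations
#' obtained by summing the weighted compositions of all environments
#' (environments 1 and 2 carry fixed feed compositions).
#'
#' @inheritParams micromixing_sources
#' @param s3 weighted composition of environment 3.
#' @return mean composition vector.
#' @export
mean_composition <- function(P1, P2, s3, phi1, phi2) {
  P1 * phi1 + P2 * phi2 + s3
}

#' Environment-3 mixture fraction from its transported content
#'
#' `xi3 = (P3 * xi3 content) / P3`, clamped to `[0, 1]`.  When `P3 = 0`
#' there is no mixed fluid and the value is undefined; a flagged default of
#' 0.5 is returned (attribute `undefined = TRUE`).
#'
#' @param xi3_content transported scalar `P3 * xi3`.
#' @param P3 mixed-environment probability.
#' @return `xi3` in `[0, 1]`.
#' @export
env3_mixture_fraction <- function(xi3_content, P3) {
  if (P3 <= 0) {
    out <- 0.5
    attr(out, "undefined") <- TRUE
    return(out)
  }
  min(max(xi3_content / P3, 0), 1)
}
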