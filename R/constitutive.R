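# Pointwise material laws: kinematics, hyperelastic stress, tube-law pore
# pressure, porosity penalization, permeability pull-back.

#' Material parameters of the poroelastic medium
#'
#' Collects the constitutive constants in one validated object. `G`, `q1`
#' and `q2` are quoted in kPa at the interface and stored in Pa. The
#' tube-law constants default to the coronary-vessel values
#' `q1 = 0.022 kPa`, `q2 = 1.009 kPa`, `q3 = 80`; the penalization scale
#' `c` keeps porosity above `phi_crit` (the arctangent penalization has
#' slowly decaying tails, so `c` must remain small compared to the driving
#' pressures or it biases the pore pressure at the reference state --
#' hence the 1 Pa default). `eps = 0.001` and `phi_crit = 1e-5` are chosen
#' for solver robustness.
#'
#' @param G skeleton shear modulus, kPa.
#' @param q1,q2 tube-law constants, kPa.
#' @param q3 tube-law exponent, dimensionless.
#' @param c_pen penalization reference pressure, Pa.
#' @param eps penalization width, dimensionless.
#' @param phi_crit critical porosity floor, dimensionless.
#' @param mu blood viscosity, Pa s.
#' @param alpha pressure stabilization parameter (stable range 0.1-0.3).
#' @param phi0_min floor applied to reference porosities entering the
#'   tube law, so elements without vessels still carry a background
#'   microvascular porosity.
#' @return a `material_params` list, pressures in Pa.
#' @export
material_params <- function(G = 5, q1 = 0.022, q2 = 1.009, q3 = 80,
                            c_pen = 1, eps = 0.001, phi_crit = 1e-5,
                            mu = 0.004, alpha = 0.2, phi0_min = 1e-3) {
  stopifnot(G > 0, q3 > 0, eps > 0, eps < 1, phi_crit >= 0,
            mu > 0, alpha >= 0, phi0_min > phi_crit)
  structure(list(
    G = kpa_to_pa(G), q1 = kpa_to_pa(q1), q2 = kpa_to_pa(q2), q3 = q3,
    c_pen = c_pen, eps = eps, phi_crit = phi_crit, mu = mu, alpha = alpha,
    phi0_min = phi0_min
  ), class = "material_params")
}

#' Finite-strain kinematics from a displacement gradient
#'
#' Builds the deformation gradient `F = I + grad_u` and its derived
#' measures: `J = det F`, right Cauchy-Green tensor `C = F^T F`, the
#' distortional tensor `C_bar = J^(-2/3) C` (unit determinant by
#' construction) and its first invariant `I1_bar = tr C_bar`.
#'
#' @param grad_u 3 x 3 displacement gradient (d u_i / d X_j).
#' @return a `kinematics` list with fields `F`, `J`, `C`, `C_bar`,
#'   `I1_bar`.
#' @examples
#' kin <- kinematics_from_grad(diag(c(1, 0, 0)))  # uniaxial stretch to 2
#' kin$J       # 2
#' kin$I1_bar  # 2^(-2/3) * 6
#' @export
kinematics_from_grad <- function(grad_u) {
  F <- diag(3) + grad_u
  J <- det(F)
  if (J <= 0) stop("non-positive Jacobian determinant (J = ", format(J), ")")
  C <- t(F) %*% F
  C_bar <- J^(-2 / 3) * C
  structure(list(F = F, J = J, C = C, C_bar = C_bar,
                 I1_bar = sum(diag(C_bar))), class = "kinematics")
}

# --- tube-law pore fluid energy ---------------------------------------------
#
# v = m_star + phi0 is the current pore volume fraction (per unit reference
# volume). The pore-volume energy U_PV and penalization energy U_c are
#
#   U_PV(m) = (q1/q3) e^{q3 v} - q1 e^{q3 phi0} m
#             + q2 (v log(v/phi0) - v) + const,     U_PV(0) = 0
#   U_c(m)  = c * atan((v - phi_crit) / eps)
#
# whose m-derivatives give the pore pressure contributions
#
#   p_PV = q1 (e^{q3 v} - e^{q3 phi0}) + q2 log(v / phi0)
#   p_c  = c * eps / (eps^2 + (v - phi_crit)^2)
#
# p_PV vanishes at the reference state; p_c is a soft barrier that grows
# to c/eps as v approaches phi_crit from above.

# Below v_ext = phi_crit the logarithmic tube law is extended linearly in
# m (C1 continuous): a floating-point guard so that assembly is defined
# for any trial state. Above phi_crit the true law applies, whose log term
# saturates the pore volume just above zero under strong suction, keeping
# m* > -(phi0 + O(phi_crit)).
pore_v_ext <- function(phi0, pm) pmax(pm$phi_crit, 1e-12) + 0 * phi0

# vectorized energies/pressures; phi0 already floored by the caller
pore_energy_pv <- function(m_star, phi0, pm) {
  v <- m_star + phi0
  vm <- pore_v_ext(phi0, pm)
  vv <- pmax(v, vm)
  U <- (pm$q1 / pm$q3) * exp(pm$q3 * vv) -
    pm$q1 * exp(pm$q3 * phi0) * (vv - phi0) +
    pm$q2 * (vv * log(vv / phi0) - vv) -
    ((pm$q1 / pm$q3) * exp(pm$q3 * phi0) - pm$q2 * phi0)
  low <- v < vm
  if (any(low)) {
    p_vm <- pm$q1 * (exp(pm$q3 * vm) - exp(pm$q3 * phi0)) + pm$q2 * log(vm / phi0)
    dp_vm <- pm$q1 * pm$q3 * exp(pm$q3 * vm) + pm$q2 / vm
    dv <- (v - vm)[low]
    U[low] <- U[low] + p_vm[low] * dv + 0.5 * dp_vm[low] * dv^2
  }
  U
}

pore_energy_c <- function(m_star, phi0, pm) {
  v <- m_star + phi0
  pm$c_pen * atan((v - pm$phi_crit) / pm$eps)
}

# p_PV, p_c and derivatives w.r.t. m_star, vectorized
pore_pressure_terms <- function(m_star, phi0, pm) {
  v <- m_star + phi0
  vm <- pore_v_ext(phi0, pm)
  vv <- pmax(v, vm)
  e_v <- exp(pm$q3 * vv)
  p_pv <- pm$q1 * (e_v - exp(pm$q3 * phi0)) + pm$q2 * log(vv / phi0)
  dpv <- pm$q1 * pm$q3 * e_v + pm$q2 / vv
  d2pv <- pm$q1 * pm$q3^2 * e_v - pm$q2 / vv^2
  low <- v < vm
  if (any(low)) {
    p_pv[low] <- p_pv[low] + dpv[low] * (v - vv)[low]
    d2pv[low] <- 0
  }
  d <- v - pm$phi_crit
  den <- pm$eps^2 + d^2
  p_c <- pm$c_pen * pm$eps / den
  dp_dm <- dpv - 2 * pm$c_pen * pm$eps * d / den^2
  d2p_dm2 <- d2pv - 2 * pm$c_pen * pm$eps * (pm$eps^2 - 3 * d^2) / den^3
  list(p_pv = p_pv, p_c = p_c, dp_dm = dp_dm, d2p_dm2 = d2p_dm2)
}

#' Pore-fluid pressure contributions from the tube law
#'
#' Evaluates the two constitutive pore-pressure contributions and their
#' derivative at a state `(m_star, phi0)`: the tube-law (pore-volume) part
#' `p_PV = q1 (e^(q3 v) - e^(q3 phi0)) + q2 log(v / phi0)` with
#' `v = m_star + phi0`, which vanishes at the reference state, and the
#' porosity penalization `p_c = c eps / (eps^2 + (v - phi_crit)^2)`. The
#' total pore pressure of a compartment is `p + p_PV + p_c`, where `p` is
#' the skeleton pressure. Both closed forms are exact derivatives of the
#' corresponding free-energy terms (verified by finite differences in the
#' test suite).
#'
#' @param m_star added pore fluid volume per unit reference volume.
#' @param phi0 reference porosity of the compartment.
#' @param params a [material_params()].
#' @param p skeleton pressure, Pa (optional; enters only the total).
#' @return a `pore_pressure` list: `p_PV`, `p_c`, `dp_dm`
#'   (`d(p_PV + p_c)/dm*`), and `p_pore = p + p_PV + p_c` (Pa).
#' @examples
#' pp <- pore_fluid_pressure(0.001, 0.01, material_params())
#' pp$p_PV
#' @export
pore_fluid_pressure <- function(m_star, phi0, params, p = 0) {
  stopifnot(inherits(params, "material_params"))
  phi0 <- pmax(phi0, params$phi0_min)
  if (any(m_star + phi0 <= 0))
    stop("non-positive pore volume fraction (m* + phi0 <= 0)")
  tr <- pore_pressure_terms(m_star, phi0, params)
  structure(list(
    p_PV = tr$p_pv, p_c = tr$p_c, dp_dm = tr$dp_dm,
    p_pore = p + tr$p_pv + tr$p_c
  ), class = "pore_pressure")
}

#' Second Piola-Kirchhoff stress of the poroelastic skeleton
#'
#' Isochoric neo-Hookean stress plus the skeleton-pressure term:
#' `S = G (J^(-2/3) I - (I1_bar / 3) C^(-1)) - p J C^(-1)`,
#' which is `2 dPsi/dC` for the free energy
#' `W = G/2 (I1_bar - 3) - p (J - 1 - sum m_i*)`.
#'
#' @param kin a [kinematics_from_grad()] object.
#' @param p skeleton pressure, Pa.
#' @param G shear modulus, Pa (note: Pa here, not kPa -- pass
#'   `material_params()$G`).
#' @return 3 x 3 symmetric stress tensor, Pa.
#' @export
pk2_stress <- function(kin, p, G) {
  stopifnot(inherits(kin, "kinematics"))
  Cinv <- solve(kin$C)
  G * (kin$J^(-2 / 3) * diag(3) - (kin$I1_bar / 3) * Cinv) - p * kin$J * Cinv
}

#' Pull back a permeability tensor to the reference configuration
#'
#' The Lagrangian permeability is `K00 = J F^(-1) K0 F^(-T)`; the added
#' mass dependent permeability is `K0m = K00 * dp_dm`, where `dp_dm` is
#' the derivative of the constitutive pore pressure with respect to the
#' added pore volume. Symmetry is preserved exactly and positive
#' semi-definiteness follows from that of `K0`.
#'
#' @param K0 3 x 3 symmetric PSD permeability tensor, mm^2/(Pa s).
#' @param kin a [kinematics_from_grad()] object.
#' @param dp_dm scalar `d(p_PV + p_c)/dm*`, Pa.
#' @return list with `K00` and `K0m`.
#' @export
pull_back_permeability <- function(K0, kin, dp_dm = 1) {
  stopifnot(inherits(kin, "kinematics"))
  Finv <- solve(kin$F)
  K00 <- kin$J * Finv %*% K0 %*% t(Finv)
  K00 <- (K00 + t(K00)) / 2   # exact symmetrization against round-off
  list(K00 = K00, K0m = K00 * dp_dm)
}
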