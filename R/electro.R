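# Electrokinetic side-calculations: Debye screening length, Debye-Huckel
# zeta-to-charge conversion for a sphere, surface charge density in e/um^2,
# and the theoretical S_T ~ sigma^2 lambda scaling between two conditions.

#' Electrolyte state
#'
#' @param ionic_strength Ionic strength I, mol/m^3 (1 mM of a 1:1 salt =
#'   1 mol/m^3).
#' @param temperature Absolute temperature, K.
#' @param relative_permittivity Relative permittivity of the solvent
#'   (default 78.5, water near 298 K).
#' @return Object of class `electrolyte_state`.
#' @export
electrolyte_state <- function(ionic_strength, temperature = 298.15,
                              relative_permittivity = 78.5) {
  check_that(ionic_strength >= 0, "ionic_strength must be >= 0 (mol/m^3)")
  check_that(temperature > 0, "temperature must be > 0 (K)")
  check_that(relative_permittivity > 0, "relative_permittivity must be > 0")
  structure(
    list(ionic_strength = ionic_strength, temperature = temperature,
         relative_permittivity = relative_permittivity),
    class = "electrolyte_state"
  )
}

#' Debye screening length
#'
#' `lambda = sqrt(eps0 eps_r kB T / (2 NA e^2 I))` with I in mol/m^3; the
#' inverse-square-root dependence on ionic strength means higher salt gives
#' a shorter screening length.
#'
#' @param state An [electrolyte_state()] with `ionic_strength > 0`.
#' @return Debye length, m.
#' @export
#' @examples
#' debye_length(electrolyte_state(1, 298, 78.5))   # ~9.6 nm at 1 mM
debye_length <- function(state) {
  check_that(inherits(state, "electrolyte_state"), "state must be an electrolyte_state")
  if (state$ionic_strength <= 0) {
    stop_soret("ionic_strength is zero: the screening length is infinite; supply I > 0")
  }
  sqrt(.const$eps0 * state$relative_permittivity * .const$kB * state$temperature /
         (2 * .const$NA_ * .const$e^2 * state$ionic_strength))
}

#' Total surface charge from the zeta potential (Debye-Huckel sphere)
#'
#' `Q = 4 pi eps0 eps_r R (1 + kappa R) zeta`, converted to elementary
#' charges. Valid in the moderate-potential (Debye-Huckel) regime; a warning
#' is issued above 50 mV.
#'
#' @param zeta Zeta potential, V.
#' @param radius_R Particle radius, m.
#' @param state An [electrolyte_state()].
#' @return Total charge in elementary charges (signed).
#' @export
charge_from_zeta <- function(zeta, radius_R, state) {
  check_that(radius_R > 0, "radius_R must be > 0 (m)")
  check_that(inherits(state, "electrolyte_state"), "state must be an electrolyte_state")
  if (abs(zeta) > 0.05) {
    warning(sprintf(paste0("|zeta| = %.3g mV exceeds the moderate-potential regime ",
                           "(~50 mV) where the Debye-Huckel approximation holds"),
                    abs(zeta) * 1e3))
  }
  kappa <- if (state$ionic_strength > 0) 1 / debye_length(state) else 0
  Q_coulomb <- 4 * pi * .const$eps0 * state$relative_permittivity *
    radius_R * (1 + kappa * radius_R) * zeta
  Q_coulomb / .const$e
}

#' Zeta potential from the total surface charge
#'
#' Inverse of [charge_from_zeta()].
#'
#' @param charge_Q Total charge, elementary charges (signed).
#' @param radius_R Particle radius, m.
#' @param state An [electrolyte_state()].
#' @return Zeta potential, V.
#' @export
zeta_from_charge <- function(charge_Q, radius_R, state) {
  check_that(radius_R > 0, "radius_R must be > 0 (m)")
  kappa <- if (state$ionic_strength > 0) 1 / debye_length(state) else 0
  charge_Q * .const$e /
    (4 * pi * .const$eps0 * state$relative_permittivity *
       radius_R * (1 + kappa * radius_R))
}

#' Surface charge density in elementary charges per square micrometre
#'
#' `sigma = Q / (4 pi R^2)` with the radius expressed in um, matching the
#' conventional e/um^2 reporting unit.
#'
#' @param charge_Q Total charge, elementary charges.
#' @param radius_R Particle radius, m.
#' @return Charge density, e/um^2 (signed).
#' @export
surface_charge_density <- function(charge_Q, radius_R) {
  check_that(radius_R > 0, "radius_R must be > 0 (m)")
  charge_Q / (4 * pi * (radius_R * 1e6)^2)
}

#' Predicted Soret-coefficient ratio from the sigma^2 lambda scaling
#'
#' The theoretical scaling `S_T ~ sigma^2 lambda` (quadratic in the surface
#' charge density, linear in the Debye length) fixes the ratio of S_T
#' between two conditions without an absolute prefactor:
#' `(sigma1^2 lambda1) / (sigma2^2 lambda2)`.
#'
#' @param sigma1,sigma2 Surface charge densities (any common unit).
#' @param lambda1,lambda2 Debye lengths (any common unit).
#' @return Dimensionless predicted ratio S_T1 / S_T2.
#' @export
#' @examples
#' soret_scaling_ratio(2, 1, 1, 1)   # doubling sigma at fixed lambda -> 4
soret_scaling_ratio <- function(sigma1, lambda1, sigma2, lambda2) {
  check_that(all(c(sigma1, lambda1, sigma2, lambda2) > 0),
             "all inputs must be > 0 (the scaling fixes ratios of magnitudes)")
  (sigma1^2 * lambda1) / (sigma2^2 * lambda2)
}

#' Electrokinetic summary table in instrument units
#'
#' Convenience wrapper accepting the units the quantities are usually
#' stated in (mV, nm, mM) and returning Debye length, kappa R, total charge
#' and surface charge density.
#'
#' @param zeta_mV Zeta potential, mV.
#' @param radius_nm Particle radius, nm.
#' @param ionic_strength_mM Ionic strength, mM (= mol/m^3).
#' @param temperature_K Temperature, K.
#' @param eps_r Relative permittivity.
#' @return One-row data.frame: `lambda_nm`, `kappa_R`, `Q_e`,
#'   `sigma_e_per_um2`.
#' @export
electro_summary <- function(zeta_mV, radius_nm, ionic_strength_mM,
                            temperature_K = 298.15, eps_r = 78.5) {
  state <- electrolyte_state(ionic_strength_mM, temperature_K, eps_r)
  R <- radius_nm * 1e-9
  lambda <- debye_length(state)
  Q <- charge_from_zeta(zeta_mV * 1e-3, R, state)
  data.frame(
    zeta_mV = zeta_mV, radius_nm = radius_nm,
    ionic_strength_mM = ionic_strength_mM,
    lambda_nm = lambda * 1e9,
    kappa_R = R / lambda,
    Q_e = Q,
    sigma_e_per_um2 = surface_charge_density(Q, R)
  )
}
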