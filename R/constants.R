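#' Physical constants and unit conversions
#'
#' The package works in the natural units of membrane simulation: lengths in
#' nm, energies in kJ/mol, forces (line tensions) in pN.  Two constants tie
#' these together:
#'
#' * the Boltzmann constant \eqn{k_B = 0.00831446} kJ mol^-1 K^-1, so that
#'   \eqn{k_B T \approx 2.58} kJ/mol at 310 K;
#' * the mechanical conversion 1 kJ mol^-1 nm^-1 = 1.66054 pN (equivalently
#'   1 pN nm = 0.602214 kJ/mol).
#'
#' @name poremech-units
#' @keywords internal
NULL

# Boltzmann constant [kJ mol^-1 K^-1]
.kB <- 0.00831446

# 1 kJ mol^-1 nm^-1 in pN
.pN_per_kJ_mol_nm <- 1.66054

# 1 pN nm in kJ mol^-1 (inverse of the above)
.kJ_mol_per_pN_nm <- 1 / .pN_per_kJ_mol_nm

#' Thermodynamic context
#'
#' Bundle of temperature and derived thermal energy used across the package.
#'
#' @param temperature Absolute temperature in K.  Default 310 K
#'   (physiological).  Must lie in (250, 400).
#'
#' @return A list with elements `temperature` (K), `kB`
#'   (kJ mol^-1 K^-1) and `kT` (kJ/mol).
#' @examples
#' thermo_context()$kT       # ~2.58 kJ/mol
#' thermo_context(298)$kT
#' @export
thermo_context <- function(temperature = 310) {
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      temperature <= 250 || temperature >= 400) {
    abort("`temperature` must be a single value in (250, 400) K.",
          class = "poremech_validation_error")
  }
  list(temperature = temperature, kB = .kB, kT = .kB * temperature)
}

#' Convert between kJ/mol/nm and pN
#'
#' Line tensions are naturally obtained in kJ mol^-1 nm^-1 (energy per rim
#' length) but conventionally reported in pN.
#'
#' @param x Numeric vector to convert.
#' @return Numeric vector in the target unit.
#' @examples
#' kj_mol_nm_to_pn(37.15)  # ~61.7 pN
#' @export
kj_mol_nm_to_pn <- function(x) x * .pN_per_kJ_mol_nm

#' @rdname kj_mol_nm_to_pn
#' @export
pn_to_kj_mol_nm <- function(x) x * .kJ_mol_per_pN_nm
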