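#' Symmetric 1:1 electrolyte
#'
#' Describes the bathing electrolyte on both sides of the membrane. Only
#' symmetric monovalent salts (e.g. KCl) are supported; concentrations are
#' equal in both reservoirs.
#'
#' @param bulk_concentration Bulk salt concentration in mol/L.
#' @param temperature Absolute temperature in K.
#' @param diffusion_coefficient_cation,diffusion_coefficient_anion Ion
#'   diffusion coefficients in m^2/s. Defaults are the infinite-dilution
#'   values for K+ and Cl- at 25 C.
#' @param relative_permittivity Relative dielectric constant of the solvent.
#'
#' @return An object of class `electrolyte`.
#' @examples
#' kcl_1m <- electrolyte(1)
#' debye_length(kcl_1m)
#' @export
electrolyte <- function(bulk_concentration = 1,
                        temperature = 298,
                        diffusion_coefficient_cation = .D_K,
                        diffusion_coefficient_anion = .D_Cl,
                        relative_permittivity = 78.4) {
  stopifnot(is.numeric(bulk_concentration), length(bulk_concentration) == 1)
  if (bulk_concentration <= 0) stop("bulk_concentration must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  if (diffusion_coefficient_cation <= 0 || diffusion_coefficient_anion <= 0)
    stop("diffusion coefficients must be positive")
  structure(
    list(bulk_concentration = bulk_concentration,
         temperature = temperature,
         diffusion_coefficient_cation = diffusion_coefficient_cation,
         diffusion_coefficient_anion = diffusion_coefficient_anion,
         relative_permittivity = relative_permittivity,
         cation_valence = 1L, anion_valence = -1L),
    class = "electrolyte")
}

#' Debye screening length
#'
#' \eqn{\lambda_D = \sqrt{\epsilon_r \epsilon_0 k_B T / (2 N_A e^2 c_0)}}
#' for a symmetric 1:1 electrolyte; sets the range over which lumen charges
#' are felt by diffusing ions.
#'
#' @param elec An [electrolyte()].
#' @return Screening length in nm.
#' @examples
#' debye_length(electrolyte(1))    # ~0.30 nm in 1 M KCl
#' debye_length(electrolyte(0.1))  # ~0.96 nm
#' @export
debye_length <- function(elec) {
  stopifnot(inherits(elec, "electrolyte"))
  c_num <- elec$bulk_concentration * 1000 * .const$NA_  # particles/m^3
  lam <- sqrt(elec$relative_permittivity * .const$eps0 * .const$kB *
                elec$temperature / (2 * c_num * .const$e^2))
  lam * 1e9
}

#' @export
print.electrolyte <- function(x, ...) {
  cat(sprintf("<electrolyte> %.3g M 1:1 salt, T = %.1f K, D+ = %.3g, D- = %.3g m^2/s\n",
              x$bulk_concentration, x$temperature,
              x$diffusion_coefficient_cation, x$diffusion_coefficient_anion))
  invisible(x)
}
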