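#' Cylindrical pore geometry
#'
#' The pore is idealized as a cylinder of radius `radius` and length `length`
#' (both nm). The axial coordinate runs from z = 0 at the cis entrance to
#' z = L at the trans entrance; positive applied voltage drives cations from
#' cis to trans, and positive current is cation flux cis to trans.
#'
#' @param radius Pore radius in nm.
#' @param length Pore length in nm.
#' @return A `pore_geometry` object.
#' @examples
#' pore_geometry()  # aerolysin-like defaults: 1.4 nm diameter, 10 nm long
#' @export
pore_geometry <- function(radius = 0.7, length = 10) {
  if (!(radius > 0 && length > 0)) stop("radius and length must be positive")
  if (radius >= length) stop("pore must be longer than its radius")
  structure(list(radius = radius, length = length), class = "pore_geometry")
}

#' Ring of fixed charge in the pore lumen
#'
#' A ring of identical charged residues at one axial position, e.g. the 7
#' copies of a charged side chain contributed by each protomer of heptameric
#' aerolysin.
#'
#' @param axial_position Axial position in nm from the cis entrance.
#' @param valence Signed charge per residue in elementary charges (non-zero).
#' @param multiplicity Number of copies in the ring (>= 1).
#' @return A `lumen_charge` object.
#' @export
lumen_charge <- function(axial_position, valence, multiplicity = 7L) {
  if (valence == 0) stop("valence must be non-zero")
  if (multiplicity < 1) stop("multiplicity must be >= 1")
  if (axial_position < 0) stop("axial_position must be >= 0")
  structure(list(axial_position = axial_position, valence = valence,
                 multiplicity = as.integer(multiplicity)),
            class = "lumen_charge")
}

#' Electrodiffusion transport problem
#'
#' Bundles pore geometry, the discrete lumen charge distribution and the
#' electrolyte into the one-dimensional steady-state electrodiffusion model
#' used for open-pore IV prediction. Each charge ring contributes a screened
#' Coulomb well/barrier evaluated on the pore axis,
#' \eqn{w_i(z) = z_s q_i m_i \ell_B e^{-d_i/\lambda} / d_i} (in kT), with
#' \eqn{d_i = \sqrt{(z - z_i)^2 + a^2}}; the applied voltage adds a linear
#' potential across the pore (uniform field, access resistance neglected).
#'
#' @param geometry A [pore_geometry()].
#' @param charges List of [lumen_charge()] objects (possibly empty).
#' @param elec An [electrolyte()].
#' @param well_screening_length Screening length of the charge wells in nm;
#'   defaults to the Debye length of `elec`.
#' @param bjerrum_length Bjerrum length in nm (0.7 nm in water at 25 C).
#' @param n_grid Number of axial grid points (>= 512).
#' @return A `transport_problem` object.
#' @examples
#' tp <- transport_problem(charges = list(lumen_charge(5, -1)))
#' iv <- iv_curve(tp, seq(-0.2, 0.2, by = 0.01))
#' rectification_factor(iv)
#' @export
transport_problem <- function(geometry = pore_geometry(),
                              charges = list(),
                              elec = electrolyte(),
                              well_screening_length = NULL,
                              bjerrum_length = 0.7,
                              n_grid = 4096L) {
  stopifnot(inherits(geometry, "pore_geometry"), inherits(elec, "electrolyte"))
  if (inherits(charges, "lumen_charge")) charges <- list(charges)
  for (ch in charges) {
    stopifnot(inherits(ch, "lumen_charge"))
    if (ch$axial_position > geometry$length)
      stop("charge axial_position outside the pore")
  }
  if (is.null(well_screening_length)) well_screening_length <- debye_length(elec)
  if (well_screening_length <= 0) stop("screening length must be positive")
  if (n_grid < 512) stop("n_grid must be >= 512")
  structure(list(geometry = geometry, charges = charges, electrolyte = elec,
                 well_screening_length = well_screening_length,
                 bjerrum_length = bjerrum_length, n_grid = as.integer(n_grid)),
            class = "transport_problem")
}

#' @export
print.transport_problem <- function(x, ...) {
  cat(sprintf("<transport_problem> a = %.2f nm, L = %.1f nm, %d charge ring(s), %.3g M salt\n",
              x$geometry$radius, x$geometry$length, length(x$charges),
              x$electrolyte$bulk_concentration))
  invisible(x)
}

.species_valence <- function(species) {
  switch(match.arg(species, c("cation", "anion")), cation = 1, anion = -1)
}

#' Potential energy landscape of a diffusing ion
#'
#' The dimensionless (kT units) potential experienced by a cation or anion
#' along the pore axis: the linear applied-voltage ramp plus the screened
#' ring-charge contributions.
#'
#' @param problem A [transport_problem()].
#' @param species `"cation"` or `"anion"`.
#' @param voltage Applied transmembrane voltage in V (|V| <= 1).
#' @param clip Potentials are clipped at +/- this value (kT) with a warning,
#'   to avoid overflow in the Boltzmann factors.
#' @return A list with `grid` (axial positions, nm) and `values` (kT).
#' @export
species_potential <- function(problem, species = c("cation", "anion"),
                              voltage = 0, clip = 50) {
  stopifnot(inherits(problem, "transport_problem"))
  if (abs(voltage) > 1) stop("|voltage| must be <= 1 V")
  zs <- .species_valence(species)
  L <- problem$geometry$length
  a <- problem$geometry$radius
  grid <- seq(0, L, length.out = problem$n_grid)
  kT <- .const$kB * problem$electrolyte$temperature
  w <- zs * .const$e * voltage * (1 - grid / L) / kT
  lam <- problem$well_screening_length
  lB <- problem$bjerrum_length
  for (ch in problem$charges) {
    d <- sqrt((grid - ch$axial_position)^2 + a^2)
    w <- w + zs * ch$valence * ch$multiplicity * lB * exp(-d / lam) / d
  }
  if (any(abs(w) > clip)) {
    warning("potential clipped at +/-", clip, " kT")
    w <- pmin(pmax(w, -clip), clip)
  }
  list(grid = grid, values = w)
}

# Integral of exp(W(z)) over [0, L] assuming W piecewise linear between grid
# points (exponentially fitted quadrature; exact for linear W). `shift` has
# already been subtracted from w. Returns the cumulative integral at each
# grid point (in the units of `grid`).
.cum_int_exp <- function(grid, w) {
  n <- length(grid)
  h <- diff(grid)
  dw <- diff(w)
  ew <- exp(w)
  seg <- ifelse(abs(dw) > 1e-12,
                h * (ew[-1] - ew[-n]) / dw,
                h * 0.5 * (ew[-1] + ew[-n]))
  c(0, cumsum(seg))
}

# Per-species steady-state flux density (particles m^-2 s^-1) and potential.
# Boundary concentrations are in local Boltzmann equilibrium with the charge
# landscape, c(0) = c0 exp(-W_charge(0)), so that c(0) exp(W(0)) = c0 e^{z_s u}
# and c(L) exp(W(L)) = c0 (u = eV/kT): the flux vanishes exactly at V = 0 for
# any charge set and reduces to the interior-charge expression when the ring
# potentials vanish at the pore mouths.
.species_flux <- function(problem, species, voltage, clip = 50) {
  pot <- species_potential(problem, species, voltage, clip = clip)
  w <- pot$values
  m <- max(w)
  ci <- .cum_int_exp(pot$grid * 1e-9, w - m)  # metres
  D <- if (species == "cation") problem$electrolyte$diffusion_coefficient_cation
       else problem$electrolyte$diffusion_coefficient_anion
  c_num <- problem$electrolyte$bulk_concentration * 1000 * .const$NA_
  zs <- .species_valence(species)
  u <- zs * .const$e * voltage / (.const$kB * problem$electrolyte$temperature)
  J <- D * c_num * (exp(u - m) - exp(-m)) / ci[length(ci)]
  list(J = J, pot = pot, shift = m, cumint = ci, D = D, c_num = c_num, u = u)
}

#' Steady-state ionic current through the pore
#'
#' Solves the one-dimensional steady-state Nernst-Planck problem on the
#' species potential landscapes by exact quadrature. Boundary concentrations
#' are in local Boltzmann equilibrium with the charge landscape, which gives
#' \eqn{J_s = D_s c_0 (e^{z_s eV/k_BT} - 1) / \int_0^L e^{W_s(z)} dz} per
#' species and \eqn{I = \pi a^2 e (J_{+} - J_{-})}; the current vanishes
#' identically at V = 0 for any charge set.
#'
#' @inheritParams species_potential
#' @return Current in A.
#' @export
steady_state_current <- function(problem, voltage) {
  Jp <- .species_flux(problem, "cation", voltage)$J
  Jm <- .species_flux(problem, "anion", voltage)$J
  A <- pi * (problem$geometry$radius * 1e-9)^2
  A * .const$e * (Jp - Jm)
}

#' Open-pore IV curve
#'
#' @param problem A [transport_problem()].
#' @param voltages Sorted vector of voltages in V.
#' @return An `iv_curve` object with fields `voltages` (V) and `currents` (A).
#' @export
iv_curve <- function(problem, voltages = seq(-0.2, 0.2, length.out = 81)) {
  if (is.unsorted(voltages, strictly = TRUE)) stop("voltages must be strictly increasing")
  currents <- vapply(voltages, function(v) steady_state_current(problem, v),
                     numeric(1))
  new_iv_curve(voltages, currents)
}

#' Construct an IV curve from voltage/current samples
#'
#' @param voltages Strictly increasing voltages in V.
#' @param currents Currents in A, same length.
#' @return An `iv_curve` object.
#' @export
new_iv_curve <- function(voltages, currents) {
  if (length(voltages) != length(currents)) stop("length mismatch")
  if (is.unsorted(voltages, strictly = TRUE)) stop("voltages must be strictly increasing")
  structure(list(voltages = as.numeric(voltages), currents = as.numeric(currents)),
            class = "iv_curve")
}

#' @export
print.iv_curve <- function(x, ...) {
  cat(sprintf("<iv_curve> %d points, V in [%.3g, %.3g] V, I in [%.3g, %.3g] A\n",
              length(x$voltages), min(x$voltages), max(x$voltages),
              min(x$currents), max(x$currents)))
  invisible(x)
}

#' Interpolate an IV curve
#'
#' Linear interpolation of current at arbitrary voltages within the span of
#' the curve.
#'
#' @param iv An `iv_curve`.
#' @param voltages Voltages in V.
#' @return Currents in A.
#' @export
iv_interpolate <- function(iv, voltages) {
  stopifnot(inherits(iv, "iv_curve"))
  if (any(voltages < min(iv$voltages) | voltages > max(iv$voltages)))
    stop("voltage outside the span of the IV curve")
  stats::approx(iv$voltages, iv$currents, xout = voltages)$y
}

#' Rectification factor
#'
#' \eqn{\beta = (I_{+} - |I_{-}|) / (I_{+} + |I_{-}|)} with
#' \eqn{I_{\pm} = I(\pm v_{ref})}; a unitless value in \[-1, 1\] quantifying
#' the asymmetry of the open-pore IV curve. Negative \eqn{\beta} means the
#' pore conducts more at negative voltage.
#'
#' @param iv An `iv_curve` spanning at least +/- `vref`.
#' @param vref Reference voltage in V (paper convention: 0.1 V).
#' @return Dimensionless rectification factor.
#' @export
rectification_factor <- function(iv, vref = 0.1) {
  Ip <- iv_interpolate(iv, vref)
  Im <- iv_interpolate(iv, -vref)
  den <- Ip + abs(Im)
  if (den == 0) stop("zero total current at +/-vref")
  (Ip - abs(Im)) / den
}

#' Steady-state ion concentration profile
#'
#' Concentration of one species along the pore axis at steady state,
#' \eqn{c_s(z) = e^{-W_s(z)} [ c_s(0) e^{W_s(0)} - (J_s / D_s) \int_0^z e^{W_s} ]},
#' with boundary concentrations in Boltzmann equilibrium with the charge
#' landscape (equal to \eqn{c_0} when the ring potentials vanish at the
#' mouths).
#'
#' @inheritParams species_potential
#' @return A list with `grid` (nm) and `concentration` (mol/L).
#' @export
concentration_profile <- function(problem, species = c("cation", "anion"),
                                  voltage = 0) {
  species <- match.arg(species)
  fl <- .species_flux(problem, species, voltage)
  w <- fl$pot$values
  m <- fl$shift
  n <- length(w)
  ratio <- fl$cumint / fl$cumint[n]
  conc_rel <- exp(-(w - m)) *
    (exp(fl$u - m) - (exp(fl$u - m) - exp(-m)) * ratio)
  list(grid = fl$pot$grid,
       concentration = problem$electrolyte$bulk_concentration * conc_rel)
}

#' Rectification versus charge position
#'
#' Scans the rectification factor obtained when a single charge ring is added
#' to a base problem at each of a set of axial positions, all other
#' parameters fixed.
#'
#' @param base_problem A [transport_problem()].
#' @param valence Signed valence of the added ring (0 leaves the problem
#'   unchanged).
#' @param positions Axial positions in nm, within \[0, L\].
#' @param multiplicity Ring multiplicity.
#' @param vref Reference voltage for the rectification factor.
#' @return Numeric vector of rectification factors, one per position.
#' @export
charge_position_scan <- function(base_problem, valence, positions,
                                 multiplicity = 7L, vref = 0.1) {
  L <- base_problem$geometry$length
  if (any(positions < 0 | positions > L)) stop("positions outside [0, L]")
  vapply(positions, function(z) {
    pb <- base_problem
    if (valence != 0)
      pb$charges <- c(pb$charges, list(lumen_charge(z, valence, multiplicity)))
    iv <- iv_curve(pb, c(-vref, 0, vref))
    rectification_factor(iv, vref)
  }, numeric(1))
}

#' Bulk-limited cylinder conductance
#'
#' The conductance of a cylinder of electrolyte with the pore's geometry,
#' \eqn{G = \sigma \pi a^2 / L}, using the Nernst-Einstein conductivity
#' \eqn{\sigma = N_A e^2 c_0 (D_+ + D_-) / k_B T}. This is the upper
#' (barrier-free) limit for the pore conductance; for aerolysin geometry in
#' 1 M KCl it is about 2 nS.
#'
#' @param geometry A [pore_geometry()].
#' @param elec An [electrolyte()].
#' @return Conductance in S.
#' @examples
#' bulk_conductance() * 1e9  # nS
#' @export
bulk_conductance <- function(geometry = pore_geometry(), elec = electrolyte()) {
  c_num <- elec$bulk_concentration * 1000 * .const$NA_
  sigma <- c_num * .const$e^2 *
    (elec$diffusion_coefficient_cation + elec$diffusion_coefficient_anion) /
    (.const$kB * elec$temperature)
  sigma * pi * (geometry$radius * 1e-9)^2 / (geometry$length * 1e-9)
}
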