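# Independent finite-difference steady-state solver of the 1D Nernst-Planck
# problem d/dz[D(c' + c W')] = 0 with Boltzmann boundary concentrations,
# used as an oracle for the quadrature-based current. Plain central
# differences on a fine grid; solved with the Thomas algorithm.
fd_species_current <- function(problem, species, voltage, n = 4001) {
  kT <- 1.380649e-23 * problem$electrolyte$temperature
  e <- 1.602176634e-19
  zs <- if (species == "cation") 1 else -1
  L <- problem$geometry$length
  a <- problem$geometry$radius
  z <- seq(0, L, length.out = n)
  w <- zs * e * voltage * (1 - z / L) / kT
  wc <- numeric(n)
  for (ch in problem$charges) {
    d <- sqrt((z - ch$axial_position)^2 + a^2)
    wc <- wc + zs * ch$valence * ch$multiplicity * problem$bjerrum_length *
      exp(-d / problem$well_screening_length) / d
  }
  w <- w + wc
  h <- (z[2] - z[1]) * 1e-9
  wp <- c(0, (w[3:n] - w[1:(n - 2)]) / (2 * h), 0)   # dW/dz, 1/m
  wp[1] <- (w[2] - w[1]) / h; wp[n] <- (w[n] - w[n - 1]) / h
  # interior: (c[i+1] - 2 c[i] + c[i-1])/h^2 + ((c wp)[i+1] - (c wp)[i-1])/(2h) = 0
  lower <- 1 / h^2 - wp[1:(n - 2)] / (2 * h)
  diagm <- rep(-2 / h^2, n - 2)
  upper <- 1 / h^2 + wp[3:n] / (2 * h)
  c_num <- problem$electrolyte$bulk_concentration * 1000 * 6.02214076e23
  c0v <- c_num * exp(-(wc[1]))
  cLv <- c_num * exp(-(wc[n]))
  rhs <- numeric(n - 2)
  rhs[1] <- -lower[1] * c0v
  rhs[n - 2] <- -upper[n - 2] * cLv
  # Thomas algorithm
  m <- n - 2
  cp <- numeric(m); dp <- numeric(m)
  cp[1] <- upper[1] / diagm[1]; dp[1] <- rhs[1] / diagm[1]
  for (i in 2:m) {
    denom <- diagm[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / denom
  }
  sol <- numeric(m)
  sol[m] <- dp[m]
  for (i in (m - 1):1) sol[i] <- dp[i] - cp[i] * sol[i + 1]
  cc <- c(c0v, sol, cLv)
  D <- if (species == "cation") problem$electrolyte$diffusion_coefficient_cation
       else problem$electrolyte$diffusion_coefficient_anion
  # flux -D(c' + c W') evaluated at interior points, averaged
  i <- seq(2, n - 1)
  J <- -D * ((cc[i + 1] - cc[i - 1]) / (2 * h) + cc[i] * wp[i])
  mean(J)
}

fd_current <- function(problem, voltage, n = 4001) {
  A <- pi * (problem$geometry$radius * 1e-9)^2
  e <- 1.602176634e-19
  A * e * (fd_species_current(problem, "cation", voltage, n) -
           fd_species_current(problem, "anion", voltage, n))
}

# random charged-pore problems for symmetry / oracle sweeps
random_problem <- function(n_rings = 3, seed = 1, equal_D = TRUE) {
  set.seed(seed)
  elec <- if (equal_D)
    electrolyte(1, diffusion_coefficient_cation = 2e-9,
                diffusion_coefficient_anion = 2e-9)
  else electrolyte(1)
  charges <- lapply(seq_len(n_rings), function(i)
    lumen_charge(stats::runif(1, 0.5, 9.5), sample(c(-1, 1), 1), sample(1:7, 1)))
  transport_problem(charges = charges, elec = elec)
}

mirror_problem <- function(problem, conjugate = FALSE) {
  L <- problem$geometry$length
  problem$charges <- lapply(problem$charges, function(ch) {
    ch$axial_position <- L - ch$axial_position
    if (conjugate) ch$valence <- -ch$valence
    ch
  })
  problem
}

conjugate_problem <- function(problem) {
  problem$charges <- lapply(problem$charges, function(ch) {
    ch$valence <- -ch$valence; ch })
  problem
}
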