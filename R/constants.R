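# CODATA 2018 values, SI units.
.const <- list(
  e    = 1.602176634e-19,   # elementary charge, C
  kB   = 1.380649e-23,      # Boltzmann constant, J/K
  NA_  = 6.02214076e23,     # Avogadro constant, 1/mol
  eps0 = 8.8541878128e-12   # vacuum permittivity, F/m
)

# Infinite-dilution diffusion coefficients of K+ and Cl- in water at 25 C,
# m^2/s (standard tabulated values).
.D_K  <- 1.957e-9
.D_Cl <- 2.032e-9
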