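# Internal unit system: amu, Angstrom, ps.  In these units energies are
# amu A^2 / ps^2 (= 10 J/mol) and angular frequencies are rad/ps.

# Boltzmann constant, kcal/(mol K) -- used for reported entropies
.kB.kcal <- 1.987204e-3

# Boltzmann constant, amu A^2 / (ps^2 K)
.kB.int <- 8.31446261815324 / 10

# Molar reduced Planck constant, amu A^2 / ps
.hbar.int <- 1.054571817e-34 * 6.02214076e23 / 1e-11

# rad/ps -> wavenumber (cm^-1): nu = omega / (2 pi c)
.omega.to.cm1 <- 1 / (2 * pi * 2.99792458e-2)

# Relative eigenvalue tolerance below which a mode is treated as external /
# numerically zero (lambda < tol * lambda_max)
.lambda.rel.tol <- 1e-6

# Variance below this (A^2) is treated as exactly zero in normalized
# cross-correlations
.zero.var.tol <- 1e-12
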