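# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately written by a different route than the
# package implementation it checks.

# Horn quaternion-based optimal-superposition RMSD: maximizes the correlation
# via the largest eigenvalue of the 4x4 quaternion matrix.  Independent of the
# SVD/Kabsch route used by the fitting code.
quaternion_rmsd <- function(ref, mob) {
  a <- sweep(ref, 2L, colMeans(ref))
  b <- sweep(mob, 2L, colMeans(mob))
  M <- crossprod(b, a)   # sum over atoms of b_i a_i^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4L, 4L, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lam) / nrow(ref)
  sqrt(max(msd, 0))
}

# random rotation matrix (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# random symmetric positive-definite matrix with eigenvalues in [lo, hi]
random_spd <- function(d, lo = 0.5, hi = 3) {
  v <- qr.Q(qr(matrix(rnorm(d * d), d)))
  v %*% (seq(lo, hi, length.out = d) * t(v))
}

# random orthonormal basis (columns)
random_orthonormal <- function(d, k = d) qr.Q(qr(matrix(rnorm(d * k), d, k)))[, seq_len(k), drop = FALSE]

# Ornstein-Uhlenbeck velocity series with known correlation time tau0 (ps):
# exact AR(1) discretization, stationary start
ou_velocities <- function(n_frames, n_atoms, dt, tau0) {
  rho <- exp(-dt / tau0)
  v <- array(0, dim = c(n_frames, n_atoms, 3L))
  v[1L, , ] <- rnorm(n_atoms * 3L)
  for (f in 2:n_frames)
    v[f, , ] <- rho * v[f - 1L, , ] + sqrt(1 - rho^2) * rnorm(n_atoms * 3L)
  velocity_series(v, frame_interval = dt)
}

# draw F frames of an N-atom system from N(mu, Sigma) by Cholesky --
# independent of the package's eigen-decomposition sampler
chol_frames <- function(mu_flat, Sigma, n_frames, frame_interval = 1) {
  L <- chol(Sigma)
  X <- matrix(rnorm(n_frames * length(mu_flat)), n_frames) %*% L
  X <- sweep(X, 2L, mu_flat, `+`)
  frame_ensemble(rrscan:::xyz_to_coords(X), frame_interval, aligned_to = "oracle")
}

# the quantum-harmonic-oscillator entropy summed by plain evaluation
# (molar hbar and kB in amu-Angstrom-ps units, from CODATA values)
qho_entropy_oracle <- function(omega_ps, temperature) {
  kB_kcal <- 1.987204e-3
  hbar <- 1.054571817e-34 * 6.02214076e23 / 1e-11
  x <- hbar * omega_ps / (0.831446261815324 * temperature)
  kB_kcal * sum(x / (exp(x) - 1) - log(1 - exp(-x)))
}

# small constant-geometry ensemble helper
const_ensemble <- function(frame, n_frames, dt = 1, aligned = "const") {
  co <- array(rep(frame, each = n_frames), dim = c(n_frames, nrow(frame), 3L))
  frame_ensemble(co, dt, aligned_to = aligned)
}
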