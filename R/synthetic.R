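#' Synthetic harmonic models with closed-form entropy
#'
#' The generator side of the package: multivariate-Gaussian ensembles drawn
#' from harmonic models with exactly known spectra, so every analysis stage
#' (covariance, quasi-harmonic modes, entropy, projections) can be validated
#' against analytic values without any molecular-dynamics engine.
#'
#' @name synthetic
NULL

# internal constructor; lambda descending, modes mass-weighted orthonormal
harmonic_model <- function(topology, mean_structure, lambda, modes, temperature) {
  spec <- structure(list(frequencies_cm1 = NULL, omega_ps = NULL,
                         lambda = lambda, modes = modes,
                         temperature = temperature, n_dropped = 0L,
                         masses = topology$mass),
                    class = "QHSpectrum")
  spec$omega_ps <- sqrt(.kB.int * temperature / lambda)
  spec$frequencies_cm1 <- spec$omega_ps * .omega.to.cm1
  structure(list(topology = topology, mean_structure = mean_structure,
                 spectrum = spec, temperature = temperature,
                 analytic_entropy = config_entropy(spec, scope = "protein")$S),
            class = "HarmonicModel")
}

#' @export
print.HarmonicModel <- function(x, ...) {
  cat("HarmonicModel:", x$topology$n_atoms, "atoms,",
      length(x$spectrum$lambda), "internal modes at", x$temperature, "K;",
      "analytic S =", format(x$analytic_entropy, digits = 6), "kcal/(mol K)\n")
  invisible(x)
}

#' Elastic-network harmonic model
#'
#' Builds an isotropic-spring (anisotropic-network) Hessian from all atom
#' pairs within a distance cutoff, mass-weights it, and keeps the 3N-6
#' internal modes: the model's covariance is \eqn{k_B T} times the
#' pseudo-inverse of the Hessian with the 6 external modes removed, and its
#' configurational entropy is known in closed form from the exact spectrum.
#'
#' @param coordinates \code{N x 3} equilibrium coordinates, Angstrom.
#' @param masses per-atom masses, amu.
#' @param cutoff contact cutoff, Angstrom (default 8, the usual
#'   elastic-network choice).
#' @param spring_k uniform spring constant, amu/ps^2 (default 1, which puts
#'   the mode frequencies in the low-wavenumber range typical of collective
#'   protein motions).
#' @param resid residue index per atom (default: all atoms in residue 1).
#' @param temperature K.
#' @return A \code{HarmonicModel}.
#' @export
build_enm_model <- function(coordinates, masses, cutoff = 8, spring_k = 1,
                            resid = NULL, temperature = 300) {
  coordinates <- as.matrix(coordinates)
  n <- nrow(coordinates)
  if (n < 2L) stop("need at least 2 atoms")
  if (is.null(resid)) resid <- rep(1L, n)
  top <- topology(mass = masses, resid = resid)
  d <- as.matrix(stats::dist(coordinates))
  contact <- d <= cutoff & upper.tri(d)
  if (min(d[upper.tri(d)]) > cutoff)
    stop("cutoff ", cutoff, " A is below the minimum interatomic distance (",
         format(min(d[upper.tri(d)]), digits = 4), " A): no contacts")
  # connectivity of the contact graph (breadth-first search)
  adj <- contact | t(contact)
  comp <- integer(n); comp[1L] <- 1L; queue <- 1L; ncomp <- 1L
  repeat {
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[i, ] & comp == 0L)
      comp[nb] <- comp[i]
      queue <- c(queue, nb)
    }
    nxt <- which(comp == 0L)[1L]
    if (is.na(nxt)) break
    ncomp <- ncomp + 1L; comp[nxt] <- ncomp; queue <- nxt
  }
  if (ncomp > 1L)
    stop("contact graph is disconnected at cutoff ", cutoff, " A: components of sizes ",
         paste(tabulate(comp), collapse = ", "))
  H <- matrix(0, 3L * n, 3L * n)
  pairs <- which(contact, arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    e <- (coordinates[j, ] - coordinates[i, ]) / d[i, j]
    K <- spring_k * tcrossprod(e)
    ii <- (3L * i - 2L):(3L * i); jj <- (3L * j - 2L):(3L * j)
    H[ii, ii] <- H[ii, ii] + K
    H[jj, jj] <- H[jj, jj] + K
    H[ii, jj] <- H[ii, jj] - K
    H[jj, ii] <- H[jj, ii] - K
  }
  sm <- rep(sqrt(masses), each = 3L)
  Hw <- H / tcrossprod(sm)
  eg <- eigen((Hw + t(Hw)) / 2, symmetric = TRUE)   # omega^2 descending
  vals <- eg$values
  # external (and any genuinely floppy) modes fall below tolerance and are
  # excluded from the model; a connected graph leaves 6 external zeros
  # (5 for collinear geometries, e.g. a diatomic)
  keep <- which(vals >= .lambda.rel.tol * max(vals))
  omega2 <- vals[keep]
  if (!length(keep)) stop("no stiff modes: Hessian is numerically zero")
  # reorder ascending omega (descending lambda) to match spectrum convention
  ord <- rev(seq_along(keep))
  lambda <- .kB.int * temperature / omega2[ord]
  modes <- eg$vectors[, keep, drop = FALSE][, ord, drop = FALSE]
  harmonic_model(top, coordinates, lambda, modes, temperature)
}

#' Default toy system: a 3-residue, 12-atom chain
#'
#' A small non-collinear chain (4 atoms per residue, carbon masses) connected
#' at the default 8 Angstrom elastic-network cutoff: big enough for residue
#' sub-blocks, small enough for exhaustive oracles.
#'
#' @param n_residues,atoms_per_residue chain layout.
#' @param spring_k,cutoff,temperature passed to \code{\link{build_enm_model}}.
#' @return A \code{HarmonicModel}.
#' @export
toy_chain_model <- function(n_residues = 3, atoms_per_residue = 4,
                            spring_k = 1, cutoff = 8, temperature = 300) {
  n <- n_residues * atoms_per_residue
  t <- seq_len(n)
  coords <- cbind(1.5 * t, 1.2 * sin(1.7 * t), 0.8 * cos(0.9 * t))
  build_enm_model(coords, masses = rep(12.011, n), cutoff = cutoff,
                  spring_k = spring_k,
                  resid = rep(seq_len(n_residues), each = atoms_per_residue),
                  temperature = temperature)
}

#' Covariance matrix of a harmonic model
#'
#' \eqn{C = M^{-1/2} V \Lambda V^T M^{-1/2}} over the model's internal modes.
#'
#' @param model a \code{HarmonicModel}.
#' @return A \code{CovarianceMatrix}.
#' @export
model_covariance <- function(model) {
  stopifnot(inherits(model, "HarmonicModel"))
  sm <- rep(sqrt(model$topology$mass), each = 3L)
  V <- model$spectrum$modes
  sigma <- V %*% (model$spectrum$lambda * t(V))
  as_covariance(sigma / tcrossprod(sm),
                mean = as.vector(t(model$mean_structure)), aligned = TRUE)
}

# draw multivariate-Gaussian frames given a mass-weighted spectrum
gaussian_frames <- function(mean_flat, lambda, modes, masses, n_frames,
                            seed = NULL, frame_interval = 1) {
  if (n_frames < 1L) stop("need at least one frame")
  if (!is.null(seed)) set.seed(seed)
  k <- length(lambda)
  Z <- matrix(stats::rnorm(n_frames * k), n_frames, k)
  X <- Z %*% (sqrt(lambda) * t(modes))        # mass-weighted displacements
  X <- sweep(X, 2L, rep(sqrt(masses), each = 3L), `/`)
  X <- sweep(X, 2L, as.numeric(mean_flat), `+`)
  frame_ensemble(xyz_to_coords(X), frame_interval = frame_interval,
                 aligned_to = "model_mean")
}

#' Sample frames from a harmonic model
#'
#' Draws \code{n_frames} from the model's multivariate normal distribution
#' (mean structure, covariance); deterministic under a fixed seed.  Frames are
#' generated in the model frame and marked as aligned to the model mean.
#'
#' @param model a \code{HarmonicModel}.
#' @param n_frames number of frames.
#' @param seed integer seed (optional but recommended).
#' @param frame_interval nominal frame spacing, ps (metadata only; the draws
#'   are uncorrelated in time).
#' @return A \code{FrameEnsemble}.
#' @export
sample_frames <- function(model, n_frames, seed = NULL, frame_interval = 1) {
  stopifnot(inherits(model, "HarmonicModel"))
  gaussian_frames(as.vector(t(model$mean_structure)), model$spectrum$lambda,
                  model$spectrum$modes, model$topology$mass, n_frames,
                  seed = seed, frame_interval = frame_interval)
}

#' Emulate a rigid-residue constraint on a harmonic model
#'
#' Projects the fluctuations of one residue's \code{3m}-dimensional
#' coordinate block onto its rigid-body subspace (3 translations + up to 3
#' rotations about the mean geometry), in mass-weighted coordinates.  The
#' residue keeps moving as a rigid body inside the protein but loses its
#' internal degrees of freedom; the resulting covariance stays positive
#' semi-definite and the analytic entropy is recomputed from the new
#' spectrum.  This is a covariance-space emulation of a constrained
#' integrator: sufficient to exercise every analysis operation, but it cannot
#' reproduce dynamical re-equilibration effects of constrained MD.
#'
#' @param model a \code{HarmonicModel}.
#' @param resid residue to hold rigid.
#' @return A new \code{HarmonicModel}; a 1-atom residue (already rigid)
#'   returns the model unchanged.
#' @export
apply_rigid_residue <- function(model, resid) {
  stopifnot(inherits(model, "HarmonicModel"))
  top <- model$topology
  atoms <- residue_atoms(top, resid)
  m <- length(atoms)
  if (m == 1L) return(model)
  idx <- coord_indices(atoms)
  p <- model$mean_structure[atoms, , drop = FALSE]
  p <- sweep(p, 2L, colMeans(p))
  sq <- sqrt(top$mass[atoms])
  # rigid-body basis, mass-weighted: translations + rotations about the mean
  B <- matrix(0, 3L * m, 6L)
  for (k in 1:3) B[seq(k, 3L * m, by = 3L), k] <- sq
  ex <- diag(3)
  for (k in 1:3) {
    rot <- t(vapply(seq_len(m), function(a) {
      v <- c(ex[k, 2] * p[a, 3] - ex[k, 3] * p[a, 2],
             ex[k, 3] * p[a, 1] - ex[k, 1] * p[a, 3],
             ex[k, 1] * p[a, 2] - ex[k, 2] * p[a, 1])
      sq[a] * v
    }, numeric(3)))
    B[, 3L + k] <- as.vector(t(rot))
  }
  qrB <- qr(B)
  Q <- qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE]
  P <- tcrossprod(Q)
  V <- model$spectrum$modes
  sigma <- V %*% (model$spectrum$lambda * t(V))
  G <- diag(nrow(sigma))
  G[idx, idx] <- P
  sigma2 <- G %*% sigma %*% G
  eg <- eigen((sigma2 + t(sigma2)) / 2, symmetric = TRUE)
  keep <- eg$values >= .lambda.rel.tol * max(eg$values)
  harmonic_model(top, model$mean_structure,
                 eg$values[keep], eg$vectors[, keep, drop = FALSE],
                 model$temperature)
}

#' Shift a harmonic model's mean along a mode
#'
#' Two-state generator: displaces the mean structure by
#' \code{magnitude * M^{-1/2} direction_mode} (mass-weighted displacement of
#' the stated magnitude), leaving the covariance unchanged -- an idealized
#' population shift between sub-states.
#'
#' @param model a \code{HarmonicModel}.
#' @param direction_mode unit-norm 3N vector in mass-weighted coordinates
#'   (e.g. a column of \code{model$spectrum$modes}).
#' @param magnitude displacement in amu^1/2 Angstrom.
#' @return A new \code{HarmonicModel} with the shifted mean.
#' @export
two_state_shift <- function(model, direction_mode, magnitude) {
  stopifnot(inherits(model, "HarmonicModel"))
  direction_mode <- as.numeric(direction_mode)
  if (abs(sqrt(sum(direction_mode^2)) - 1) > 1e-6)
    stop("'direction_mode' must be unit-norm")
  disp <- magnitude * direction_mode / rep(sqrt(model$topology$mass), each = 3L)
  mean2 <- model$mean_structure + matrix(disp, ncol = 3L, byrow = TRUE)
  harmonic_model(model$topology, mean2, model$spectrum$lambda,
                 model$spectrum$modes, model$temperature)
}
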