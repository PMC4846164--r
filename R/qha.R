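#' Fit a quasi-harmonic model to a conformational ensemble
#'
#' The central estimator of the package.  The sampled fluctuation distribution
#' is modelled as a multivariate Gaussian on an effective harmonic potential
#' whose force constants come from the inverse coordinate covariance
#' (\eqn{F = k_B T C^{-1}}).  Fitting proceeds as: (optional) least-squares
#' superposition of every frame onto the reference, coordinate covariance with
#' population divisor, mass-weighted diagonalization into quasi-harmonic modes,
#' and quantum-harmonic-oscillator configurational entropy over the 3n-6
#' internal modes.
#'
#' @param ensemble a \code{FrameEnsemble}.  If not yet superposed it is fitted
#'   to \code{reference} (default: its first frame, the usual convention).
#' @param topology matching \code{Topology}.
#' @param temperature K (default 300).
#' @param reference superposition reference (\code{N x 3}); default first
#'   frame.
#' @param tol relative eigenvalue tolerance for mode dropping.
#' @return Object of class \code{"qha"}: list with \code{covariance}
#'   (\code{CovarianceMatrix}), \code{spectrum} (\code{QHSpectrum}),
#'   \code{entropy} (\code{EntropyResult}), \code{mean_structure}
#'   (\code{N x 3}), \code{topology}, \code{temperature}, \code{n_frames},
#'   \code{call}.
#' @seealso \code{\link{residue_entropies}}, \code{\link{project_frames}},
#'   \code{\link{pca_contributions}}
#' @examples
#' model <- toy_chain_model()
#' ens <- sample_frames(model, 2000, seed = 1)
#' fit <- qha(ens, model$topology)
#' fit
#' coef(fit)[1:5]           # lowest quasi-harmonic frequencies, cm^-1
#' fit$entropy$S            # kcal/(mol K)
#' @export
qha <- function(ensemble, topology, temperature = 300, reference = NULL,
                tol = .lambda.rel.tol) {
  stopifnot(inherits(ensemble, "FrameEnsemble"), inherits(topology, "Topology"))
  if (topology$n_atoms != ensemble$n_atoms)
    stop("topology/ensemble atom mismatch")
  cl <- match.call()
  if (identical(ensemble$aligned_to, "none") || !is.null(reference))
    ensemble <- superpose(ensemble, reference)
  cv <- covariance_matrix(ensemble)
  spec <- qh_modes(cv, topology, temperature = temperature,
                   drop_external = TRUE, tol = tol)
  ent <- config_entropy(spec, scope = "protein")
  structure(list(covariance = cv, spectrum = spec, entropy = ent,
                 mean_structure = matrix(cv$mean, ncol = 3L, byrow = TRUE),
                 topology = topology, temperature = temperature,
                 n_frames = ensemble$n_frames, call = cl),
            class = "qha")
}

#' @export
print.qha <- function(x, ...) {
  cat("Quasi-harmonic fit:", x$topology$n_atoms, "atoms,", x$n_frames,
      "frames,", x$temperature, "K\n")
  cat("  modes retained:", length(x$spectrum$omega_ps),
      "( dropped:", x$spectrum$n_dropped, ")\n")
  cat("  S_config =", format(x$entropy$S, digits = 6), "kcal/(mol K)\n")
  invisible(x)
}

#' @export
summary.qha <- function(object, ...) {
  nu <- object$spectrum$frequencies_cm1
  pc <- pca_contributions(object$spectrum)
  out <- list(n_atoms = object$topology$n_atoms,
              n_residues = object$topology$residue_count,
              n_frames = object$n_frames,
              temperature = object$temperature,
              n_modes = length(nu), n_dropped = object$spectrum$n_dropped,
              S = object$entropy$S,
              freq_range_cm1 = range(nu),
              n_modes_90pct = pc$n_modes_to_threshold,
              freq_at_90pct_cm1 = nu[pc$n_modes_to_threshold])
  class(out) <- "summary.qha"
  out
}

#' @export
print.summary.qha <- function(x, ...) {
  cat("Quasi-harmonic model fit\n")
  cat("  system:", x$n_atoms, "atoms /", x$n_residues, "residues;",
      x$n_frames, "frames at", x$temperature, "K\n")
  cat("  modes:", x$n_modes, "retained,", x$n_dropped, "dropped (external/zero)\n")
  cat("  frequencies:", format(x$freq_range_cm1[1], digits = 4), "-",
      format(x$freq_range_cm1[2], digits = 4), "cm^-1\n")
  cat("  S_config:", format(x$S, digits = 6), "kcal/(mol K)\n")
  cat("  90% of variance in", x$n_modes_90pct, "modes (up to",
      format(x$freq_at_90pct_cm1, digits = 4), "cm^-1 )\n")
  invisible(x)
}

#' @export
coef.qha <- function(object, ...) object$spectrum$frequencies_cm1

#' Plot method: density of states of the fitted spectrum
#'
#' @param x a \code{qha} fit.
#' @param bin_width histogram bin width, cm^-1.
#' @param ... passed to \code{barplot}.
#' @export
plot.qha <- function(x, bin_width = NULL, ...) {
  nu <- x$spectrum$frequencies_cm1
  if (is.null(bin_width)) bin_width <- max(diff(range(nu)) / 30, 1e-6)
  dos <- density_of_states(x$spectrum, bin_width)
  graphics::barplot(dos$count, names.arg = signif(dos$bin_lower, 3),
                    xlab = expression(frequency ~ (cm^-1)),
                    ylab = "mode count", space = 0, ...)
  invisible(dos)
}

#' Simulate frames from a fitted quasi-harmonic model
#'
#' Draws \code{nsim} multivariate-Gaussian frames about the fitted mean with
#' the fitted mode variances, i.e. treats the quasi-harmonic fit as a
#' generative harmonic model.
#'
#' @param object a \code{qha} fit.
#' @param nsim number of frames.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A \code{FrameEnsemble} (marked aligned to the fit's mean).
#' @export
simulate.qha <- function(object, nsim = 1, seed = NULL, ...) {
  spec <- object$spectrum
  gaussian_frames(mean_flat = object$covariance$mean,
                  lambda = spec$lambda, modes = spec$modes,
                  masses = object$topology$mass, n_frames = nsim, seed = seed,
                  frame_interval = 1)
}

#' Residuals of a quasi-harmonic fit
#'
#' Per-frame deviation (RMSD, Angstrom) of the superposed frames from the
#' fitted mean structure; a direct measure of the fluctuation amplitude the
#' Gaussian model is describing.
#'
#' @param object a \code{qha} fit.
#' @param ensemble the (superposed) ensemble the model was fitted to.
#' @param ... unused.
#' @return Numeric vector of per-frame RMSDs about the mean.
#' @export
residuals.qha <- function(object, ensemble, ...) {
  stopifnot(inherits(ensemble, "FrameEnsemble"))
  rmsd_series(ensemble, object$mean_structure, fit = FALSE)$rmsd
}

#' Entropy contributions of all residues
#'
#' Applies \code{\link{residue_entropy}} to every residue of a fit (or of a
#' covariance + topology pair).
#'
#' @param fit a \code{qha} object, or a \code{CovarianceMatrix}.
#' @param topology required when \code{fit} is a covariance.
#' @param temperature K.
#' @param normalized also compute per-atom normalized entropies.
#' @return Data frame with columns \code{resid}, \code{S}, \code{n_modes},
#'   \code{n_atoms}, and (if requested) \code{S_per_atom}.
#' @export
residue_entropies <- function(fit, topology = NULL, temperature = NULL,
                              normalized = FALSE) {
  if (inherits(fit, "qha")) {
    cov <- fit$covariance
    topology <- fit$topology
    if (is.null(temperature)) temperature <- fit$temperature
  } else {
    cov <- fit
    if (is.null(topology)) stop("'topology' required with a covariance input")
    if (is.null(temperature)) temperature <- 300
  }
  rows <- lapply(seq_len(topology$residue_count), function(r) {
    er <- residue_entropy(cov, topology, r, temperature = temperature)
    m <- length(residue_atoms(topology, r))
    data.frame(resid = r, S = er$S, n_modes = er$n_modes_used, n_atoms = m)
  })
  out <- do.call(rbind, rows)
  if (normalized) out$S_per_atom <- out$S / out$n_atoms
  out
}
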