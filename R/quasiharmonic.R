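#' Quasi-harmonic modes from a coordinate covariance
#'
#' Extracts effective vibrational modes of the sampled fluctuation
#' distribution.  The force-constant matrix on the effective harmonic
#' potential is \eqn{F = k_B T\, C^{-1}} and the mode frequencies solve the
#' secular equation \eqn{\det(F - \omega^2 M) = 0}.  Numerically this is done
#' by diagonalizing the mass-weighted covariance
#' \eqn{\sigma = M^{1/2} C M^{1/2}}: its eigenvalues \eqn{\lambda_k} give
#' \eqn{\omega_k = \sqrt{k_B T / \lambda_k}} and its eigenvectors are the
#' modes, which avoids inverting the (typically rank-deficient) covariance.
#' The two routes are mathematically equivalent on full-rank input, a fact the
#' test suite asserts rather than assumes.
#'
#' @param cov a \code{CovarianceMatrix} (whole system or residue sub-block).
#' @param topology matching \code{Topology}, or a numeric vector of per-atom
#'   masses (amu).
#' @param temperature temperature in K (default 300, the usual simulation
#'   temperature).
#' @param drop_external for whole-system scope the 6 lowest-\eqn{\lambda}
#'   retained modes (the residual external translations/rotations left after
#'   least-squares fitting) are dropped even when above tolerance, leaving
#'   3n-6 modes (default \code{TRUE}); residue sub-blocks, which are never
#'   re-aligned, keep all above-tolerance modes (\code{FALSE}).
#' @param tol relative eigenvalue tolerance: modes with
#'   \eqn{\lambda < tol \cdot \lambda_{max}} are treated as numerically zero
#'   and dropped.
#' @return Object of class \code{"QHSpectrum"}: \code{frequencies_cm1}
#'   (ascending), \code{omega_ps} (rad/ps), \code{lambda} (amu Angstrom^2,
#'   descending, i.e. matching the frequency order), \code{modes} (3n x k,
#'   orthonormal, mass-weighted coordinates, column k belongs to frequency k),
#'   \code{temperature}, \code{n_dropped}, \code{masses}.
#' @export
qh_modes <- function(cov, topology, temperature = 300,
                     drop_external = TRUE, tol = .lambda.rel.tol) {
  stopifnot(inherits(cov, "CovarianceMatrix"))
  masses <- if (inherits(topology, "Topology")) topology$mass else as.numeric(topology)
  if (length(masses) != cov$n_atoms) stop("mass vector does not match covariance size")
  if (any(masses <= 0)) stop("masses must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  sm <- rep(sqrt(masses), each = 3L)
  sigma <- cov$matrix * tcrossprod(sm)      # M^1/2 C M^1/2
  eg <- eigen(sigma, symmetric = TRUE)      # eigenvalues descending
  lam <- eg$values
  lmax <- max(lam, 0)
  if (lmax <= 0) stop("all covariance eigenvalues are zero or negative")
  if (min(lam) < -tol * lmax)
    stop("covariance has a significantly negative eigenvalue: not PSD")
  keep <- lam >= tol * lmax
  if (drop_external) {
    # whole-system scope retains exactly 3n-6 modes: the 6 external
    # translations/rotations are near-zero after fitting and fall below
    # tolerance on clean input, but are dropped here even when they survive
    # the tolerance cut (e.g. full-rank toy covariances)
    target <- 3L * length(masses) - 6L
    if (target < 1L) stop("need at least 3 atoms for 3n-6 internal modes")
    n_extra <- sum(keep) - target
    if (n_extra > 0L) {
      kept_idx <- which(keep)
      keep[kept_idx[(length(kept_idx) - n_extra + 1L):length(kept_idx)]] <- FALSE
    }
  }
  if (!any(keep)) stop("no modes above tolerance")
  lam_k <- lam[keep]
  modes <- eg$vectors[, keep, drop = FALSE]
  omega <- sqrt(.kB.int * temperature / lam_k)   # rad/ps, ascending
  # deterministic sign: largest-magnitude component positive
  for (k in seq_len(ncol(modes))) {
    j <- which.max(abs(modes[, k]))
    if (modes[j, k] < 0) modes[, k] <- -modes[, k]
  }
  structure(list(frequencies_cm1 = omega * .omega.to.cm1,
                 omega_ps = omega, lambda = lam_k, modes = modes,
                 temperature = temperature, n_dropped = sum(!keep),
                 masses = masses),
            class = "QHSpectrum")
}

#' @export
print.QHSpectrum <- function(x, ...) {
  cat("QHSpectrum:", length(x$omega_ps), "modes (", x$n_dropped, "dropped ) at",
      x$temperature, "K; frequencies",
      format(min(x$frequencies_cm1), digits = 4), "-",
      format(max(x$frequencies_cm1), digits = 4), "cm^-1\n")
  invisible(x)
}

# spectrum constructed directly from known frequencies (synthetic models, tests)
spectrum_from_omega <- function(omega_ps, modes = NULL, temperature = 300,
                                masses = NULL, n_dropped = 0L) {
  o <- sort(omega_ps)
  structure(list(frequencies_cm1 = o * .omega.to.cm1, omega_ps = o,
                 lambda = .kB.int * temperature / o^2,
                 modes = modes, temperature = temperature,
                 n_dropped = n_dropped, masses = masses),
            class = "QHSpectrum")
}

#' Quantum-harmonic-oscillator configurational entropy of a mode spectrum
#'
#' \deqn{S = k_B \sum_i \left[\frac{x_i}{e^{x_i}-1} - \ln(1-e^{-x_i})\right],
#' \quad x_i = \hbar\omega_i / k_B T,}
#' summed over the retained quasi-harmonic modes (3n-6 for a whole protein).
#' This is exact for a harmonic system and an approximation of the
#' configurational entropy within the harmonic limit.
#'
#' @param spectrum a \code{QHSpectrum}.
#' @param scope descriptor stored in the result (\code{"protein"} or a residue
#'   id).
#' @return Object of class \code{"EntropyResult"}: \code{S} in kcal/(mol K),
#'   \code{n_modes_used}, \code{temperature}, \code{scope},
#'   \code{normalized_per_atom} (NULL until normalized).
#' @export
config_entropy <- function(spectrum, scope = "protein") {
  stopifnot(inherits(spectrum, "QHSpectrum"))
  omega <- spectrum$omega_ps
  if (!length(omega)) stop("empty spectrum")
  if (any(omega <= 0)) stop("non-positive frequency in retained modes")
  x <- .hbar.int * omega / (.kB.int * spectrum$temperature)
  s_modes <- x / expm1(x) - log1p(-exp(-x))
  structure(list(S = .kB.kcal * sum(s_modes), n_modes_used = length(omega),
                 temperature = spectrum$temperature, scope = scope,
                 normalized_per_atom = NULL),
            class = "EntropyResult")
}

#' @export
print.EntropyResult <- function(x, ...) {
  cat("Configurational entropy (", x$scope, "): S =",
      format(x$S, digits = 6), "kcal/(mol K) from", x$n_modes_used,
      "modes at", x$temperature, "K\n")
  if (!is.null(x$normalized_per_atom))
    cat("  per atom:", format(x$normalized_per_atom, digits = 6),
        "kcal/(mol K atom)\n")
  invisible(x)
}

#' Entropy contribution of one residue
#'
#' Applies the quasi-harmonic machinery to the residue's \code{3m x 3m}
#' sub-covariance block.  All above-tolerance modes of the block are retained
#' (no 6-mode removal: the subsystem is not re-aligned, so its rigid-body
#' motion within the protein frame is genuine fluctuation).  Correlation
#' entropy between the residue and the rest of the system is excluded by
#' construction.
#'
#' @param cov whole-system \code{CovarianceMatrix}.
#' @param topology matching \code{Topology}.
#' @param resid residue index.
#' @param temperature K.
#' @param drop_external drop 6 external modes of the block as well
#'   (default \code{FALSE}; see Details in \code{\link{qh_modes}}).
#' @return An \code{EntropyResult} with \code{scope = resid}; a singular
#'   (frozen) block yields \code{S = 0} with a warning.
#' @export
residue_entropy <- function(cov, topology, resid, temperature = 300,
                            drop_external = FALSE) {
  sub <- residue_submatrix(cov, topology, resid)
  atoms <- residue_atoms(topology, resid)
  spec <- tryCatch(
    qh_modes(sub, topology$mass[atoms], temperature = temperature,
             drop_external = drop_external),
    error = function(e) {
      if (grepl("zero or negative|no modes above tolerance", conditionMessage(e)))
        NULL
      else stop(e)
    })
  if (is.null(spec)) {
    warning("residue ", resid, ": no modes above tolerance; S = 0")
    return(structure(list(S = 0, n_modes_used = 0L, temperature = temperature,
                          scope = resid, normalized_per_atom = NULL),
                     class = "EntropyResult"))
  }
  config_entropy(spec, scope = resid)
}

#' Normalize a residue entropy by its atom count
#'
#' @param result an \code{EntropyResult} with residue scope.
#' @param topology matching \code{Topology}.
#' @return The result with \code{normalized_per_atom = S / m_atoms} filled in.
#' @export
normalize_residue_entropy <- function(result, topology) {
  stopifnot(inherits(result, "EntropyResult"))
  if (identical(result$scope, "protein"))
    stop("normalization is defined for residue scope")
  m <- length(residue_atoms(topology, result$scope))
  result$normalized_per_atom <- result$S / m
  result
}

#' Density of states of a quasi-harmonic spectrum
#'
#' Histogram of retained mode frequencies; bin edges start at 0.
#'
#' @param spectrum a \code{QHSpectrum}.
#' @param bin_width bin width in cm^-1.
#' @return Data frame with \code{bin_lower}, \code{bin_upper}, \code{count};
#'   counts sum to the number of retained modes.
#' @export
density_of_states <- function(spectrum, bin_width) {
  stopifnot(inherits(spectrum, "QHSpectrum"))
  if (!is.numeric(bin_width) || bin_width <= 0) stop("'bin_width' must be positive")
  nu <- spectrum$frequencies_cm1
  edges <- seq(0, by = bin_width, length.out = ceiling(max(nu) / bin_width) + 1L)
  if (max(edges) <= max(nu)) edges <- c(edges, max(edges) + bin_width)
  h <- hist(nu, breaks = edges, plot = FALSE)
  data.frame(bin_lower = utils::head(edges, -1L), bin_upper = utils::tail(edges, -1L),
             count = h$counts)
}

#' Persist / restore a quasi-harmonic spectrum (CSV + JSON-free plain text)
#'
#' Writes frequencies and modes as CSV with a small header carrying the
#' temperature and drop count.
#'
#' @param spectrum a \code{QHSpectrum}.
#' @param file output path (CSV).
#' @return \code{file} invisibly (\code{write_spectrum}); a \code{QHSpectrum}
#'   (\code{read_spectrum}).
#' @export
write_spectrum <- function(spectrum, file) {
  stopifnot(inherits(spectrum, "QHSpectrum"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste0("# temperature_K,", spectrum$temperature),
               paste0("# n_dropped,", spectrum$n_dropped)), con)
  df <- data.frame(frequency_cm1 = spectrum$frequencies_cm1,
                   lambda_amuA2 = spectrum$lambda)
  if (!is.null(spectrum$modes))
    df <- cbind(df, as.data.frame(spectrum$modes))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(file) {
  hdr <- readLines(file, n = 2L)
  temperature <- as.numeric(sub("# temperature_K,", "", hdr[1], fixed = TRUE))
  n_dropped <- as.integer(sub("# n_dropped,", "", hdr[2], fixed = TRUE))
  df <- utils::read.csv(file, skip = 2L)
  modes <- if (ncol(df) > 2L) as.matrix(df[, -(1:2), drop = FALSE]) else NULL
  if (!is.null(modes)) dimnames(modes) <- NULL
  omega <- df$frequency_cm1 / .omega.to.cm1
  spectrum_from_omega(omega, modes = modes, temperature = temperature,
                      n_dropped = n_dropped)
}
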