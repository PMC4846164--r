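#' Coordinate covariance matrix of a superposed ensemble
#'
#' Builds the \code{3N x 3N} covariance of Cartesian coordinates over frames,
#' two-pass (mean, then deviations) with the population divisor \code{F}.
#' Because frames must be least-squares fitted first, overall translation and
#' rotation are projected out, leaving (at least) six near-zero eigenvalues.
#'
#' @param ensemble a superposed \code{FrameEnsemble} with at least 2 frames.
#' @return Object of class \code{"CovarianceMatrix"}: list with \code{matrix}
#'   (3N x 3N, Angstrom^2), \code{mean} (3N mean coordinates), \code{n_atoms},
#'   \code{n_frames_used}, \code{aligned}.
#' @export
covariance_matrix <- function(ensemble) {
  stopifnot(inherits(ensemble, "FrameEnsemble"))
  if (identical(ensemble$aligned_to, "none"))
    stop("covariance requires a superposed ensemble")
  if (ensemble$n_frames < 2L) stop("need at least 2 frames")
  xyz <- ensemble_xyz(ensemble)
  mu <- colMeans(xyz)
  xc <- sweep(xyz, 2L, mu)
  cv <- crossprod(xc) / nrow(xc)
  cv <- (cv + t(cv)) / 2
  structure(list(matrix = cv, mean = mu, n_atoms = ensemble$n_atoms,
                 n_frames_used = ensemble$n_frames, aligned = TRUE),
            class = "CovarianceMatrix")
}

# wrap an externally built covariance (synthetic models, sub-blocks)
as_covariance <- function(mat, mean = NULL, n_frames = NA_integer_, aligned = TRUE) {
  mat <- (mat + t(mat)) / 2
  structure(list(matrix = mat, mean = mean, n_atoms = nrow(mat) / 3L,
                 n_frames_used = n_frames, aligned = aligned),
            class = "CovarianceMatrix")
}

#' @export
print.CovarianceMatrix <- function(x, ...) {
  cat("CovarianceMatrix:", nrow(x$matrix), "x", ncol(x$matrix),
      "(", x$n_atoms, "atoms ), from", x$n_frames_used, "frames\n")
  invisible(x)
}

#' Normalized cross-correlation matrix
#'
#' Per-atom-pair normalized covariance
#' \eqn{C_{ij} = (\langle r_i\cdot r_j\rangle - \langle r_i\rangle\cdot\langle
#' r_j\rangle) / \sqrt{(\langle r_i^2\rangle-\langle r_i\rangle^2)(\langle
#' r_j^2\rangle-\langle r_j\rangle^2)}}, i.e. the trace of the 3x3 cross block
#' over geometric-mean variances.  +1 is fully correlated motion, -1 fully
#' anti-correlated, 0 uncorrelated or motion along orthogonal directions.
#'
#' @param cov a \code{CovarianceMatrix}.
#' @param topology matching \code{Topology}.
#' @param subset atom selection: \code{"calpha"} (atoms named \code{"CA"};
#'   default when atom names are available), \code{"all"}, or an integer vector
#'   of atom indices.
#' @return Object of class \code{"CrossCorrelationMatrix"}: list with
#'   \code{matrix} (M x M), \code{atoms} (indices used).  Atoms with variance
#'   below the zero tolerance give \code{NA} rows/columns with a warning.
#' @export
cross_correlation <- function(cov, topology, subset = NULL) {
  stopifnot(inherits(cov, "CovarianceMatrix"), inherits(topology, "Topology"))
  if (topology$n_atoms != cov$n_atoms) stop("topology/covariance atom mismatch")
  atoms <- resolve_subset(topology, subset)
  m <- length(atoms)
  tr <- function(i, j) {
    ii <- 3L * (i - 1L); jj <- 3L * (j - 1L)
    cov$matrix[ii + 1L, jj + 1L] + cov$matrix[ii + 2L, jj + 2L] +
      cov$matrix[ii + 3L, jj + 3L]
  }
  v <- vapply(atoms, function(i) tr(i, i), numeric(1))
  dead <- v < .zero.var.tol
  if (any(dead))
    warning(sum(dead), " atom(s) with (near-)zero variance: correlations set to NA")
  cc <- matrix(NA_real_, m, m)
  for (a in seq_len(m)) {
    if (dead[a]) next
    for (b in a:m) {
      if (dead[b]) next
      cc[a, b] <- cc[b, a] <- tr(atoms[a], atoms[b]) / sqrt(v[a] * v[b])
    }
  }
  structure(list(matrix = cc, atoms = atoms),
            class = "CrossCorrelationMatrix")
}

resolve_subset <- function(topology, subset) {
  if (is.null(subset)) {
    subset <- if (!is.null(topology$name) && any(topology$name == "CA"))
      "calpha" else "all"
  }
  if (is.numeric(subset)) {
    atoms <- as.integer(subset)
    if (any(atoms < 1L | atoms > topology$n_atoms)) stop("atom subset out of range")
    return(atoms)
  }
  switch(match.arg(subset, c("calpha", "all")),
         all = seq_len(topology$n_atoms),
         calpha = {
           if (is.null(topology$name)) stop("topology has no atom names; cannot select C-alpha")
           a <- which(topology$name == "CA")
           if (!length(a)) stop("no C-alpha atoms in topology")
           a
         })
}

#' Per-residue sub-covariance block
#'
#' Restricts the whole-system covariance to the rows/columns of one residue's
#' atoms (backbone and side chain).  No re-alignment of the subsystem is
#' performed, and cross-terms to the rest of the system are excluded: the
#' block quantifies only the residue's own fluctuation as embedded in the
#' full-system frame.
#'
#' @param cov a \code{CovarianceMatrix}.
#' @param topology matching \code{Topology}.
#' @param resid residue index.
#' @return A \code{CovarianceMatrix} of size \code{3m x 3m} for the residue's
#'   m atoms.
#' @export
residue_submatrix <- function(cov, topology, resid) {
  stopifnot(inherits(cov, "CovarianceMatrix"))
  atoms <- residue_atoms(topology, resid)
  idx <- coord_indices(atoms)
  as_covariance(cov$matrix[idx, idx, drop = FALSE],
                mean = cov$mean[idx], n_frames = cov$n_frames_used,
                aligned = cov$aligned)
}

#' Write a matrix object to CSV
#'
#' @param x a \code{CovarianceMatrix}, \code{CrossCorrelationMatrix}, or plain
#'   matrix.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_matrix_csv <- function(x, file) {
  m <- if (is.matrix(x)) x else x$matrix
  utils::write.table(m, file, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(file)
}
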