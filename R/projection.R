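#' Per-mode variance contributions
#'
#' Fraction of the total (internal) fluctuation variance carried by each
#' retained quasi-harmonic mode, the cumulative contribution, and the number
#' of modes needed to reach a threshold (default 90%).  Translational and
#' rotational modes are already excluded from a whole-system spectrum.
#'
#' @param spectrum a \code{QHSpectrum}.
#' @param threshold cumulative-variance threshold in (0, 1].
#' @return List with \code{fractions} (descending variance order, i.e.
#'   ascending frequency), \code{cumulative}, \code{n_modes_to_threshold}.
#' @export
pca_contributions <- function(spectrum, threshold = 0.90) {
  stopifnot(inherits(spectrum, "QHSpectrum"))
  lam <- spectrum$lambda
  if (!length(lam)) stop("empty spectrum")
  frac <- lam / sum(lam)      # lambda stored descending
  cum <- cumsum(frac)
  list(fractions = frac, cumulative = cum,
       n_modes_to_threshold = which(cum >= threshold - 1e-12)[1L])
}

#' Project frames onto quasi-harmonic modes
#'
#' \eqn{p_k(t) = v_k \cdot M^{1/2} (x(t) - \bar x)}: mass-weighted
#' displacement of each frame from the mean, projected on orthonormal mode
#' vectors.  Frames must be superposed to the same reference used for the
#' covariance, so translation and rotation are projected out.
#'
#' @param ensemble a superposed \code{FrameEnsemble}.
#' @param spectrum a \code{QHSpectrum} carrying masses and modes.
#' @param mode_ids which modes (columns) to project on; default PC1.
#' @param mean_flat 3N mean coordinates defining the origin; default the
#'   ensemble's own mean.
#' @return \code{F x k} matrix of projections (amu^1/2 Angstrom).
#' @export
project_frames <- function(ensemble, spectrum, mode_ids = 1L, mean_flat = NULL) {
  stopifnot(inherits(ensemble, "FrameEnsemble"), inherits(spectrum, "QHSpectrum"))
  if (is.null(spectrum$modes)) stop("spectrum carries no mode vectors")
  xyz <- ensemble_xyz(ensemble)
  if (ncol(xyz) != nrow(spectrum$modes)) stop("ensemble/mode dimension mismatch")
  if (is.null(mean_flat)) mean_flat <- colMeans(xyz)
  sm <- rep(sqrt(spectrum$masses), each = 3L)
  xc <- sweep(xyz, 2L, mean_flat)
  xw <- sweep(xc, 2L, sm, `*`)
  xw %*% spectrum$modes[, mode_ids, drop = FALSE]
}

#' Signed and unsigned overlaps between two mode sets
#'
#' Dot products between the columns of two orthonormal mode matrices.  The
#' sign of an eigenvector is arbitrary, so per-mode summaries use \code{|dot|}.
#'
#' @param modes_a,modes_b \code{3N x k} matrices of unit-norm columns.
#' @return Object of class \code{"ModeOverlapReport"}: \code{dot_matrix}
#'   (|A| x |B| signed), \code{unsigned_diag} (per-mode \code{|dot|} of
#'   matched columns, length \code{min(kA, kB)}).
#' @export
mode_overlap <- function(modes_a, modes_b) {
  modes_a <- as.matrix(modes_a); modes_b <- as.matrix(modes_b)
  if (nrow(modes_a) != nrow(modes_b)) stop("mode sets have different dimension")
  chk <- function(m, lab) {
    nrm <- sqrt(colSums(m^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("columns of ", lab, " are not unit-norm")
  }
  chk(modes_a, "modes_a"); chk(modes_b, "modes_b")
  dm <- crossprod(modes_a, modes_b)
  k <- min(ncol(modes_a), ncol(modes_b))
  structure(list(dot_matrix = dm,
                 unsigned_diag = abs(dm[cbind(seq_len(k), seq_len(k))])),
            class = "ModeOverlapReport")
}

#' @export
print.ModeOverlapReport <- function(x, ...) {
  cat("ModeOverlapReport:", nrow(x$dot_matrix), "x", ncol(x$dot_matrix),
      "signed dot products; |diag| =",
      paste(format(x$unsigned_diag, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Mode coherence across trajectory blocks
#'
#' Validates the physical significance of low-frequency modes: for each of the
#' k lowest-frequency modes, the unsigned dot product between every block
#' spectrum and the full-trajectory spectrum is computed, and summarized as a
#' per-mode mean and SD.  Also returns the all-pairs block-by-block PC1
#' overlap matrix.
#'
#' @param block_spectra list of \code{QHSpectrum}, one per trajectory block
#'   (at least 2).
#' @param full_spectrum \code{QHSpectrum} of the concatenated trajectory.
#' @param k_modes number of low-frequency modes to compare (default 5).
#' @return List with \code{per_mode} (data frame: \code{mode},
#'   \code{unsigned_mean}, \code{unsigned_sd}), \code{block_dots}
#'   (blocks x k matrix of |dot| against the full spectrum) and
#'   \code{pc1_pairs} (blocks x blocks signed PC1 dot matrix).
#' @export
coherence_check <- function(block_spectra, full_spectrum, k_modes = 5L) {
  if (length(block_spectra) < 2L) stop("need at least 2 blocks")
  dim_of <- function(s) nrow(s$modes)
  d <- dim_of(full_spectrum)
  if (any(vapply(block_spectra, dim_of, 0) != d))
    stop("blocks have differing atom sets")
  k_modes <- min(k_modes, ncol(full_spectrum$modes),
                 min(vapply(block_spectra, function(s) ncol(s$modes), 0L)))
  bd <- t(vapply(block_spectra, function(s) {
    abs(colSums(s$modes[, seq_len(k_modes), drop = FALSE] *
                  full_spectrum$modes[, seq_len(k_modes), drop = FALSE]))
  }, numeric(k_modes)))
  if (k_modes == 1L) bd <- matrix(bd, ncol = 1L)
  pc1 <- vapply(block_spectra, function(s) s$modes[, 1L], numeric(d))
  list(per_mode = data.frame(mode = seq_len(k_modes),
                             unsigned_mean = colMeans(bd),
                             unsigned_sd = apply(bd, 2L, stats::sd)),
       block_dots = bd,
       pc1_pairs = crossprod(pc1))
}

#' Project an ensemble onto two state-specific PC1 axes
#'
#' Maps every frame to its (mass-weighted) displacement components along two
#' PC1 vectors -- typically the first quasi-harmonic modes of the unbound and
#' bound reference runs.  The axes are used as-is (raw oblique projection, no
#' re-orthogonalization), about a stated common mean.
#'
#' @param ensemble a superposed \code{FrameEnsemble}.
#' @param axis_a,axis_b unit-norm 3N vectors (mass-weighted coordinates).
#' @param common_mean 3N reference mean coordinates (flat); typically the mean
#'   structure of the unperturbed reference state.
#' @param masses per-atom masses (amu).
#' @param state_label,run_id metadata carried in the result.
#' @param mass_weighted project in mass-weighted coordinates (default) or
#'   plain Cartesian.
#' @return Object of class \code{"ProjectionCloud"}: \code{points} (F x 2),
#'   \code{state_label}, \code{run_id}, \code{axis_dot} (signed dot of the two
#'   axes, documenting their obliquity).
#' @export
project_2d <- function(ensemble, axis_a, axis_b, common_mean, masses,
                       state_label = NA_character_, run_id = NA_character_,
                       mass_weighted = TRUE) {
  stopifnot(inherits(ensemble, "FrameEnsemble"))
  axis_a <- as.numeric(axis_a); axis_b <- as.numeric(axis_b)
  for (ax in list(axis_a, axis_b))
    if (abs(sqrt(sum(ax^2)) - 1) > 1e-6) stop("axes must be unit-norm")
  xyz <- ensemble_xyz(ensemble)
  if (ncol(xyz) != length(axis_a) || length(axis_a) != length(axis_b))
    stop("axis/ensemble dimension mismatch")
  xc <- sweep(xyz, 2L, as.numeric(common_mean))
  if (mass_weighted) xc <- sweep(xc, 2L, rep(sqrt(masses), each = 3L), `*`)
  structure(list(points = cbind(a = xc %*% axis_a, b = xc %*% axis_b),
                 state_label = state_label, run_id = run_id,
                 axis_dot = sum(axis_a * axis_b)),
            class = "ProjectionCloud")
}

#' Distance between two projected ensembles
#'
#' Separation of two clouds in the 2D PC1-PC1 chart.  The default is the
#' Euclidean distance between cloud centroids; \code{method = "mode"} instead
#' uses the distance between the peaks of 2D histograms (density-mode
#' variant).
#'
#' @param cloud_a,cloud_b \code{ProjectionCloud}s on the same axes.
#' @param method \code{"centroid"} (default) or \code{"mode"}.
#' @param nbins histogram bins per axis for \code{method = "mode"}.
#' @return Scalar distance (same units as the projections).
#' @export
distribution_distance <- function(cloud_a, cloud_b,
                                  method = c("centroid", "mode"), nbins = 25L) {
  stopifnot(inherits(cloud_a, "ProjectionCloud"), inherits(cloud_b, "ProjectionCloud"))
  method <- match.arg(method)
  pa <- cloud_a$points; pb <- cloud_b$points
  if (!nrow(pa) || !nrow(pb)) stop("empty projection cloud")
  if (method == "centroid") {
    sqrt(sum((colMeans(pa) - colMeans(pb))^2))
  } else {
    peak <- function(p) {
      rng_x <- range(pa[, 1], pb[, 1]); rng_y <- range(pa[, 2], pb[, 2])
      bx <- seq(rng_x[1], rng_x[2], length.out = nbins + 1L)
      by <- seq(rng_y[1], rng_y[2], length.out = nbins + 1L)
      ix <- pmin(pmax(findInterval(p[, 1], bx, all.inside = TRUE), 1L), nbins)
      iy <- pmin(pmax(findInterval(p[, 2], by, all.inside = TRUE), 1L), nbins)
      h <- table(factor(ix, levels = seq_len(nbins)),
                 factor(iy, levels = seq_len(nbins)))
      w <- which(h == max(h), arr.ind = TRUE)[1L, ]
      c((bx[w[1]] + bx[w[1] + 1L]) / 2, (by[w[2]] + by[w[2] + 1L]) / 2)
    }
    sqrt(sum((peak(pa) - peak(pb))^2))
  }
}

#' Export a projection cloud as tidy CSV
#'
#' @param cloud a \code{ProjectionCloud}.
#' @param file output path.
#' @param frame_interval spacing of the projected frames, ps (for the time
#'   column); default 1.
#' @return \code{file}, invisibly.
#' @export
write_cloud_csv <- function(cloud, file, frame_interval = 1) {
  df <- data.frame(run_id = cloud$run_id, state = cloud$state_label,
                   t_ps = seq_len(nrow(cloud$points)) * frame_interval,
                   pc1_a = cloud$points[, 1], pc1_b = cloud$points[, 2])
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
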