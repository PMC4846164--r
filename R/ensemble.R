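#' Conformational frame ensemble
#'
#' Holds F frames of N-atom Cartesian coordinates (Angstrom) with timing
#' metadata.  Frames are stored as an \code{F x N x 3} array; frame f is taken
#' to sit at time \code{origin_time_ns * 1000 + f * frame_interval} ps.
#'
#' @param coords numeric array \code{F x N x 3} (or a single \code{N x 3}
#'   matrix, promoted to one frame).
#' @param frame_interval spacing between stored frames, ps.
#' @param origin_time time offset of the ensemble start, ns (default 0).
#' @param aligned_to character descriptor of the superposition reference, or
#'   \code{"none"} if frames are not superposed.
#' @return Object of class \code{"FrameEnsemble"}.
#' @export
frame_ensemble <- function(coords, frame_interval, origin_time = 0,
                           aligned_to = "none") {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  d <- dim(coords)
  if (length(d) != 3L || d[3] != 3L)
    stop("'coords' must be an F x N x 3 array")
  if (d[1] < 1L) stop("ensemble needs at least one frame")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("'frame_interval' must be positive (ps)")
  structure(list(coords = coords, frame_interval = frame_interval,
                 origin_time = origin_time, aligned_to = aligned_to,
                 n_frames = d[1], n_atoms = d[2]),
            class = "FrameEnsemble")
}

#' @export
print.FrameEnsemble <- function(x, ...) {
  cat("FrameEnsemble:", x$n_frames, "frames x", x$n_atoms, "atoms;",
      x$frame_interval, "ps spacing; aligned to:", x$aligned_to, "\n")
  invisible(x)
}

# F x 3N matrix in x1 y1 z1 x2 ... order (bio3d xyz convention)
ensemble_xyz <- function(ensemble) {
  d <- dim(ensemble$coords)
  m <- matrix(aperm(ensemble$coords, c(3L, 2L, 1L)), nrow = d[1], byrow = TRUE)
  m
}

xyz_to_coords <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  f <- nrow(xyz); n <- ncol(xyz) / 3L
  aperm(array(t(xyz), dim = c(3L, n, f)), c(3L, 2L, 1L))
}

# minimum RMSD over rotations+translations (Kabsch, proper rotations only)
kabsch_rmsd <- function(ref, mob) {
  a <- sweep(ref, 2L, colMeans(ref))
  b <- sweep(mob, 2L, colMeans(mob))
  sv <- svd(crossprod(a, b))
  s <- sv$d
  if (det(sv$u %*% t(sv$v)) < 0) s[3L] <- -s[3L]
  msd <- (sum(a^2) + sum(b^2) - 2 * sum(s)) / nrow(ref)
  sqrt(max(msd, 0))
}

single_frame <- function(x) {
  if (inherits(x, "FrameEnsemble")) {
    if (x$n_frames != 1L) stop("expected a single-frame reference")
    x <- x$coords[1L, , , drop = TRUE]
  }
  if (!is.matrix(x) || ncol(x) != 3L) stop("reference must be an N x 3 matrix")
  x
}

#' Discard equilibration and subsample an ensemble
#'
#' Keeps frames strictly after the discard window, sampled every
#' \code{interval} ps; the first retained frame sits at
#' \code{discard_ns + interval} (half-open window convention), so a 30 ns
#' production window at 2 ps spacing yields exactly 15,000 frames.
#'
#' @param ensemble a \code{FrameEnsemble}.
#' @param discard_ns length of the initial window to drop, ns.
#' @param interval_ps sampling interval, ps; must be a positive multiple of the
#'   stored frame spacing.
#' @return A \code{FrameEnsemble} of the retained frames, with
#'   \code{origin_time} advanced by the discarded duration.
#' @export
select_frames <- function(ensemble, discard_ns, interval_ps) {
  stopifnot(inherits(ensemble, "FrameEnsemble"))
  dt <- ensemble$frame_interval
  total_ps <- ensemble$n_frames * dt
  discard_ps <- discard_ns * 1000
  if (discard_ps >= total_ps)
    stop("discard window (", discard_ns, " ns) leaves no frames from ",
         total_ps / 1000, " ns")
  stride <- interval_ps / dt
  if (interval_ps <= 0 || abs(stride - round(stride)) > 1e-9)
    stop("interval (", interval_ps, " ps) is not a positive multiple of the ",
         "stored frame spacing (", dt, " ps)")
  stride <- as.integer(round(stride))
  first_ps <- discard_ps + interval_ps
  first_idx <- first_ps / dt
  if (abs(first_idx - round(first_idx)) > 1e-9)
    stop("discard window is not commensurate with the stored frame spacing")
  idx <- seq(as.integer(round(first_idx)), ensemble$n_frames, by = stride)
  frame_ensemble(ensemble$coords[idx, , , drop = FALSE],
                 frame_interval = interval_ps,
                 origin_time = ensemble$origin_time + discard_ns,
                 aligned_to = ensemble$aligned_to)
}

#' Least-squares superposition onto a reference frame
#'
#' Removes rigid-body translation and rotation of every frame by an unweighted
#' all-atom least-squares fit to the reference (via \code{bio3d::fit.xyz}).
#'
#' @param ensemble a \code{FrameEnsemble}.
#' @param reference an \code{N x 3} matrix or single-frame ensemble; defaults
#'   to the first frame.
#' @param label descriptor stored in \code{aligned_to}.
#' @return The superposed \code{FrameEnsemble}.
#' @export
superpose <- function(ensemble, reference = NULL, label = NULL) {
  stopifnot(inherits(ensemble, "FrameEnsemble"))
  if (is.null(reference)) {
    reference <- ensemble$coords[1L, , , drop = TRUE]
    if (is.null(label)) label <- "first_frame"
  }
  ref <- single_frame(reference)
  if (nrow(ref) != ensemble$n_atoms)
    stop("reference atom count (", nrow(ref), ") does not match ensemble (",
         ensemble$n_atoms, ")")
  cen <- sweep(ref, 2L, colMeans(ref))
  if (nrow(ref) < 3L || qr(cen)$rank < 2L)
    stop("superposition undefined: fewer than 3 non-collinear atoms")
  xyz <- ensemble_xyz(ensemble)
  inds <- seq_len(3L * nrow(ref))
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(ref)), mobile = xyz,
                           fixed.inds = inds, mobile.inds = inds)
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1L)
  frame_ensemble(xyz_to_coords(fitted),
                 frame_interval = ensemble$frame_interval,
                 origin_time = ensemble$origin_time,
                 aligned_to = if (is.null(label)) "reference" else label)
}

#' Per-frame RMSD against a reference structure
#'
#' Best-fit (rotation + translation, unweighted) RMSD
#' \eqn{R = \sqrt{\sum_i |r_i^0 - U r_i|^2 / N}} for every frame.
#'
#' @inheritParams superpose
#' @param fit superpose each frame before measuring (default \code{TRUE});
#'   with \code{FALSE} the raw coordinate RMSD is returned.
#' @return Data frame with columns \code{frame_time_ps} and \code{rmsd}.
#' @export
rmsd_series <- function(ensemble, reference = NULL, fit = TRUE) {
  stopifnot(inherits(ensemble, "FrameEnsemble"))
  if (is.null(reference)) reference <- ensemble$coords[1L, , , drop = TRUE]
  ref <- single_frame(reference)
  if (nrow(ref) != ensemble$n_atoms) stop("reference atom count mismatch")
  xyz <- ensemble_xyz(ensemble)
  r <- if (fit) {
    # per-frame best-fit minimum via the SVD closed form, which stays defined
    # for the degenerate (< 3 atoms or collinear) cases that strict
    # superposition refuses
    apply(xyz, 1L, function(fr)
      kabsch_rmsd(ref, matrix(fr, ncol = 3L, byrow = TRUE)))
  } else {
    dev2 <- sweep(xyz, 2L, as.vector(t(ref)))^2
    sqrt(rowSums(dev2) / ensemble$n_atoms)
  }
  t_ps <- ensemble$origin_time * 1000 + seq_len(ensemble$n_frames) * ensemble$frame_interval
  data.frame(frame_time_ps = t_ps, rmsd = r)
}

#' Average structure of a superposed ensemble
#'
#' @param ensemble a superposed \code{FrameEnsemble} (the per-atom mean of
#'   unaligned frames is meaningless and is refused).
#' @return An \code{N x 3} matrix of mean coordinates.
#' @export
average_structure <- function(ensemble) {
  stopifnot(inherits(ensemble, "FrameEnsemble"))
  if (identical(ensemble$aligned_to, "none"))
    stop("ensemble is not superposed; call superpose() first")
  colMeans(ensemble$coords, dims = 1L)
}

#' Read an ensemble from a multi-model PDB file
#'
#' @param file path to a PDB with one MODEL per frame.
#' @param frame_interval frame spacing, ps.
#' @param origin_time start offset, ns.
#' @return A \code{FrameEnsemble}.
#' @export
read_ensemble_pdb <- function(file, frame_interval, origin_time = 0) {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  frame_ensemble(xyz_to_coords(pdb$xyz), frame_interval, origin_time)
}

#' Read an ensemble from a DCD trajectory
#'
#' @param file path to a DCD file.
#' @inheritParams read_ensemble_pdb
#' @return A \code{FrameEnsemble}.
#' @export
read_ensemble_dcd <- function(file, frame_interval, origin_time = 0) {
  xyz <- bio3d::read.dcd(file, verbose = FALSE)
  frame_ensemble(xyz_to_coords(xyz), frame_interval, origin_time)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble a \code{FrameEnsemble}.
#' @param topology matching \code{Topology} (residue numbers, names).
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, topology, file) {
  stopifnot(inherits(ensemble, "FrameEnsemble"), inherits(topology, "Topology"))
  if (topology$n_atoms != ensemble$n_atoms) stop("topology/ensemble atom mismatch")
  nm <- if (is.null(topology$name)) rep("CA", topology$n_atoms) else topology$name
  el <- if (is.null(topology$element)) rep("C", topology$n_atoms) else topology$element
  bio3d::write.pdb(file = file, xyz = ensemble_xyz(ensemble),
                   resno = topology$resid, resid = rep("ALA", topology$n_atoms),
                   eleno = topology$atom_id, elety = nm, elesy = el)
  invisible(file)
}

#' Write a per-frame series as tidy CSV
#'
#' @param series data frame (e.g. from \code{rmsd_series} or
#'   \code{velocity_autocorrelation}).
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_series_csv <- function(series, file) {
  utils::write.csv(series, file, row.names = FALSE)
  invisible(file)
}
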