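#' Velocity series container
#'
#' @param velocities numeric array \code{F x N x 3}, Angstrom/ps.
#' @param frame_interval spacing between stored frames, ps.
#' @return Object of class \code{"VelocitySeries"}.
#' @export
velocity_series <- function(velocities, frame_interval) {
  if (is.matrix(velocities)) velocities <- array(velocities, dim = c(1L, dim(velocities)))
  d <- dim(velocities)
  if (length(d) != 3L || d[3] != 3L) stop("'velocities' must be F x N x 3")
  if (!all(is.finite(velocities))) stop("velocities must be finite")
  if (frame_interval <= 0) stop("'frame_interval' must be positive (ps)")
  structure(list(velocities = velocities, frame_interval = frame_interval,
                 n_frames = d[1], n_atoms = d[2]),
            class = "VelocitySeries")
}

#' Velocity autocorrelation function and relaxation time
#'
#' Computes the normalized VACF
#' \eqn{C(\tau) = \langle v(t) \cdot v(t+\tau)\rangle / \langle v^2 \rangle}
#' averaged over atoms and time origins, and a relaxation time.  The default
#' relaxation-time definition is the first \eqn{1/e} crossing of the
#' normalized VACF (linearly interpolated between samples); the alternative
#' \code{"integral"} definition integrates the VACF over the computed lags
#' (trapezoid rule).
#'
#' @param vel a \code{VelocitySeries} (at least 2 frames).
#' @param max_lag largest lag, in frames, to evaluate (default
#'   \code{min(F - 1, 2000)}).
#' @param atoms optional atom subset (indices); default all atoms.
#' @param method relaxation-time definition, \code{"crossing"} (1/e, default)
#'   or \code{"integral"}.
#' @return A list with \code{vacf} (data frame: \code{lag_ps}, \code{vacf})
#'   and \code{relaxation_time_ps}.
#' @export
velocity_autocorrelation <- function(vel, max_lag = NULL, atoms = NULL,
                                     method = c("crossing", "integral")) {
  stopifnot(inherits(vel, "VelocitySeries"))
  method <- match.arg(method)
  if (vel$n_frames < 2L) stop("need at least 2 frames")
  v <- vel$velocities
  if (!is.null(atoms)) v <- v[, atoms, , drop = FALSE]
  d <- dim(v)
  V <- matrix(aperm(v, c(3L, 2L, 1L)), nrow = d[1], byrow = TRUE)  # F x 3N
  f <- d[1]
  if (is.null(max_lag)) max_lag <- min(f - 1L, 2000L)
  max_lag <- min(max_lag, f - 1L)
  cc <- numeric(max_lag + 1L)
  for (tau in 0:max_lag) {
    i1 <- seq_len(f - tau)
    cc[tau + 1L] <- sum(V[i1, , drop = FALSE] * V[i1 + tau, , drop = FALSE]) /
      (length(i1) * d[2])
  }
  if (cc[1L] <= 0) stop("zero velocities: VACF normalization undefined")
  cc <- cc / cc[1L]
  lag_ps <- (0:max_lag) * vel$frame_interval
  relax <- if (method == "integral") {
    sum(diff(lag_ps) * (utils::head(cc, -1L) + utils::tail(cc, -1L)) / 2)
  } else {
    thr <- exp(-1)
    k <- which(cc <= thr)[1L]
    if (is.na(k)) NA_real_
    else if (k == 1L) 0
    else {
      # linear interpolation between samples k-1 and k
      lag_ps[k - 1L] + (cc[k - 1L] - thr) / (cc[k - 1L] - cc[k]) *
        (lag_ps[k] - lag_ps[k - 1L])
    }
  }
  list(vacf = data.frame(lag_ps = lag_ps, vacf = cc),
       relaxation_time_ps = relax)
}
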