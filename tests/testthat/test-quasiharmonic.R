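kB_int <- 0.831446261815324   # amu A^2 / (ps^2 K), for closed-form oracles

test_that("single isotropic atom gives the closed-form oscillator frequency", {
  m <- 15.999; k <- 2.5; temp <- 300
  cv <- rrscan:::as_covariance(diag(3L) * kB_int * temp / k)
  spec <- qh_modes(cv, m, temperature = temp, drop_external = FALSE)
  expect_equal(spec$omega_ps, rep(sqrt(k / m), 3L), tolerance = 1e-10)
  # triply degenerate, orthonormal modes
  expect_equal(crossprod(spec$modes), diag(3L), tolerance = 1e-10)
})

test_that("frequencies scale as 1/sqrt(mass) at fixed covariance", {
  # sigma = M^1/2 C M^1/2 doubles when masses double, so lambda doubles and
  # omega = sqrt(kBT/lambda) shrinks by sqrt(2)
  set.seed(14)
  cv <- rrscan:::as_covariance(random_spd(9L, 0.5, 2))
  s1 <- qh_modes(cv, rep(10, 3L), drop_external = FALSE)
  s2 <- qh_modes(cv, rep(20, 3L), drop_external = FALSE)
  expect_equal(s2$omega_ps, s1$omega_ps / sqrt(2), tolerance = 1e-10)
})

test_that("sigma-eigenvalue route equals the explicit C^-1 secular solve", {
  # full-rank 5-atom toy: F = kBT C^-1, det(F - w^2 M) = 0 solved densely
  set.seed(15)
  n <- 5L; temp <- 300
  masses <- c(12.011, 14.007, 15.999, 1.008, 32.06)
  C <- random_spd(3L * n, 0.3, 2.5)
  spec <- qh_modes(rrscan:::as_covariance(C), masses, temperature = temp,
                   drop_external = FALSE)
  Fmat <- kB_int * temp * solve(C)
  ism <- rep(1 / sqrt(masses), each = 3L)
  W <- eigen(t(Fmat * ism) * ism, symmetric = TRUE, only.values = TRUE)$values
  omega_oracle <- sqrt(sort(W))
  expect_equal(spec$omega_ps, omega_oracle, tolerance = 1e-8)
})

test_that("whole-system scope retains exactly 3n-6 modes", {
  set.seed(16)
  n <- 5L
  spec <- qh_modes(rrscan:::as_covariance(random_spd(3L * n)), rep(12, n))
  expect_equal(length(spec$omega_ps), 3L * n - 6L)
  expect_equal(spec$n_dropped, 6L)
  # frequencies ascending and positive; modes orthonormal
  expect_true(all(diff(spec$omega_ps) >= 0))
  expect_true(all(spec$omega_ps > 0))
  expect_equal(crossprod(spec$modes), diag(ncol(spec$modes)), tolerance = 1e-8)
})

test_that("tolerance never drops a mode above 1e-6 of the largest eigenvalue", {
  set.seed(17)
  v <- random_orthonormal(9L)
  lam <- c(1, 1e-2, 1e-5, rep(2e-6, 3L), rep(1e-9, 3L))  # 3 below tol
  cv <- rrscan:::as_covariance(v %*% (lam * t(v)))
  spec <- qh_modes(cv, rep(12, 3L), drop_external = FALSE)
  expect_equal(length(spec$omega_ps), 6L)
})

test_that("per-mode oscillator entropy matches the printed-formula oracle", {
  temp <- 300
  # one mode at x = hbar w / kBT = 1
  omega1 <- kB_int * temp / 6.35078
  spec <- rrscan:::spectrum_from_omega(omega1, temperature = temp)
  s <- config_entropy(spec)
  expect_equal(s$S / 1.987204e-3, 1.04066, tolerance = 1e-4)
  expect_equal(s$S, qho_entropy_oracle(omega1, temp), tolerance = 1e-12)

  # stiff-mode limit: contribution -> 0
  s_stiff <- config_entropy(rrscan:::spectrum_from_omega(omega1 * 100, temperature = temp))
  expect_lt(s_stiff$S, 1e-12)

  # monotonicity: S increases with T, decreases when a frequency increases
  spec_multi <- rrscan:::spectrum_from_omega(c(0.5, 1, 2) * omega1, temperature = temp)
  s300 <- config_entropy(spec_multi)$S
  s320 <- config_entropy(rrscan:::spectrum_from_omega(c(0.5, 1, 2) * omega1,
                                                      temperature = 320))$S
  expect_gt(s320, s300)
  s_up <- config_entropy(rrscan:::spectrum_from_omega(c(0.6, 1, 2) * omega1,
                                                      temperature = temp))$S
  expect_lt(s_up, s300)

  expect_error(config_entropy(rrscan:::spectrum_from_omega(numeric(0))), "empty|non-positive")
})

test_that("pipeline entropy converges to the analytic value with frame count", {
  model <- toy_chain_model()
  fcounts <- c(1e3L, 1e4L, 1e5L)
  # average the absolute recovery error over replicates at each frame count;
  # the error shrinks like 1/sqrt(F), i.e. a negative log-log slope
  errs <- vapply(fcounts, function(f) {
    mean(vapply(1:3, function(rep) {
      fit <- qha(sample_frames(model, f, seed = 100 * rep + f), model$topology)
      abs(fit$entropy$S - model$analytic_entropy)
    }, numeric(1)))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(errs) ~ log(fcounts)))[2L]
  expect_lt(slope, -0.2)
  expect_lt(errs[3L], errs[1L])
  # 2% recovery at 15,000 frames
  fit15 <- qha(sample_frames(model, 15000L, seed = 77), model$topology)
  expect_lt(abs(fit15$entropy$S - model$analytic_entropy) / model$analytic_entropy, 0.02)
})

test_that("entropy is invariant to a whole-trajectory rigid motion before fitting", {
  model <- toy_chain_model()
  ens <- sample_frames(model, 4000L, seed = 19)
  fit0 <- qha(superpose(ens, model$mean_structure), model$topology)
  R <- random_rotation()
  co <- ens$coords
  for (f in seq_len(dim(co)[1L]))
    co[f, , ] <- co[f, , ] %*% t(R) + matrix(c(5, -3, 2), 12L, 3L, byrow = TRUE)
  moved <- frame_ensemble(co, 1)
  fitR <- qha(superpose(moved, model$mean_structure %*% t(R)), model$topology)
  expect_equal(fitR$entropy$S, fit0$entropy$S, tolerance = 1e-6)
})

test_that("residue entropies are additive for independent residues", {
  top <- topology(mass = rep(c(12, 16), 3L), resid = rep(1:3, each = 2L))
  set.seed(20)
  bd <- matrix(0, 18L, 18L)
  for (r in 1:3) {
    idx <- rrscan:::coord_indices(residue_atoms(top, r))
    bd[idx, idx] <- random_spd(6L, 0.5, 1.5)
  }
  cv <- rrscan:::as_covariance(bd)
  s_whole <- config_entropy(qh_modes(cv, top, drop_external = FALSE))$S
  s_res <- sum(vapply(1:3, function(r) residue_entropy(cv, top, r)$S, numeric(1)))
  expect_equal(s_res, s_whole, tolerance = 1e-10)
})

test_that("frozen residues report zero entropy with a warning", {
  top <- topology(mass = rep(12, 4L), resid = c(1L, 1L, 2L, 2L))
  bd <- matrix(0, 12L, 12L)
  bd[1:6, 1:6] <- random_spd(6L)
  cv <- rrscan:::as_covariance(bd)
  expect_warning(s2 <- residue_entropy(cv, top, 2L), "S = 0")
  expect_equal(s2$S, 0)
  expect_equal(s2$n_modes_used, 0L)
})

test_that("per-atom normalization flattens equal-dynamics residues", {
  # residues with identical per-atom dynamics but different sizes
  top <- topology(mass = rep(12, 6L), resid = c(1L, 1L, 1L, 1L, 2L, 2L))
  block <- random_spd(6L, 0.8, 1.2)
  bd <- matrix(0, 18L, 18L)
  bd[1:6, 1:6] <- block; bd[7:12, 7:12] <- block; bd[13:18, 13:18] <- block
  cv <- rrscan:::as_covariance(bd)
  e1 <- normalize_residue_entropy(residue_entropy(cv, top, 1L), top)
  e2 <- normalize_residue_entropy(residue_entropy(cv, top, 2L), top)
  expect_gt(e1$S, e2$S)  # raw entropy scales with size
  expect_equal(e1$normalized_per_atom, e2$normalized_per_atom, tolerance = 1e-10)

  # arithmetic: S = 0.10 over 10 atoms -> 0.010/atom
  topA <- topology(mass = rep(12, 10L), resid = rep(1L, 10L))
  fake <- structure(list(S = 0.10, n_modes_used = 30L, temperature = 300,
                         scope = 1L, normalized_per_atom = NULL),
                    class = "EntropyResult")
  expect_equal(normalize_residue_entropy(fake, topA)$normalized_per_atom, 0.010)
})

test_that("density of states conserves mode count and starts at zero", {
  set.seed(22)
  spec <- qh_modes(rrscan:::as_covariance(random_spd(15L)), rep(12, 5L))
  dos <- density_of_states(spec, bin_width = 5)
  expect_equal(sum(dos$count), length(spec$omega_ps))
  expect_equal(dos$bin_lower[1L], 0)
  wide <- density_of_states(spec, bin_width = 1e5)
  expect_equal(wide$count[1L], length(spec$omega_ps))
  expect_error(density_of_states(spec, -1), "positive")
  # histogram depends only on frequencies, not on mode vectors
  spec2 <- spec; spec2$modes <- NULL
  expect_equal(density_of_states(spec2, 5), dos)
})

test_that("spectra round-trip through CSV persistence", {
  set.seed(23)
  spec <- qh_modes(rrscan:::as_covariance(random_spd(9L)), rep(12, 3L),
                   drop_external = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(spec, f)
  back <- read_spectrum(f)
  expect_equal(back$frequencies_cm1, spec$frequencies_cm1, tolerance = 1e-10)
  expect_equal(back$modes, spec$modes, tolerance = 1e-10)
  expect_equal(back$temperature, spec$temperature)
})
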