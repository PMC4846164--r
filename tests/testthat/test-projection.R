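test_that("PCA contribution fractions are exact bookkeeping", {
  spec <- rrscan:::spectrum_from_omega(c(1, 2, 3, 4))  # lambda prop 1,1/4,1/9,1/16
  spec$lambda <- c(4, 3, 2, 1)                          # impose the toy variances
  pc <- pca_contributions(spec)
  expect_equal(pc$fractions, c(0.4, 0.3, 0.2, 0.1))
  expect_equal(pc$cumulative, cumsum(c(0.4, 0.3, 0.2, 0.1)))
  expect_equal(pc$n_modes_to_threshold, 3L)   # 0.9 reached at 3 modes
  expect_equal(sum(pc$fractions), 1)
  expect_true(all(diff(pc$cumulative) >= 0))

  spec$lambda <- rep(2, 10L)
  expect_equal(pca_contributions(spec)$n_modes_to_threshold, 9L)  # ceil(0.9 m)
})

test_that("frame projections respect orthonormality and recover mode variances", {
  model <- toy_chain_model()
  spec <- model$spectrum
  mu <- as.vector(t(model$mean_structure))

  # frame exactly at the mean projects to zero on every mode
  ens0 <- const_ensemble(model$mean_structure, 1L, aligned = "model_mean")
  p0 <- project_frames(ens0, spec, mode_ids = 1:5, mean_flat = mu)
  expect_lt(max(abs(p0)), 1e-10)

  # displacement c * M^-1/2 * mode_1 projects to (c, 0, 0, ...)
  cval <- 0.8
  disp <- cval * spec$modes[, 1L] / rep(sqrt(model$topology$mass), each = 3L)
  frame1 <- model$mean_structure + matrix(disp, ncol = 3L, byrow = TRUE)
  p1 <- project_frames(const_ensemble(frame1, 1L, aligned = "model_mean"),
                       spec, mode_ids = 1:4, mean_flat = mu)
  expect_equal(as.numeric(p1), c(cval, 0, 0, 0), tolerance = 1e-8)

  # projection variance matches lambda_k within 5% at 1e4 frames
  ens <- sample_frames(model, 1e4L, seed = 41)
  pr <- project_frames(ens, spec, mode_ids = 1:3, mean_flat = mu)
  v <- apply(pr, 2L, stats::var)
  expect_lt(max(abs(v - spec$lambda[1:3]) / spec$lambda[1:3]), 0.05)
  expect_lt(max(abs(colMeans(pr))), 3 * sqrt(max(spec$lambda[1:3]) / 1e4) * 1.5)
})

test_that("mode overlaps are unsigned-summarized and match brute force", {
  d <- 50L
  set.seed(43)
  A <- random_orthonormal(d, 5L)
  expect_equal(mode_overlap(A, A)$unsigned_diag, rep(1, 5L), tolerance = 1e-10)

  B <- random_orthonormal(d, 5L)
  ov <- mode_overlap(A, B)
  expect_equal(ov$dot_matrix, crossprod(A, B), tolerance = 1e-12)  # brute force
  expect_true(all(abs(ov$dot_matrix) <= 1 + 1e-10))

  # sign flip of any input vector leaves unsigned summaries unchanged
  Bf <- B; Bf[, 2L] <- -Bf[, 2L]
  expect_equal(mode_overlap(A, Bf)$unsigned_diag, ov$unsigned_diag, tolerance = 1e-12)

  # orthogonal complement modes overlap at zero
  full <- random_orthonormal(d, d)
  expect_lt(max(abs(mode_overlap(full[, 1:3, drop = FALSE],
                                 full[, 4:6, drop = FALSE])$dot_matrix)), 1e-10)

  # mean |dot| of random unit vectors approaches sqrt(2/(pi d))
  dots <- replicate(400, abs(sum(random_orthonormal(d, 1L) * random_orthonormal(d, 1L))))
  expect_equal(mean(dots), sqrt(2 / (pi * d)), tolerance = 0.15)

  expect_error(mode_overlap(A * 2, B), "unit-norm")
})

test_that("block coherence is high for a gapped spectrum, low for degenerate", {
  n <- 6L
  coords <- cbind(2 * seq_len(n), 1.5 * sin(1:n), cos(1.3 * (1:n)))
  model <- build_enm_model(coords, masses = rep(12, n), cutoff = 8)
  # soften PC1 dramatically -> clear spectral gap
  gap <- model
  gap$spectrum$lambda[1L] <- 50 * gap$spectrum$lambda[2L]
  blocks <- lapply(1:4, function(b)
    qha(sample_frames(gap, 2000L, seed = 500 + b), model$topology)$spectrum)
  full <- qha(sample_frames(gap, 8000L, seed = 999), model$topology)$spectrum
  ch <- coherence_check(blocks, full, k_modes = 3L)
  expect_gt(ch$per_mode$unsigned_mean[1L], 0.9)
  expect_equal(dim(ch$pc1_pairs), c(4L, 4L))
  expect_equal(diag(ch$pc1_pairs), rep(1, 4L), tolerance = 1e-8)

  # identical blocks are perfectly self-consistent
  same <- coherence_check(list(full, full), full, k_modes = 2L)
  expect_equal(same$per_mode$unsigned_mean, rep(1, 2L), tolerance = 1e-8)

  # isotropic (fully degenerate) fluctuations: PC1 is arbitrary, overlap near
  # the random-vector baseline, far from 1
  iso <- model
  iso$spectrum$lambda <- rep(iso$spectrum$lambda[1L], length(iso$spectrum$lambda))
  blocks_i <- lapply(1:4, function(b)
    qha(sample_frames(iso, 1500L, seed = 700 + b), model$topology)$spectrum)
  full_i <- qha(sample_frames(iso, 1500L, seed = 799), model$topology)$spectrum
  ch_i <- coherence_check(blocks_i, full_i, k_modes = 1L)
  expect_lt(ch_i$per_mode$unsigned_mean[1L], 0.8)

  expect_error(coherence_check(list(full), full), "at least 2")
})

test_that("2D projection and cloud distances behave geometrically", {
  model <- toy_chain_model()
  d <- 3L * model$topology$n_atoms
  mu <- as.vector(t(model$mean_structure))
  ax_a <- model$spectrum$modes[, 1L]
  ax_b <- model$spectrum$modes[, 2L]     # exactly orthogonal here

  # frames displaced along axis_a only stay on the x-axis of the chart
  co <- array(0, dim = c(3L, model$topology$n_atoms, 3L))
  for (f in 1:3) {
    disp <- (f / 2) * ax_a / rep(sqrt(model$topology$mass), each = 3L)
    co[f, , ] <- model$mean_structure + matrix(disp, ncol = 3L, byrow = TRUE)
  }
  cl <- project_2d(frame_ensemble(co, 1, aligned_to = "m"), ax_a, ax_b, mu,
                   model$topology$mass)
  expect_equal(as.numeric(cl$points[, 2L]), rep(0, 3L), tolerance = 1e-9)
  expect_equal(as.numeric(cl$points[, 1L]), (1:3) / 2, tolerance = 1e-9)

  # ensemble centred at the common mean has centroid ~ (0,0)
  ens <- sample_frames(model, 5000L, seed = 55)
  cl0 <- project_2d(ens, ax_a, ax_b, mu, model$topology$mass)
  se0 <- sqrt(max(model$spectrum$lambda[1:2]) / 5000)
  expect_lt(max(abs(colMeans(cl0$points))), 4 * se0)

  # identical clouds at distance 0; (3,4) shift gives 5
  expect_equal(distribution_distance(cl0, cl0), 0)
  cl_shift <- cl0
  cl_shift$points <- sweep(cl0$points, 2L, c(3, 4), `+`)
  expect_equal(distribution_distance(cl0, cl_shift), 5, tolerance = 1e-10)
  # symmetry and joint-translation invariance
  expect_equal(distribution_distance(cl_shift, cl0), 5, tolerance = 1e-10)
  cl_a2 <- cl0; cl_a2$points <- sweep(cl0$points, 2L, c(-7, 2), `+`)
  cl_b2 <- cl_shift; cl_b2$points <- sweep(cl_shift$points, 2L, c(-7, 2), `+`)
  expect_equal(distribution_distance(cl_a2, cl_b2), 5, tolerance = 1e-10)

  # two-Gaussian centroid separation recovered within 3 SE at 1e4 points;
  # the imposed shift is 2 SD of the softest mode so it is well resolved
  mag <- 2 * sqrt(model$spectrum$lambda[1L])
  shifted <- two_state_shift(model, ax_a, magnitude = mag)
  ens_b <- sample_frames(shifted, 1e4L, seed = 56)
  cl_u <- project_2d(sample_frames(model, 1e4L, seed = 57), ax_a, ax_b, mu,
                     model$topology$mass, state_label = "unbound")
  cl_v <- project_2d(ens_b, ax_a, ax_b, mu, model$topology$mass,
                     state_label = "bound")
  se <- sqrt(2 * model$spectrum$lambda[1L] / 1e4)
  expect_lt(abs(distribution_distance(cl_u, cl_v) - mag), 3 * se)

  # density-mode variant exists and is in the same ballpark (bin resolution)
  dm <- distribution_distance(cl_u, cl_v, method = "mode")
  expect_lt(abs(dm - mag), sqrt(model$spectrum$lambda[1L]))

  expect_error(project_2d(ens, ax_a * 2, ax_b, mu, model$topology$mass), "unit-norm")
})
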