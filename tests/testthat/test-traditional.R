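test_that("FFT reconstruction localises fringes and conserves energy", {
  zero <- oct_volume(array(0, dim = c(16, 2, 2, 2)))
  expect_true(all(fft_reconstruct(zero)$data == 0))
  # single cosine at bin 7, amplitude a: arg-max of I(z) at 7
  sc <- data.frame(z = 7, amplitude = 1.3, phase = 1.1, dynamic = FALSE)
  sim <- simulate_volume(sim_config(K = 64, X = 2, Y = 2, N = 2, scatterers = sc,
                                    dc_offset = 3, noise_sigma = 0, seed = 1))
  iv <- fft_reconstruct(sim$volume)
  expect_equal(iv$Z, 32L)
  expect_identical(which.max(iv$data[, 1, 1, 1]), 7L)
  expect_equal(max(iv$data[, 1, 1, 1]), 1.3 * 64 / 2, tolerance = 1e-9)
  # Parseval on the mean-subtracted A-line, both sides independent
  e <- sim$volume$data[, 2, 2, 1] - mean(sim$volume$data[, 2, 2, 1])
  lhs <- sum(Mod(fft(e))^2)
  rhs <- 64 * sum(e^2)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("traditional summation projection matches the depth-loop oracle", {
  sim <- tiny_phantom(seed = 61)
  iv <- fft_reconstruct(sim$volume)
  p <- traditional_summation_projection(iv, 2)
  oracle <- matrix(0, iv$X, iv$Y)
  for (x in seq_len(iv$X)) for (y in seq_len(iv$Y)) {
    oracle[x, y] <- sum(iv$data[, x, y, 2])
  }
  expect_equal(unclass(p), oracle, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(traditional_summation_projection(iv, 9), "out of range")
})

test_that("traditional projection ranks pixels like the phantom reflectivity", {
  sim <- simulate_volume(default_phantom_config(seed = 1))
  tp <- traditional_summation_projection(fft_reconstruct(sim$volume))
  rho <- cor(as.numeric(tp), as.numeric(sim$truth$reflectivity_map),
             method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("multi-repeat ground truth averages repeats and reduces noise", {
  # noise-free static phantom: ground truth equals any single-repeat projection
  sim <- simulate_volume(static_config(N = 12))
  gt <- ground_truth_structural(sim$volume)
  single <- traditional_summation_projection(fft_reconstruct(sim$volume), 3)
  expect_equal(unclass(gt), unclass(single), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_identical(attr(gt, "n_repeats_used"), 12L)
  # insufficient repeats rejected
  expect_error(ground_truth_structural(tiny_phantom(seed = 3)$volume),
               "N >= 12")
  # with noise: averaging shrinks the pixel-wise fluctuation around the
  # noise-free projection (a constant magnitude-noise floor shifts both, so
  # compare variances, ~1/12 expected)
  cfg <- static_config(N = 12)
  cfg$noise_sigma <- 0.5
  noisy <- simulate_volume(cfg)
  gt_noisy <- ground_truth_structural(noisy$volume)
  single_noisy <- traditional_summation_projection(fft_reconstruct(noisy$volume), 1)
  var_gt <- stats::var(as.numeric(gt_noisy - single))
  var_single <- stats::var(as.numeric(single_noisy - single))
  expect_lt(var_gt, var_single / 2)
})

test_that("volumetric speckle variance matches the voxel loop oracle", {
  sim <- tiny_phantom(seed = 71)
  iv <- fft_reconstruct(sim$volume)
  sv <- sv3d(iv)
  oracle <- matrix(0, iv$X, iv$Y)
  for (x in seq_len(iv$X)) for (y in seq_len(iv$Y)) {
    acc <- 0
    for (z in seq_len(iv$Z)) {
      v <- iv$data[z, x, y, ]
      acc <- acc + sum((v - mean(v))^2) / length(v)
    }
    oracle[x, y] <- acc
  }
  expect_equal(unclass(sv), oracle, ignore_attr = TRUE, tolerance = 1e-12)
  # static noise-free volume -> zero map
  static_iv <- fft_reconstruct(simulate_volume(static_config())$volume)
  expect_lt(max(sv3d(static_iv)), 1e-18)
  # vessels brighter than background
  expect_gt(median(sv[sim$truth$vessel_mask]), median(sv[!sim$truth$vessel_mask]))
})

test_that("frame-wise eigen filtering cancels static volumes and finds vessels", {
  static_iv <- fft_reconstruct(simulate_volume(static_config())$volume)
  fe <- frame_ed(static_iv)
  expect_lt(sum(fe^2) / sum(static_iv$data^2), 1e-20)
  expect_true(all(attr(fe, "r_per_frame") == 1L))
  sim <- tiny_phantom(seed = 81)
  iv <- fft_reconstruct(sim$volume)
  fe2 <- frame_ed(iv)
  expect_gt(median(fe2[sim$truth$vessel_mask]),
            median(fe2[!sim$truth$vessel_mask]))
  # per-frame r matches an independent recount
  for (y in c(1L, 8L)) {
    P <- t(matrix(iv$data[, , y, , drop = FALSE], nrow = iv$Z * iv$X))
    lam <- eigen(P %*% t(P) / nrow(P), symmetric = TRUE, only.values = TRUE)$values
    expect_identical(attr(fe2, "r_per_frame")[y], sum(lam > mean(lam)))
  }
})

test_that("a shallow scatterer keeps its depth bin through decimation + FFT", {
  sc <- data.frame(z = 11, amplitude = 1, phase = 0.3, dynamic = FALSE)
  sim <- simulate_volume(sim_config(K = 128, X = 2, Y = 2, N = 2, scatterers = sc,
                                    dc_offset = 2, noise_sigma = 0, seed = 4))
  iv_half <- fft_reconstruct(downsample_volume_half(sim$volume))
  expect_equal(iv_half$Z, 32L)
  expect_identical(which.max(iv_half$data[, 1, 1, 1]), 11L)
})
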