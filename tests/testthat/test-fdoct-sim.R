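test_that("a scatterer-free configuration yields pure DC", {
  cfg <- sim_config(K = 8, X = 2, Y = 3, N = 2, n_static_scatterers = 0,
                    n_dynamic_scatterers = 0, dc_offset = 5, noise_sigma = 0,
                    seed = 3)
  sim <- simulate_volume(cfg)
  expect_true(all(sim$volume$data == 5))
  expect_equal(dim(sim$volume$data), c(8L, 2L, 3L, 2L))
})

test_that("a single static fringe reconstructs at its depth bin", {
  sc <- data.frame(z = 10, amplitude = 1, phase = 0, dynamic = FALSE)
  cfg <- sim_config(K = 64, X = 2, Y = 2, N = 2, scatterers = sc,
                    dc_offset = 0, noise_sigma = 0, seed = 1)
  sim <- simulate_volume(cfg)
  for (x in 1:2) for (y in 1:2) {
    mag <- oracle_dft_mag(sim$volume$data[, x, y, 1])
    expect_identical(which.max(mag), 10L)
  }
})

test_that("same seed and config give bit-identical volume and truth", {
  cfg <- default_phantom_config(K = 64, X = 12, Y = 12, seed = 21)
  a <- simulate_volume(cfg)
  b <- simulate_volume(cfg)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth, b$truth)
})

test_that("phantom ground truth is internally consistent", {
  sim <- tiny_phantom(seed = 7)
  truth <- sim$truth
  tab <- truth$scatterer_table
  # vessel mask true exactly where a dynamic scatterer exists
  dyn_pixels <- unique(tab[tab$dynamic, c("x", "y")])
  mask_from_table <- matrix(FALSE, nrow(truth$vessel_mask), ncol(truth$vessel_mask))
  mask_from_table[as.matrix(dyn_pixels)] <- TRUE
  expect_identical(truth$vessel_mask, mask_from_table)
  expect_true(all(truth$reflectivity_map >= 0))
  # reflectivity is the per-pixel amplitude sum
  agg <- rowsum(tab$amplitude, group = (tab$y - 1L) * nrow(truth$vessel_mask) + tab$x)
  expect_equal(truth$reflectivity_map[as.integer(rownames(agg))],
               as.numeric(agg))
  # depths are distinct within an A-line
  expect_false(any(duplicated(tab[, c("x", "y", "z")])))
})

test_that("static pixels are repeat-identical when noise and jitter are off", {
  sim <- simulate_volume(static_config())
  v <- sim$volume$data
  for (n in 2:dim(v)[4]) {
    expect_equal(max(abs(v[, , , n] - v[, , , 1])), 0)
  }
})

test_that("dynamic pixels decorrelate across repeats, static ones do not", {
  sim <- tiny_phantom(seed = 13, noise_sigma = 0)
  v <- sim$volume$data
  mask <- sim$truth$vessel_mask
  cor_repeats <- function(x, y) cor(v[, x, y, 1], v[, x, y, 2])
  vessel_idx <- which(mask, arr.ind = TRUE)
  static_idx <- which(!mask, arr.ind = TRUE)
  cv <- mean(mapply(cor_repeats, vessel_idx[, 1], vessel_idx[, 2]))
  cs <- mean(mapply(cor_repeats, static_idx[, 1], static_idx[, 2]))
  expect_gt(cs, cv)
  expect_gt(cs, 0.999)  # static A-lines identical up to machine noise
})

test_that("aliasing misconfigurations and bad geometry are rejected", {
  sc <- data.frame(z = 40, amplitude = 1, phase = 0, dynamic = FALSE)
  expect_error(sim_config(K = 64, X = 2, Y = 2, scatterers = sc),
               "aliasing")
  expect_error(sim_config(K = 9, X = 2, Y = 2), "even")
  expect_error(sim_config(K = 64, X = 2, Y = 2, N = 1), "N")
  expect_error(
    sim_config(K = 64, X = 8, Y = 8,
               vessel_spec = list(vessel_disk(c(8, 8), 4))) |> simulate_volume(),
    "outside")
})

test_that("half-band down-sampling keeps odd-numbered samples", {
  cfg <- sim_config(K = 8, X = 1, Y = 1, N = 2, n_static_scatterers = 0,
                    n_dynamic_scatterers = 0, dc_offset = 0, noise_sigma = 0,
                    seed = 1)
  sim <- simulate_volume(cfg)
  sim$volume$data[, 1, 1, ] <- 1:8
  ds <- downsample_volume_half(sim$volume)
  expect_equal(as.numeric(ds$data[, 1, 1, 1]), c(1, 3, 5, 7))
  expect_equal(ds$K, 4L)
  expect_true(ds$downsampled)
  # idempotent in shape: twice yields K/4
  expect_equal(downsample_volume_half(ds)$K, 2L)
  # odd K rejected
  odd <- oct_volume(array(0, dim = c(3, 1, 1, 2)))
  expect_error(downsample_volume_half(odd), "even")
})

test_that("a fringe below K/4 survives half-band down-sampling at its bin", {
  sc <- data.frame(z = 9, amplitude = 1, phase = 0.7, dynamic = FALSE)
  cfg <- sim_config(K = 64, X = 1, Y = 1, N = 2, scatterers = sc,
                    dc_offset = 0, noise_sigma = 0, seed = 2)
  sim <- simulate_volume(cfg)
  before <- oracle_dft_mag(sim$volume$data[, 1, 1, 1])
  after <- oracle_dft_mag(downsample_volume_half(sim$volume)$data[, 1, 1, 1])
  expect_identical(which.max(before), 9L)
  expect_identical(which.max(after), 9L)
})
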