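# Small phantoms shared across tests. Everything is generated in code with
# fixed seeds; nothing is stored on disk.

# tiny noisy phantom with vessels (16 x 16, K = 64)
tiny_phantom <- function(seed = 11L, N = 4L, ...) {
  simulate_volume(default_phantom_config(K = 64L, X = 16L, Y = 16L, N = N,
                                         seed = seed, ...))
}

# static-only, noise-free configuration: every repeat is identical
static_config <- function(K = 64L, X = 8L, Y = 8L, N = 4L, seed = 5L) {
  sim_config(K = K, X = X, Y = Y, N = N,
             n_static_scatterers = 3L, n_dynamic_scatterers = 0L,
             vessel_spec = list(), dynamic_amplitude_jitter = 0,
             noise_sigma = 0, seed = seed)
}

# seeded random projection stack (pure array, no simulator involvement)
random_stack <- function(N = 4L, X = 16L, Y = 16L, seed = 42L) {
  s <- array(0, dim = c(N, X, Y))
  set.seed(seed)
  s[] <- rnorm(N * X * Y)
  structure(s, class = c("oct_projection_stack", class(s)))
}

# independent loop oracles -----------------------------------------------

oracle_projection_sum <- function(vol, n) {
  out <- matrix(0, vol$X, vol$Y)
  for (x in seq_len(vol$X)) for (y in seq_len(vol$Y)) {
    acc <- 0
    for (k in seq_len(vol$K)) acc <- acc + vol$data[k, x, y, n]
    out[x, y] <- acc
  }
  out
}

oracle_stack_variance <- function(stack) {
  d <- dim(stack)
  out <- matrix(0, d[2L], d[3L])
  for (x in seq_len(d[2L])) for (y in seq_len(d[3L])) {
    v <- stack[, x, y]
    out[x, y] <- sum((v - mean(v))^2) / length(v)
  }
  out
}

oracle_gram <- function(stack) {
  d <- dim(stack)
  N <- d[1L]
  G <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    acc <- 0
    for (x in seq_len(d[2L])) for (y in seq_len(d[3L])) {
      acc <- acc + stack[i, x, y] * stack[j, x, y]
    }
    G[i, j] <- acc / N
  }
  G
}

oracle_mse <- function(a, b) {
  acc <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    acc <- acc + (a[i, j] - b[i, j])^2
  }
  acc / (nrow(a) * ncol(a))
}

# literal windowed SSIM with a uniform w x w window, valid positions only
oracle_ssim_uniform <- function(a, gt, w, K1 = 0.01, K2 = 0.03, L = NULL) {
  if (is.null(L)) L <- max(gt) - min(gt)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2; C3 <- C2 / 2
  vals <- c()
  for (i in seq_len(nrow(a) - w + 1L)) for (j in seq_len(ncol(a) - w + 1L)) {
    pa <- a[i:(i + w - 1L), j:(j + w - 1L)]
    pg <- gt[i:(i + w - 1L), j:(j + w - 1L)]
    mua <- mean(pa); mug <- mean(pg)
    va <- mean(pa^2) - mua^2; vg <- mean(pg^2) - mug^2
    cab <- mean(pa * pg) - mua * mug
    l <- (2 * mua * mug + C1) / (mua^2 + mug^2 + C1)
    cc <- (2 * sqrt(va) * sqrt(vg) + C2) / (va + vg + C2)
    s <- (cab + C3) / (sqrt(va) * sqrt(vg) + C3)
    vals <- c(vals, l * cc * s)
  }
  mean(vals)
}

# brute-force magnitude DFT of one A-line at integer bins 1..K/2
oracle_dft_mag <- function(e) {
  K <- length(e)
  i <- 0:(K - 1)
  vapply(seq_len(K %/% 2), function(z) {
    Mod(sum(e * exp(-2i * pi * z * i / K)))
  }, numeric(1))
}
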