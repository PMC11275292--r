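test_that("correlation matrix of simple stacks has the expected structure", {
  # two identical frames: [[s, s], [s, s]] with s = ||f||^2 / 2, rank 1
  f <- matrix(rnorm(12, 2), 3, 4)
  stk <- array(0, dim = c(2, 3, 4))
  stk[1, , ] <- f; stk[2, , ] <- f
  C <- projection_correlation_matrix(stk)
  s <- sum(f^2) / 2
  expect_equal(C, matrix(s, 2, 2))
  expect_equal(qr(C)$rank, 1L)
  # orthogonal frames: diagonal matrix
  stk2 <- array(0, dim = c(2, 2, 2))
  stk2[1, , ] <- c(1, 0, 0, 0)
  stk2[2, , ] <- c(0, 2, 0, 0)
  expect_equal(projection_correlation_matrix(stk2), diag(c(0.5, 2)))
})

test_that("correlation matrix matches the brute-force Gram oracle", {
  stk <- random_stack(N = 3, X = 4, Y = 4, seed = 8)
  C <- projection_correlation_matrix(stk)
  expect_equal(C, oracle_gram(stk), tolerance = 1e-12)
  # Hermitian, PSD, trace identity
  expect_equal(C, t(C))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
  expect_equal(sum(ev), sum(diag(C)))
  expect_true(all(diff(ev) <= 1e-12))
})

test_that("automatic eigenvector-removal count follows the above-mean rule", {
  expect_identical(select_r_auto(c(4, 1, 1, 1, 1)), 1L)
  expect_identical(select_r_auto(c(3, 3, 3, 3)), 0L)
  expect_error(select_r_auto(numeric(0)), "empty")
  expect_error(select_r_auto(c(1, 2, 3)), "decreasing")
  set.seed(123)
  for (i in 1:200) {
    lam <- sort(rexp(sample(2:8, 1)), decreasing = TRUE)
    expect_identical(select_r_auto(lam), sum(lam > sum(lam) / length(lam)))
  }
})

test_that("eigen filtering cancels a static-only stack exactly", {
  sim <- simulate_volume(static_config())
  stk <- rupp_projection_stack(sim$volume)
  fit <- rupp_ed(stk)
  expect_identical(fit$filter$r, 1L)
  expect_lt(sum(fit$filter$residual_stack^2) / sum(unclass(stk)^2), 1e-20)
  expect_true(all(rupp_sv(stk) == 0))
})

test_that("r = 0 gives the identity filter and r >= N errors", {
  stk <- random_stack(seed = 9)
  fit <- rupp_ed(stk, r = 0)
  expect_identical(unclass(fit$filter$residual_stack), unclass(stk))
  expect_equal(unclass(fit$projection),
               apply(abs(stk), c(2, 3), mean), ignore_attr = TRUE)
  expect_error(rupp_ed(stk, r = 4), "r must satisfy")
  # all-equal eigenvalues trigger the r = 0 warning path
  stk2 <- array(0, dim = c(2, 2, 2))
  stk2[1, , ] <- c(1, 0, 0, 0)
  stk2[2, , ] <- c(0, 1, 0, 0)
  expect_warning(rupp_ed(stk2), "no dominant clutter")
})

test_that("eigen filter residual equals the least-squares subspace complement", {
  stk <- random_stack(N = 4, X = 12, Y = 12, seed = 14)
  fit <- rupp_ed(stk, r = 2)
  P <- matrix(unclass(stk), nrow = 4)
  Q <- fit$filter$eigenvectors[, 1:2]
  # independent least-squares projection of every pixel column onto span(Q)
  coef <- qr.solve(Q, P)
  oracle_resid <- P - Q %*% coef
  expect_lt(max(abs(matrix(fit$filter$residual_stack, nrow = 4) - oracle_resid)),
            1e-10)
})

test_that("eigen subspace removal is idempotent", {
  stk <- random_stack(N = 4, X = 10, Y = 10, seed = 15)
  fit <- rupp_ed(stk, r = 2)
  Q <- fit$filter$eigenvectors[, 1:2]
  R1 <- matrix(fit$filter$residual_stack, nrow = 4)
  R2 <- R1 - Q %*% (t(Q) %*% R1)
  expect_lt(max(abs(R2 - R1)), 1e-10)
})

test_that("speckle variance matches the loop oracle and its invariances", {
  stk <- random_stack(N = 4, X = 9, Y = 7, seed = 16)
  sv <- rupp_sv(stk)
  expect_equal(unclass(sv), oracle_stack_variance(stk),
               ignore_attr = TRUE, tolerance = 1e-14)
  # hand example: values {0, 2} -> variance 1
  stk2 <- array(0, dim = c(2, 1, 1)); stk2[, 1, 1] <- c(0, 2)
  expect_equal(as.numeric(rupp_sv(stk2)), 1)
  # adding a common image to every frame changes nothing
  offset <- matrix(rnorm(63), 9, 7)
  stk_off <- unclass(stk)
  for (n in 1:4) stk_off[n, , ] <- stk_off[n, , ] + offset
  expect_equal(unclass(rupp_sv(stk_off)), unclass(sv),
               ignore_attr = TRUE, tolerance = 1e-10)
  # quadratic scaling
  expect_equal(unclass(rupp_sv(stk * 3)), 9 * unclass(sv),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("angiography maps light up vessels on the default phantom", {
  sim <- simulate_volume(default_phantom_config(seed = 1))
  stk <- rupp_projection_stack(sim$volume)
  mask <- sim$truth$vessel_mask
  sv <- rupp_sv(stk)
  ed <- rupp_ed(stk)$projection
  expect_gt(median(sv[mask]), median(sv[!mask]))
  expect_gt(median(ed[mask]), median(ed[!mask]))
  expect_gt(vessel_detection_auc(sv, mask), 0.90)
})
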