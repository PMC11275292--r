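#' Mean squared error between two images
#'
#' \deqn{MSE = \sum_x \sum_y (a_{x,y} - gt_{x,y})^2 / (X Y)}
#'
#' @param a,gt numeric matrices of identical shape.
#' @return Nonnegative scalar.
#' @export
oct_mse <- function(a, gt) {
  if (!identical(dim(a), dim(gt))) {
    stop("image shapes differ", call. = FALSE)
  }
  mean((a - gt)^2)
}

#' Peak signal-to-noise ratio (input-peak convention)
#'
#' \deqn{PSNR = 10 \log_{10}(Proj_{maximum}^2 / MSE)} with `Proj_maximum`
#' the maximum value of the *input* image `a` (not a bit-depth constant),
#' which makes the metric deliberately asymmetric in its arguments. A
#' conventional fixed peak can be supplied via `peak`.
#'
#' @param a input image (numeric matrix).
#' @param gt ground-truth image of identical shape.
#' @param peak optional fixed peak value overriding `max(a)`.
#' @return PSNR in dB; `Inf` when the images are identical (zero MSE).
#' @export
oct_psnr <- function(a, gt, peak = NULL) {
  m <- oct_mse(a, gt)
  if (is.null(peak)) peak <- max(a)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

# Banded matrix applying a 1D valid-mode correlation with kernel w along one
# axis: (n - w + 1) x n.
valid_filter_matrix <- function(n, w) {
  k <- length(w)
  if (k > n) stop("window larger than image", call. = FALSE)
  Tm <- matrix(0, n - k + 1L, n)
  for (i in seq_len(n - k + 1L)) Tm[i, i:(i + k - 1L)] <- w
  Tm
}

gaussian_kernel_1d <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

#' Structural similarity index (luminance-contrast-structure form)
#'
#' Windowed SSIM built from the three stabilised comparison functions,
#' \deqn{SSIM = mean\big( C_l^\alpha \, C_c^\beta \, C_s^\gamma \big)}
#' with
#' \eqn{C_l = (2\mu_a\mu_g + C_1)/(\mu_a^2 + \mu_g^2 + C_1)},
#' \eqn{C_c = (2\sigma_a\sigma_g + C_2)/(\sigma_a^2 + \sigma_g^2 + C_2)},
#' \eqn{C_s = (\sigma_{ag} + C_3)/(\sigma_a\sigma_g + C_3)},
#' \eqn{C_1 = (K_1 L)^2}, \eqn{C_2 = (K_2 L)^2}, \eqn{C_3 = C_2/2}.
#' Local statistics use a sliding window evaluated at fully-interior
#' positions (valid mode, no padding). Defaults follow the de-facto standard
#' toolbox settings: Gaussian 11 x 11 window with sigma 1.5, `K1 = 0.01`,
#' `K2 = 0.03`, and dynamic range `L = max(gt) - min(gt)`. The structure
#' term can be negative; for non-integer `gamma` it is raised as
#' `sign(s) * |s|^gamma`.
#'
#' @param a,gt numeric matrices of identical shape.
#' @param alpha,beta,gamma positive exponents of the three terms.
#' @param window `"gaussian"` or `"uniform"`.
#' @param window_size odd window side length.
#' @param sigma Gaussian window standard deviation (pixels).
#' @param K1,K2 stabiliser constants.
#' @param dynamic_range value range `L`; default `max(gt) - min(gt)` (1 is
#'   used for a constant ground truth).
#' @return SSIM in `[-1, 1]`; 1 exactly when the images are identical.
#' @export
oct_ssim <- function(a, gt, alpha = 1, beta = 1, gamma = 1,
                     window = c("gaussian", "uniform"), window_size = 11L,
                     sigma = 1.5, K1 = 0.01, K2 = 0.03,
                     dynamic_range = NULL) {
  if (!identical(dim(a), dim(gt))) stop("image shapes differ", call. = FALSE)
  if (alpha <= 0 || beta <= 0 || gamma <= 0) {
    stop("SSIM exponents must be positive", call. = FALSE)
  }
  window <- match.arg(window)
  window_size <- stopifnot_scalar_int(window_size, "window_size", min = 1)
  if (window_size > min(dim(a))) stop("window larger than image", call. = FALSE)
  if (is.null(dynamic_range)) dynamic_range <- diff(range(gt))
  if (dynamic_range <= 0) dynamic_range <- 1
  w <- if (window == "gaussian") gaussian_kernel_1d(window_size, sigma)
       else rep(1 / window_size, window_size)
  T1 <- valid_filter_matrix(nrow(a), w)
  T2 <- valid_filter_matrix(ncol(a), w)
  win_mean <- function(x) T1 %*% x %*% t(T2)

  mu_a <- win_mean(a); mu_g <- win_mean(gt)
  var_a <- pmax(win_mean(a * a) - mu_a^2, 0)
  var_g <- pmax(win_mean(gt * gt) - mu_g^2, 0)
  cov_ag <- win_mean(a * gt) - mu_a * mu_g

  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  C3 <- C2 / 2
  l <- (2 * mu_a * mu_g + C1) / (mu_a^2 + mu_g^2 + C1)
  cc <- (2 * sqrt(var_a) * sqrt(var_g) + C2) / (var_a + var_g + C2)
  s <- (cov_ag + C3) / (sqrt(var_a) * sqrt(var_g) + C3)
  pow_signed <- function(x, p) sign(x) * abs(x)^p
  mean(pow_signed(l, alpha) * pow_signed(cc, beta) * pow_signed(s, gamma))
}

#' Full image-quality report against a ground-truth image
#'
#' Computes MSE, PSNR and SSIM in one pass. For comparisons *across*
#' reconstruction methods, whose outputs live on incommensurable scales (a
#' raw spectral sum vs a magnitude-spectrum sum vs a variance), both images
#' are min-max normalised to `[0, 1]` first (`normalize = TRUE`, the
#' default); set `normalize = FALSE` for the bare metrics on raw values.
#'
#' @param a input image.
#' @param gt ground-truth image of identical shape.
#' @param normalize min-max rescale both images to `[0, 1]` before the
#'   metrics.
#' @param method optional label stored in the report.
#' @param ... passed to [oct_ssim()].
#' @return An `oct_metrics` list: `psnr`, `ssim`, `mse`, `elapsed_seconds`
#'   (informational wall clock), `method`, `shape`, `normalized`.
#' @export
compare_projections <- function(a, gt, normalize = TRUE, method = NA_character_,
                                ...) {
  t0 <- proc.time()[["elapsed"]]
  aa <- unclass(a); gg <- unclass(gt)
  attributes(aa) <- list(dim = dim(a)); attributes(gg) <- list(dim = dim(gt))
  if (normalize) {
    aa <- normalize01(aa)
    gg <- normalize01(gg)
  }
  out <- structure(
    list(psnr = oct_psnr(aa, gg),
         ssim = oct_ssim(aa, gg, ...),
         mse = oct_mse(aa, gg),
         elapsed_seconds = proc.time()[["elapsed"]] - t0,
         method = method,
         shape = dim(a),
         normalized = isTRUE(normalize)),
    class = "oct_metrics")
  out
}

#' @export
print.oct_metrics <- function(x, ...) {
  cat(sprintf("<oct_metrics%s> PSNR %.3f dB | SSIM %.4f | MSE %.4g\n",
              if (is.na(x$method)) "" else paste0(":", x$method),
              x$psnr, x$ssim, x$mse))
  invisible(x)
}

#' Vessel detection AUC of an angiography map
#'
#' Area under the ROC curve of the map values as a score for the binary
#' vessel mask, computed exactly from the rank statistic (Mann-Whitney
#' form, ties averaged). 1 means perfect separation of vessel from static
#' pixels, 0.5 chance level.
#'
#' @param map numeric matrix of angiography scores.
#' @param mask logical matrix of the same shape (`TRUE` = vessel).
#' @return AUC in `[0, 1]`.
#' @export
vessel_detection_auc <- function(map, mask) {
  if (!identical(dim(map), dim(mask))) stop("shape mismatch", call. = FALSE)
  pos <- as.logical(mask)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("mask needs both classes", call. = FALSE)
  r <- rank(as.numeric(map))
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
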