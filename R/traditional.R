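#' FFT A-line reconstruction of a raw volume
#'
#' The reference pipeline's first step: per A-line, the mean over the
#' wavenumber axis is subtracted (DC/background removal), an unnormalised
#' forward DFT is applied, and the magnitudes of the positive-frequency bins
#' `1..K/2` are kept as the depth-resolved intensity signal `I(z)`. A fringe
#' at depth bin `z` therefore reconstructs at depth index `z`.
#'
#' @param vol an [oct_volume()] with even K.
#' @return An `oct_intensity_volume`: nonnegative Z x X x Y x N array with
#'   `Z = K/2` (depth axis first) plus geometry fields.
#' @export
fft_reconstruct <- function(vol) {
  stopifnot(inherits(vol, "oct_volume"))
  if (vol$K %% 2L != 0L) stop("K must be even", call. = FALSE)
  if (!all(is.finite(vol$data))) stop("non-finite input volume", call. = FALSE)
  K <- vol$K
  Z <- K %/% 2L
  M <- matrix(vol$data, nrow = K)
  M <- sweep(M, 2L, colMeans(M))
  FT <- stats::mvfft(M)
  I <- Mod(FT[2:(Z + 1L), , drop = FALSE])   # frequencies 1..K/2
  structure(
    list(data = array(I, dim = c(Z, vol$X, vol$Y, vol$N)),
         Z = Z, X = vol$X, Y = vol$Y, N = vol$N,
         downsampled = vol$downsampled, seed = vol$seed),
    class = "oct_intensity_volume")
}

#' @export
print.oct_intensity_volume <- function(x, ...) {
  cat(sprintf("<oct_intensity_volume> %d x %d x %d x %d (Z x X x Y x N)\n",
              x$Z, x$X, x$Y, x$N))
  invisible(x)
}

#' Traditional depth-summation structural projection
#'
#' The reference structural projection: per-pixel sum of the reconstructed
#' intensity signal over depth, \eqn{Proj(x,y) = \sum_{z=1}^{Z} I_{x,y}(z)}.
#'
#' @param ivol an `oct_intensity_volume` from [fft_reconstruct()].
#' @param repeat_index which repeat to project, in `1..N`.
#' @return An `oct_projection` (provenance `"traditional"`).
#' @export
traditional_summation_projection <- function(ivol, repeat_index = 1L) {
  stopifnot(inherits(ivol, "oct_intensity_volume"))
  repeat_index <- stopifnot_scalar_int(repeat_index, "repeat_index", min = 1)
  if (repeat_index > ivol$N) {
    stop(sprintf("repeat_index %d out of range [1, %d]", repeat_index, ivol$N),
         call. = FALSE)
  }
  values <- colSums(matrix(ivol$data[, , , repeat_index], nrow = ivol$Z))
  new_projection(matrix(values, ivol$X, ivol$Y),
                 provenance = "traditional", downsampled = ivol$downsampled)
}

#' Multi-repeat ground-truth structural projection
#'
#' Averages the reconstructed A-line intensities over `n_repeats` repeated
#' acquisitions (12 by convention: repeated averaging is the standard
#' noise-reduction route to a reference image when no true ground truth
#' exists in vivo), then depth-sums the averaged A-lines into a projection.
#'
#' @param vol an [oct_volume()] with `N >= n_repeats`.
#' @param n_repeats repeats to average (default 12).
#' @return An `oct_projection` (provenance `"ground_truth"`) with attribute
#'   `n_repeats_used`.
#' @export
ground_truth_structural <- function(vol, n_repeats = 12L) {
  stopifnot(inherits(vol, "oct_volume"))
  n_repeats <- stopifnot_scalar_int(n_repeats, "n_repeats", min = 2)
  if (vol$N < n_repeats) {
    stop(sprintf("ground truth needs N >= %d repeats, volume has %d",
                 n_repeats, vol$N), call. = FALSE)
  }
  ivol <- fft_reconstruct(vol)
  use <- ivol$data[, , , seq_len(n_repeats), drop = FALSE]
  mean_I <- array(rowMeans(matrix(use, ncol = n_repeats)),
                  dim = c(ivol$Z, ivol$X, ivol$Y))
  values <- colSums(matrix(mean_I, nrow = ivol$Z))
  p <- new_projection(matrix(values, ivol$X, ivol$Y),
                      provenance = "ground_truth",
                      downsampled = vol$downsampled)
  attr(p, "n_repeats_used") <- n_repeats
  p
}

#' Volumetric speckle-variance angiography (traditional baseline)
#'
#' Per-voxel population variance over the N repeats of the reconstructed
#' intensity volume, then depth-summed to a 2D angiography map. This is the
#' 3D counterpart of [rupp_sv()] and the conventional intensity-based OCTA
#' baseline.
#'
#' @param ivol an `oct_intensity_volume` with `N >= 2`.
#' @return An `oct_angio` map (method `"sv3d"`).
#' @export
sv3d <- function(ivol) {
  stopifnot(inherits(ivol, "oct_intensity_volume"))
  if (ivol$N < 2L) stop("need N >= 2 repeats", call. = FALSE)
  M <- matrix(ivol$data, ncol = ivol$N)      # voxels x repeats
  m <- rowMeans(M)
  v <- rowMeans((M - m)^2)
  vmap <- array(v, dim = c(ivol$Z, ivol$X, ivol$Y))
  new_angio(matrix(colSums(matrix(vmap, nrow = ivol$Z)), ivol$X, ivol$Y),
            method = "sv3d")
}

#' Frame-wise eigen-decomposition angiography (traditional baseline)
#'
#' Generic eigen clutter filter on the reconstructed volume: for every
#' slow-axis position y the N repeated B-frames are flattened to an
#' N x (Z*X) Casorati matrix, the dominant eigenvectors of its correlation
#' matrix are removed (automatic `r`: eigenvalues above their mean), the
#' residual frames are collapsed by the mean of absolute values over N and
#' depth-summed to one image row; the rows assemble the map.
#'
#' @param ivol an `oct_intensity_volume` with `N >= 2`.
#' @param r `"auto"` or integer removal count in `[0, N)` used for every
#'   B-frame position.
#' @return An `oct_angio` map (method `"frame_ed"`) with attribute
#'   `r_per_frame` (integer vector, one entry per y).
#' @export
frame_ed <- function(ivol, r = "auto") {
  stopifnot(inherits(ivol, "oct_intensity_volume"))
  if (ivol$N < 2L) stop("need N >= 2 repeats", call. = FALSE)
  Z <- ivol$Z; X <- ivol$X; Y <- ivol$Y; N <- ivol$N
  map <- matrix(0, X, Y)
  r_used <- integer(Y)
  for (y in seq_len(Y)) {
    frames <- ivol$data[, , y, , drop = FALSE]     # Z x X x 1 x N
    P <- t(matrix(frames, nrow = Z * X))            # N x (Z*X)
    ef <- ed_filter_casorati(P, r = r, warn_r0 = FALSE)
    r_used[y] <- ef$r
    resid <- matrix(colMeans(abs(ef$residual)), nrow = Z)  # Z x X
    map[, y] <- colSums(resid)
  }
  out <- new_angio(map, method = "frame_ed")
  attr(out, "r_per_frame") <- r_used
  out
}
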