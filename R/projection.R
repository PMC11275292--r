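#' Structural en-face projection by spectral summation (no Fourier transform)
#'
#' The zero-frequency DFT coefficient of a real signal is the plain sum of its
#' samples, and the depth-summed reconstructed A-line is dominated by the same
#' quantity, so summing the raw interferogram over the wavenumber axis yields
#' a structural projection without any Fourier transform:
#' \deqn{Proj(x, y) = \sum_{k=1}^{K} E_{x,y}(k).}
#' Only summation is performed on this code path; no background subtraction
#' or windowing is applied (an optional reference offset can be removed with
#' `background`).
#'
#' @param vol an [oct_volume()].
#' @param repeat_index which repeat to project, in `1..N`.
#' @param background optional scalar subtracted from every sample before
#'   summation (off by default; the DC term carries the depth-integrated
#'   sample power that forms the image).
#' @return An `oct_projection` (X x Y matrix, provenance `"rupp"`).
#' @examples
#' sim <- simulate_volume(default_phantom_config(K = 64, X = 16, Y = 16, seed = 1))
#' p <- rupp_structural_projection(sim$volume)
#' p
#' @export
rupp_structural_projection <- function(vol, repeat_index = 1L, background = 0) {
  stopifnot(inherits(vol, "oct_volume"))
  repeat_index <- stopifnot_scalar_int(repeat_index, "repeat_index", min = 1)
  if (repeat_index > vol$N) {
    stop(sprintf("repeat_index %d out of range [1, %d]", repeat_index, vol$N),
         call. = FALSE)
  }
  slab <- vol$data[, , , repeat_index]
  if (background != 0) slab <- slab - background
  values <- colSums(matrix(slab, nrow = vol$K))
  new_projection(matrix(values, vol$X, vol$Y),
                 provenance = "rupp", downsampled = vol$downsampled)
}

#' Repeat-resolved stack of spectral-summation projections
#'
#' Projects every repeat of the volume with [rupp_structural_projection()]
#' and stacks them in acquisition order. The stack is the input of the 2D
#' angiography filters; it decomposes conceptually into static clutter, a
#' flow (angiography) component that varies over the repeats, and noise.
#'
#' @param vol an [oct_volume()] with `N >= 2`.
#' @return An `oct_projection_stack`: an N x X x Y array (frame n in row n).
#' @seealso [rupp_sv()], [rupp_ed()]
#' @export
rupp_projection_stack <- function(vol) {
  stopifnot(inherits(vol, "oct_volume"))
  if (vol$N < 2L) {
    stop("angiography needs at least 2 repeats (N >= 2)", call. = FALSE)
  }
  frames <- array(0, dim = c(vol$N, vol$X, vol$Y))
  for (n in seq_len(vol$N)) {
    frames[n, , ] <- rupp_structural_projection(vol, n)
  }
  structure(frames, downsampled = vol$downsampled,
            class = c("oct_projection_stack", class(frames)))
}

#' @export
print.oct_projection_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<oct_projection_stack> %d frames of %d x %d, range [%.4g, %.4g]\n",
              d[1L], d[2L], d[3L], min(x), max(x)))
  invisible(x)
}
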