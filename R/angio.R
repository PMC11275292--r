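#' Frame correlation matrix of a projection stack
#'
#' Flattens the N x X x Y stack to its Casorati matrix `P` (one frame per
#' row, X*Y columns) and returns the N x N sample correlation matrix
#' \deqn{\hat C = \frac{1}{N} P P^H.} For the real-valued spectral-summation
#' path the Hermitian transpose reduces to the transpose, but conjugation is
#' kept so the same kernel serves complex frame-wise baselines.
#'
#' @param stack an `oct_projection_stack` (or any N x X x Y array, N >= 2).
#' @return An N x N symmetric positive semidefinite matrix.
#' @export
projection_correlation_matrix <- function(stack) {
  stopifnot(length(dim(stack)) == 3L)
  if (dim(stack)[1L] < 2L) stop("need N >= 2 frames", call. = FALSE)
  if (!all(is.finite(stack))) {
    stop("degenerate stack: non-finite frame values", call. = FALSE)
  }
  P <- casorati(stack)
  (P %*% Conj(t(P))) / nrow(P)
}

#' Automatic eigenvector-removal count for clutter filtering
#'
#' The number of clutter eigenvectors to remove is the count of eigenvalues
#' strictly greater than the arithmetic mean of all eigenvalues: the dominant
#' components above the mean represent the static-tissue clutter. May return
#' 0 when all eigenvalues are equal (no dominant clutter).
#'
#' @param eigenvalues numeric vector sorted in decreasing order.
#' @return Integer `r`, `0 <= r < length(eigenvalues) + 1`.
#' @export
select_r_auto <- function(eigenvalues) {
  if (length(eigenvalues) == 0L) stop("empty eigenvalue vector", call. = FALSE)
  if (is.unsorted(rev(eigenvalues), strictly = FALSE)) {
    stop("eigenvalues must be sorted in decreasing order", call. = FALSE)
  }
  sum(eigenvalues > mean(eigenvalues))
}

# Shared eigen-decomposition clutter filter on a Casorati matrix (frames as
# rows). Returns the correlation matrix, its eigensystem, the removal count r
# and the residual after projecting the rows off the top-r eigenvector span.
ed_filter_casorati <- function(P, r = "auto", warn_r0 = FALSE) {
  N <- nrow(P)
  C <- (P %*% Conj(t(P))) / N
  es <- eigen(C, symmetric = TRUE)
  if (identical(r, "auto")) {
    r <- select_r_auto(es$values)
    if (r == 0L && warn_r0) {
      warning("all eigenvalues equal their mean: no dominant clutter, ",
              "filter is the identity (r = 0)", call. = FALSE)
    }
  } else {
    r <- stopifnot_scalar_int(r, "r", min = 0)
    if (r >= N) stop(sprintf("r must satisfy 0 <= r < N = %d", N), call. = FALSE)
  }
  if (r > 0L) {
    Er <- es$vectors[, seq_len(r), drop = FALSE]
    residual <- P - Er %*% (Conj(t(Er)) %*% P)
  } else {
    residual <- P
  }
  list(correlation = C, values = es$values, vectors = es$vectors,
       r = as.integer(r), residual = residual)
}

#' Eigen-decomposition clutter filtering of a projection stack (2D OCTA)
#'
#' Decomposes the frame correlation matrix
#' \eqn{\hat C = M \Lambda M^H} (eigenvalues sorted decreasingly) and removes
#' the `r` dominant eigenvectors from the stack:
#' \deqn{Proj_a = (Id - \sum_{i=1}^{r} e_i e_i^H) \cdot Proj^N.}
#' With `r = "auto"`, `r` is the number of eigenvalues above their mean
#' ([select_r_auto()]). The N residual frames are collapsed to one
#' angiography map as the mean of their absolute values.
#'
#' @param stack an `oct_projection_stack` (N x X x Y, N >= 2).
#' @param r `"auto"` or an integer in `[0, N)`; `r = 0` is the identity
#'   filter.
#' @return A list with components
#'   \describe{
#'     \item{projection}{`oct_angio` map (X x Y, nonnegative, method
#'       `"rupp_ed"`),}
#'     \item{filter}{an `eigen_filter` object: `correlation` (N x N),
#'       `eigenvalues`, `eigenvectors`, `r`, `residual_stack` (N x X x Y).}
#'   }
#' @examples
#' sim <- simulate_volume(default_phantom_config(K = 64, X = 16, Y = 16, seed = 1))
#' fit <- rupp_ed(rupp_projection_stack(sim$volume))
#' fit$filter
#' @export
rupp_ed <- function(stack, r = "auto") {
  stopifnot(length(dim(stack)) == 3L)
  d <- dim(stack)
  if (d[1L] < 2L) stop("need N >= 2 frames", call. = FALSE)
  if (!all(is.finite(stack))) {
    stop("degenerate stack: non-finite frame values", call. = FALSE)
  }
  ef <- ed_filter_casorati(casorati(stack), r = r, warn_r0 = TRUE)
  angio <- matrix(colMeans(abs(ef$residual)), d[2L], d[3L])
  filter <- structure(
    list(correlation = ef$correlation, eigenvalues = ef$values,
         eigenvectors = ef$vectors, r = ef$r,
         residual_stack = array(ef$residual, dim = d)),
    class = "eigen_filter")
  list(projection = new_angio(angio, method = "rupp_ed"), filter = filter)
}

#' @export
print.eigen_filter <- function(x, ...) {
  cat(sprintf("<eigen_filter> N = %d frames, r = %d removed\n",
              length(x$eigenvalues), x$r))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Speckle-variance angiography on a projection stack (2D OCTA)
#'
#' Per-pixel population variance of the N repeated projections:
#' \deqn{Proj_a(x, y) = \frac{1}{N} \sum_{n=1}^{N} (Proj_n - Proj_{mean})^2,}
#' where `Proj_mean` is the pixel-wise mean frame. Static pixels carry only
#' the noise variance; flow pixels decorrelate across repeats and light up.
#' The divisor is N (population variance), and the map is reported as a
#' variance, not a standard deviation.
#'
#' @param stack an `oct_projection_stack` (N x X x Y, N >= 2).
#' @return An `oct_angio` map (X x Y, nonnegative, method `"rupp_sv"`).
#' @export
rupp_sv <- function(stack) {
  stopifnot(length(dim(stack)) == 3L)
  d <- dim(stack)
  if (d[1L] < 2L) stop("need N >= 2 frames", call. = FALSE)
  P <- casorati(stack)
  m <- colMeans(P)
  v <- colMeans(sweep(P, 2L, m)^2)
  new_angio(matrix(v, d[2L], d[3L]), method = "rupp_sv")
}
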