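#' Raw interference volume container
#'
#' Wraps a 4D array of real-valued detector samples in the fixed axis order
#' K x X x Y x N (wavenumber, fast lateral, slow lateral, repeat). This is the
#' sole measured input of both projection pipelines. Optional acquisition
#' metadata (centre wavelength, sweep rate, ...) is carried along but never
#' used by the mathematics.
#'
#' @param data numeric 4D array, dimensions K x X x Y x N, finite values only.
#' @param seed integer seed the volume was simulated with, or `NA` for
#'   externally acquired data.
#' @param config the [sim_config()] used to generate the volume, if any.
#' @param downsampled logical; `TRUE` if the spectral axis has been decimated
#'   by [downsample_volume_half()].
#' @param metadata named list of acquisition metadata, carried but unused.
#' @return An object of class `oct_volume` with elements `data`, `K`, `X`,
#'   `Y`, `N`, `seed`, `config`, `downsampled`, `metadata`.
#' @seealso [simulate_volume()], [downsample_volume_half()], [read_volume()]
#' @export
oct_volume <- function(data, seed = NA_integer_, config = NULL,
                       downsampled = FALSE, metadata = list()) {
  d <- dim(data)
  if (length(d) != 4L) {
    stop("raw volume must be a 4D array ordered K x X x Y x N", call. = FALSE)
  }
  if (!is.numeric(data) || anyNA(data) || !all(is.finite(data))) {
    stop("raw volume must contain finite numeric values only", call. = FALSE)
  }
  structure(
    list(
      data = data,
      K = d[1L], X = d[2L], Y = d[3L], N = d[4L],
      seed = seed, config = config,
      downsampled = isTRUE(downsampled),
      metadata = metadata
    ),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  cat(sprintf(
    "<oct_volume> %d x %d x %d x %d (K x X x Y x N)%s\n",
    x$K, x$X, x$Y, x$N,
    if (x$downsampled) ", spectrally downsampled" else ""
  ))
  cat(sprintf("  range [%.4g, %.4g]", min(x$data), max(x$data)))
  if (!is.na(x$seed)) cat(sprintf(", seed %d", x$seed))
  cat("\n")
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$data)

# En-face projection container: an X x Y matrix plus provenance.
new_projection <- function(values, provenance = c("rupp", "traditional", "ground_truth"),
                           downsampled = FALSE) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(values))
  structure(values,
            provenance = provenance,
            downsampled = isTRUE(downsampled),
            class = c("oct_projection", class(values)))
}

#' @export
print.oct_projection <- function(x, ...) {
  cat(sprintf("<oct_projection:%s> %d x %d, range [%.4g, %.4g]%s\n",
              attr(x, "provenance"), nrow(x), ncol(x), min(x), max(x),
              if (isTRUE(attr(x, "downsampled"))) " (downsampled source)" else ""))
  invisible(x)
}

new_angio <- function(values, method) {
  stopifnot(is.matrix(values), all(is.finite(values)), all(values >= 0))
  structure(values, method = method,
            class = c("oct_angio", class(values)))
}

#' @export
print.oct_angio <- function(x, ...) {
  cat(sprintf("<oct_angio:%s> %d x %d, range [%.4g, %.4g]\n",
              attr(x, "method"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}
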