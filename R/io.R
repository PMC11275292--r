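#' Write / read a raw volume container
#'
#' Volumes are stored as a single-file hierarchical container holding the
#' `raw` dataset (K x X x Y x N array), the geometry attributes K/X/Y/N, the
#' seed and a configuration echo, and — when simulated — the phantom ground
#' truth (`reflectivity`, `vessel_mask`) alongside. The container is an
#' RDS-serialised validated list; the round trip is lossless and
#' bit-identical.
#'
#' @param vol an [oct_volume()].
#' @param path file path (conventionally `.octvol`).
#' @param truth optional `oct_phantom_truth` saved alongside the raw data.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   list with `volume` (an `oct_volume`) and `truth` (an
#'   `oct_phantom_truth` or `NULL`).
#' @export
write_volume <- function(vol, path, truth = NULL) {
  stopifnot(inherits(vol, "oct_volume"))
  if (!is.null(truth)) stopifnot(inherits(truth, "oct_phantom_truth"))
  payload <- list(
    format = "rupp-volume", version = 1L,
    raw = vol$data,
    K = vol$K, X = vol$X, Y = vol$Y, N = vol$N,
    seed = vol$seed, config = vol$config,
    downsampled = vol$downsampled, metadata = vol$metadata,
    reflectivity = if (!is.null(truth)) truth$reflectivity_map,
    vessel_mask = if (!is.null(truth)) truth$vessel_mask,
    scatterer_table = if (!is.null(truth)) truth$scatterer_table
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt volume container: ", conditionMessage(e), call. = FALSE)
  })
  if (!is.list(payload) || !identical(payload$format, "rupp-volume")) {
    stop("not a rupp volume container (missing format marker)", call. = FALSE)
  }
  if (is.null(payload$raw)) {
    stop("volume container is missing the 'raw' dataset", call. = FALSE)
  }
  d <- dim(payload$raw)
  if (length(d) != 4L) {
    stop("shape mismatch: 'raw' dataset must have 4 axes (K x X x Y x N), ",
         "found ", length(d), call. = FALSE)
  }
  declared <- c(payload$K, payload$X, payload$Y, payload$N)
  if (length(declared) != 4L || !all(d == declared)) {
    stop("shape mismatch: declared K/X/Y/N attributes disagree with the ",
         "'raw' dataset dimensions", call. = FALSE)
  }
  vol <- oct_volume(payload$raw,
                    seed = if (is.null(payload$seed)) NA_integer_ else payload$seed,
                    config = payload$config,
                    downsampled = isTRUE(payload$downsampled),
                    metadata = if (is.null(payload$metadata)) list() else payload$metadata)
  truth <- NULL
  if (!is.null(payload$reflectivity)) {
    truth <- structure(
      list(reflectivity_map = payload$reflectivity,
           vessel_mask = payload$vessel_mask,
           scatterer_table = payload$scatterer_table),
      class = "oct_phantom_truth")
  }
  list(volume = vol, truth = truth)
}

#' Export / import a projection as a 16-bit TIFF (or PNG preview)
#'
#' Projections are kept at native floating precision throughout the
#' pipeline; display quantisation happens only here. Values are min-max
#' normalised to `[0, 1]` and written at the requested bit depth. Import
#' returns the quantised values in `[0, 1]`.
#'
#' @param proj numeric matrix (`oct_projection` / `oct_angio`).
#' @param path output path; extension `.tif`/`.tiff` or `.png`.
#' @param bits bits per sample for TIFF (8 or 16; default 16).
#' @return `export_projection` returns `path` invisibly; `import_projection`
#'   returns a plain numeric matrix in `[0, 1]`.
#' @export
export_projection <- function(proj, path, bits = 16L) {
  img <- normalize01(unclass(as.matrix(proj)))
  ext <- tolower(tools::file_ext(path))
  # image writers treat rows as the vertical axis; transpose so x runs across
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(t(img), path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    png::writePNG(t(img), path)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname export_projection
#' @export
import_projection <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  t(img)
}
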