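#' Vessel geometry primitives for the phantom
#'
#' Dynamic (flow) regions of the synthetic phantom are described as a set of
#' geometric primitives in the lateral X-Y plane: filled disks and straight
#' tubes (segments with a half-width). Pixels covered by at least one
#' primitive receive dynamic scatterers and are marked in the ground-truth
#' vessel mask.
#'
#' @param center,from,to numeric length-2 pixel coordinates `(x, y)`.
#' @param radius,halfwidth positive extent in pixels.
#' @return A vessel primitive (a small classed list) for use in the
#'   `vessel_spec` field of [sim_config()].
#' @export
vessel_disk <- function(center, radius) {
  stopifnot(length(center) == 2L, is.numeric(center), radius > 0)
  structure(list(type = "disk", center = as.numeric(center),
                 radius = as.numeric(radius)), class = "vessel_region")
}

#' @rdname vessel_disk
#' @export
vessel_tube <- function(from, to, halfwidth) {
  stopifnot(length(from) == 2L, length(to) == 2L, halfwidth > 0)
  structure(list(type = "tube", from = as.numeric(from), to = as.numeric(to),
                 halfwidth = as.numeric(halfwidth)), class = "vessel_region")
}

# Rasterise the vessel primitives to a logical X x Y mask. Errors if any
# primitive extends beyond the lateral grid.
rasterize_vessels <- function(vessel_spec, X, Y) {
  mask <- matrix(FALSE, X, Y)
  if (length(vessel_spec) == 0L) return(mask)
  gx <- matrix(seq_len(X), X, Y)
  gy <- matrix(rep(seq_len(Y), each = X), X, Y)
  for (v in vessel_spec) {
    if (!inherits(v, "vessel_region")) {
      stop("vessel_spec entries must be created by vessel_disk()/vessel_tube()",
           call. = FALSE)
    }
    if (v$type == "disk") {
      lo <- v$center - v$radius
      hi <- v$center + v$radius
      if (lo[1] < 1 || lo[2] < 1 || hi[1] > X || hi[2] > Y) {
        stop("vessel disk extends outside the X x Y grid", call. = FALSE)
      }
      mask <- mask | ((gx - v$center[1])^2 + (gy - v$center[2])^2 <= v$radius^2)
    } else {
      lo <- pmin(v$from, v$to) - v$halfwidth
      hi <- pmax(v$from, v$to) + v$halfwidth
      if (lo[1] < 1 || lo[2] < 1 || hi[1] > X || hi[2] > Y) {
        stop("vessel tube extends outside the X x Y grid", call. = FALSE)
      }
      # distance from each pixel centre to the segment from-to
      d <- v$to - v$from
      len2 <- sum(d^2)
      if (len2 == 0) {
        dist2 <- (gx - v$from[1])^2 + (gy - v$from[2])^2
      } else {
        t <- ((gx - v$from[1]) * d[1] + (gy - v$from[2]) * d[2]) / len2
        t <- pmin(pmax(t, 0), 1)
        dist2 <- (gx - (v$from[1] + t * d[1]))^2 + (gy - (v$from[2] + t * d[2]))^2
      }
      mask <- mask | (dist2 <= v$halfwidth^2)
    }
  }
  mask
}

#' Simulation configuration for synthetic FD-OCT interferograms
#'
#' Describes a swept-source OCT acquisition of a phantom made of discrete
#' scatterers: per A-line, `n_static_scatterers` static reflectors at random
#' depths plus, inside vessel regions, `n_dynamic_scatterers` flow reflectors
#' whose phase is redrawn (and amplitude jittered) independently at every
#' repeat. The detector signal per wavenumber index `i = 0..K-1` is
#' \deqn{E(i) = B + g \sum_j a_j(n)^2 + \sum_j a_j(n)\cos(2\pi z_j i/K + \phi_j(n)) + \epsilon_i}
#' with \eqn{\epsilon_i \sim N(0, \sigma^2)}. The `g`-weighted term is the
#' depth-integrated sample power riding on the detector DC, which is what the
#' spectral-summation projection reads out. Depth bin `z` maps to discrete
#' frequency `z` cycles per `K` samples, so the magnitude DFT of an A-line
#' peaks at bin `z`.
#'
#' @param K wavenumber samples per A-line (even, >= 8). Default 768 matches a
#'   typical swept-source acquisition.
#' @param X,Y lateral grid size (fast, slow axis). Defaults 400 x 400.
#' @param N repeated scans per slow-axis position (>= 2). Default 4.
#' @param n_static_scatterers static reflectors per A-line.
#' @param n_dynamic_scatterers flow reflectors per vessel A-line.
#' @param depth_range fraction of the Nyquist depth `K/2` that scatterers may
#'   occupy; the default 0.5 confines them to the superficial half, emulating
#'   light attenuation in tissue.
#' @param dc_offset detector background level `B` (>= 0).
#' @param sample_dc_gain weight `g` of the depth-integrated sample power on
#'   the DC level.
#' @param vessel_spec list of [vessel_disk()]/[vessel_tube()] primitives
#'   marking dynamic pixels.
#' @param dynamic_amplitude_jitter fractional per-repeat amplitude jitter of
#'   dynamic scatterers: `a_j(n) = a_j (1 + jitter * u_n)`, `u_n ~ U(-1, 1)`.
#' @param dynamic_phase_mode `"redraw"` (uniform random phase per repeat,
#'   full decorrelation) or `"fixed"`.
#' @param noise_sigma additive white Gaussian noise standard deviation on the
#'   detector samples.
#' @param amplitude_range range of the uniform scatterer amplitude draw.
#' @param scatterers optional explicit data.frame with columns `z`,
#'   `amplitude`, `phase`, `dynamic`, applied identically to every A-line
#'   (dynamic rows only inside vessel pixels); overrides the random draw.
#' @param seed integer RNG seed; identical seed + config give bit-identical
#'   output.
#' @param metadata optional named list carried on the volume, unused by the
#'   mathematics.
#' @return A `sim_config` object (validated list).
#' @seealso [simulate_volume()], [default_phantom_config()]
#' @export
sim_config <- function(K = 768, X = 400, Y = 400, N = 4,
                       n_static_scatterers = 6,
                       n_dynamic_scatterers = 3,
                       depth_range = 0.5,
                       dc_offset = 10,
                       sample_dc_gain = 0.5,
                       vessel_spec = list(),
                       dynamic_amplitude_jitter = 0.5,
                       dynamic_phase_mode = c("redraw", "fixed"),
                       noise_sigma = 0.2,
                       amplitude_range = c(0.5, 1.5),
                       scatterers = NULL,
                       seed = 1L,
                       metadata = list()) {
  K <- stopifnot_scalar_int(K, "K", min = 8)
  if (K %% 2L != 0L) stop("'K' must be even", call. = FALSE)
  X <- stopifnot_scalar_int(X, "X", min = 1)
  Y <- stopifnot_scalar_int(Y, "Y", min = 1)
  N <- stopifnot_scalar_int(N, "N", min = 2)
  n_static_scatterers <- stopifnot_scalar_int(n_static_scatterers,
                                              "n_static_scatterers", min = 0)
  n_dynamic_scatterers <- stopifnot_scalar_int(n_dynamic_scatterers,
                                               "n_dynamic_scatterers", min = 0)
  stopifnot(depth_range > 0, depth_range <= 1,
            dc_offset >= 0, sample_dc_gain >= 0,
            dynamic_amplitude_jitter >= 0, noise_sigma >= 0,
            length(amplitude_range) == 2L,
            amplitude_range[1] > 0, diff(amplitude_range) >= 0)
  dynamic_phase_mode <- match.arg(dynamic_phase_mode)
  seed <- stopifnot_scalar_int(seed, "seed")
  if (!is.null(scatterers)) {
    stopifnot(is.data.frame(scatterers),
              all(c("z", "amplitude", "phase", "dynamic") %in% names(scatterers)))
    if (any(scatterers$z >= K / 2)) {
      stop("scatterer depth at or beyond the Nyquist depth K/2: ",
           "aliasing misconfiguration", call. = FALSE)
    }
    if (any(scatterers$z < 1)) stop("scatterer depths must be >= 1", call. = FALSE)
  }
  zmax <- floor(depth_range * K / 2 - 1e-9)
  if (is.null(scatterers) && n_static_scatterers + n_dynamic_scatterers > 0 &&
      zmax < 1) {
    stop("depth_range * K / 2 leaves no usable depth bin", call. = FALSE)
  }
  structure(
    list(K = K, X = X, Y = Y, N = N,
         n_static_scatterers = n_static_scatterers,
         n_dynamic_scatterers = n_dynamic_scatterers,
         depth_range = depth_range, dc_offset = dc_offset,
         sample_dc_gain = sample_dc_gain, vessel_spec = vessel_spec,
         dynamic_amplitude_jitter = dynamic_amplitude_jitter,
         dynamic_phase_mode = dynamic_phase_mode,
         noise_sigma = noise_sigma, amplitude_range = amplitude_range,
         scatterers = scatterers, seed = seed, metadata = metadata),
    class = "sim_config"
  )
}

#' Desk-scale default phantom configuration
#'
#' A 64 x 64 lateral grid with 256 spectral samples and 4 repeats: the same
#' statistical structure as a full 768 x 400 x 400 x 4 acquisition at a size
#' every test and example can afford. The vessel tree is two crossing tubes
#' and one disk (~13% of pixels dynamic).
#'
#' @param K,X,Y,N geometry overrides.
#' @param seed RNG seed.
#' @param ... further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
default_phantom_config <- function(K = 256, X = 64, Y = 64, N = 4, seed = 1L, ...) {
  # clamp primitive anchor points so the full extent stays on the grid even
  # for very small test grids
  clamp <- function(p, margin) {
    pmin(pmax(p, 1 + margin), c(X, Y) - margin)
  }
  r_disk <- 0.08 * min(X, Y)
  vessels <- list(
    vessel_tube(from = clamp(c(0.12 * X, 0.08 * Y), 1.5),
                to = clamp(c(0.88 * X, 0.92 * Y), 1.5), halfwidth = 1.5),
    vessel_tube(from = clamp(c(0.08 * X, 0.70 * Y), 1.0),
                to = clamp(c(0.92 * X, 0.30 * Y), 1.0), halfwidth = 1.0),
    vessel_disk(center = clamp(c(0.75 * X, 0.22 * Y), r_disk), radius = r_disk)
  )
  sim_config(K = K, X = X, Y = Y, N = N, vessel_spec = vessels, seed = seed, ...)
}

#' Simulate a raw FD-OCT interference volume with known ground truth
#'
#' Draws the phantom (scatterer depths, amplitudes, phases and the vessel
#' mask) and synthesises the K x X x Y x N detector volume per the forward
#' model documented in [sim_config()]. Static scatterers keep amplitude and
#' phase across repeats; dynamic scatterers are redrawn per repeat, which is
#' what every angiography statistic in the package detects.
#'
#' @param config a [sim_config()].
#' @return A list with components
#'   \describe{
#'     \item{volume}{an [oct_volume()] of raw interference samples,}
#'     \item{truth}{an `oct_phantom_truth`: `reflectivity_map` (X x Y sums of
#'       scatterer amplitudes), `vessel_mask` (X x Y logical, `TRUE` exactly
#'       where at least one dynamic scatterer exists), and `scatterer_table`
#'       (one row per scatterer: `x`, `y`, `z`, `amplitude`, `phase`,
#'       `dynamic`).}
#'   }
#' @examples
#' sim <- simulate_volume(default_phantom_config(K = 64, X = 16, Y = 16, seed = 7))
#' sim$volume
#' mean(sim$truth$vessel_mask)
#' @export
simulate_volume <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$K; X <- config$X; Y <- config$Y; N <- config$N
  XY <- X * Y
  zmax <- floor(config$depth_range * K / 2 - 1e-9)

  with_seed(config$seed, {
    mask <- rasterize_vessels(config$vessel_spec, X, Y)
    vpix <- which(mask)            # column-major pixel indices

    if (is.null(config$scatterers)) {
      ns <- config$n_static_scatterers
      nd <- config$n_dynamic_scatterers
      n_stat <- ns * XY
      n_dyn <- nd * length(vpix)
      if (ns + nd > zmax) {
        stop("more scatterers per A-line than usable depth bins", call. = FALSE)
      }
      # Depths are distinct within an A-line: each discrete reflector occupies
      # its own axial resolution cell. A uniform random permutation of the
      # usable bins per pixel gives static bins (rows 1..ns) and, inside
      # vessels, dynamic bins (rows ns+1..ns+nd).
      if (ns + nd > 0L) {
        ord <- apply(matrix(runif(zmax * XY), zmax, XY), 2L, order)
      }
      sc <- data.frame(
        pixel = c(rep(seq_len(XY), each = ns), rep(vpix, each = nd)),
        z = c(if (n_stat) as.integer(ord[seq_len(ns), , drop = FALSE]) else integer(0),
              if (n_dyn) as.integer(ord[ns + seq_len(nd), vpix, drop = FALSE]) else integer(0)),
        amplitude = runif(n_stat + n_dyn, config$amplitude_range[1],
                          config$amplitude_range[2]),
        phase = runif(n_stat + n_dyn, 0, 2 * pi),
        dynamic = rep(c(FALSE, TRUE), c(n_stat, n_dyn))
      )
    } else {
      tab <- config$scatterers
      stat_rows <- tab[!tab$dynamic, , drop = FALSE]
      dyn_rows <- tab[tab$dynamic, , drop = FALSE]
      sc <- data.frame(
        pixel = c(rep(seq_len(XY), each = nrow(stat_rows)),
                  rep(vpix, each = nrow(dyn_rows))),
        z = c(rep(stat_rows$z, times = XY), rep(dyn_rows$z, times = length(vpix))),
        amplitude = c(rep(stat_rows$amplitude, times = XY),
                      rep(dyn_rows$amplitude, times = length(vpix))),
        phase = c(rep(stat_rows$phase, times = XY),
                  rep(dyn_rows$phase, times = length(vpix))),
        dynamic = c(rep(FALSE, nrow(stat_rows) * XY),
                    rep(TRUE, nrow(dyn_rows) * length(vpix)))
      )
    }
    if (any(sc$z >= K / 2)) {
      stop("scatterer depth at or beyond the Nyquist depth K/2: ",
           "aliasing misconfiguration", call. = FALSE)
    }

    # ground truth
    refl <- matrix(0, X, Y)
    if (nrow(sc)) {
      agg <- rowsum(sc$amplitude, group = sc$pixel)
      refl[as.integer(rownames(agg))] <- agg[, 1L]
    }
    truth_mask <- matrix(FALSE, X, Y)
    truth_mask[unique(sc$pixel[sc$dynamic])] <- TRUE
    truth <- structure(
      list(reflectivity_map = refl,
           vessel_mask = truth_mask,
           scatterer_table = data.frame(
             x = (sc$pixel - 1L) %% X + 1L,
             y = (sc$pixel - 1L) %/% X + 1L,
             z = sc$z, amplitude = sc$amplitude, phase = sc$phase,
             dynamic = sc$dynamic)),
      class = "oct_phantom_truth")

    # shared fringe basis over the distinct depths present
    dyn <- sc$dynamic
    n_dyn_sc <- sum(dyn)
    if (nrow(sc)) {
      zu <- sort(unique(sc$z))
      theta <- outer(0:(K - 1), zu) * (2 * pi / K)
      Cb <- cos(theta); Sb <- sin(theta)
      zi <- match(sc$z, zu)
      grp <- (sc$pixel - 1L) * length(zu) + zi   # (depth, pixel) cell
    }

    vol <- array(0, dim = c(K, X, Y, N))
    for (n in seq_len(N)) {
      a_n <- sc$amplitude
      phi_n <- sc$phase
      if (n_dyn_sc) {
        if (config$dynamic_phase_mode == "redraw") {
          phi_n[dyn] <- runif(n_dyn_sc, 0, 2 * pi)
        }
        if (config$dynamic_amplitude_jitter > 0) {
          a_n[dyn] <- a_n[dyn] *
            (1 + config$dynamic_amplitude_jitter * runif(n_dyn_sc, -1, 1))
        }
      }
      dc <- rep(config$dc_offset, XY)
      En <- matrix(0, K, XY)
      if (nrow(sc)) {
        uv <- rowsum(cbind(a_n * cos(phi_n), a_n * sin(phi_n)), group = grp)
        cells <- as.integer(rownames(uv))
        U <- matrix(0, length(zu), XY); V <- matrix(0, length(zu), XY)
        U[cells] <- uv[, 1L]; V[cells] <- uv[, 2L]
        En <- Cb %*% U - Sb %*% V
        if (config$sample_dc_gain > 0) {
          pw <- rowsum(a_n^2, group = sc$pixel)
          dc[as.integer(rownames(pw))] <- dc[as.integer(rownames(pw))] +
            config$sample_dc_gain * pw[, 1L]
        }
      }
      En <- En + rep(dc, each = K)
      if (config$noise_sigma > 0) {
        En <- En + matrix(rnorm(K * XY, sd = config$noise_sigma), K, XY)
      }
      vol[, , , n] <- En
    }

    list(volume = oct_volume(vol, seed = config$seed, config = config,
                             metadata = config$metadata),
         truth = truth)
  })
}

#' @export
print.oct_phantom_truth <- function(x, ...) {
  cat(sprintf("<oct_phantom_truth> %d x %d, %d scatterers (%d dynamic), %.1f%% vessel pixels\n",
              nrow(x$reflectivity_map), ncol(x$reflectivity_map),
              nrow(x$scatterer_table), sum(x$scatterer_table$dynamic),
              100 * mean(x$vessel_mask)))
  invisible(x)
}

#' Half-band spectral down-sampling of a raw volume
#'
#' Keeps the odd-numbered spectral samples (1st, 3rd, 5th, ... in 1-based
#' indexing), halving K and therefore the Nyquist depth. This emulates
#' acquisition-time decimation: it is the only entry point for the
#' "with down-sampling" pipeline variants, and a fringe at depth bin
#' `z < K/4` survives at the same bin of the shorter spectrum.
#'
#' @param vol an [oct_volume()] with even K.
#' @return An [oct_volume()] with `K/2` spectral samples, flagged
#'   `downsampled`.
#' @export
downsample_volume_half <- function(vol) {
  stopifnot(inherits(vol, "oct_volume"))
  if (vol$K %% 2L != 0L) {
    stop("down-sampling requires an even number of spectral samples", call. = FALSE)
  }
  keep <- seq(1L, vol$K, by = 2L)
  oct_volume(vol$data[keep, , , , drop = FALSE],
             seed = vol$seed, config = vol$config,
             downsampled = TRUE, metadata = vol$metadata)
}
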