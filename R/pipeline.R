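#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the simulation (or an input
#' volume path), the structural method, an optional angiography method, the
#' down-sampling flag, the eigen-filter `r` policy, SSIM parameters and
#' output paths. Round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param sim a [sim_config()] describing the phantom (used when `input`
#'   is `NULL`).
#' @param input optional path of a stored volume (see [read_volume()]);
#'   overrides `sim`.
#' @param structural_method `"rupp"` or `"traditional"`.
#' @param angio_method `NULL` (structural only) or one of `"rupp-sv"`,
#'   `"rupp-ed"`, `"sv3d"`, `"frame-ed"`.
#' @param downsample apply [downsample_volume_half()] before processing.
#' @param r eigen-filter removal count policy: `"auto"` or an integer.
#' @param gt_repeats repeats used for the synthetic ground truth (default
#'   12); the ground-truth acquisition re-simulates the same phantom (same
#'   seed and static scatterer field) with this many repeats.
#' @param evaluate compute PSNR/SSIM/MSE against the ground truth.
#' @param ssim named list of overrides passed to [oct_ssim()].
#' @param out_image,out_report optional output paths (TIFF/PNG image, JSON
#'   report).
#' @param seed seed override applied to `sim` (kept in sync so one value
#'   drives the whole run).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = default_phantom_config(),
                            input = NULL,
                            structural_method = c("rupp", "traditional"),
                            angio_method = NULL,
                            downsample = FALSE,
                            r = "auto",
                            gt_repeats = 12L,
                            evaluate = TRUE,
                            ssim = list(),
                            out_image = NULL,
                            out_report = NULL,
                            seed = NULL) {
  structural_method <- match.arg(structural_method)
  if (!is.null(angio_method)) {
    angio_method <- match.arg(angio_method,
                              c("rupp-sv", "rupp-ed", "sv3d", "frame-ed"))
  }
  if (!is.null(seed)) {
    sim$seed <- stopifnot_scalar_int(seed, "seed")
  }
  structure(
    list(sim = sim, input = input,
         structural_method = structural_method,
         angio_method = angio_method,
         downsample = isTRUE(downsample), r = r,
         gt_repeats = stopifnot_scalar_int(gt_repeats, "gt_repeats", min = 2),
         evaluate = isTRUE(evaluate), ssim = ssim,
         out_image = out_image, out_report = out_report),
    class = "pipeline_config")
}

# sim_config <-> plain list (for lossless YAML round trips)
sim_config_to_list <- function(sc) {
  x <- unclass(sc)
  x$vessel_spec <- lapply(x$vessel_spec, unclass)
  if (!is.null(x$scatterers)) x$scatterers <- as.list(x$scatterers)
  x
}

sim_config_from_list <- function(x) {
  x$vessel_spec <- lapply(x$vessel_spec, function(v) {
    if (v$type == "disk") vessel_disk(unlist(v$center), v$radius)
    else vessel_tube(unlist(v$from), unlist(v$to), v$halfwidth)
  })
  if (!is.null(x$scatterers)) x$scatterers <- as.data.frame(x$scatterers)
  x$metadata <- if (is.null(x$metadata)) list() else x$metadata
  do.call(sim_config, x[setdiff(names(x), character(0))])
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` the reconstructed `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$sim <- sim_config_to_list(x$sim)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- sim_config_from_list(x$sim)
  pipeline_config(sim = sim, input = x$input,
                  structural_method = x$structural_method,
                  angio_method = x$angio_method,
                  downsample = x$downsample, r = x$r,
                  gt_repeats = x$gt_repeats, evaluate = x$evaluate,
                  ssim = if (is.null(x$ssim)) list() else x$ssim,
                  out_image = x$out_image, out_report = x$out_report)
}

#' Run one end-to-end projection pipeline
#'
#' Executes simulate (or load) -> optional down-sampling -> structural
#' projection -> optional angiography -> optional evaluation against the
#' multi-repeat synthetic ground truth, logging per-stage wall-clock
#' timings. Timings are informational only — they depend on the machine —
#' but they are the practical point of the spectral-summation path, so they
#' are always reported. Deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return A `rupp_report` list: the output `image` (projection or angio
#'   map), `metrics` (an `oct_metrics` or `NULL`), `timings` (named seconds
#'   per stage), `r` (eigen filter removal count, if any), `config` echo,
#'   and the `truth` used for evaluation (if simulated).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  tic <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    list(value = value, elapsed = proc.time()[["elapsed"]] - t0)
  }
  say <- function(...) if (!quiet) message(sprintf(...))

  # --- acquire ---
  st <- tic({
    if (!is.null(config$input)) {
      read_volume(config$input)
    } else {
      simulate_volume(config$sim)
    }
  })
  sim <- st$value
  timings["acquire"] <- st$elapsed
  vol <- sim$volume
  truth <- sim$truth
  say("acquire: %.3fs (%d x %d x %d x %d)", st$elapsed, vol$K, vol$X, vol$Y, vol$N)

  if (config$downsample) {
    st <- tic(downsample_volume_half(vol))
    vol <- st$value
    timings["downsample"] <- st$elapsed
  }

  r_used <- NA_integer_
  if (is.null(config$angio_method)) {
    st <- tic(switch(config$structural_method,
      rupp = rupp_structural_projection(vol),
      traditional = traditional_summation_projection(fft_reconstruct(vol))
    ))
    image <- st$value
    timings["projection"] <- st$elapsed
  } else {
    st <- tic(switch(config$angio_method,
      "rupp-sv" = rupp_sv(rupp_projection_stack(vol)),
      "rupp-ed" = {
        fit <- rupp_ed(rupp_projection_stack(vol), r = config$r)
        r_used <- fit$filter$r
        fit$projection
      },
      "sv3d" = sv3d(fft_reconstruct(vol)),
      "frame-ed" = frame_ed(fft_reconstruct(vol), r = config$r)
    ))
    image <- st$value
    timings["angiography"] <- st$elapsed
  }
  say("%s: %.3fs", if (is.null(config$angio_method)) "projection" else "angiography",
      st$elapsed)

  metrics <- NULL
  if (config$evaluate) {
    if (!is.null(config$input)) {
      stop("evaluation needs a simulated phantom (ground truth regeneration)",
           call. = FALSE)
    }
    st <- tic({
      gt_sim_cfg <- config$sim
      gt_sim_cfg$N <- config$gt_repeats
      gt_sim <- simulate_volume(gt_sim_cfg)
      if (is.null(config$angio_method)) {
        ground_truth_structural(gt_sim$volume, n_repeats = config$gt_repeats)
      } else {
        frame_ed(fft_reconstruct(gt_sim$volume))
      }
    })
    gt <- st$value
    timings["ground_truth"] <- st$elapsed
    st <- tic(do.call(compare_projections,
                      c(list(a = image, gt = gt,
                             method = if (is.null(config$angio_method))
                               config$structural_method else config$angio_method),
                        config$ssim)))
    metrics <- st$value
    timings["evaluate"] <- st$elapsed
    say("evaluate: PSNR %.2f dB, SSIM %.3f", metrics$psnr, metrics$ssim)
  }

  if (!is.null(config$out_image)) export_projection(image, config$out_image)
  report <- structure(
    list(image = image, metrics = metrics, timings = timings,
         r = r_used, config = config, truth = truth),
    class = "rupp_report")
  if (!is.null(config$out_report)) {
    jsonlite::write_json(
      list(psnr = if (is.null(metrics)) NULL else metrics$psnr,
           ssim = if (is.null(metrics)) NULL else metrics$ssim,
           mse = if (is.null(metrics)) NULL else metrics$mse,
           elapsed_seconds = as.list(timings),
           method = if (is.null(config$angio_method))
             config$structural_method else config$angio_method,
           r = if (is.na(r_used)) NULL else r_used,
           shape = dim(image)),
      config$out_report, auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

#' @export
print.rupp_report <- function(x, ...) {
  method <- if (is.null(x$config$angio_method)) {
    paste0("structural/", x$config$structural_method)
  } else {
    paste0("angio/", x$config$angio_method)
  }
  cat(sprintf("<rupp_report> %s%s, image %d x %d\n", method,
              if (x$config$downsample) " (downsampled)" else "",
              nrow(x$image), ncol(x$image)))
  cat("  timings:",
      paste(sprintf("%s %.3fs", names(x$timings), x$timings), collapse = ", "),
      "\n")
  if (!is.null(x$metrics)) {
    cat(sprintf("  PSNR %.3f dB | SSIM %.4f | MSE %.4g\n",
                x$metrics$psnr, x$metrics$ssim, x$metrics$mse))
  }
  if (!is.na(x$r)) cat(sprintf("  eigen filter removed r = %d component(s)\n", x$r))
  invisible(x)
}
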