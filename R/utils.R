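# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state afterwards
# so simulation calls do not perturb user scripts.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopifnot_scalar_int <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x != round(x)) {
    stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
  }
  if (x < min) stop(sprintf("'%s' must be >= %s", name, min), call. = FALSE)
  as.integer(x)
}

# Flatten an N x X x Y stack to its Casorati matrix: one frame per row,
# pixels in column-major (x fastest) order. With the repeat axis first this
# is just a dim drop.
casorati <- function(frames) {
  stopifnot(length(dim(frames)) == 3L)
  matrix(frames, nrow = dim(frames)[1L])
}

# Min-max rescale to [0, 1]; constant images map to all zeros.
normalize01 <- function(x) {
  r <- range(x)
  if (r[2L] > r[1L]) (x - r[1L]) / (r[2L] - r[1L]) else x * 0
}
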