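# misc internal helpers

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# round-half-up to integer (voxel index rounding for crops)
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Separable Gaussian blur of a 3D array
#'
#' Truncated discrete Gaussian (radius `ceiling(2.5 * sigma)`) applied along
#' each axis with replicated edges.
#'
#' @param vol 3D numeric array.
#' @param sigma standard deviation in voxels.
#' @return Blurred array, same dimensions.
#' @keywords internal
gaussian_blur3 <- function(vol, sigma = 0.8) {
  if (sigma <= 0) return(vol)
  r <- ceiling(2.5 * sigma)
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  dims <- dim(vol)
  for (ax in 1:3) {
    n <- dims[ax]
    acc <- array(0, dims)
    for (s in -r:r) {
      idx <- clamp(seq_len(n) + s, 1L, n)
      shifted <- switch(ax,
                        vol[idx, , , drop = FALSE],
                        vol[, idx, , drop = FALSE],
                        vol[, , idx, drop = FALSE])
      acc <- acc + w[s + r + 1L] * shifted
    }
    vol <- acc
  }
  vol
}
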