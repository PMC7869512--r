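#' Simulate random-walk blob trajectories
#'
#' Each blob performs an independent isotropic Gaussian random walk with
#' i.i.d. per-frame increments of standard deviation `step_sigma` voxels.
#' Starting positions are uniform over the interior box
#' `[radius, dim - radius]`, and the chosen boundary policy keeps every
#' coordinate inside that box so a blob of the given radius always fits in
#' the volume.
#'
#' @param n_blobs number of blobs.
#' @param dims spatial volume extent `(nx, ny, nz)` in voxels.
#' @param n_frames number of time points.
#' @param step_sigma per-axis step standard deviation, voxels.
#' @param boundary `"reflect"` (mirror at the interior box) or `"clip"`.
#' @param radius blob radius in voxels (the boundary margin).
#' @param seed optional RNG seed for reproducibility.
#' @return A `traceset` with one trace per blob and one marker per frame.
#' @export
simulate_random_walks <- function(n_blobs = 5, dims = c(50, 50, 50),
                                  n_frames = 100, step_sigma = 1,
                                  boundary = c("reflect", "clip"),
                                  radius = 3, seed = NULL) {
  boundary <- match.arg(boundary)
  if (n_blobs < 1) stop("`n_blobs` must be >= 1", call. = FALSE)
  if (step_sigma <= 0) stop("`step_sigma` must be > 0", call. = FALSE)
  if (any(dims <= 2 * radius)) {
    stop("`dims` too small to contain a blob of this radius", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  lo <- rep(radius, 3)
  hi <- dims - radius

  reflect <- function(p, lo, hi) {
    period <- 2 * (hi - lo)
    y <- (p - lo) %% period
    y <- ifelse(y > period / 2, period - y, y)
    lo + y
  }

  walks <- purrr::map_dfr(seq_len(n_blobs), function(b) {
    pos <- matrix(0, n_frames, 3)
    pos[1, ] <- stats::runif(3, lo, hi)
    if (n_frames > 1) {
      steps <- matrix(stats::rnorm(3 * (n_frames - 1), sd = step_sigma),
                      n_frames - 1, 3)
      for (f in 2:n_frames) {
        p <- pos[f - 1, ] + steps[f - 1, ]
        pos[f, ] <- if (boundary == "reflect") {
          reflect(p, lo, hi)
        } else {
          pmin(pmax(p, lo), hi)
        }
      }
    }
    tibble::tibble(
      trace_id = sprintf("blob_%d", b), label = "ground_truth",
      t = 0:(n_frames - 1), x = pos[, 1], y = pos[, 2], z = pos[, 3]
    )
  })
  as_traceset(walks, provenance = list(format = "simulation",
                                       step_sigma = step_sigma,
                                       boundary = boundary, radius = radius))
}

#' Rasterize blob traces into a 4D stack
#'
#' Paints, at every frame, a solid sphere of the given radius and intensity
#' around each marker position onto a uniform background. A voxel (center
#' at its integer index) is set to `intensity` iff it lies within `radius`
#' (Euclidean) of any marker of that frame.
#'
#' @param traces a `traceset` of blob centers.
#' @param dims spatial extent `(nx, ny, nz)`.
#' @param n_frames number of frames of the output stack.
#' @param radius sphere radius, voxels.
#' @param intensity,background grey levels (default 8-bit 200 on 20).
#' @param dtype stack dtype, see [stack4d()].
#' @return A [stack4d()] object.
#' @export
rasterize_blobs <- function(traces, dims, n_frames, radius = 3,
                            intensity = 200, background = 20,
                            dtype = "uint8") {
  traces <- as_traceset(traces, provenance = attr(traces, "provenance"))
  if (nrow(traces) > 0) {
    inside <- traces$x >= 0 & traces$x <= dims[1] - 1 &
      traces$y >= 0 & traces$y <= dims[2] - 1 &
      traces$z >= 0 & traces$z <= dims[3] - 1 &
      traces$t < n_frames
    if (!all(inside)) stop("marker outside the volume or frame range", call. = FALSE)
  }
  vox <- array(background, dim = c(dims, n_frames))
  for (i in seq_len(nrow(traces))) {
    cx <- traces$x[i]; cy <- traces$y[i]; cz <- traces$z[i]
    tt <- traces$t[i] + 1L
    xr <- max(0, ceiling(cx - radius)):min(dims[1] - 1, floor(cx + radius))
    yr <- max(0, ceiling(cy - radius)):min(dims[2] - 1, floor(cy + radius))
    zr <- max(0, ceiling(cz - radius)):min(dims[3] - 1, floor(cz + radius))
    if (length(xr) == 0 || length(yr) == 0 || length(zr) == 0) next
    dx2 <- (xr - cx)^2; dy2 <- (yr - cy)^2; dz2 <- (zr - cz)^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    block <- vox[xr + 1L, yr + 1L, zr + 1L, tt, drop = FALSE]
    block[array(d2 <= radius^2, dim = dim(block))] <- intensity
    vox[xr + 1L, yr + 1L, zr + 1L, tt] <- block
  }
  stack4d(vox, dtype = dtype)
}

#' Corrupt a stack with salt & pepper noise
#'
#' Each voxel is independently replaced, with probability `density`, by an
#' extreme level: half the corrupted voxels get `salt_level`, half
#' `pepper_level` (in expectation).
#'
#' @param stack a [stack4d()] object.
#' @param density corruption probability per voxel, in `[0, 1]`.
#' @param salt_level,pepper_level replacement grey levels (default the
#'   stack's dynamic-range extremes).
#' @param seed optional RNG seed.
#' @return A corrupted copy of `stack`.
#' @export
add_salt_pepper <- function(stack, density = 0.01,
                            salt_level = NULL, pepper_level = NULL,
                            seed = NULL) {
  stopifnot(inherits(stack, "stack4d"))
  if (density < 0 || density > 1) stop("`density` must be in [0, 1]", call. = FALSE)
  if (is.null(salt_level)) salt_level <- stack$dtype_range[2]
  if (is.null(pepper_level)) pepper_level <- stack$dtype_range[1]
  if (!is.null(seed)) set.seed(seed)
  vox <- stack$voxels
  n <- length(vox)
  corrupt <- stats::runif(n) < density
  if (any(corrupt)) {
    salt <- stats::runif(sum(corrupt)) < 0.5
    vals <- ifelse(salt, salt_level, pepper_level)
    vox[corrupt] <- vals
  }
  stack4d(vox, dtype = stack$dtype, dtype_range = stack$dtype_range)
}

#' Generate the synthetic demonstration dataset
#'
#' Composes [simulate_random_walks()], [rasterize_blobs()] and
#' [add_salt_pepper()] into the package's reference toy scene: five equally
#' sized spherical blobs performing a random walk through a
#' `50 x 50 x 50` volume over 100 frames, with salt & pepper noise over the
#' whole stack, returned together with the ground-truth traces.
#'
#' @param seed RNG seed driving walks and noise.
#' @param n_blobs,dims,n_frames scene geometry (defaults: 5 blobs,
#'   `50 x 50 x 50`, 100 frames).
#' @param step_sigma walk step standard deviation, voxels.
#' @param radius blob radius, voxels.
#' @param intensity,background 8-bit grey levels of blobs and background.
#' @param noise_density salt & pepper corruption probability.
#' @return A list with elements `stack` ([stack4d()]) and `traces`
#'   (ground-truth `traceset`).
#' @export
generate_toy_dataset <- function(seed = 1, n_blobs = 5, dims = c(50, 50, 50),
                                 n_frames = 100, step_sigma = 1, radius = 3,
                                 intensity = 200, background = 20,
                                 noise_density = 0.01) {
  set.seed(seed)
  traces <- simulate_random_walks(
    n_blobs = n_blobs, dims = dims, n_frames = n_frames,
    step_sigma = step_sigma, radius = radius
  )
  stack <- rasterize_blobs(
    traces, dims = dims, n_frames = n_frames, radius = radius,
    intensity = intensity, background = background
  )
  stack <- add_salt_pepper(stack, density = noise_density)
  list(stack = stack, traces = traces)
}
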