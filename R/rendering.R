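#' Opacity thresholding of a visualized volume
#'
#' Sets the opacity to zero wherever the visualized (negative, normalized)
#' intensity strictly exceeds `theta`; everywhere else the base opacity is
#' kept. Useful to suppress bright-view artifacts and impulse noise.
#'
#' @param view 3D array of visualized intensities in `[0, 1]`
#'   (see [to_view_volume()]).
#' @param base 3D array of opacities in `[0, 1]`, same shape as `view`.
#' @param theta threshold in `[0, 1]`.
#' @return 3D opacity array, same shape as `view`.
#' @export
opacity_threshold <- function(view, base, theta) {
  if (!identical(dim(view), dim(base))) {
    stop("`view` and `base` must have identical dimensions", call. = FALSE)
  }
  if (theta < 0 || theta > 1) stop("`theta` must lie in [0, 1]", call. = FALSE)
  out <- base
  out[view > theta] <- 0
  out
}

#' Transparency transfer function
#'
#' Maps visualized intensities to opacities under a single parameter
#' `tau >= -1`. For `tau` in `[-1, 0]` every voxel gets the constant opacity
#' `1 + tau`. For `tau > 0` the opacity is `view^tau`: voxels that are dark
#' in the negative view (bright in the original image) become the most
#' transparent, which helps isolate dark compact particles.
#'
#' @param view 3D array of visualized intensities in `[0, 1]`.
#' @param tau transparency parameter in `[-1, Inf)`.
#' @return 3D opacity array in `[0, 1]`.
#' @export
transparency_map <- function(view, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < -1) {
    stop("`tau` must be a single number >= -1", call. = FALSE)
  }
  if (tau <= 0) {
    out <- array(1 + tau, dim = dim(view))
  } else {
    out <- view^tau
    out[view == 0] <- 0  # 0^tau := 0, continuous from above
  }
  out
}

#' Trilinear resampling of a volume
#'
#' Resamples the volume on a finer (or coarser) grid by separable linear
#' interpolation. Output grid point `i` (0-based) along an axis samples the
#' input at coordinate `i / factor`, clamped to the input extent
#' (clamp-to-edge), so the output never exceeds the input's value range.
#'
#' @param view 3D numeric array.
#' @param factor per-axis positive scale factors, length 1 or 3; output dims
#'   are `round(dim(view) * factor)`.
#' @return Resampled 3D array.
#' @export
resample_trilinear <- function(view, factor) {
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  if (length(factor) != 3L || any(factor <= 0)) {
    stop("`factor` must be 1 or 3 positive numbers", call. = FALSE)
  }
  d_in <- dim(view)
  d_out <- pmax(1L, as.integer(round(d_in * factor)))

  # per-axis sample coordinates, clamped to the voxel-index range
  coords <- lapply(1:3, function(ax) {
    pmin(pmax((seq_len(d_out[ax]) - 1) / factor[ax], 0), d_in[ax] - 1)
  })
  lo <- lapply(1:3, function(ax) pmin(floor(coords[[ax]]), d_in[ax] - 1))
  hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1, d_in[ax] - 1))
  fr <- lapply(1:3, function(ax) coords[[ax]] - lo[[ax]])

  out <- array(0, dim = d_out)
  # separable: interpolate along x for both z planes, then y, then z
  for (k in seq_len(d_out[3])) {
    z0 <- lo[[3]][k] + 1L; z1 <- hi[[3]][k] + 1L; fz <- fr[[3]][k]
    plane <- matrix(0, d_out[1], d_out[2])
    for (j in seq_len(d_out[2])) {
      y0 <- lo[[2]][j] + 1L; y1 <- hi[[2]][j] + 1L; fy <- fr[[2]][j]
      x0 <- lo[[1]] + 1L; x1 <- hi[[1]] + 1L; fx <- fr[[1]]
      interp_line <- function(zz) {
        a <- view[, y0, zz][x0] * (1 - fx) + view[, y0, zz][x1] * fx
        b <- view[, y1, zz][x0] * (1 - fx) + view[, y1, zz][x1] * fx
        a * (1 - fy) + b * fy
      }
      plane[, j] <- interp_line(z0) * (1 - fz) + interp_line(z1) * fz
    }
    out[, , k] <- plane
  }
  out
}
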