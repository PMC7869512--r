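#' 4D image stack objects
#'
#' A `stack4d` wraps a 4D voxel grid of grey levels with its dimension and
#' dynamic-range metadata. Axis order is `(x, y, z, t)` mapped to array
#' dimensions 1..4; all external coordinates are 0-based and voxel intervals
#' are half-open.
#'
#' @param voxels numeric 4D array, dimensions `(nx, ny, nz, nt)`.
#' @param dtype one of `"uint8"`, `"uint16"`, `"float"`.
#' @param dtype_range length-2 numeric `(min_level, max_level)`. Defaults to
#'   the full range of the integer dtype, or the observed range for floats.
#' @return A `stack4d` object.
#' @export
#' @examples
#' s <- stack4d(array(0:23, dim = c(2, 3, 2, 2)), dtype = "uint8")
#' dim(s$voxels)
stack4d <- function(voxels, dtype = "uint8", dtype_range = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L) {
    stop("`voxels` must be a 4D array (x, y, z, t)", call. = FALSE)
  }
  if (any(dim(voxels) < 1L)) {
    stop("all stack dimensions must be >= 1", call. = FALSE)
  }
  dtype <- match.arg(dtype, c("uint8", "uint16", "float"))
  if (is.null(dtype_range)) {
    dtype_range <- switch(dtype,
      uint8  = c(0, 255),
      uint16 = c(0, 65535),
      float  = range(voxels)
    )
  }
  dtype_range <- as.numeric(dtype_range)
  if (length(dtype_range) != 2L || dtype_range[2] < dtype_range[1]) {
    stop("`dtype_range` must be (min_level, max_level) with max >= min", call. = FALSE)
  }
  if (min(voxels) < dtype_range[1] || max(voxels) > dtype_range[2]) {
    stop("voxel values fall outside `dtype_range`", call. = FALSE)
  }
  structure(
    list(voxels = voxels, dtype = dtype, dtype_range = dtype_range),
    class = "stack4d"
  )
}

#' @export
print.stack4d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<stack4d> %d x %d x %d voxels, %d frames, dtype %s, range [%g, %g]\n",
    d[1], d[2], d[3], d[4], x$dtype, x$dtype_range[1], x$dtype_range[2]
  ))
  invisible(x)
}

#' @export
dim.stack4d <- function(x) dim(x$voxels)

#' @export
`==.stack4d` <- function(e1, e2) {
  identical(dim(e1$voxels), dim(e2$voxels)) &&
    all(e1$voxels == e2$voxels) &&
    identical(e1$dtype, e2$dtype) &&
    all(e1$dtype_range == e2$dtype_range)
}

#' Half-open 3D region of interest
#'
#' Each interval is a 0-based half-open `[lo, hi)` pair in voxel units.
#'
#' @param x_interval,y_interval,z_interval integer pairs `(lo, hi)`, `lo < hi`.
#' @return An `roi3d` object.
#' @export
roi3d <- function(x_interval, y_interval, z_interval) {
  ivs <- list(x = x_interval, y = y_interval, z = z_interval)
  for (ax in names(ivs)) {
    iv <- ivs[[ax]]
    if (length(iv) != 2L || any(iv != floor(iv)) || iv[1] < 0 || iv[2] <= iv[1]) {
      stop(sprintf("%s_interval must be a non-empty half-open integer interval", ax),
           call. = FALSE)
    }
  }
  structure(lapply(ivs, as.integer), class = "roi3d")
}

#' Crop a stack to a 3D region of interest
#'
#' Extracts the sub-block of voxels covered by `roi` at every frame. The
#' result owns its data: mutating it never touches the input.
#'
#' @param stack a [stack4d()] object.
#' @param roi an [roi3d()] object contained in the stack's spatial dims.
#' @return A `stack4d` with spatial dims equal to the interval lengths.
#' @export
crop_roi <- function(stack, roi) {
  stopifnot(inherits(stack, "stack4d"), inherits(roi, "roi3d"))
  d <- dim(stack$voxels)
  if (roi$x[2] > d[1] || roi$y[2] > d[2] || roi$z[2] > d[3]) {
    stop("ROI exceeds stack dimensions", call. = FALSE)
  }
  sub <- stack$voxels[
    (roi$x[1] + 1L):roi$x[2],
    (roi$y[1] + 1L):roi$y[2],
    (roi$z[1] + 1L):roi$z[2],
    ,
    drop = FALSE
  ]
  stack4d(sub, dtype = stack$dtype, dtype_range = stack$dtype_range)
}

#' Negative normalized view of one frame
#'
#' The displayed ("visualized") intensity is the negative of the raw grey
#' level, rescaled to `[0, 1]`: bright raw voxels become dark view voxels.
#' This is the input to the opacity transfer functions in
#' [opacity_threshold()] and [transparency_map()].
#'
#' @param stack a [stack4d()] object.
#' @param t 0-based frame index.
#' @return A 3D array of class `view_volume` with values in `[0, 1]`.
#' @export
to_view_volume <- function(stack, t) {
  stopifnot(inherits(stack, "stack4d"))
  d <- dim(stack$voxels)
  if (length(t) != 1L || t != floor(t) || t < 0 || t >= d[4]) {
    stop(sprintf("frame index t must be in [0, %d)", d[4]), call. = FALSE)
  }
  rng <- stack$dtype_range
  if (rng[2] <= rng[1]) {
    stop("degenerate dtype_range: max_level must exceed min_level", call. = FALSE)
  }
  v <- (rng[2] - stack$voxels[, , , t + 1L, drop = TRUE]) / (rng[2] - rng[1])
  v <- array(v, dim = d[1:3])
  class(v) <- c("view_volume", class(v))
  v
}

# --- TIFF + sidecar JSON persistence ----------------------------------------
# Layout: one multi-page TIFF per dataset; page index = t * nz + z
# (z fastest); each page is an ny x nx matrix (image rows = y). A sidecar
# JSON <path>.json records nx, ny, nz, nt, dtype and dtype_range.

sidecar_path <- function(path) paste0(path, ".json")

#' Save a stack as multi-page TIFF with JSON sidecar
#'
#' Pages are ordered z-fastest, then t. Integer dtypes round-trip bit
#' exactly; `"float"` stacks are stored as 32-bit floats.
#'
#' @param stack a [stack4d()] object.
#' @param path destination TIFF path; `<path>.json` is written alongside.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path) {
  stopifnot(inherits(stack, "stack4d"))
  d <- dim(stack$voxels)
  rng <- stack$dtype_range
  bps <- switch(stack$dtype, uint8 = 8L, uint16 = 16L, float = 32L)
  scale <- switch(stack$dtype, uint8 = 255, uint16 = 65535, float = NA_real_)
  pages <- vector("list", d[3] * d[4])
  for (tt in seq_len(d[4])) {
    for (zz in seq_len(d[3])) {
      page <- t(stack$voxels[, , zz, tt])  # ny x nx, rows = y
      if (!is.na(scale)) {
        page <- page / scale
      } else {
        # float pages are stored normalized to [0,1] over dtype_range
        page <- if (rng[2] > rng[1]) (page - rng[1]) / (rng[2] - rng[1]) else page * 0
      }
      pages[[(tt - 1L) * d[3] + zz]] <- page
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bps, reduce = FALSE)
  meta <- list(
    nx = d[1], ny = d[2], nz = d[3], nt = d[4],
    dtype = stack$dtype, dtype_range = rng
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a stack from multi-page TIFF
#'
#' Reads the layout written by [save_stack()]. Without a sidecar, `nz` must
#' be given and the page count must be divisible by it; dtype is then
#' inferred from the TIFF sample depth.
#'
#' @param path TIFF path.
#' @param nz number of z-slices per frame (ignored when the sidecar exists).
#' @return A [stack4d()] object.
#' @export
load_stack <- function(path, nz = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    nz <- meta$nz
  }
  if (is.null(nz)) stop("`nz` required when no sidecar JSON is present", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)
  if (n_pages %% nz != 0L) {
    stop(sprintf("page count %d not divisible by nz = %d", n_pages, nz), call. = FALSE)
  }
  dims <- unique(lapply(pages, function(p) dim(p)))
  if (length(dims) != 1L) stop("mixed page sizes in TIFF", call. = FALSE)
  ny <- dims[[1]][1]; nx <- dims[[1]][2]
  nt <- n_pages %/% nz
  vox <- array(0, dim = c(nx, ny, nz, nt))
  for (tt in seq_len(nt)) {
    for (zz in seq_len(nz)) {
      vox[, , zz, tt] <- t(pages[[(tt - 1L) * nz + zz]])
    }
  }
  dtype <- if (is.null(meta)) {
    bps <- attr(pages[[1]], "bits.per.sample")
    if (is.null(bps)) bps <- 8L
    switch(as.character(bps), "8" = "uint8", "16" = "uint16", "float")
  } else {
    meta$dtype
  }
  # readTIFF returns samples normalized to [0,1]; undo per dtype
  if (dtype == "uint8") {
    vox <- round(vox * 255)
  } else if (dtype == "uint16") {
    vox <- round(vox * 65535)
  }
  if (is.null(meta)) {
    stack4d(vox, dtype = dtype, dtype_range = if (dtype == "float") c(0, 1) else NULL)
  } else if (dtype == "float") {
    rng <- meta$dtype_range
    stack4d(rng[1] + vox * (rng[2] - rng[1]), dtype = "float", dtype_range = rng)
  } else {
    stack4d(vox, dtype = dtype, dtype_range = meta$dtype_range)
  }
}
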