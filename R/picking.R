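#' 3D segment
#'
#' @param a,b distinct 3D points (numeric length 3), voxel coordinates.
#' @return A `segment3d` object.
#' @export
segment3d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3L || length(b) != 3L || !all(is.finite(c(a, b)))) {
    stop("segment endpoints must be finite 3D points", call. = FALSE)
  }
  if (all(a == b)) stop("segment endpoints must be distinct", call. = FALSE)
  structure(list(a = a, b = b), class = "segment3d")
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Cast a picking segment through the volume
#'
#' Un-projects a 2D click on the viewing plane into the chord of the
#' volume's bounding box along the viewing direction (orthographic
#' projection). The viewing plane passes through the coordinate origin,
#' orthogonal to `view_dir`; its in-plane basis is built from the
#' sign-canonicalized direction so that a click yields the same chord when
#' the view is reversed (endpoints are ordered along `view_dir`, entry
#' first). With `view_dir = (0, 0, 1)` the click `(cx, cy)` maps to the
#' chord from `(cx, cy, 0)` to `(cx, cy, nz)`.
#'
#' @param click numeric length 2, in-plane coordinates of the click.
#' @param view_dir non-zero 3D viewing direction.
#' @param bounds spatial extent `(nx, ny, nz)` of the volume in voxels.
#' @return A [segment3d()]: the chord of the box `[0,nx]x[0,ny]x[0,nz]`.
#' @export
cast_pick_segment <- function(click, view_dir, bounds) {
  view_dir <- as.numeric(view_dir)
  nrm <- sqrt(sum(view_dir^2))
  if (nrm == 0) stop("`view_dir` must be non-zero", call. = FALSE)
  w <- view_dir / nrm
  # canonical direction: first non-zero component positive
  wc <- w
  nz_comp <- which(abs(wc) > 1e-12)[1]
  if (wc[nz_comp] < 0) wc <- -wc
  up <- c(0, 0, 1)
  if (sqrt(sum(cross3(up, wc)^2)) < 1e-9) up <- c(0, 1, 0)
  u <- cross3(up, wc); u <- u / sqrt(sum(u^2))
  v <- cross3(wc, u)
  p0 <- click[1] * u + click[2] * v

  # slab clipping of the line p0 + s*w against [0,bounds]
  tmin <- -Inf; tmax <- Inf
  for (ax in 1:3) {
    if (abs(w[ax]) < 1e-14) {
      if (p0[ax] < 0 || p0[ax] > bounds[ax]) {
        stop("pick ray misses the volume", call. = FALSE)
      }
    } else {
      t1 <- (0 - p0[ax]) / w[ax]
      t2 <- (bounds[ax] - p0[ax]) / w[ax]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmax < tmin) stop("pick ray misses the volume", call. = FALSE)
  segment3d(p0 + tmin * w, p0 + tmax * w)
}

#' Locate a 3D marker from two picking segments
#'
#' Two clicks from different view angles produce two (usually skew)
#' piercing segments; the marker is placed at the midpoint of the shortest
#' segment connecting them. Closest points are computed on the bounded
#' segments (parameters clamped to `[0, 1]`), not on the infinite lines.
#' Parallel segments do not error: the midpoint of the overlap region is
#' used and the result is flagged degenerate.
#'
#' @param s1,s2 [segment3d()] objects.
#' @param warn_gap warn when the residual gap between the two segments
#'   exceeds this many voxels (likely a mis-click); `Inf` disables.
#' @return A list with `point` (3D marker position), `gap` (distance
#'   between the closest points, voxels) and `degenerate` (TRUE for
#'   parallel segments).
#' @export
locate_marker <- function(s1, s2, warn_gap = Inf) {
  stopifnot(inherits(s1, "segment3d"), inherits(s2, "segment3d"))
  d1 <- s1$b - s1$a
  d2 <- s2$b - s2$a
  r <- s1$a - s2$a
  a <- sum(d1 * d1); e <- sum(d2 * d2)
  b <- sum(d1 * d2); c_ <- sum(d1 * r); f <- sum(d2 * r)
  denom <- a * e - b * b
  degenerate <- denom <= 1e-12 * a * e

  clamp01 <- function(x) min(max(x, 0), 1)
  if (degenerate) {
    # parallel: intersect the projection of s2 onto s1's parameter with [0,1]
    t_c <- -c_ / a                 # param on s1 closest to s2$a
    t_d <- sum(d1 * (s2$b - s1$a)) / a
    ovl <- c(max(0, min(t_c, t_d)), min(1, max(t_c, t_d)))
    s <- if (ovl[1] <= ovl[2]) mean(ovl) else clamp01(mean(c(t_c, t_d)))
    p1 <- s1$a + s * d1
    t <- clamp01(sum(d2 * (p1 - s2$a)) / e)
    p2 <- s2$a + t * d2
  } else {
    s <- clamp01((b * f - c_ * e) / denom)
    t <- (b * s + f) / e
    if (t < 0) {
      t <- 0; s <- clamp01(-c_ / a)
    } else if (t > 1) {
      t <- 1; s <- clamp01((b - c_) / a)
    }
    p1 <- s1$a + s * d1
    p2 <- s2$a + t * d2
  }
  gap <- sqrt(sum((p1 - p2)^2))
  if (is.finite(warn_gap) && gap > warn_gap) {
    warning(sprintf("picking segments are %.3f voxels apart; possible mis-click", gap))
  }
  list(point = (p1 + p2) / 2, gap = gap, degenerate = degenerate)
}
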