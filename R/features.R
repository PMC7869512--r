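#' Canonical names of the 14 trajectory descriptors
#'
#' Six route-based descriptors (geometry of the path) followed by eight
#' hourly-law-based descriptors (moments of the speed and acceleration
#' sets).
#'
#' @return Character vector of length 14.
#' @export
feature_names <- function() {
  c("total_displacement", "mean_angle", "angle_std", "tortuosity",
    "energy", "entropy",
    "mean_velocity", "velocity_std", "velocity_skewness",
    "velocity_kurtosis",
    "mean_acceleration", "acceleration_std", "acceleration_skewness",
    "acceleration_kurtosis")
}

#' Kinematic sets of one trace
#'
#' From the time-ordered markers `p_f` at frames `F`, derives the sets the
#' descriptors are built on: displacements
#' `D_f = ||p_{f+1} - p_f||`, turning angles (arccos of the normalized dot
#' product of consecutive displacement vectors; steps of zero length are
#' skipped), speeds `V_f = D_f / (F(f+1) - F(f))` and accelerations as the
#' forward difference of speeds over the frame gap,
#' `A_f = (V_{f+1} - V_f) / (F(f+1) - F(f))`.
#'
#' @param trace data frame of one trace's markers (`t`, `x`, `y`, `z`);
#'   rows are sorted by `t` internally.
#' @return A `trace_kinematics` list: `frames`, `positions` (n x 3 matrix),
#'   `displacements`, `angles`, `velocities`, `accelerations`.
#' @export
kinematic_sets <- function(trace) {
  trace <- tibble::as_tibble(trace)
  trace <- trace[order(trace$t), ]
  n <- nrow(trace)
  if (n < 2) stop("a trace needs at least 2 markers", call. = FALSE)
  p <- as.matrix(trace[, c("x", "y", "z")])
  f <- as.numeric(trace$t)
  dp <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
  disp <- sqrt(rowSums(dp^2))
  gaps <- diff(f)

  angles <- double(0)
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      n1 <- disp[i]; n2 <- disp[i + 1]
      if (n1 == 0 || n2 == 0) next  # undefined turn on a zero-length step
      cosang <- sum(dp[i, ] * dp[i + 1, ]) / (n1 * n2)
      angles <- c(angles, acos(min(max(cosang, -1), 1)))
    }
  }
  vel <- disp / gaps
  acc <- if (n >= 3) diff(vel) / gaps[-(n - 1)] else double(0)
  structure(
    list(frames = f, positions = p, displacements = disp, angles = angles,
         velocities = vel, accelerations = acc),
    class = "trace_kinematics"
  )
}

# histogram probabilities over the coordinate's own min-max range
axis_pdf <- function(v, n_bins) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(1)  # all mass in a single bin
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(
    pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins
  )
  counts / length(v)
}

sample_sd <- function(v) if (length(v) >= 2) stats::sd(v) else NA_real_

# population-moment (1/n) skewness and raw kurtosis, as used for both
# the speed and the acceleration sets
moment_skewness <- function(v) {
  n <- length(v)
  if (n < 2) return(NA_real_)
  m <- mean(v); m2 <- mean((v - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((v - m)^3) / m2^1.5
}

moment_kurtosis <- function(v) {
  n <- length(v)
  if (n < 2) return(NA_real_)
  m <- mean(v); m2 <- mean((v - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((v - m)^4) / m2^2
}

#' Route-based descriptors
#'
#' Geometry-of-path features: total displacement (sum of step lengths),
#' mean and sample standard deviation of the turning angles, tortuosity
#' (path length over first-to-last chord; 1 for a straight path, undefined
#' when the chord is zero), and the energy and entropy of the per-axis
#' coordinate distributions, estimated by normalized histograms over each
#' axis's own range (`energy = sum over axes and bins of p^2`,
#' `entropy = -sum of p log2 p`, with `0 log 0 := 0`).
#'
#' @param kin a [kinematic_sets()] result.
#' @param n_bins histogram bins per axis for the coordinate pdf estimate.
#' @return A one-row tibble with the 6 route-based features; undefined
#'   values are `NA`.
#' @export
route_features <- function(kin, n_bins = 10) {
  stopifnot(inherits(kin, "trace_kinematics"))
  if (n_bins < 1) stop("`n_bins` must be >= 1", call. = FALSE)
  delta <- sum(kin$displacements)
  p <- kin$positions
  chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  pdfs <- lapply(1:3, function(ax) axis_pdf(p[, ax], n_bins))
  energy <- sum(vapply(pdfs, function(q) sum(q^2), 0))
  entropy <- -sum(vapply(pdfs, function(q) {
    q <- q[q > 0]
    sum(q * log2(q))
  }, 0))
  tibble::tibble(
    total_displacement = delta,
    mean_angle = if (length(kin$angles) > 0) mean(kin$angles) else NA_real_,
    angle_std = sample_sd(kin$angles),
    tortuosity = if (chord > 0) delta / chord else NA_real_,
    energy = energy,
    entropy = entropy
  )
}

#' Hourly-law-based descriptors
#'
#' Moments of the speed and acceleration sets: mean, sample standard
#' deviation (`n - 1` denominator), skewness and raw (non-excess) kurtosis
#' computed from population (`1/n`) central moments.
#'
#' @param kin a [kinematic_sets()] result.
#' @return A one-row tibble with the 8 hourly-law features; entries whose
#'   set is too small (or has zero variance, for skewness/kurtosis) are
#'   `NA`.
#' @export
hourly_features <- function(kin) {
  stopifnot(inherits(kin, "trace_kinematics"))
  v <- kin$velocities; a <- kin$accelerations
  tibble::tibble(
    mean_velocity = if (length(v) >= 1) mean(v) else NA_real_,
    velocity_std = sample_sd(v),
    velocity_skewness = moment_skewness(v),
    velocity_kurtosis = moment_kurtosis(v),
    mean_acceleration = if (length(a) >= 1) mean(a) else NA_real_,
    acceleration_std = sample_sd(a),
    acceleration_skewness = moment_skewness(a),
    acceleration_kurtosis = moment_kurtosis(a)
  )
}

#' Extract the 14 descriptors of one trace
#'
#' @param trace data frame of one trace's markers (`t`, `x`, `y`, `z`).
#' @param n_bins histogram bins per axis, see [route_features()].
#' @return A one-row tibble with exactly the 14 columns of
#'   [feature_names()].
#' @export
extract_features <- function(trace, n_bins = 10) {
  trace <- tibble::as_tibble(trace)
  if (nrow(trace) < 4) {
    stop(sprintf(paste0(
      "trace has %d markers; 4 are required for the full descriptor set ",
      "(with %d markers only displacement/velocity sets are computable)"),
      nrow(trace), nrow(trace)), call. = FALSE)
  }
  kin <- kinematic_sets(trace)
  out <- dplyr::bind_cols(route_features(kin, n_bins = n_bins),
                          hourly_features(kin))
  out[, feature_names()]
}

#' Extract descriptors for every trace of a set
#'
#' Traces too short for the full descriptor set (fewer than 4 markers) are
#' dropped with a message; their count is attached as attribute
#' `n_dropped`.
#'
#' @param ts a trace set.
#' @param n_bins histogram bins per axis, see [route_features()].
#' @return A tibble with `trace_id`, `n_markers` and the 14 feature
#'   columns.
#' @export
compute_features <- function(ts, n_bins = 10) {
  ts <- as_traceset(ts, provenance = attr(ts, "provenance"))
  by_trace <- split(ts, ts$trace_id)
  lens <- vapply(by_trace, nrow, 0L)
  short <- lens < 4
  if (any(short)) {
    message(sprintf("dropping %d trace(s) with fewer than 4 markers",
                    sum(short)))
  }
  rows <- purrr::imap_dfr(by_trace[!short], function(tr, id) {
    dplyr::bind_cols(tibble::tibble(trace_id = id, n_markers = nrow(tr)),
                     extract_features(tr, n_bins = n_bins))
  })
  attr(rows, "n_dropped") <- sum(short)
  rows
}
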