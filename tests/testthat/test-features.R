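straight_trace <- function(n = 5) {
  tibble::tibble(trace_id = "s", t = 0:(n - 1), x = as.numeric(0:(n - 1)),
                 y = 0, z = 0)
}

test_that("kinematic sets have the declared sizes and closed forms", {
  kin <- kinematic_sets(straight_trace(5))
  expect_equal(kin$displacements, rep(1, 4))
  expect_equal(kin$angles, rep(0, 3))
  expect_equal(kin$velocities, rep(1, 4))
  expect_equal(kin$accelerations, rep(0, 3))

  # right-angle turn
  turn <- tibble::tibble(trace_id = "r", t = 0:2, x = c(0, 1, 1),
                         y = c(0, 0, 1), z = 0)
  expect_equal(kinematic_sets(turn)$angles, pi / 2)

  # frame gap enters the speed denominator
  gap <- tibble::tibble(trace_id = "g", t = c(0, 1, 3), x = c(0, 2, 6),
                        y = 0, z = 0)
  kg <- kinematic_sets(gap)
  expect_equal(kg$velocities, c(2 / 1, 4 / 2))
  expect_equal(kg$accelerations, (2 - 2) / 1)

  # zero-length steps are skipped in the angle set
  still <- tibble::tibble(trace_id = "z", t = 0:3, x = c(0, 0, 1, 2),
                          y = 0, z = 0)
  expect_equal(kinematic_sets(still)$angles, 0)

  expect_error(kinematic_sets(straight_trace(1)), "at least 2")
})

test_that("route features: straight line and single-bin closed forms", {
  kin <- kinematic_sets(straight_trace(6))
  rf <- route_features(kin)
  expect_equal(rf$total_displacement, 5)
  expect_equal(rf$tortuosity, 1)
  expect_equal(rf$mean_angle, 0)
  expect_equal(rf$angle_std, 0)

  # all markers at one point: per-axis mass in one bin
  stationary <- tibble::tibble(trace_id = "p", t = 0:4, x = 2, y = 3, z = 4)
  rs <- route_features(kinematic_sets(stationary))
  expect_equal(rs$energy, 3)
  expect_equal(rs$entropy, 0)
  expect_true(is.na(rs$tortuosity))  # zero net displacement is flagged
})

test_that("route features match a naive loop oracle on a listed trace", {
  set.seed(71)
  tr <- tibble::tibble(trace_id = "o", t = 0:9,
                       x = runif(10, 0, 10), y = runif(10, 0, 10),
                       z = runif(10, 0, 10))
  kin <- kinematic_sets(tr)
  rf <- route_features(kin, n_bins = 10)

  # naive oracle
  p <- as.matrix(tr[, c("x", "y", "z")])
  delta <- 0
  for (i in 1:9) delta <- delta + sqrt(sum((p[i + 1, ] - p[i, ])^2))
  expect_equal(rf$total_displacement, delta)
  angs <- c()
  for (i in 1:8) {
    u <- p[i + 1, ] - p[i, ]; v <- p[i + 2, ] - p[i + 1, ]
    angs <- c(angs, acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))
  }
  expect_equal(rf$mean_angle, mean(angs))
  expect_equal(rf$angle_std, sd(angs))
  expect_equal(rf$tortuosity, delta / sqrt(sum((p[10, ] - p[1, ])^2)))

  hist_p <- function(v) {
    br <- seq(min(v), max(v), length.out = 11)
    h <- hist(v, breaks = br, plot = FALSE)$counts / length(v)
    h
  }
  en <- 0; ent <- 0
  for (ax in 1:3) {
    q <- hist_p(p[, ax])
    en <- en + sum(q^2)
    ent <- ent - sum(ifelse(q > 0, q * log2(q), 0))
  }
  expect_equal(rf$energy, en)
  expect_equal(rf$entropy, ent)
})

test_that("hourly features use sample std and 1/n moment normalizations", {
  # constant speed
  hf0 <- hourly_features(kinematic_sets(straight_trace(5)))
  expect_equal(hf0$mean_velocity, 1)
  expect_equal(hf0$velocity_std, 0)
  expect_equal(hf0$mean_acceleration, 0)
  expect_equal(hf0$acceleration_std, 0)

  # V = {1, 2, 3}: mean 2, sample std 1
  tr <- tibble::tibble(trace_id = "v", t = 0:3, x = c(0, 1, 3, 6), y = 0, z = 0)
  hf <- hourly_features(kinematic_sets(tr))
  expect_equal(hf$mean_velocity, 2)
  expect_equal(hf$velocity_std, 1)

  # V = {1, 1, 4}: brute-force moment oracle with 1/n normalizations
  tr2 <- tibble::tibble(trace_id = "w", t = 0:3, x = c(0, 1, 2, 6), y = 0, z = 0)
  hf2 <- hourly_features(kinematic_sets(tr2))
  v <- c(1, 1, 4)
  m2 <- mean((v - mean(v))^2); m3 <- mean((v - mean(v))^3)
  m4 <- mean((v - mean(v))^4)
  expect_equal(hf2$velocity_skewness, m3 / m2^1.5)
  expect_equal(hf2$velocity_kurtosis, m4 / m2^2)  # raw, not excess
})

test_that("the full descriptor vector has exactly the 14 canonical entries", {
  set.seed(73)
  tr <- tibble::tibble(trace_id = "f", t = 0:7, x = rnorm(8), y = rnorm(8),
                       z = rnorm(8))
  fv <- extract_features(tr)
  expect_identical(names(fv), feature_names())
  expect_equal(ncol(fv), 14)
  expect_error(extract_features(tr[1:3, ]), "4 are required")
})

test_that("descriptors are invariant under translation, rotation and time reversal", {
  set.seed(79)
  tr <- tibble::tibble(trace_id = "i", t = 0:11, x = cumsum(rnorm(12)),
                       y = cumsum(rnorm(12)), z = cumsum(rnorm(12)))
  fv <- extract_features(tr)

  shifted <- tr
  shifted$x <- shifted$x + 100; shifted$y <- shifted$y - 40
  expect_equal(as.numeric(extract_features(shifted)), as.numeric(fv),
               tolerance = 1e-9)

  Q <- random_rotation(81)
  p <- as.matrix(tr[, c("x", "y", "z")]) %*% t(Q)
  rot <- tibble::tibble(trace_id = "i", t = tr$t, x = p[, 1], y = p[, 2],
                        z = p[, 3])
  fr <- extract_features(rot)
  invariant <- c("total_displacement", "mean_angle", "angle_std", "tortuosity",
                 "mean_velocity", "velocity_std", "velocity_skewness",
                 "velocity_kurtosis", "mean_acceleration", "acceleration_std",
                 "acceleration_skewness", "acceleration_kurtosis")
  expect_equal(as.numeric(fr[, invariant]), as.numeric(fv[, invariant]),
               tolerance = 1e-9)

  # scaling multiplies displacement by s, leaves tortuosity and angles alone
  s <- 3.7
  scaled <- tr
  scaled$x <- scaled$x * s; scaled$y <- scaled$y * s; scaled$z <- scaled$z * s
  fs <- extract_features(scaled)
  expect_equal(fs$total_displacement, s * fv$total_displacement)
  expect_equal(fs$tortuosity, fv$tortuosity)
  expect_equal(fs$mean_angle, fv$mean_angle)

  # reversed straight line keeps path/chord geometry
  st <- straight_trace(6)
  rev_st <- st
  rev_st$x <- rev(st$x)
  expect_equal(extract_features(rev_st)$total_displacement,
               extract_features(st)$total_displacement)
  expect_equal(extract_features(rev_st)$tortuosity,
               extract_features(st)$tortuosity)
})

test_that("per-set extraction drops short traces with a count", {
  ts <- as_traceset(dplyr::bind_rows(
    tibble::tibble(trace_id = "long", t = 0:9, x = rnorm(10), y = rnorm(10),
                   z = rnorm(10)),
    tibble::tibble(trace_id = "short", t = 0:1, x = 1:2, y = 0, z = 0)
  ))
  expect_message(f <- compute_features(ts), "dropping 1")
  expect_equal(nrow(f), 1)
  expect_equal(attr(f, "n_dropped"), 1)
  expect_true(all(feature_names() %in% names(f)))
})
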