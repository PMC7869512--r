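# Fixtures and independent oracles shared across the suite. Everything is
# generated in code under fixed seeds; no binary fixtures on disk.

random_stack <- function(dims, seed = 1, dtype = "uint8") {
  set.seed(seed)
  hi <- if (dtype == "uint16") 65535L else 255L
  stack4d(array(sample(0:hi, prod(dims), replace = TRUE), dim = dims),
          dtype = dtype)
}

random_traceset <- function(n_traces = 3, n_frames = 10, seed = 1,
                            extent = 30) {
  set.seed(seed)
  as_traceset(purrr::map_dfr(seq_len(n_traces), function(i) {
    tibble::tibble(
      trace_id = sprintf("tr_%02d", i),
      t = 0:(n_frames - 1),
      x = runif(n_frames, 0, extent),
      y = runif(n_frames, 0, extent),
      z = runif(n_frames, 0, extent)
    )
  }))
}

# traces with prescribed lengths (frames 0..len-1), for stratification tests
traceset_with_lengths <- function(lengths, seed = 1) {
  set.seed(seed)
  as_traceset(purrr::imap_dfr(lengths, function(len, i) {
    tibble::tibble(
      trace_id = sprintf("len%03d_%02d", len, i),
      t = 0:(len - 1),
      x = runif(len, 0, 50), y = runif(len, 0, 50), z = runif(len, 0, 50)
    )
  }))
}

# exhaustive maximum-weight matching: enumerate every matching on the
# allowed edges and return the best total weight (independent of igraph)
oracle_matching_weight <- function(dist_mat, allowed, epsilon) {
  nc <- nrow(dist_mat)
  ng <- ncol(dist_mat)
  best <- 0
  recurse <- function(i, used, w) {
    if (i > nc) {
      best <<- max(best, w)
      return(invisible())
    }
    recurse(i + 1, used, w)  # leave test marker i unmatched
    for (g in seq_len(ng)) {
      if (allowed[i, g] && !used[g]) {
        used[g] <- TRUE
        recurse(i + 1, used, w + 1 / (epsilon + dist_mat[i, g]))
        used[g] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, ng), 0)
  best
}

# dense 2-parameter grid search for the closest points of two segments,
# iteratively refined; independent of the closed-form solver
oracle_segment_closest <- function(s1, s2, n = 201, iters = 3) {
  d1 <- s1$b - s1$a
  d2 <- s2$b - s2$a
  tr <- c(0, 1); sr <- c(0, 1)
  for (it in seq_len(iters)) {
    ts <- seq(tr[1], tr[2], length.out = n)
    ss <- seq(sr[1], sr[2], length.out = n)
    p <- cbind(s1$a[1] + ts * d1[1], s1$a[2] + ts * d1[2], s1$a[3] + ts * d1[3])
    q <- cbind(s2$a[1] + ss * d2[1], s2$a[2] + ss * d2[2], s2$a[3] + ss * d2[3])
    d2m <- outer(rowSums(p^2), rowSums(q^2), `+`) - 2 * p %*% t(q)
    idx <- arrayInd(which.min(d2m), dim(d2m))
    step_t <- (tr[2] - tr[1]) / (n - 1)
    step_s <- (sr[2] - sr[1]) / (n - 1)
    t_best <- ts[idx[1]]; s_best <- ss[idx[2]]
    tr <- c(max(0, t_best - step_t), min(1, t_best + step_t))
    sr <- c(max(0, s_best - step_s), min(1, s_best + step_s))
  }
  p_best <- s1$a + t_best * d1
  q_best <- s2$a + s_best * d2
  list(point = (p_best + q_best) / 2,
       gap = sqrt(sum((p_best - q_best)^2)))
}

# two motion families for the clustering study: isotropic Gaussian random
# walks (step sigma 1) vs directed walks (unit drift + sigma 0.2 noise)
simulate_two_family_traces <- function(seed, n_per = 25, n_frames = 50) {
  set.seed(seed)
  mk <- function(id, p) {
    tibble::tibble(trace_id = id, t = 0:(nrow(p) - 1),
                   x = p[, 1], y = p[, 2], z = p[, 3])
  }
  rows <- vector("list", 2 * n_per)
  for (i in seq_len(n_per)) {
    steps <- matrix(rnorm(3 * (n_frames - 1), sd = 1), ncol = 3)
    rows[[i]] <- mk(sprintf("diffusive_%02d", i), apply(rbind(0, steps), 2, cumsum))
  }
  for (i in seq_len(n_per)) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    steps <- matrix(rep(dir, each = n_frames - 1), ncol = 3) +
      matrix(rnorm(3 * (n_frames - 1), sd = 0.2), ncol = 3)
    rows[[n_per + i]] <- mk(sprintf("directed_%02d", i),
                            apply(rbind(0, steps), 2, cumsum))
  }
  as_traceset(dplyr::bind_rows(rows))
}

family_of <- function(trace_ids) ifelse(grepl("^diffusive", trace_ids), 1L, 2L)

label_agreement <- function(labels, truth) {
  max(mean(labels == truth), mean(labels == 3L - truth))
}

# random rigid rotation (det +1) for equivariance checks
random_rotation <- function(seed) {
  set.seed(seed)
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

jitter_traces <- function(ts, sigma, seed) {
  set.seed(seed)
  n <- nrow(ts)
  ts$x <- ts$x + rnorm(n, sd = sigma)
  ts$y <- ts$y + rnorm(n, sd = sigma)
  ts$z <- ts$z + rnorm(n, sd = sigma)
  ts$trace_id <- paste0("test_", ts$trace_id)
  as_traceset(ts)
}
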