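test_that("standardization gives zero-mean unit-sd columns and is idempotent", {
  X <- tibble::tibble(a = c(1, 3, 5, 7), b = c(2, 2, 4, 4), c = rep(1, 4))
  expect_warning(Z <- standardize_features(X), "constant")
  expect_equal(mean(Z$a), 0)
  expect_equal(sd(Z$a), 1)
  expect_equal(Z$a, (c(1, 3, 5, 7) - 4) / sd(c(1, 3, 5, 7)), tolerance = 1e-12)
  expect_true(all(Z$c == 0))

  # two-point column z-scores to +-0.707
  two <- standardize_features(tibble::tibble(v = c(1, 3)))
  expect_equal(two$v, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  # idempotence
  Z2 <- suppressWarnings(standardize_features(Z))
  expect_equal(as.matrix(Z2[, c("a", "b")]), as.matrix(Z[, c("a", "b")]),
               tolerance = 1e-12)

  # non-finite rows are dropped with a message
  Xna <- tibble::tibble(a = c(1, 2, NA, 4), b = c(1, 2, 3, 4))
  expect_message(Zna <- standardize_features(Xna), "dropping 1")
  expect_equal(nrow(Zna), 3)
})

test_that("EM recovers two well-separated clouds and is seed-deterministic", {
  set.seed(83)
  X <- rbind(matrix(rnorm(40, -10), 20, 2), matrix(rnorm(40, 10), 20, 2))
  truth <- rep(1:2, each = 20)
  hits <- 0
  for (s in 1:20) {
    fit <- fit_em_gmm(X, 2, seed = s)
    if (label_agreement(fit$labels, truth) == 1) hits <- hits + 1
  }
  expect_gte(hits, 20 * 0.99)

  f1 <- fit_em_gmm(X, 2, seed = 5)
  f2 <- fit_em_gmm(X, 2, seed = 5)
  expect_identical(f1$labels, f2$labels)
  expect_equal(f1$loglik, f2$loglik)

  # log-likelihood trace is non-decreasing
  expect_true(all(diff(f1$loglik_trace) >= -1e-8))

  # k = 1: single component centered at the column means
  f0 <- fit_em_gmm(X, 1, seed = 1)
  expect_equal(as.numeric(f0$means), colMeans(X), tolerance = 1e-9)
  expect_true(all(f0$labels == 1))

  # duplicating every row preserves the partition structure
  fit_dup <- fit_em_gmm(rbind(X, X), 2, seed = 5)
  expect_equal(fit_dup$labels[1:40], fit_dup$labels[41:80])

  expect_error(fit_em_gmm(X[1:3, ], 5, seed = 1), "exceeds")
})

test_that("EM agrees with an independent mixture fit on separated data", {
  set.seed(89)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 6), 30, 2))
  fit <- fit_em_gmm(X, 2, seed = 2)
  withr::local_package("mclust")
  mfit <- mclust::Mclust(X, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(label_agreement(fit$labels, mfit$classification), 1)
})

test_that("validity indices match definition-level oracles", {
  # tight 1D pairs {0, 0.1} vs {10, 10.1}: enumerating the four points
  # gives per-point widths 1 - 0.1/10.05 (outer points) and 1 - 0.1/9.95
  # (inner points), mean 0.99
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c(1, 1, 2, 2)
  vi <- validity_indices(X, lab)
  expect_equal(vi$silhouette,
               mean(c(1 - 0.1 / 10.05, 1 - 0.1 / 9.95,
                      1 - 0.1 / 9.95, 1 - 0.1 / 10.05)),
               tolerance = 1e-9)

  # two clusters drawn from the same cloud: a ~ b, silhouette ~ 0
  set.seed(95)
  cloud <- rnorm(60)
  vs <- validity_indices(matrix(cloud, ncol = 1),
                         rep(1:2, each = 30))
  expect_lt(abs(vs$silhouette), 0.1)

  # random 12-point labeling against naive loop oracles
  set.seed(97)
  Xr <- matrix(rnorm(36), 12, 3)
  labr <- sample(1:2, 12, replace = TRUE)
  labr[1:2] <- 1:2  # both clusters non-empty
  vr <- validity_indices(Xr, labr)

  D <- as.matrix(dist(Xr))
  sil <- sapply(1:12, function(i) {
    own <- which(labr == labr[i] & seq_len(12) != i)
    oth <- which(labr != labr[i])
    if (length(own) == 0) return(0)
    a <- mean(D[i, own]); b <- mean(D[i, oth])
    (b - a) / max(a, b)
  })
  expect_equal(vr$silhouette, mean(sil), tolerance = 1e-9)

  cen <- rbind(colMeans(Xr[labr == 1, , drop = FALSE]),
               colMeans(Xr[labr == 2, , drop = FALSE]))
  S <- sapply(1:2, function(c_) {
    mean(sqrt(rowSums(sweep(Xr[labr == c_, , drop = FALSE], 2, cen[c_, ])^2)))
  })
  M <- sqrt(sum((cen[1, ] - cen[2, ])^2))
  expect_equal(vr$davies_bouldin, mean(c((S[1] + S[2]) / M, (S[1] + S[2]) / M)),
               tolerance = 1e-9)
  g <- colMeans(Xr)
  B <- sum(labr == 1) * sum((cen[1, ] - g)^2) + sum(labr == 2) * sum((cen[2, ] - g)^2)
  W <- sum(sapply(1:12, function(i) sum((Xr[i, ] - cen[labr[i], ])^2)))
  expect_equal(vr$calinski_harabasz, (B / 1) / (W / 10), tolerance = 1e-9)
  expect_equal(vr$sym_between_within, M / max(S), tolerance = 1e-9)

  # silhouette cross-checked against the reference implementation
  ref <- mean(cluster::silhouette(labr, dist(Xr))[, "sil_width"])
  expect_equal(vr$silhouette, ref, tolerance = 1e-9)

  expect_error(validity_indices(Xr, rep(1, 12)), "2 non-empty")
})

test_that("subset search enumerates 2^N - 1 subsets and is reproducible", {
  set.seed(101)
  X <- tibble::tibble(
    f1 = c(rnorm(12, 0), rnorm(12, 8)),
    f2 = rnorm(24),
    f3 = rnorm(24)
  )
  res <- subset_search(X, k_values = c(2, 3), seed = 11, n_init = 3)
  expect_equal(nrow(res$records), (2^3 - 1) * 2)
  expect_equal(length(unique(res$records$subset_mask)), 7)

  res2 <- subset_search(X, k_values = c(2, 3), seed = 11, n_init = 3)
  expect_identical(res$records$subset, res2$records$subset)
  expect_equal(res$records$silhouette, res2$records$silhouette)
  expect_identical(res$best_fit$labels, res2$best_fit$labels)

  # the separated feature wins, at k = 2
  expect_equal(res$best$k, 2)
  expect_match(res$best$subset, "f1")

  expect_error(subset_search(X, k_values = 2, max_features = 2), "subsets")
  expect_error(subset_search(X, k_values = 30), "k_values")
})

test_that("broom-style accessors expose fits and searches as tibbles", {
  set.seed(103)
  X <- rbind(matrix(rnorm(15, -4), 15, 1), matrix(rnorm(15, 4), 15, 1))
  fit <- fit_em_gmm(X, 2, seed = 3)
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 2)
  expect_true(all(c("component", "weight", "size") %in% names(td)))
  expect_equal(sum(td$size), 30)
  gl <- generics::glance(fit)
  expect_equal(gl$k, 2)
  aug <- generics::augment(fit)
  expect_equal(nrow(aug), 30)
  expect_s3_class(aug$.cluster, "factor")

  Xs <- tibble::tibble(a = c(rnorm(10), rnorm(10, 6)), b = rnorm(20))
  res <- subset_search(Xs, k_values = 2, seed = 5, n_init = 2)
  expect_s3_class(generics::tidy(res), "tbl_df")
  expect_equal(nrow(generics::glance(res)), 1)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
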