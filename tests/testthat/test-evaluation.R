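frame0 <- function(m) tibble::tibble(t = 0L, x = m[, 1], y = m[, 2], z = m[, 3])

test_that("the 3x3 instance of the matching contract scores as enumerated", {
  C <- frame0(rbind(c(0, 0, 0), c(1, 0, 0), c(9, 9, 9)))
  G <- frame0(rbind(c(0.2, 0, 0), c(1.1, 0, 0), c(5, 5, 5)))
  mr <- match_markers(C, G, d = 2)
  dist_mat <- as.matrix(stats::dist(rbind(as.matrix(C[, 2:4]),
                                          as.matrix(G[, 2:4]))))[1:3, 4:6]
  oracle <- oracle_matching_weight(dist_mat, dist_mat < 2, 1e-9)
  expect_equal(mr$total_weight, oracle, tolerance = 1e-9)
  expect_equal(mr$tp, 2L)  # both near pairs are < d/2; the far pair has no edge
  expect_equal(mr$fp, 1L)
  expect_equal(mr$fn, 1L)
})

test_that("matching equals exhaustive enumeration on random small instances", {
  set.seed(41)
  for (rep in 1:100) {
    nc <- sample(0:6, 1)
    ng <- sample(0:6, 1)
    d <- runif(1, 0.5, 3)
    C <- frame0(matrix(runif(3 * nc, 0, 4), ncol = 3))
    G <- frame0(matrix(runif(3 * ng, 0, 4), ncol = 3))
    mr <- match_markers(C, G, d = d)
    expect_identical(mr$tp + mr$fp, nc)
    expect_identical(mr$tp + mr$fn, ng)
    if (nc > 0 && ng > 0) {
      dist_mat <- sqrt(outer(rowSums(as.matrix(C[, 2:4])^2),
                             rowSums(as.matrix(G[, 2:4])^2), `+`) -
                         2 * as.matrix(C[, 2:4]) %*% t(as.matrix(G[, 2:4])))
      oracle <- oracle_matching_weight(dist_mat, dist_mat < d, 1e-9)
      expect_equal(mr$total_weight, oracle, tolerance = 1e-6)
    }
  }
})

test_that("enlarging d never loses true positives", {
  set.seed(43)
  C <- frame0(matrix(runif(30, 0, 6), ncol = 3))
  G <- frame0(matrix(runif(30, 0, 6), ncol = 3))
  tps <- sapply(c(0.5, 1, 2, 4, 8), function(d) match_markers(C, G, d = d)$tp)
  expect_true(all(diff(tps) >= 0))
})

test_that("swapping test and gold swaps precision and recall, keeps F1", {
  set.seed(47)
  C <- frame0(matrix(runif(18, 0, 4), ncol = 3))
  G <- frame0(matrix(runif(24, 0, 4), ncol = 3))
  a <- match_markers(C, G, d = 2)
  b <- match_markers(G, C, d = 2)
  sa <- precision_recall_f1(a$tp, a$fp, a$fn)
  sb <- precision_recall_f1(b$tp, b$fp, b$fn)
  expect_equal(sa$precision, sb$recall)
  expect_equal(sa$recall, sb$precision)
  expect_equal(sa$f1, sb$f1)
})

test_that("time-locked matching refuses cross-frame pairs", {
  C <- tibble::tibble(t = 0L, x = 0, y = 0, z = 0)
  G <- tibble::tibble(t = 1L, x = 0, y = 0, z = 0)
  expect_equal(match_markers(C, G, d = 5)$tp, 0L)
  expect_equal(match_markers(C, G, d = 5, time_locked = FALSE)$tp, 1L)
})

test_that("precision/recall/F1 follow the printed formulas with 0/0 -> 0", {
  expect_equal(unlist(precision_recall_f1(10, 0, 0)), c(precision = 1, recall = 1, f1 = 1))
  expect_equal(unlist(precision_recall_f1(0, 5, 5)), c(precision = 0, recall = 0, f1 = 0))
  s <- precision_recall_f1(3, 1, 2)
  expect_equal(s$precision, 0.75)
  expect_equal(s$recall, 0.6)
  expect_equal(s$f1, 2 / 3)
  expect_error(precision_recall_f1(-1, 0, 0), "non-negative")
})

test_that("duration strata reproduce the four-bin partition", {
  ts <- traceset_with_lengths(c(10, 30, 60, 90))
  q <- stratify_by_length(ts)
  expect_equal(attr(q, "mean_length"), 47.5)
  q <- q[order(q$length), ]
  expect_identical(as.character(q$bin), c("very_low", "average", "good", "good"))

  # equal lengths: L = Fbar > 0.75 Fbar, so everything is good
  same <- stratify_by_length(traceset_with_lengths(rep(20, 5)))
  expect_true(all(same$bin == "good"))

  # predicate-loop oracle on many random lengths
  set.seed(53)
  lens <- sample(4:120, 300, replace = TRUE)
  q2 <- stratify_by_length(traceset_with_lengths(lens))
  fbar <- mean(q2$length)
  oracle_bin <- function(L) {
    if (L <= 0.25 * fbar) "very_low"
    else if (L <= 0.5 * fbar) "low"
    else if (L <= 0.75 * fbar) "average"
    else "good"
  }
  expect_identical(as.character(q2$bin), vapply(q2$length, oracle_bin, ""))
})

test_that("trace-set evaluation: perfect, missing and shifted cases", {
  ts <- random_traceset(4, 20, seed = 59)
  rep_self <- evaluate_traceset(ts, ts, d = 6)
  expect_true(all(rep_self$pairs$f1 == 1))
  expect_equal(rep_self$macro_f1, 1)
  expect_equal(rep_self$micro$f1, 1)

  # one perfect and one fully missed trace in the same bin: macro F1 0.5
  gold <- traceset_with_lengths(c(20, 20))
  test <- gold[gold$trace_id == unique(gold$trace_id)[1], ]
  r <- evaluate_traceset(test, gold, d = 6)
  good_bin <- r$bins[r$bins$bin == "good", ]
  expect_equal(good_bin$macro_f1, 0.5)

  # shifting every test marker by exactly d kills every match (the
  # distance gate is strict); traces are kept > 2d apart so no marker can
  # fall near a neighbouring trace either
  lanes <- as_traceset(purrr::map_dfr(1:3, function(i) {
    tibble::tibble(trace_id = sprintf("lane_%d", i), t = 0:9,
                   x = 20 * i, y = as.numeric(0:9), z = 0)
  }))
  shifted <- lanes
  shifted$x <- shifted$x + 6
  r0 <- evaluate_traceset(shifted, lanes, d = 6)
  expect_true(all(r0$pairs$f1 == 0))
})

test_that("an explicit pairing overrides the optimal assignment", {
  gold <- random_traceset(2, 10, seed = 61)
  test <- gold
  test$trace_id <- paste0("pred_", test$trace_id)
  # deliberately cross the pairing: each test trace against the wrong gold
  ids <- unique(gold$trace_id)
  wrong <- stats::setNames(rev(ids), paste0("pred_", ids))
  r <- evaluate_traceset(test, gold, d = 6, pairing = wrong)
  expect_true(all(r$pairs$f1 < 1))
  right <- stats::setNames(ids, paste0("pred_", ids))
  r2 <- evaluate_traceset(test, gold, d = 6, pairing = right)
  expect_true(all(r2$pairs$f1 == 1))
})

test_that("tidiers expose the report as tibbles", {
  ts <- random_traceset(3, 12, seed = 67)
  r <- evaluate_traceset(ts, ts, d = 4)
  td <- generics::tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("gold_id", "tp", "f1", "bin") %in% names(td)))
  gl <- generics::glance(r)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$macro_f1, 1)
  p <- ggplot2::autoplot(r)
  expect_s3_class(p, "ggplot")
})
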