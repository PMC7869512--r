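#' Match predicted markers against gold-standard markers
#'
#' Builds an undirected bipartite graph between the test markers `C` and
#' gold markers `G`, with an edge for every pair closer than `d` (and, when
#' `time_locked`, sharing the same frame), weighted
#' `w = 1 / (epsilon + ||c - g||)`, and computes the maximum-weight
#' bipartite matching. A matched test marker is a true positive when its
#' pair distance is below `d/2`; unmatched test markers count as false
#' positives and unmatched gold markers as false negatives. A matched pair
#' at distance in `[d/2, d)` contributes one FP and one FN, which keeps the
#' identities `TP + FP = |C|` and `TP + FN = |G|`.
#'
#' @param test,gold data frames of markers with columns `x`, `y`, `z` and,
#'   when `time_locked`, `t`.
#' @param d distance gate in voxels; roughly the expected object diameter.
#' @param epsilon small positive constant guarding the weight against
#'   division by zero for coincident markers.
#' @param time_locked only allow matches between markers of the same frame.
#' @return A `match_result`: list with `pairs` (tibble of matched index
#'   pairs and distances), `tp`, `fp`, `fn` and `total_weight`.
#' @export
match_markers <- function(test, gold, d = 6, epsilon = 1e-9,
                          time_locked = TRUE) {
  if (d <= 0) stop("`d` must be > 0", call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  test <- tibble::as_tibble(test)
  gold <- tibble::as_tibble(gold)
  nc <- nrow(test); ng <- nrow(gold)

  empty <- tibble::tibble(test_idx = integer(), gold_idx = integer(),
                          distance = double())
  if (nc == 0 || ng == 0) {
    return(structure(list(pairs = empty, tp = 0L, fp = nc, fn = ng,
                          total_weight = 0),
                     class = "match_result"))
  }

  cm <- as.matrix(test[, c("x", "y", "z")])
  gm <- as.matrix(gold[, c("x", "y", "z")])
  # pairwise distances, gated by frame equality when time-locked
  d2 <- outer(rowSums(cm^2), rowSums(gm^2), `+`) - 2 * cm %*% t(gm)
  dist_mat <- sqrt(pmax(d2, 0))
  ok <- dist_mat < d
  if (time_locked) {
    ok <- ok & outer(test$t, gold$t, `==`)
  }
  edges <- which(ok, arr.ind = TRUE)
  if (nrow(edges) == 0) {
    return(structure(list(pairs = empty, tp = 0L, fp = nc, fn = ng,
                          total_weight = 0),
                     class = "match_result"))
  }
  w <- 1 / (epsilon + dist_mat[edges])
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nc), rep(TRUE, ng)),
    edges = as.vector(t(cbind(edges[, 1], nc + edges[, 2])))
  )
  m <- igraph::max_bipartite_match(g, weights = w)
  matched_c <- which(!is.na(m$matching[seq_len(nc)]))
  pairs <- tibble::tibble(
    test_idx = matched_c,
    gold_idx = as.integer(m$matching[matched_c]) - nc
  )
  pairs$distance <- dist_mat[cbind(pairs$test_idx, pairs$gold_idx)]
  tp <- sum(pairs$distance < d / 2)
  structure(
    list(pairs = pairs, tp = as.integer(tp), fp = nc - as.integer(tp),
         fn = ng - as.integer(tp),
         total_weight = sum(1 / (epsilon + pairs$distance))),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs | TP %d  FP %d  FN %d\n",
              nrow(x$pairs), x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; any score whose
#' denominator is zero is defined as 0 (a fully missed trace scores 0, not
#' NaN).
#'
#' @param tp,fp,fn non-negative counts (vectorized).
#' @return A tibble with columns `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  tibble::tibble(precision = p, recall = r, f1 = f1)
}

quality_bin_levels <- c("very_low", "low", "average", "good")

#' Stratify traces into duration-based quality bins
#'
#' With `L` the length of a trace in frames and `Fbar` the mean length over
#' the set, traces fall into four bins: very_low (`L <= 0.25 Fbar`), low
#' (`0.25 Fbar < L <= 0.5 Fbar`), average (`0.5 Fbar < L <= 0.75 Fbar`) and
#' good (`L > 0.75 Fbar`). Short traces are a raw proxy for unreliable
#' automatic tracking.
#'
#' @param ts a trace set.
#' @return A tibble with `trace_id`, `length` and `bin` (ordered factor);
#'   the mean length is attached as attribute `mean_length`.
#' @export
stratify_by_length <- function(ts) {
  ts <- as_traceset(ts, provenance = attr(ts, "provenance"))
  if (nrow(ts) == 0) stop("cannot stratify an empty trace set", call. = FALSE)
  lens <- dplyr::summarise(dplyr::group_by(ts, .data$trace_id),
                           length = dplyr::n(), .groups = "drop")
  fbar <- mean(lens$length)
  lens$bin <- cut(
    lens$length,
    breaks = c(-Inf, 0.25 * fbar, 0.5 * fbar, 0.75 * fbar, Inf),
    labels = quality_bin_levels, right = TRUE, ordered_result = TRUE
  )
  attr(lens, "mean_length") <- fbar
  lens
}

# Optimal one-to-one correspondence between test and gold traces:
# maximize summed per-pair TP, smaller summed matched distance as
# tie-break (via composite matching weights).
pair_traces <- function(test, gold, d, epsilon) {
  tids <- unique(test$trace_id)
  gids <- unique(gold$trace_id)
  nt <- length(tids); ng <- length(gids)
  tp_mat <- matrix(0L, nt, ng)
  dist_mat <- matrix(0, nt, ng)
  res_list <- vector("list", nt * ng)
  for (i in seq_len(nt)) {
    for (j in seq_len(ng)) {
      mr <- match_markers(test[test$trace_id == tids[i], ],
                          gold[gold$trace_id == gids[j], ],
                          d = d, epsilon = epsilon, time_locked = TRUE)
      tp_mat[i, j] <- mr$tp
      dist_mat[i, j] <- sum(mr$pairs$distance)
      res_list[[(i - 1L) * ng + j]] <- mr
    }
  }
  # composite weight: TP dominates, then smaller summed distance
  w_mat <- tp_mat + 1 / (2 + dist_mat)
  edges <- as.matrix(expand.grid(i = seq_len(nt), j = seq_len(ng)))
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nt), rep(TRUE, ng)),
    edges = as.vector(t(cbind(edges[, 1], nt + edges[, 2])))
  )
  m <- igraph::max_bipartite_match(g, weights = w_mat[edges])
  matched <- which(!is.na(m$matching[seq_len(nt)]))
  tibble::tibble(
    test_id = tids[matched],
    gold_id = gids[as.integer(m$matching[matched]) - nt],
    result = res_list[(matched - 1L) * ng +
                        (as.integer(m$matching[matched]) - nt)]
  )
}

#' Evaluate a trace set against a gold standard
#'
#' Establishes a one-to-one correspondence between test and gold traces
#' (optimal assignment maximizing the summed per-pair true positives, or an
#' explicit id mapping via `pairing`), scores each trace pair with
#' [match_markers()] (time-locked), derives per-pair precision/recall/F1,
#' and aggregates: macro-averaged F1 per duration-quality bin of the gold
#' traces, plus pooled micro scores. Gold traces left without a partner
#' count all their markers as false negatives (F1 = 0); test traces without
#' a partner contribute all their markers as false positives to the micro
#' pool.
#'
#' @param test,gold trace sets (see [as_traceset()]).
#' @param d,epsilon matching parameters, see [match_markers()].
#' @param pairing optional named character vector mapping test trace ids to
#'   gold trace ids, overriding the optimal assignment.
#' @return An `eval_report`: list with `pairs` (per-gold-trace tibble of
#'   counts, scores and quality bin), `bins` (per-bin macro/micro summary),
#'   `micro` (pooled scores) and `config`.
#' @export
evaluate_traceset <- function(test, gold, d = 6, epsilon = 1e-9,
                              pairing = NULL) {
  test <- as_traceset(test, provenance = attr(test, "provenance"))
  gold <- as_traceset(gold, provenance = attr(gold, "provenance"))
  strata <- stratify_by_length(gold)

  if (is.null(pairing)) {
    assigned <- pair_traces(test, gold, d, epsilon)
  } else {
    keep <- names(pairing) %in% test$trace_id & pairing %in% gold$trace_id
    pairing <- pairing[keep]
    assigned <- tibble::tibble(
      test_id = names(pairing), gold_id = unname(pairing),
      result = purrr::map2(names(pairing), unname(pairing), function(ti, gi) {
        match_markers(test[test$trace_id == ti, ], gold[gold$trace_id == gi, ],
                      d = d, epsilon = epsilon, time_locked = TRUE)
      })
    )
  }

  gold_lens <- stats::setNames(strata$length, strata$trace_id)
  pairs <- tibble::tibble(
    gold_id = strata$trace_id,
    test_id = NA_character_,
    tp = 0L, fp = 0L,
    fn = as.integer(gold_lens[strata$trace_id]),
    bin = strata$bin
  )
  for (r in seq_len(nrow(assigned))) {
    i <- match(assigned$gold_id[r], pairs$gold_id)
    mr <- assigned$result[[r]]
    pairs$test_id[i] <- assigned$test_id[r]
    pairs$tp[i] <- mr$tp
    pairs$fp[i] <- mr$fp
    pairs$fn[i] <- mr$fn
  }
  pairs <- dplyr::bind_cols(pairs,
                            precision_recall_f1(pairs$tp, pairs$fp, pairs$fn))

  bins <- dplyr::summarise(
    dplyr::group_by(pairs, .data$bin, .drop = FALSE),
    n_traces = dplyr::n(),
    macro_f1 = ifelse(dplyr::n() > 0, mean(.data$f1), NA_real_),
    tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
    .groups = "drop"
  )
  bins <- dplyr::bind_cols(bins, precision_recall_f1(bins$tp, bins$fp, bins$fn))

  # micro pool: paired counts plus markers of test traces left unpaired
  stray_fp <- sum(!(test$trace_id %in% assigned$test_id))
  micro_tp <- sum(pairs$tp)
  micro_fp <- sum(pairs$fp) + stray_fp
  micro_fn <- sum(pairs$fn)
  micro <- dplyr::bind_cols(
    tibble::tibble(tp = micro_tp, fp = micro_fp, fn = micro_fn),
    precision_recall_f1(micro_tp, micro_fp, micro_fn)
  )

  structure(
    list(pairs = pairs, bins = bins, micro = micro,
         macro_f1 = mean(pairs$f1),
         config = list(d = d, epsilon = epsilon,
                       mean_length = attr(strata, "mean_length"))),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d gold traces | macro F1 %.3f | micro F1 %.3f (d = %g)\n",
              nrow(x$pairs), x$macro_f1, x$micro$f1, x$config$d))
  print(x$bins[, c("bin", "n_traces", "macro_f1", "f1")])
  invisible(x)
}
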