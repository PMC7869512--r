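#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation report
#'
#' @param x an `eval_report` from [evaluate_traceset()].
#' @param ... unused.
#' @return Per-gold-trace tibble of counts, scores and quality bin.
#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) x$pairs

#' One-row summary of an evaluation report
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @return Tibble with macro F1, micro precision/recall/F1 and `d`.
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    n_gold_traces = nrow(x$pairs),
    macro_f1 = x$macro_f1,
    micro_precision = x$micro$precision,
    micro_recall = x$micro$recall,
    micro_f1 = x$micro$f1,
    d = x$config$d
  )
}

#' Plot per-quality-bin tracking performance
#'
#' Bar chart of the macro-averaged F1 score in each duration-quality bin,
#' the usual way to judge which quality strata of an automatic tracker are
#' reliable enough to analyse.
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$bin, y = .data$macro_f1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "trace quality (duration bin)", y = "macro F1",
                  title = sprintf("Tracking quality by duration bin (d = %g)",
                                  object$config$d)) +
    ggplot2::theme_minimal()
}

#' Tidy an EM Gaussian mixture fit
#'
#' @param x an `em_gmm` from [fit_em_gmm()].
#' @param ... unused.
#' @return Per-component tibble: weight, size and mean vector columns.
#' @exportS3Method generics::tidy
tidy.em_gmm <- function(x, ...) {
  means <- tibble::as_tibble(x$means, .name_repair = ~ paste0("mean_", seq_along(.x)))
  dplyr::bind_cols(
    tibble::tibble(component = seq_len(x$k), weight = x$weights,
                   size = tabulate(x$labels, x$k)),
    means
  )
}

#' One-row summary of an EM fit
#'
#' @param x an `em_gmm`.
#' @param ... unused.
#' @return Tibble with k, log-likelihood and iteration count.
#' @exportS3Method generics::glance
glance.em_gmm <- function(x, ...) {
  tibble::tibble(k = x$k, loglik = x$loglik, n_iter = x$n_iter,
                 n_obs = nrow(x$data))
}

#' Attach cluster labels to the observations
#'
#' @param x an `em_gmm`.
#' @param data optional tibble the model was fitted on (defaults to the
#'   stored feature matrix).
#' @param ... unused.
#' @return `data` with a `.cluster` factor column appended.
#' @exportS3Method generics::augment
augment.em_gmm <- function(x, data = NULL, ...) {
  if (is.null(data)) {
    m <- x$data
    if (is.null(colnames(m))) colnames(m) <- paste0("x", seq_len(ncol(m)))
    data <- tibble::as_tibble(m)
  }
  data <- tibble::as_tibble(data)
  data$.cluster <- factor(x$labels)
  data
}

#' Tidy a subset search
#'
#' @param x a `subset_search` from [subset_search()].
#' @param ... unused.
#' @return One row per (feature subset, k) with all index scores and the
#'   consensus average rank.
#' @exportS3Method generics::tidy
tidy.subset_search <- function(x, ...) x$records

#' One-row summary of a subset search
#'
#' @param x a `subset_search`.
#' @param ... unused.
#' @return The consensus-best record (subset, k, index scores).
#' @exportS3Method generics::glance
glance.subset_search <- function(x, ...) x$best

#' Plot sorted silhouette profiles per cluster count
#'
#' Overlays, for each candidate `k`, the silhouette scores of all feature
#' subsets sorted from best to worst. The `k` whose profile dominates is
#' the one the data supports.
#'
#' @param object a `subset_search`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.subset_search <- function(object, ...) {
  ggplot2::ggplot(object$profiles,
                  ggplot2::aes(x = .data$rank, y = .data$silhouette,
                               colour = factor(.data$k))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "feature subset (sorted by score)",
                  y = "mean silhouette", colour = "k",
                  title = "Sorted silhouette profiles across feature subsets") +
    ggplot2::theme_minimal()
}

#' Plot trace trajectories as orthogonal projections
#'
#' Draws each trace's path in the x-y, x-z and y-z planes, colored by
#' trace. A quick 2D stand-in for the interactive 3D view.
#'
#' @param ts a trace set.
#' @return A ggplot object faceted by projection plane.
#' @export
plot_traces <- function(ts) {
  ts <- as_traceset(ts, provenance = attr(ts, "provenance"))
  long <- dplyr::bind_rows(
    tibble::tibble(trace_id = ts$trace_id, h = ts$x, v = ts$y, plane = "x-y"),
    tibble::tibble(trace_id = ts$trace_id, h = ts$x, v = ts$z, plane = "x-z"),
    tibble::tibble(trace_id = ts$trace_id, h = ts$y, v = ts$z, plane = "y-z")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$h, y = .data$v,
                                     colour = .data$trace_id)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~plane) +
    ggplot2::labs(x = NULL, y = NULL, colour = "trace") +
    ggplot2::theme_minimal()
}
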