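#' Trace sets
#'
#' A trace set is a tibble with one row per marker and columns `trace_id`
#' (character), `label` (character), `t` (0-based integer frame), and the
#' real-valued voxel coordinates `x`, `y`, `z`. Within a trace there is at
#' most one marker per frame and rows are ordered by increasing `t`. A
#' `provenance` attribute records where the set came from.
#'
#' @param x a data frame with at least `trace_id`, `t`, `x`, `y`, `z`
#'   (`label` is filled with `""` when absent).
#' @param provenance list describing the source (e.g. `list(format = "xml")`).
#' @return A validated `traceset` tibble sorted by `trace_id`, `t`.
#' @export
#' @examples
#' ts <- as_traceset(tibble::tibble(
#'   trace_id = "a", t = 0:2, x = c(1, 2, 3), y = 0, z = 0
#' ))
as_traceset <- function(x, provenance = list(format = "memory")) {
  x <- tibble::as_tibble(x)
  if (!"label" %in% names(x)) x$label <- ""
  need <- c("trace_id", "label", "t", "x", "y", "z")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop(sprintf("trace set is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x <- x[, need]
  x$trace_id <- as.character(x$trace_id)
  x$label <- as.character(x$label)
  if (any(x$t != floor(x$t)) || any(x$t < 0)) {
    stop("frame indices `t` must be non-negative integers", call. = FALSE)
  }
  x$t <- as.integer(x$t)
  if (!all(is.finite(x$x) & is.finite(x$y) & is.finite(x$z))) {
    stop("marker coordinates must be finite", call. = FALSE)
  }
  dup <- duplicated(x[, c("trace_id", "t")])
  if (any(dup)) {
    d <- x[dup, ][1, ]
    stop(sprintf("trace '%s' has more than one marker at frame t = %d",
                 d$trace_id, d$t), call. = FALSE)
  }
  # one label per trace
  lbl <- unique(x[, c("trace_id", "label")])
  if (anyDuplicated(lbl$trace_id)) {
    stop("a trace must carry a single label", call. = FALSE)
  }
  x <- dplyr::arrange(x, .data$trace_id, .data$t)
  attr(x, "provenance") <- provenance
  class(x) <- c("traceset", class(x))
  x
}

#' @export
print.traceset <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<traceset> %d traces, %d markers (source: %s)\n",
              dplyr::n_distinct(x$trace_id), nrow(x),
              if (is.null(prov$format)) "?" else prov$format))
  NextMethod()
}

#' Edit one marker of a trace
#'
#' Mirrors interactive proofreading: `"add"` inserts a marker at a frame
#' that has none, `"move"` replaces the coordinates of an existing marker,
#' `"delete"` removes a frame's marker. Markers at other frames are never
#' touched.
#'
#' @param ts a trace set (see [as_traceset()]).
#' @param trace_id which trace to edit.
#' @param action one of `"add"`, `"move"`, `"delete"`.
#' @param t 0-based frame index of the marker.
#' @param x,y,z coordinates (required for add/move).
#' @return The edited trace set.
#' @export
edit_trace <- function(ts, trace_id, action = c("add", "move", "delete"),
                       t, x = NULL, y = NULL, z = NULL) {
  action <- match.arg(action)
  ts <- as_traceset(ts, provenance = attr(ts, "provenance"))
  sel <- ts$trace_id == trace_id & ts$t == t
  occupied <- any(sel)
  if (action == "add") {
    if (occupied) {
      stop(sprintf("trace '%s' already has a marker at t = %d", trace_id, t),
           call. = FALSE)
    }
    lbl <- ts$label[ts$trace_id == trace_id][1]
    if (is.na(lbl)) lbl <- ""
    new_row <- tibble::tibble(trace_id = trace_id, label = lbl,
                              t = as.integer(t), x = x, y = y, z = z)
    out <- dplyr::bind_rows(ts, new_row)
  } else {
    if (!occupied) {
      stop(sprintf("trace '%s' has no marker at t = %d", trace_id, t),
           call. = FALSE)
    }
    if (action == "move") {
      out <- ts
      out$x[sel] <- x; out$y[sel] <- y; out$z[sel] <- z
    } else {
      out <- ts[!sel, ]
    }
  }
  as_traceset(out, provenance = attr(ts, "provenance"))
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub("\"", "&quot;", s, fixed = TRUE)
}

#' Write a trace set to the XML interchange format
#'
#' Schema:
#' `<traces version="1.0"><trace id=".." label=".."><marker t="0"
#' x="12.500000" y="3.000000" z="7.250000"/>...</trace>...</traces>`.
#' Coordinates are serialized with 6 decimal places; the serialization is
#' deterministic, so write-read-write produces byte-identical files.
#'
#' @param ts a trace set.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_traces_xml <- function(ts, path) {
  ts <- as_traceset(ts, provenance = attr(ts, "provenance"))
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             "<traces version=\"1.0\">")
  for (id in unique(ts$trace_id)) {
    tr <- ts[ts$trace_id == id, ]
    lines <- c(lines, sprintf("  <trace id=\"%s\" label=\"%s\">",
                              xml_escape(id), xml_escape(tr$label[1])))
    lines <- c(lines, sprintf(
      "    <marker t=\"%d\" x=\"%.6f\" y=\"%.6f\" z=\"%.6f\"/>",
      tr$t, tr$x, tr$y, tr$z
    ))
    lines <- c(lines, "  </trace>")
  }
  lines <- c(lines, "</traces>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a trace set from the XML interchange format
#'
#' Validates the trace-set invariants (unique trace ids, at most one
#' marker per frame, all coordinate attributes present) and reports the
#' offending trace id on violation.
#'
#' @param path XML file written by [write_traces_xml()] (or compatible).
#' @return A `traceset` tibble.
#' @export
read_traces_xml <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "traces") {
    stop("root element must be <traces>", call. = FALSE)
  }
  trace_nodes <- xml2::xml_find_all(doc, "./trace")
  ids <- xml2::xml_attr(trace_nodes, "id")
  if (any(is.na(ids))) stop("<trace> element without id attribute", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate trace id '%s'", ids[duplicated(ids)][1]), call. = FALSE)
  }
  empty_rows <- tibble::tibble(trace_id = character(), label = character(),
                               t = integer(), x = double(), y = double(),
                               z = double())
  rows <- purrr::map2_dfr(trace_nodes, ids, function(node, id) {
    mk <- xml2::xml_find_all(node, "./marker")
    if (length(mk) == 0) {
      return(tibble::tibble(trace_id = character(), label = character(),
                            t = integer(), x = double(), y = double(),
                            z = double()))
    }
    vals <- lapply(c("t", "x", "y", "z"), function(at) {
      v <- xml2::xml_attr(mk, at)
      if (any(is.na(v))) {
        stop(sprintf("trace '%s': marker %d is missing attribute '%s'",
                     id, which(is.na(v))[1], at), call. = FALSE)
      }
      as.numeric(v)
    })
    lab <- xml2::xml_attr(node, "label")
    tibble::tibble(trace_id = id, label = ifelse(is.na(lab), "", lab),
                   t = vals[[1]], x = vals[[2]], y = vals[[3]], z = vals[[4]])
  })
  if (nrow(rows) == 0) rows <- empty_rows
  as_traceset(rows, provenance = list(format = "xml", path = path))
}

#' Import traces from external tracking tools
#'
#' Two read-only dialects are supported, converted to this package's
#' 0-based voxel convention:
#' \describe{
#'   \item{`ilastik_csv`}{CSV with header columns `trackId`, `frame`,
#'     `x`, `y`, `z`; frames and coordinates assumed 0-based.}
#'   \item{`diatrack_mat`}{MAT v5 container holding one `n x 4` double
#'     matrix per trace, columns `(t, x, y, z)`; frames and coordinates
#'     assumed 1-based (MATLAB convention) and shifted down by one.}
#' }
#'
#' @param path input file.
#' @param dialect `"ilastik_csv"` or `"diatrack_mat"`.
#' @return A `traceset` tibble with provenance recording the dialect.
#' @export
import_external <- function(path, dialect = c("ilastik_csv", "diatrack_mat")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (dialect == "ilastik_csv") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    need <- c("trackId", "frame", "x", "y", "z")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols) > 0) {
      stop(sprintf("ilastik CSV is missing columns: %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    out <- tibble::tibble(
      trace_id = as.character(df$trackId), label = "",
      t = df$frame, x = df$x, y = df$y, z = df$z
    )
  } else {
    vars <- read_mat5(path)
    if (length(vars) == 0) stop("MAT file holds no trace variables", call. = FALSE)
    out <- purrr::imap_dfr(vars, function(m, nm) {
      if (!is.matrix(m) || ncol(m) != 4L) {
        stop(sprintf("MAT variable '%s' is not an n x 4 trace matrix", nm),
             call. = FALSE)
      }
      tibble::tibble(trace_id = nm, label = "",
                     t = m[, 1] - 1, x = m[, 2] - 1, y = m[, 3] - 1,
                     z = m[, 4] - 1)
    })
  }
  as_traceset(out, provenance = list(format = dialect, path = path))
}
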