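# Chart specifications and rendering.
#
# Charts are built as serialisable specification objects first, so layout is
# deterministic and testable, then rendered to SVG (with hover titles for
# interactivity) or wrapped into a standalone HTML page. In propagation
# charts each X category is a lineage labelled with all of its accessions —
# labelling with one accession would make a merge look like a removal — and
# the release tick marks of the two databases are drawn on opposite margins
# so that a missing point under an unsynchronised calendar reads as "no
# release", not as an absence (the striping artefact).

.db_colour <- c(SWISSPROT = "#2166ac", TREMBL = "#b2182b")

.new_chart <- function(kind, title, x_axis, y_axis, series,
                       annotations = NULL, extra = NULL) {
  structure(c(list(kind = kind, title = title, x_axis = x_axis,
                   y_axis = y_axis, series = series,
                   annotations = annotations), extra),
            class = "chart_spec")
}

#' @export
print.chart_spec <- function(x, ...) {
  npts <- sum(vapply(x$series, function(s) nrow(s$points), integer(1)))
  cat("chart_spec [", x$kind, "]: ", x$title, " (", npts, " points, ",
      length(x$series), " series)\n", sep = "")
  invisible(x)
}

#' Propagation scatter chart for one sentence
#'
#' X axis: one category per lineage (labelled with every accession the
#' lineage has carried), ordered by first appearance then accession string.
#' Y axis: release dates. One point per occurrence triple, coloured by
#' database (blue Swiss-Prot, red TrEMBL) and carrying the accession list
#' and release identifier as hover metadata. Swiss-Prot release marks are
#' annotated down the left margin, TrEMBL down the right.
#'
#' @param trace a [build_trace()] result.
#' @param index the index the trace was built from.
#' @param max_categories dense charts are capped at this many lineages; the
#'   overflow count is recorded in the spec's \code{overflow} field.
#' @return a \code{chart_spec}.
#' @export
propagation_chart <- function(trace, index, max_categories = 100L) {
  stopifnot(inherits(trace, "propagation_trace"))
  occ <- trace$occurrences
  if (nrow(occ) == 0L) stop("empty trace")
  first_seen <- vapply(split(occ$date, occ$lineage_id), min, numeric(1))
  lins <- names(sort(first_seen))
  ord2 <- order(first_seen[lins], lins)
  lins <- lins[ord2]
  overflow <- 0L
  if (length(lins) > max_categories) {
    overflow <- length(lins) - max_categories
    lins <- lins[seq_len(max_categories)]
    occ <- occ[occ$lineage_id %in% lins, , drop = FALSE]
  }
  labels <- vapply(lins, function(l) {
    accs <- index$lineages$accessions[[match(l, index$lineages$lineage_id)]]
    paste(accs, collapse = "; ")
  }, character(1))
  series <- lapply(c("SWISSPROT", "TREMBL"), function(db) {
    sub <- occ[occ$database == db, , drop = FALSE]
    pts <- data.frame(
      x = match(sub$lineage_id, lins),
      y = as.character(sub$date),
      hover = sprintf("%s @ %s", labels[match(sub$lineage_id, lins)],
                      sub$release_id),
      stringsAsFactors = FALSE)
    pts <- pts[order(pts$x, pts$y), , drop = FALSE]
    rownames(pts) <- NULL
    list(label = db, points = pts, style = list(colour = unname(.db_colour[db])))
  })
  cal <- index$calendar
  in_range <- cal$date >= min(trace$occurrences$date) &
              cal$date <= max(trace$occurrences$date)
  ann <- list(
    left = data.frame(release_id = cal$release_id[in_range & cal$database == "SWISSPROT"],
                      date = as.character(cal$date[in_range & cal$database == "SWISSPROT"]),
                      stringsAsFactors = FALSE),
    right = data.frame(release_id = cal$release_id[in_range & cal$database == "TREMBL"],
                       date = as.character(cal$date[in_range & cal$database == "TREMBL"]),
                       stringsAsFactors = FALSE))
  .new_chart("PROPAGATION",
             title = trace$sentence_text,
             x_axis = list(label = "entry (all accessions of the lineage)",
                           categories = unname(labels)),
             y_axis = list(label = "release date", type = "date"),
             series = series, annotations = ann,
             extra = list(overflow = overflow))
}

#' Entry-count timeline chart for one sentence
#'
#' @param series an [occurrence_timeline()] result.
#' @return a \code{chart_spec} whose single series carries the input values
#'   unchanged, with the maximum annotated as the peak.
#' @export
timeline_chart <- function(series) {
  if (is.null(series) || nrow(series) == 0L) stop("empty series")
  pts <- data.frame(x = as.character(series$date),
                    y = series$n_entries,
                    hover = sprintf("%s: %d entries", series$release_id,
                                    series$n_entries),
                    stringsAsFactors = FALSE)
  peak <- which.max(series$n_entries)
  .new_chart("TIMELINE",
             title = "entries containing the sentence over time",
             x_axis = list(label = "release date", type = "date"),
             y_axis = list(label = "number of entries"),
             series = list(list(label = "entries", points = pts,
                                style = list(colour = "#333333"))),
             annotations = list(peak = list(
               release_id = series$release_id[peak],
               n_entries = series$n_entries[peak])))
}

.stat_chart <- function(stats_tbl, column, title, ylab, log_y = FALSE) {
  series <- lapply(intersect(c("SWISSPROT", "TREMBL"), unique(stats_tbl$database)),
                   function(db) {
    sub <- stats_tbl[stats_tbl$database == db, , drop = FALSE]
    sub <- sub[!is.na(sub[[column]]), , drop = FALSE]
    pts <- data.frame(x = as.character(sub$date), y = sub[[column]],
                      hover = sprintf("%s: %g", sub$release_id, sub[[column]]),
                      stringsAsFactors = FALSE)
    list(label = db, points = pts, style = list(colour = unname(.db_colour[db])))
  })
  .new_chart("STATS", title = title,
             x_axis = list(label = "release date", type = "date"),
             y_axis = list(label = ylab, log = log_y),
             series = series)
}

#' Corpus-statistics charts
#'
#' Builds the standard reuse figures from a [release_stats()] table: totals,
#' averages per entry and per sentence, unique and singleton counts and
#' percentages, the percentage of unannotated entries and, when histograms
#' are supplied, log-log reuse-distribution charts.
#'
#' @param stats_tbl a [release_stats()] table.
#' @param histograms optional named list (release_id to
#'   [reuse_histogram()] output) for reuse-distribution charts.
#' @return named list of \code{chart_spec} objects.
#' @export
stats_charts <- function(stats_tbl, histograms = NULL) {
  out <- list(
    total = .stat_chart(stats_tbl, "total", "total sentences", "sentences"),
    unique = .stat_chart(stats_tbl, "unique", "unique sentences", "sentences"),
    singleton = .stat_chart(stats_tbl, "singleton", "singleton sentences",
                            "sentences"),
    pct_unique = .stat_chart(stats_tbl, "pct_unique",
                             "percentage of unique sentences", "%"),
    pct_singleton = .stat_chart(stats_tbl, "pct_singleton",
                                "percentage of singleton sentences", "%"),
    avg_sentences_per_entry = .stat_chart(stats_tbl, "avg_sentences_per_entry",
                                          "average sentences per annotated entry",
                                          "sentences / entry"),
    avg_entries_per_sentence = .stat_chart(stats_tbl, "avg_entries_per_sentence",
                                           "average entries per sentence",
                                           "entries / sentence"),
    pct_unannotated = .stat_chart(stats_tbl, "pct_unannotated",
                                  "entries without textual annotation", "%")
  )
  for (rid in names(histograms)) {
    h <- histograms[[rid]]
    pts <- data.frame(x = h$occurrence_count, y = h$n_sentences,
                      hover = sprintf("%d sentences occur %d time(s)",
                                      h$n_sentences, h$occurrence_count),
                      stringsAsFactors = FALSE)
    out[[paste0("reuse_", rid)]] <- .new_chart(
      "STATS", title = paste("sentence reuse distribution,", rid),
      x_axis = list(label = "occurrence count", log = TRUE),
      y_axis = list(label = "number of sentences", log = TRUE),
      series = list(list(label = rid, points = pts,
                         style = list(colour = "#333333"))))
  }
  out
}

#' Serialise a chart spec to JSON
#'
#' The serialisation is canonical: identical specs yield byte-identical
#' JSON, making chart output snapshot-testable.
#'
#' @param spec a \code{chart_spec}.
#' @return a JSON string.
#' @export
chart_json <- function(spec) {
  as.character(jsonlite::toJSON(unclass(spec), dataframe = "rows",
                                auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE))
}

.svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# minimal deterministic SVG rendering; every point carries a <title> so
# hovering reveals the accession/release metadata
chart_svg <- function(spec, width = 720, height = 480) {
  pad <- 60
  all_pts <- do.call(rbind, lapply(spec$series, `[[`, "points"))
  if (is.null(all_pts) || nrow(all_pts) == 0L)
    all_pts <- data.frame(x = 1, y = 1, hover = "")
  xs <- all_pts$x
  if (!is.null(spec$x_axis$categories)) {
    xr <- c(0.5, length(spec$x_axis$categories) + 0.5)
    xnum <- function(v) as.numeric(v)
  } else if (identical(spec$x_axis$type, "date")) {
    xnum <- function(v) as.numeric(as.Date(v))
    xr <- range(xnum(xs))
  } else {
    xnum <- function(v) as.numeric(v)
    xr <- range(xnum(xs))
  }
  ynum <- if (identical(spec$y_axis$type, "date"))
    function(v) as.numeric(as.Date(v)) else function(v) as.numeric(v)
  yr <- range(ynum(all_pts$y))
  if (diff(xr) == 0) xr <- xr + c(-1, 1)
  if (diff(yr) == 0) yr <- yr + c(-1, 1)
  sx <- function(v) pad + (xnum(v) - xr[1]) / diff(xr) * (width - 2 * pad)
  sy <- function(v) height - pad - (ynum(v) - yr[1]) / diff(yr) * (height - 2 * pad)
  el <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                  width, height),
          sprintf('<text x="%d" y="20" font-size="12">%s</text>', pad,
                  .svg_escape(substr(spec$title, 1, 90))))
  for (s in spec$series) {
    p <- s$points
    if (nrow(p) == 0L) next
    col <- s$style$colour
    if (spec$kind %in% c("TIMELINE", "STATS") && nrow(p) > 1L) {
      path <- paste(sprintf("%.1f,%.1f", sx(p$x), sy(p$y)), collapse = " ")
      el <- c(el, sprintf('<polyline fill="none" stroke="%s" points="%s"/>',
                          col, path))
    }
    el <- c(el, sprintf(
      '<circle cx="%.1f" cy="%.1f" r="4" fill="%s"><title>%s</title></circle>',
      sx(p$x), sy(p$y), col, .svg_escape(p$hover)))
  }
  ann <- spec$annotations
  if (!is.null(ann$left) && nrow(ann$left))
    el <- c(el, sprintf('<text x="4" y="%.1f" font-size="8">%s</text>',
                        sy(ann$left$date), .svg_escape(ann$left$release_id)))
  if (!is.null(ann$right) && nrow(ann$right))
    el <- c(el, sprintf('<text x="%d" y="%.1f" font-size="8">%s</text>',
                        width - pad + 6, sy(ann$right$date),
                        .svg_escape(ann$right$release_id)))
  c(el, "</svg>")
}

#' Render a chart spec to a file
#'
#' \code{"svg"} writes a standalone SVG whose points expose their metadata
#' as hover titles; \code{"html"} wraps the SVG and the canonical JSON spec
#' in a single self-contained page; \code{"png"} rasterises through the
#' \pkg{grDevices} png device.
#'
#' @param spec a \code{chart_spec}.
#' @param file output path.
#' @param format one of \code{"svg"}, \code{"html"}, \code{"png"}.
#' @param width,height image size in pixels.
#' @return \code{file}, invisibly.
#' @export
render_chart <- function(spec, file, format = c("svg", "html", "png"),
                         width = 720, height = 480) {
  format <- match.arg(format)
  if (format == "svg") {
    writeLines(chart_svg(spec, width, height), file)
  } else if (format == "html") {
    html <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
              sprintf("<title>%s</title></head><body>",
                      .svg_escape(substr(spec$title, 1, 90))),
              chart_svg(spec, width, height),
              "<script type='application/json' id='chart-spec'>",
              chart_json(spec),
              "</script></body></html>")
    writeLines(html, file)
  } else {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off())
    .plot_chart_base(spec)
  }
  invisible(file)
}

# base-graphics fallback used for raster output
.plot_chart_base <- function(spec) {
  all_pts <- do.call(rbind, lapply(spec$series, `[[`, "points"))
  xn <- if (!is.null(spec$x_axis$categories)) as.numeric(all_pts$x)
        else if (identical(spec$x_axis$type, "date")) as.numeric(as.Date(all_pts$x))
        else as.numeric(all_pts$x)
  yn <- if (identical(spec$y_axis$type, "date")) as.numeric(as.Date(all_pts$y))
        else as.numeric(all_pts$y)
  graphics::plot(range(xn), range(yn), type = "n",
                 xlab = spec$x_axis$label, ylab = spec$y_axis$label,
                 main = substr(spec$title, 1, 60))
  for (s in spec$series) {
    p <- s$points
    if (nrow(p) == 0L) next
    px <- if (!is.null(spec$x_axis$categories)) as.numeric(p$x)
          else if (identical(spec$x_axis$type, "date")) as.numeric(as.Date(p$x))
          else as.numeric(p$x)
    py <- if (identical(spec$y_axis$type, "date")) as.numeric(as.Date(p$y))
          else as.numeric(p$y)
    graphics::points(px, py, col = s$style$colour, pch = 19)
    if (spec$kind %in% c("TIMELINE", "STATS"))
      graphics::lines(px, py, col = s$style$colour)
  }
}
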